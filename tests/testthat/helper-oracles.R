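# Independent oracles, written from first principles and kept free of the
# package's scanning / testing code paths.

# --- naive degenerate-motif scanner --------------------------------------

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", N = "N")

oracle_revcomp <- function(pattern) {
  paste(rev(ORACLE_COMP[strsplit(pattern, "")[[1]]]), collapse = "")
}

# all 1-based starts where pattern matches exactly (sequence N matches nothing)
oracle_starts <- function(sequence, pattern) {
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  L <- length(p)
  if (length(s) < L) return(integer(0))
  hits <- integer(0)
  for (st in seq_len(length(s) - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(s[st + j - 1L] %in% ORACLE_IUPAC[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, st)
  }
  hits
}

oracle_greedy <- function(starts, L) {
  sel <- integer(0); last_end <- -1L
  for (st in sort(starts)) {
    if (st > last_end) { sel <- c(sel, st); last_end <- st + L - 1L }
  }
  sel
}

# mirrors the documented scan semantics: forward starts, reverse = RC-pattern
# starts minus palindromic duplicates, greedy non-overlap per strand
oracle_scan <- function(sequence, pattern, strand_mode = "both",
                        overlap = "allowed") {
  L <- nchar(pattern)
  fwd <- oracle_starts(sequence, pattern)
  rvs <- integer(0)
  if (strand_mode == "both") {
    rvs <- setdiff(oracle_starts(sequence, oracle_revcomp(pattern)), fwd)
  }
  if (overlap == "disallowed") {
    fwd <- oracle_greedy(fwd, L)
    rvs <- oracle_greedy(rvs, L)
  }
  data.frame(start = c(fwd, rvs) - 1L,
             strand = rep(c("+", "-"), c(length(fwd), length(rvs))))
}

# brute-force enumeration of all concrete strings matching a pattern
oracle_expand <- function(pattern) {
  p <- strsplit(pattern, "")[[1]]
  out <- ""
  for (code in p) out <- as.vector(outer(out, ORACLE_IUPAC[[code]], paste0))
  sort(out)
}

# random eligible IUPAC motif for fuzzing (degeneracy-light, like real TFBS)
random_motif <- function(max_len = 8L) {
  codes <- names(ORACLE_IUPAC)
  wt <- c(rep(10, 4), rep(1.5, 6), rep(0.5, 4), 0.5)
  repeat {
    L <- sample.int(max_len, 1L)
    pat <- paste(sample(codes, L, replace = TRUE, prob = wt), collapse = "")
    if (prod(lengths(ORACLE_IUPAC[strsplit(pat, "")[[1]]])) < 1000) return(pat)
  }
}

random_sequence <- function(max_len = 200L, n_prob = 0.02) {
  L <- sample.int(max_len, 1L)
  paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)), collapse = "")
}

# --- hypergeometric tail-sum oracle for the two-sided Fisher test ---------

oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b            # DE promoters
  n <- c + d            # non-DE promoters
  k <- a + c            # target promoters
  lo <- max(0L, k - n); hi <- min(k, m)
  logp <- vapply(lo:hi, function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }, numeric(1))
  p <- exp(logp)
  pobs <- p[a - lo + 1L]
  sum(p[p <= pobs * (1 + 1e-7)])   # two-sided: all tables as or less probable
}

# --- t-test oracles -------------------------------------------------------

oracle_welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(abs(tt), df, lower.tail = FALSE)
}

oracle_pooled_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(abs(tt), n1 + n2 - 2, lower.tail = FALSE)
}
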