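# byte -> base index lookup (A=1, C=2, G=3, T=4; anything else, incl. the
# ambiguity code N when it appears in a SEQUENCE, is 0 and matches no pattern
# position -- masked bases never inflate counts)
BASE_INDEX <- integer(128)
BASE_INDEX[utf8ToInt("A")] <- 1L
BASE_INDEX[utf8ToInt("C")] <- 2L
BASE_INDEX[utf8ToInt("G")] <- 3L
BASE_INDEX[utf8ToInt("T")] <- 4L

encode_seq <- function(sequence) {
  codes <- utf8ToInt(sequence)
  if (any(codes > 127L)) stopf("non-ASCII character in sequence")
  BASE_INDEX[codes]
}

# per-position allow table: list over pattern positions, each a logical[5]
# indexed by base index + 1 (slot 1 = non-ACGT sequence base, always FALSE)
allow_table <- function(pattern) {
  chars <- iupac_chars(pattern)
  lapply(chars, function(cc) {
    c(FALSE, c("A", "C", "G", "T") %in% IUPAC_SETS[[cc]])
  })
}

# 1-based starts of exact degenerate matches of `pattern` in encoded sequence
match_starts <- function(enc, pattern) {
  allow <- allow_table(pattern)
  L <- length(allow)
  npos <- length(enc) - L + 1L
  if (npos < 1L) return(integer(0))
  # candidate-position sieve: anchor at the most selective pattern position,
  # then filter surviving start positions one pattern position at a time
  # (survivors shrink geometrically, so later passes are cheap)
  ord <- order(vapply(allow, sum, numeric(1)))
  j0 <- ord[1]
  pos <- which(allow[[j0]][enc + 1L]) - (j0 - 1L)
  pos <- pos[pos >= 1L & pos <= npos]
  for (j in ord[-1]) {
    if (!length(pos)) break
    pos <- pos[allow[[j]][enc[pos + (j - 1L)] + 1L]]
  }
  sort(pos)
}

# greedy left-to-right selection of non-overlapping starts (width L)
greedy_nonoverlap <- function(starts, L) {
  if (length(starts) < 2L) return(starts)
  keep <- logical(length(starts))
  last_end <- -1L
  for (i in seq_along(starts)) {
    if (starts[i] > last_end) {
      keep[i] <- TRUE
      last_end <- starts[i] + L - 1L
    }
  }
  starts[keep]
}

#' Scan a sequence for exact matches of a degenerate motif
#'
#' Exact (no-mismatch) matching of an IUPAC degenerate pattern: a position
#' matches iff every sequence base lies in the base set of the aligned
#' pattern code.  An `N` in the sequence matches no pattern position.  In
#' `both`-strand mode the reverse complement of the pattern is additionally
#' scanned against the forward sequence and reported as strand `-`;
#' identical (start, end) intervals arising from palindromic patterns are
#' reported once (as `+`).  With `overlap = "disallowed"` matches are
#' selected greedily left-to-right per strand.
#'
#' @param sequence uppercase nucleotide string ({A,C,G,T,N})
#' @param motif an [iupac_motif()] or pattern string (must be eligible)
#' @param strand_mode `"both"` (default) or `"forward"`
#' @param overlap `"allowed"` (default; overlapping hits all reported) or
#'   `"disallowed"`
#' @param max_variants eligibility guard passed to [is_eligible()]
#' @return data.frame with 0-based half-open coordinates: `start`, `end`,
#'   `strand`, ordered by start then strand
#' @examples
#' scan_motif("ACGTACGT", "ACGT", strand_mode = "forward")
#' @export
scan_motif <- function(sequence, motif,
                       strand_mode = c("both", "forward"),
                       overlap = c("allowed", "disallowed"),
                       max_variants = 1000L) {
  strand_mode <- match.arg(strand_mode)
  overlap <- match.arg(overlap)
  pattern <- if (inherits(motif, "iupac_motif")) motif$pattern else toupper(motif)
  if (!is_eligible(pattern, max_variants))
    stopf("motif '%s' is ineligible (>= %d variants)", pattern, max_variants)
  enc <- encode_seq(toupper(sequence))
  L <- nchar(pattern)
  fwd <- match_starts(enc, pattern)
  rev <- integer(0)
  if (strand_mode == "both") {
    rev <- match_starts(enc, revcomp_iupac(pattern))
    rev <- setdiff(rev, fwd)   # palindromic duplicates collapse to '+'
  }
  if (overlap == "disallowed") {
    fwd <- greedy_nonoverlap(fwd, L)
    rev <- greedy_nonoverlap(rev, L)
  }
  out <- data.frame(
    start = c(fwd, rev) - 1L,
    end = c(fwd, rev) - 1L + L,
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Count motif occurrences across a promoter collection
#'
#' Applies [scan_motif()] semantics to every (promoter, motif) pair and
#' returns the occurrence-count matrix used for background statistics and
#' target calling.  All motifs must be eligible.  Internally the promoters
#' are scanned as one concatenated sequence with `N` spacers (N matches
#' nothing, and the spacer is wide enough that greedy non-overlap selection
#' cannot couple adjacent promoters), so counts are identical to
#' promoter-by-promoter scanning.
#'
#' @param promoters a `promoter_collection` (named character vector)
#' @param motifs a motif table ([motif_table()] data.frame) or character
#'   vector of patterns
#' @inheritParams scan_motif
#' @param return_matches if TRUE, also return the match-level table
#'   (gene_id, start, end, strand, motif; 0-based half-open, promoter
#'   coordinates)
#' @return integer matrix promoters x motifs with attributes `strand_mode`
#'   and `overlap` (and, if requested, a list with `counts` and `matches`)
#' @examples
#' p <- generate_promoters(sim_config(n_promoters = 5, seed = 1))
#' occ <- count_occurrences(p, c("CCAAT", "TTTSSCGC"))
#' occ
#' @export
count_occurrences <- function(promoters, motifs,
                              strand_mode = c("both", "forward"),
                              overlap = c("allowed", "disallowed"),
                              max_variants = 1000L,
                              return_matches = FALSE) {
  strand_mode <- match.arg(strand_mode)
  overlap <- match.arg(overlap)
  patterns <- if (is.data.frame(motifs)) motifs$pattern else as.character(motifs)
  patterns <- toupper(patterns)
  ids <- names(promoters)
  counts <- matrix(0L, nrow = length(promoters), ncol = length(patterns),
                   dimnames = list(ids, make.unique(patterns)))
  attr(counts, "strand_mode") <- strand_mode
  attr(counts, "overlap") <- overlap
  if (!length(patterns)) {
    return(if (return_matches)
      list(counts = counts, matches = empty_matches()) else counts)
  }
  bad <- patterns[!vapply(patterns, is_eligible, logical(1),
                          max_variants = max_variants)]
  if (length(bad))
    stopf("ineligible motif(s): %s", paste(unique(bad), collapse = ", "))

  lens <- nchar(promoters)
  maxL <- max(nchar(patterns))
  spacer <- strrep("N", maxL)
  concat <- paste(toupper(unclass(promoters)), collapse = spacer)
  enc <- encode_seq(concat)
  offsets <- cumsum(c(0L, lens[-length(lens)] + maxL))  # 0-based promoter starts
  match_list <- if (return_matches) vector("list", length(patterns))

  for (j in seq_along(patterns)) {
    pat <- patterns[j]
    L <- nchar(pat)
    fwd <- match_starts(enc, pat)
    rev <- integer(0)
    if (strand_mode == "both") {
      rev <- setdiff(match_starts(enc, revcomp_iupac(pat)), fwd)
    }
    if (overlap == "disallowed") {
      fwd <- greedy_nonoverlap(fwd, L)
      rev <- greedy_nonoverlap(rev, L)
    }
    starts <- c(fwd, rev)
    strands <- rep(c("+", "-"), c(length(fwd), length(rev)))
    prom <- findInterval(starts - 1L, offsets)       # 1..n promoter index
    tab <- tabulate(prom, nbins = length(promoters))
    counts[, j] <- counts[, j] + tab
    if (return_matches && length(starts)) {
      local_start <- starts - 1L - offsets[prom]
      match_list[[j]] <- data.frame(
        gene_id = ids[prom], start = local_start, end = local_start + L,
        strand = strands, motif = pat, stringsAsFactors = FALSE)
    }
  }
  if (return_matches) {
    matches <- if (length(m <- Filter(Negate(is.null), match_list)))
      do.call(rbind, m) else empty_matches()
    matches <- matches[order(matches$motif, matches$gene_id, matches$start), ,
                       drop = FALSE]
    rownames(matches) <- NULL
    return(list(counts = counts, matches = matches))
  }
  counts
}

empty_matches <- function() {
  data.frame(gene_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), motif = character(0),
             stringsAsFactors = FALSE)
}
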