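# IUPAC degenerate nucleotide codes: each letter denotes a set of concrete
# bases.  Degeneracy (set size) drives the variant-count eligibility filter.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Degenerate IUPAC motif
#'
#' A transcription-factor binding motif written in IUPAC degenerate code,
#' attached to the gene id of the transcription factor that recognises it.
#' The number of concrete A/C/G/T variants is derived on construction, along
#' with eligibility under the strict `< max_variants` filter used to keep
#' motif specificity bounded (default 1,000 variants).
#'
#' @param tf_gene_id gene identifier of the transcription factor
#' @param pattern motif string over IUPAC codes `ACGTRYSWKMBDHVN`
#' @param max_variants eligibility cut-off; a motif is eligible iff its
#'   variant count is strictly below this (default 1000)
#' @return an object of class `iupac_motif` with fields `tf_gene_id`,
#'   `pattern`, `variant_count`, `eligible`
#' @examples
#' m <- iupac_motif("E2F1", "TTTSSCGC")
#' m$variant_count  # 4: two S positions, 2 * 2
#' m$eligible
#' @export
iupac_motif <- function(tf_gene_id, pattern, max_variants = 1000L) {
  pattern <- toupper(as.character(pattern))
  m <- list(
    tf_gene_id = as.character(tf_gene_id),
    pattern = pattern,
    variant_count = variant_count(pattern),
    eligible = NA
  )
  m$eligible <- m$variant_count < max_variants
  class(m) <- "iupac_motif"
  m
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("IUPAC motif %s (TF %s): %d variants, %s\n",
              x$pattern, x$tf_gene_id, x$variant_count,
              if (x$eligible) "eligible" else "ineligible"))
  invisible(x)
}

#' Number of concrete variants of a degenerate motif
#'
#' Product over positions of the degeneracy of each IUPAC code
#' (A/C/G/T -> 1, two-base codes -> 2, three-base codes -> 3, N -> 4).
#' Equals the cardinality of [expand_variants()].
#'
#' @param pattern motif string over IUPAC codes
#' @return positive integer (numeric to allow counts beyond 2^31)
#' @examples
#' variant_count("ACGT")   # 1
#' variant_count("NN")     # 16
#' @export
variant_count <- function(pattern) {
  chars <- iupac_chars(pattern)
  prod(vapply(IUPAC_SETS[chars], length, integer(1)))
}

iupac_chars <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L)
    stopf("pattern must be a single nonempty string")
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad))
    stopf("invalid IUPAC code '%s' at position %d of pattern '%s'",
          chars[bad[1]], bad[1], pattern)
  chars
}

#' Eligibility of a motif under the variant-count filter
#'
#' Transcription factors are only scanned if their binding motif has strictly
#' fewer than `max_variants` concrete variants, so that highly degenerate
#' (uninformative) motifs are excluded.
#'
#' @param motif an [iupac_motif()] or a pattern string
#' @inheritParams iupac_motif
#' @return logical
#' @examples
#' is_eligible("NNNN")   # TRUE  (256 < 1000)
#' is_eligible("NNNNN")  # FALSE (1024 >= 1000)
#' @export
is_eligible <- function(motif, max_variants = 1000L) {
  vc <- if (inherits(motif, "iupac_motif")) motif$variant_count else variant_count(motif)
  vc < max_variants
}

#' Enumerate all concrete variants of an eligible motif
#'
#' Expands a degenerate pattern into the full set of concrete A/C/G/T strings
#' it matches.  Refuses ineligible motifs to guard against combinatorial
#' blow-up; the cardinality of the result always equals [variant_count()].
#'
#' @inheritParams is_eligible
#' @return character vector of concrete sequences
#' @examples
#' expand_variants("AR")  # "AA" "AG"
#' @export
expand_variants <- function(motif, max_variants = 1000L) {
  pattern <- if (inherits(motif, "iupac_motif")) motif$pattern else motif
  if (!is_eligible(pattern, max_variants))
    stopf("motif '%s' has %d variants (>= %d): refusing to expand",
          pattern, variant_count(pattern), max_variants)
  chars <- iupac_chars(pattern)
  grid <- expand.grid(rev(IUPAC_SETS[chars]),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(do.call(paste0, rev(grid)))
}

#' Reverse complement of an IUPAC pattern
#'
#' Complements degenerate codes set-wise (R <-> Y, B <-> V, ...) and reverses
#' the pattern, so scanning the result on the forward strand is equivalent to
#' scanning the original pattern on the reverse strand.
#'
#' @param pattern motif or sequence string over IUPAC codes
#' @return character string
#' @examples
#' revcomp_iupac("TTTSSCGC")
#' @export
revcomp_iupac <- function(pattern) {
  chars <- iupac_chars(pattern)
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Read a TF -> motif table
#'
#' TSV with columns `tf_gene_id` and `pattern`; rows become [iupac_motif()]
#' objects with the derived variant count and eligibility flag.
#'
#' @param path TSV path
#' @inheritParams iupac_motif
#' @return a data.frame with columns tf_gene_id, pattern, variant_count,
#'   eligible
#' @export
read_motif_table <- function(path, max_variants = 1000L) {
  df <- read_tsv_plain(path)
  if (!all(c("tf_gene_id", "pattern") %in% names(df)))
    stopf("motif table must have columns tf_gene_id and pattern")
  motif_table(df$tf_gene_id, df$pattern, max_variants)
}

#' Build a motif table from vectors
#'
#' @param tf_gene_id character vector of TF gene ids
#' @param pattern character vector of IUPAC patterns, same length
#' @inheritParams iupac_motif
#' @return data.frame with derived variant_count and eligible columns
#' @export
motif_table <- function(tf_gene_id, pattern, max_variants = 1000L) {
  stopifnot(length(tf_gene_id) == length(pattern))
  vc <- vapply(as.character(pattern), variant_count, numeric(1), USE.NAMES = FALSE)
  data.frame(
    tf_gene_id = as.character(tf_gene_id),
    pattern = toupper(as.character(pattern)),
    variant_count = vc,
    eligible = vc < max_variants,
    stringsAsFactors = FALSE
  )
}
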