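#' Background occurrence statistics per motif
#'
#' Sample mean and sample SD (n-1 denominator) of the per-promoter occurrence
#' count of each motif, over ALL promoters scanned.  These define the
#' mean +/- SD outlier thresholds used for candidate-target calling.
#'
#' @param occ occurrence matrix from [count_occurrences()] (promoters x motifs)
#' @return data.frame: motif, mean, sd, lower (mean - sd), upper (mean + sd)
#' @examples
#' occ <- matrix(c(0, 1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "ACGT"))
#' background_stats(occ)  # mean 2, sd sqrt(2.5)
#' @export
background_stats <- function(occ) {
  if (nrow(occ) < 2L)
    stopf("need >= 2 promoters: SD of occurrence counts is undefined")
  m <- colMeans(occ)
  s <- apply(occ, 2, stats::sd)
  data.frame(motif = colnames(occ), mean = unname(m), sd = unname(s),
             lower = unname(m - s), upper = unname(m + s),
             stringsAsFactors = FALSE)
}

#' Candidate target promoters by the mean +/- SD outlier rule
#'
#' A promoter is a candidate target of a motif iff its occurrence count is
#' strictly above mean + SD or strictly below mean - SD of that motif's
#' counts across all promoters.  Counts exactly at a threshold are not
#' candidates.
#'
#' @inheritParams background_stats
#' @param stats output of [background_stats()] on the same matrix
#' @return named list (one element per motif) of promoter id vectors
#' @export
candidate_targets <- function(occ, stats = background_stats(occ)) {
  if (!identical(stats$motif, colnames(occ)))
    stopf("stats do not match occurrence matrix columns")
  out <- lapply(seq_len(ncol(occ)), function(j) {
    x <- occ[, j]
    rownames(occ)[x > stats$upper[j] | x < stats$lower[j]]
  })
  names(out) <- colnames(occ)
  out
}

#' Correlate candidate-target expression with TF expression
#'
#' Pearson correlation between a transcription factor's expression profile
#' and each candidate gene's profile.  A candidate counts as a correlated
#' target iff |r| >= `threshold` — anti-correlation counts, since repressor
#' targets move opposite to the repressor.  With the study's nine samples
#' (three PD levels x three replicates) this is a screening heuristic, not an
#' inference procedure.
#'
#' @param mat log2 expression matrix (genes x samples)
#' @param samples sample sheet (used only in `mode = "group_mean"`)
#' @param tf_gene gene id of the transcription factor; must be in `mat`
#' @param candidates candidate gene ids (absent ones are skipped with a
#'   warning count in the result)
#' @param threshold absolute-correlation cut-off (default 0.8)
#' @param mode `"replicate"` (default; correlate across all samples) or
#'   `"group_mean"` (correlate across per-group means)
#' @return list: n_correlated, correlated (ids), r (named vector over scored
#'   candidates), n_skipped
#' @export
correlate_tf_targets <- function(mat, samples, tf_gene, candidates,
                                 threshold = 0.8,
                                 mode = c("replicate", "group_mean")) {
  mode <- match.arg(mode)
  if (!tf_gene %in% rownames(mat))
    stopf("TF gene '%s' absent from expression matrix", tf_gene)
  candidates <- setdiff(unique(candidates), tf_gene)
  present <- intersect(candidates, rownames(mat))
  n_skipped <- length(candidates) - length(present)
  if (mode == "group_mean") {
    idx <- match(colnames(mat), samples$sample_id)
    grp <- samples$group[idx]
    mat <- t(apply(mat, 1, function(v) tapply(v, grp, mean)[unique(grp)]))
  }
  if (!length(present)) {
    return(list(n_correlated = 0L, correlated = character(0),
                r = numeric(0), n_skipped = n_skipped))
  }
  tfv <- mat[tf_gene, ]
  r <- if (stats::sd(tfv) == 0) {
    stats::setNames(rep(NA_real_, length(present)), present)
  } else {
    suppressWarnings(drop(stats::cor(tfv, t(mat[present, , drop = FALSE]))))[present]
  }
  hit <- !is.na(r) & abs(r) >= threshold
  list(n_correlated = sum(hit), correlated = present[hit], r = r,
       n_skipped = n_skipped)
}

#' Fisher-exact TFBS enrichment in DE promoters versus all promoters
#'
#' For each motif, cross-tabulates promoter membership in the motif's target
#' set against differential-expression status over the full promoter
#' universe: a = |DE and target|, b = |DE not target|, c = |target not DE|,
#' d = rest.  Reports the sample odds ratio (a*d)/(b*c) (Inf when b*c = 0 and
#' a*d > 0; 0 when a*d = 0), the two-sided Fisher exact p-value, BH-adjusted
#' q across motifs, and the call `enriched = (q < alpha) & (odds_ratio > 1)`.
#' With an empty DE set all p-values are 1 by convention.
#'
#' A permutation alternative (`method = "permutation"`) compares the mean
#' occurrence count of the motif in DE promoters against its null
#' distribution under `n_perm` seeded shuffles of the DE labels (one-sided,
#' add-one p-value); useful as a sensitivity analysis for the count-based
#' rather than membership-based reading of enrichment.
#'
#' @param targets named list of target promoter-id sets per motif (e.g. from
#'   [candidate_targets()], or any-site sets)
#' @param de_genes DE promoter ids; must be a subset of `universe`
#' @param universe all promoter ids scanned
#' @param alpha FDR threshold for the enrichment call (default 0.05)
#' @param method `"fisher"` (default) or `"permutation"`
#' @param occ occurrence matrix, required for `method = "permutation"`
#' @param n_perm permutation rounds (default 10000)
#' @param seed RNG seed for the permutation method
#' @return data.frame: motif, a, b, c, d, odds_ratio, p, q, enriched
#' @export
enrichment_test <- function(targets, de_genes, universe, alpha = 0.05,
                            method = c("fisher", "permutation"),
                            occ = NULL, n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (!length(universe)) stopf("empty promoter universe")
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe))
    stopf("de_genes must be a subset of the universe")
  n_de <- length(de_genes)

  rows <- lapply(names(targets), function(mot) {
    tgt <- intersect(unique(targets[[mot]]), universe)
    a <- length(intersect(de_genes, tgt))
    b <- n_de - a
    cc <- length(tgt) - a
    d <- length(universe) - n_de - cc
    or <- if (a * d == 0) 0
          else if (b * cc == 0) Inf
          else (a * d) / (b * cc)
    p <- if (n_de == 0L) 1 else
      stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    data.frame(motif = mot, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  if (method == "permutation") {
    if (is.null(occ)) stopf("permutation method requires the occurrence matrix")
    out$p <- permutation_pvalues(occ, de_genes, universe, n_perm, seed)[out$motif]
  }
  out$q <- adjust_fdr(out$p)
  out$enriched <- out$q < alpha & out$odds_ratio > 1
  rownames(out) <- NULL
  out
}

# one-sided permutation p: is the mean occurrence count in DE promoters
# higher than under random DE labels?
permutation_pvalues <- function(occ, de_genes, universe, n_perm, seed) {
  occ <- occ[intersect(universe, rownames(occ)), , drop = FALSE]
  de_idx <- rownames(occ) %in% de_genes
  k <- sum(de_idx)
  obs <- colMeans(occ[de_idx, , drop = FALSE])
  if (k == 0L) return(stats::setNames(rep(1, ncol(occ)), colnames(occ)))
  with_seed(seed, {
    exceed <- numeric(ncol(occ))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(nrow(occ), k)
      exceed <- exceed + (colMeans(occ[idx, , drop = FALSE]) >= obs)
    }
    stats::setNames((exceed + 1) / (n_perm + 1), colnames(occ))
  })
}

#' Rank transcription factors by correlated-target count
#'
#' Descending by `n_correlated`; ties broken by smaller enrichment p-value,
#' then lexicographically by TF gene id.  Ranks are a permutation of
#' 1..n rows.
#'
#' @param reports data.frame with columns `tf_gene_id`, `n_correlated`, and
#'   optionally `p` (enrichment p-value used for tie-breaking)
#' @return the same data.frame, ordered, with a `rank` column added
#' @export
rank_tfs <- function(reports) {
  p <- if ("p" %in% names(reports)) reports$p else rep(1, nrow(reports))
  ord <- order(-reports$n_correlated, p, reports$tf_gene_id)
  out <- reports[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
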