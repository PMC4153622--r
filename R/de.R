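#' Per-gene log2 fold change between two groups
#'
#' Mean log2 intensity in `group` minus mean in `reference`, per gene.  The
#' reference is the lowest-PD culture in the study design this mirrors.
#'
#' @param mat numeric genes x samples matrix on the log2 scale
#' @param samples data.frame with `sample_id` and `group` matching `colnames(mat)`
#' @param group,reference group labels to contrast
#' @return named numeric vector of log2 fold changes
#' @export
log2_fold_change <- function(mat, samples, group, reference) {
  a <- group_cols(mat, samples, group)
  b <- group_cols(mat, samples, reference)
  rowMeans(mat[, a, drop = FALSE]) - rowMeans(mat[, b, drop = FALSE])
}

group_cols <- function(mat, samples, group) {
  idx <- match(colnames(mat), samples$sample_id)
  if (anyNA(idx)) stopf("matrix columns missing from sample sheet")
  cols <- which(samples$group[idx] == group)
  if (!length(cols)) stopf("group '%s' has no samples", group)
  cols
}

#' Per-gene two-sample t-test between two groups
#'
#' Two-sided t-test per gene, vectorised over the matrix.  The default is
#' the pooled-variance Student t: with three replicates per group its null
#' p-values are exactly uniform under normality, whereas the Welch
#' approximation is noticeably conservative at such small n (its
#' Satterthwaite df estimate is noisy and bounded by the pooled df).
#' `welch = TRUE` selects the unequal-variance Welch form instead.
#' Degenerate conventions: if both groups have zero variance the p-value is
#' 1 when the means are equal and 0 when they differ.
#'
#' @inheritParams log2_fold_change
#' @param welch use the Welch unequal-variance form (default FALSE)
#' @return named numeric p-value vector in [0, 1]
#' @export
de_test <- function(mat, samples, group, reference, welch = FALSE) {
  a <- mat[, group_cols(mat, samples, group), drop = FALSE]
  b <- mat[, group_cols(mat, samples, reference), drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L) stopf("need >= 2 replicates on each side")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
  }
  p <- numeric(nrow(mat))
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  ok <- !zero
  tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- if (welch) {
    se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  } else n1 + n2 - 2
  p[ok] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  names(p) <- rownames(mat)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped to [0, 1] and order-preserving; thin
#' wrapper over `stats::p.adjust(method = "BH")` so the adjustment used by the
#' DE and enrichment stages is explicit and testable in one place.
#'
#' @param p numeric p-values in [0, 1]
#' @return q-values, same length and names
#' @export
adjust_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes at explicit thresholds
#'
#' A gene is DE iff its significance value is strictly below `alpha` AND its
#' log2 fold change is strictly below `-fc_thresh` or strictly above
#' `fc_thresh` (a log2FC of exactly 0.4 is NOT called).  Direction is the
#' sign of the fold change.
#'
#' @param log2fc named numeric log2 fold changes
#' @param p_or_q significance values aligned with `log2fc` (FDR-adjusted by
#'   default in [de_table()])
#' @param fc_thresh fold-change threshold in log2 units (default 0.4)
#' @param alpha significance threshold (default 0.05)
#' @return data.frame: gene_id, log2fc, sig, is_de, direction (up/down/none)
#' @export
call_de <- function(log2fc, p_or_q, fc_thresh = 0.4, alpha = 0.05) {
  if (length(log2fc) != length(p_or_q))
    stopf("log2fc and p_or_q must be aligned")
  if (!is.null(names(log2fc)) && !is.null(names(p_or_q)) &&
      !identical(names(log2fc), names(p_or_q)))
    stopf("gene sets of log2fc and p_or_q differ")
  is_de <- (p_or_q < alpha) & (log2fc < -fc_thresh | log2fc > fc_thresh)
  direction <- ifelse(!is_de, "none", ifelse(log2fc > 0, "up", "down"))
  data.frame(
    gene_id = if (is.null(names(log2fc))) seq_along(log2fc) else names(log2fc),
    log2fc = unname(log2fc), sig = unname(p_or_q),
    is_de = unname(is_de), direction = unname(direction),
    stringsAsFactors = FALSE
  )
}

#' Differential expression table for all contrasts against a reference
#'
#' Runs the full DE chain for every non-reference group: per-gene log2 fold
#' change, per-gene Welch t-test, BH adjustment within each contrast, and the
#' strict double-threshold call of [call_de()].
#'
#' @inheritParams log2_fold_change
#' @param reference reference group label (default first group in `samples`)
#' @inheritParams call_de
#' @param use_raw_p if TRUE, apply `alpha` to raw p-values instead of BH
#'   q-values (q-values are still reported)
#' @inheritParams de_test
#' @return data.frame: gene_id, contrast, log2fc, p, q, is_de, direction
#' @examples
#' sim <- generate_expression(sim_config(n_genes = 200, seed = 1))
#' de <- de_table(sim$matrix, sim$samples)
#' table(de$contrast, de$is_de)
#' @export
de_table <- function(mat, samples, reference = samples$group[1],
                     fc_thresh = 0.4, alpha = 0.05, use_raw_p = FALSE,
                     welch = FALSE) {
  groups <- setdiff(unique(samples$group), reference)
  if (!reference %in% samples$group)
    stopf("reference group '%s' not found", reference)
  res <- lapply(groups, function(g) {
    lfc <- log2_fold_change(mat, samples, g, reference)
    p <- de_test(mat, samples, g, reference, welch = welch)
    q <- adjust_fdr(p)
    called <- call_de(lfc, if (use_raw_p) p else q, fc_thresh, alpha)
    data.frame(gene_id = called$gene_id,
               contrast = paste0(g, "_vs_", reference),
               log2fc = called$log2fc, p = unname(p), q = unname(q),
               is_de = called$is_de, direction = called$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fraction of one DE set recovered in another
#'
#' |a intersect b| / |a|: the proportion of genes differentially expressed in
#' contrast `a` that are also differentially expressed in contrast `b` (used
#' in the study design to ask how much of the early-senescence DE set
#' persists at the later PD level).
#'
#' @param de_set_a,de_set_b character identifier sets; `de_set_a` nonempty
#' @return proportion in [0, 1]
#' @export
overlap_fraction <- function(de_set_a, de_set_b) {
  de_set_a <- unique(de_set_a)
  if (!length(de_set_a)) stopf("de_set_a is empty: overlap fraction undefined")
  length(intersect(de_set_a, de_set_b)) / length(de_set_a)
}
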