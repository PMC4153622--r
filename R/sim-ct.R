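#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Builds a Ct table emulating a relative-quantification experiment: per gene
#' and group the underlying quantity is `fold * base`, Ct = -log_E(quantity),
#' with an optional per-sample loading shift (in cycles, shared by all genes
#' of that sample — removed exactly by reference-gene normalization) and
#' Gaussian Ct noise.  Reference genes have fold 1 in every group by
#' construction.  Three biological and two technical replicates per group by
#' default, mirroring the usual qPCR design.
#'
#' @param true_fold_changes genes x groups numeric matrix of fold changes
#'   relative to the first (calibrator) group, dimnames required; or a named
#'   vector, interpreted as the second group's folds in a two-group design
#'   with groups `c("PD38", "PD54")`
#' @param reference_genes character ids of reference (housekeeping) genes;
#'   appended with fold 1 if absent from `true_fold_changes`
#' @param efficiencies amplification efficiency per gene in (1, 2]; single
#'   value recycled
#' @param noise_sd SD of Gaussian Ct noise in cycles
#' @param seed RNG seed
#' @param n_bio,n_tech biological / technical replicates per group
#' @param loading_sd SD (cycles) of the per-sample loading shift (default 0)
#' @param base_ct Ct of the calibrator-level quantity (default 20 cycles)
#' @return data.frame (class `ct_table`) with columns sample_id, group,
#'   gene_id, replicate_bio, replicate_tech, Ct, efficiency
#' @examples
#' ct <- generate_ct_table(c(SUV39H1 = 0.5), reference_genes = "HPRT1",
#'                         efficiencies = 2, noise_sd = 0, seed = 1)
#' head(ct)
#' @export
generate_ct_table <- function(true_fold_changes, reference_genes,
                              efficiencies = 2, noise_sd = 0, seed = 1L,
                              n_bio = 3L, n_tech = 2L,
                              loading_sd = 0, base_ct = 20) {
  if (is.null(dim(true_fold_changes))) {
    folds <- cbind(1, as.numeric(true_fold_changes))
    rownames(folds) <- names(true_fold_changes)
    colnames(folds) <- c("PD38", "PD54")
  } else folds <- as.matrix(true_fold_changes)
  if (is.null(rownames(folds)) || is.null(colnames(folds)))
    stopf("true_fold_changes needs gene and group names")
  if (any(folds <= 0)) stopf("fold changes must be positive")
  if (length(reference_genes) < 1L) stopf("need at least one reference gene")
  add <- setdiff(reference_genes, rownames(folds))
  if (length(add)) {
    folds <- rbind(folds, matrix(1, length(add), ncol(folds),
                                 dimnames = list(add, colnames(folds))))
  }
  folds[reference_genes, ] <- 1
  genes <- rownames(folds)
  groups <- colnames(folds)
  E <- rep_len(as.numeric(efficiencies), length(genes))
  names(E) <- genes
  if (any(E <= 1 | E > 2)) stopf("efficiencies must lie in (1, 2]")

  grid <- expand.grid(replicate_tech = seq_len(n_tech),
                      gene_id = genes,
                      replicate_bio = seq_len(n_bio),
                      group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$sample_id <- paste0(grid$group, "_b", grid$replicate_bio)

  ct <- with_seed(seed, {
    samples <- unique(grid$sample_id)
    loading <- stats::rnorm(length(samples), sd = loading_sd)
    names(loading) <- samples
    e <- E[grid$gene_id]
    q <- folds[cbind(grid$gene_id, grid$group)]
    ct0 <- base_ct - log(q) / log(e)    # quantity = E^(-Ct) up to loading
    ct0 + loading[grid$sample_id] + stats::rnorm(nrow(grid), sd = noise_sd)
  })

  out <- data.frame(sample_id = grid$sample_id, group = grid$group,
                    gene_id = grid$gene_id,
                    replicate_bio = grid$replicate_bio,
                    replicate_tech = grid$replicate_tech,
                    Ct = ct, efficiency = unname(E[grid$gene_id]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ct_table", "data.frame")
  out
}
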