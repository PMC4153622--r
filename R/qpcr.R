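#' Population-doubling increment of one subculture
#'
#' Delta PD = log2(n_f / n_i): the number of doublings a culture underwent
#' between inoculation (`n_i` cells) and harvest (`n_f` cells).  Negative if
#' the culture shrank.
#'
#' @param n_f final cell count (> 0)
#' @param n_i inoculated cell count (> 0)
#' @return population doublings (real)
#' @examples
#' delta_pd(1.6e6, 5e5)  # log2(3.2)
#' @export
delta_pd <- function(n_f, n_i) {
  if (any(n_f <= 0) || any(n_i <= 0)) stopf("cell counts must be positive")
  log2(n_f / n_i)
}

#' Cumulative population-doubling level of a culture
#'
#' Running sum of per-subculture Delta PD values starting from `initial_pd`
#' (e.g. the PD level at which a cell stock was obtained).  The last entry is
#' the culture's current PD level; by log2 additivity it depends only on the
#' total expansion, not on how subcultures were partitioned.
#'
#' @param log data.frame with columns `n_i` and `n_f` (one row per
#'   subculture, in temporal order); extra columns (passage labels) are kept
#' @param initial_pd starting PD level (default 0)
#' @return data.frame `log` with columns `delta_pd` and `pd` appended;
#'   zero-row input yields a zero-row table (the level stays `initial_pd`)
#' @examples
#' cumulative_pd(data.frame(n_i = c(1, 1, 1) * 1e5, n_f = c(4, 4, 4) * 1e5),
#'               initial_pd = 19)  # PD 21, 23, 25
#' @export
cumulative_pd <- function(log, initial_pd = 0) {
  stopifnot(is.data.frame(log), all(c("n_i", "n_f") %in% names(log)))
  d <- if (nrow(log)) delta_pd(log$n_f, log$n_i) else numeric(0)
  log$delta_pd <- d
  log$pd <- initial_pd + cumsum(d)
  attr(log, "initial_pd") <- initial_pd
  log
}

#' Efficiency-corrected relative quantity
#'
#' RQ = E^(Ct_calibrator - Ct_sample): the quantity of a transcript in a
#' sample relative to the calibrator condition, given amplification
#' efficiency E (2 = perfect doubling per cycle).
#'
#' @param ct_calibrator mean Ct of the calibrator condition
#' @param ct_sample Ct of the sample
#' @param E amplification efficiency in (1, 2]
#' @return dimensionless relative quantity
#' @examples
#' relative_quantity(20, 19, 2)  # 2
#' @export
relative_quantity <- function(ct_calibrator, ct_sample, E) {
  if (any(E <= 1 | E > 2)) stopf("efficiency must lie in (1, 2]")
  E^(ct_calibrator - ct_sample)
}

#' Multi-reference-gene qPCR normalization (NRQ)
#'
#' Normalized relative quantities in the multi-reference-gene model embodied
#' by standard qPCR analysis tools: technical replicates are averaged on the
#' Ct scale first; per gene and biological sample an efficiency-corrected
#' relative quantity RQ = E^(Ct_calibrator_mean - Ct) is computed; each
#' target's RQ is divided by the geometric mean of the reference genes' RQs
#' in the same sample (cancelling per-sample loading differences); finally
#' each gene is rescaled so the geometric mean NRQ of the calibrator group is
#' 1.  The reference-gene set is a required explicit argument: results depend
#' on it, so it is never defaulted.
#'
#' @param ct a `ct_table` (see [generate_ct_table()]) with columns sample_id,
#'   group, gene_id, replicate_tech, Ct, efficiency
#' @param targets target gene ids to report (default: all non-reference genes)
#' @param reference_genes reference (housekeeping) gene ids, measured in
#'   every sample
#' @param calibrator_group group label rescaled to mean 1 (default first
#'   group in the table)
#' @return data.frame: sample_id, group, gene_id, nrq, and per-(group, gene)
#'   summary columns mean_nrq and sd_nrq (SD across biological samples)
#' @examples
#' ct <- generate_ct_table(c(SUV39H1 = 2), reference_genes = "HPRT1",
#'                         efficiencies = 2, noise_sd = 0, seed = 1)
#' nrq <- normalize_nrq(ct, reference_genes = "HPRT1")
#' unique(nrq[, c("group", "gene_id", "mean_nrq")])
#' @export
normalize_nrq <- function(ct, targets = NULL, reference_genes,
                          calibrator_group = ct$group[1]) {
  stopifnot(is.data.frame(ct))
  if (missing(reference_genes) || !length(reference_genes))
    stopf("reference_genes must be given explicitly")
  if (!calibrator_group %in% ct$group)
    stopf("calibrator group '%s' not present", calibrator_group)

  # technical replicates averaged on the Ct scale before any exponentiation
  agg <- stats::aggregate(Ct ~ sample_id + group + gene_id + efficiency,
                          data = ct, FUN = mean)
  samples <- unique(agg$sample_id)
  for (rg in reference_genes) {
    has <- unique(agg$sample_id[agg$gene_id == rg])
    miss <- setdiff(samples, has)
    if (length(miss))
      stopf("reference gene '%s' missing in sample '%s'", rg, miss[1])
  }

  # RQ per (sample, gene) against the calibrator-group mean Ct of that gene
  cal <- agg[agg$group == calibrator_group, ]
  cal_ct <- tapply(cal$Ct, cal$gene_id, mean)
  agg <- agg[agg$gene_id %in% names(cal_ct), ]
  agg$rq <- as.numeric(relative_quantity(cal_ct[agg$gene_id], agg$Ct,
                                         agg$efficiency))

  # per-sample normalization factor: geometric mean of reference RQs
  ref <- agg[agg$gene_id %in% reference_genes, ]
  nf <- tapply(log(ref$rq), ref$sample_id, mean)
  agg$nrq <- agg$rq / as.vector(exp(nf[agg$sample_id]))

  # rescale so the calibrator group's geometric-mean NRQ is 1 per gene
  calnrq <- agg[agg$group == calibrator_group, ]
  scale <- exp(tapply(log(calnrq$nrq), calnrq$gene_id, mean))
  agg$nrq <- agg$nrq / as.vector(scale[agg$gene_id])

  if (is.null(targets)) targets <- setdiff(unique(agg$gene_id), reference_genes)
  out <- agg[agg$gene_id %in% c(targets, reference_genes),
             c("sample_id", "group", "gene_id", "nrq")]
  mu <- stats::aggregate(nrq ~ group + gene_id, data = out, FUN = mean)
  names(mu)[3] <- "mean_nrq"
  sdv <- stats::aggregate(nrq ~ group + gene_id, data = out, FUN = stats::sd)
  names(sdv)[3] <- "sd_nrq"
  out <- merge(merge(out, mu, by = c("group", "gene_id")), sdv,
               by = c("group", "gene_id"))
  out <- out[order(out$gene_id, out$group, out$sample_id),
             c("sample_id", "group", "gene_id", "nrq", "mean_nrq", "sd_nrq")]
  rownames(out) <- NULL
  out
}

#' Error progression of relative SDs
#'
#' Combines relative standard deviations of quantities that enter a product
#' or quotient by quadrature: sqrt(sum(rel_sd^2)).  Used to propagate
#' technical-replicate SDs through relative-quantification ratios.
#'
#' @param relative_sds numeric vector of relative SDs (each >= 0)
#' @return combined relative SD
#' @examples
#' propagate_sd(c(0.03, 0.04))  # 0.05
#' @export
propagate_sd <- function(relative_sds) {
  if (any(relative_sds < 0)) stopf("relative SDs must be >= 0")
  sqrt(sum(relative_sds^2))
}

#' ChIP-qPCR enrichment
#'
#' Two standard quantifications of chromatin-immunoprecipitation qPCR
#' signal:
#' \describe{
#'   \item{fold_over_control}{E^(Ct_control - Ct_IP), enrichment of the IP
#'     over a mock (IgG) control.}
#'   \item{percent_input}{100 * E^((Ct_input - log_E(dilution)) - Ct_IP):
#'     IP signal as a percentage of total input chromatin, where `ct_control`
#'     is the Ct of the diluted input aliquot and `input_dilution_factor` its
#'     dilution relative to the IP (100 for a 1 percent input).}
#' }
#'
#' @param ct_ip Ct of the immunoprecipitated sample
#' @param ct_control Ct of the IgG control (`fold_over_control`) or of the
#'   diluted input aliquot (`percent_input`)
#' @param E amplification efficiency in (1, 2]
#' @param mode `"fold_over_control"` (default) or `"percent_input"`
#' @param input_dilution_factor dilution of the input aliquot (default 100)
#' @return dimensionless enrichment (fold, or percent)
#' @examples
#' chip_enrichment(22, 25, 2)                      # 8-fold over IgG
#' chip_enrichment(26.64, 26.64, 2,
#'                 mode = "percent_input")         # 1% with default dilution
#' @export
chip_enrichment <- function(ct_ip, ct_control, E = 2,
                            mode = c("fold_over_control", "percent_input"),
                            input_dilution_factor = 100) {
  mode <- match.arg(mode)
  if (any(E <= 1 | E > 2)) stopf("efficiency must lie in (1, 2]")
  if (mode == "fold_over_control") {
    E^(ct_control - ct_ip)
  } else {
    ct_input_adj <- ct_control - log(input_dilution_factor) / log(E)
    100 * E^(ct_input_adj - ct_ip)
  }
}

#' Normalize band intensities to a loading control and a reference group
#'
#' Densitometry bookkeeping for immunoblots: target band intensity divided by
#' the loading-control intensity of the same lane, then rescaled by the mean
#' ratio of the reference-group lanes so that the reference group averages 1.
#'
#' @param intensity_target numeric band intensities of the protein of interest
#' @param intensity_loading_control matched loading-control intensities (> 0)
#' @param reference_ratios ratios (target/control) of the reference-group
#'   lanes; defaults to the input ratios themselves (self-normalization)
#' @return normalized ratios (reference-group mean 1)
#' @examples
#' normalize_band(c(1.2, 0.9, 1.5), c(1, 1, 1), reference_ratios = 1.2)
#' @export
normalize_band <- function(intensity_target, intensity_loading_control,
                           reference_ratios = NULL) {
  if (any(intensity_loading_control <= 0))
    stopf("loading-control intensity must be positive")
  ratio <- intensity_target / intensity_loading_control
  ref <- if (is.null(reference_ratios)) ratio else reference_ratios
  ratio / mean(ref)
}

#' Two-sample pooled-variance Student's t-test
#'
#' Classical two-tailed Student's t (equal-variance pooling), the group
#' comparison used for the wet-lab assays.  Degenerate conventions: with zero
#' pooled variance, p = 1 when the group means are equal and p = 0 otherwise.
#' Note the expression pipeline uses Welch's unequal-variance test instead
#' ([de_test()]); the two differ when group variances differ.
#'
#' @param sample_a,sample_b numeric vectors, each length >= 2
#' @return two-sided p-value
#' @examples
#' group_ttest(c(1, 2, 3), c(11, 12, 13))
#' @export
group_ttest <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stopf("need >= 2 values per group")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
    return(if (mean(sample_a) == mean(sample_b)) 1 else 0)
  stats::t.test(sample_a, sample_b, var.equal = TRUE)$p.value
}
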