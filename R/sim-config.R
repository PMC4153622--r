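#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module.  Defaults mirror the
#' design of the fibroblast senescence study this package models: three
#' population-doubling (PD) levels with three biological replicates each,
#' 1,000 bp upstream promoter windows, log2-scale array-like intensities.
#'
#' @param n_genes number of genes in the expression matrix
#' @param n_promoters number of promoter sequences (ids shared with the first
#'   `n_promoters` gene ids so expression and promoters join on `gene_id`)
#' @param promoter_length promoter window length in bases (default 1000)
#' @param groups ordered group labels; the first is the reference/calibrator
#' @param replicates_per_group biological replicates per group (default 3)
#' @param de_fraction proportion of genes with planted differential expression
#' @param effect_size absolute planted log2 fold change for true-DE genes
#' @param noise_sd SD of i.i.d. Gaussian noise on the log2 scale
#' @param gc_content promoter GC proportion in (0, 1)
#' @param plant_rate_target expected planted motif sites per targeted promoter
#' @param plant_rate_background expected planted sites per non-target promoter
#' @param seed integer RNG seed; identical configs give byte-identical output
#'
#' @return an object of class `sim_config` (a validated named list)
#' @examples
#' cfg <- sim_config(n_genes = 100, n_promoters = 50, seed = 1)
#' cfg$groups
#' @export
sim_config <- function(n_genes = 5000L,
                       n_promoters = 2000L,
                       promoter_length = 1000L,
                       groups = c("PD38", "PD47", "PD54"),
                       replicates_per_group = 3L,
                       de_fraction = 0.1,
                       effect_size = 1.0,
                       noise_sd = 0.25,
                       gc_content = 0.41,
                       plant_rate_target = 2,
                       plant_rate_background = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_promoters = as.integer(n_promoters),
    promoter_length = as.integer(promoter_length),
    groups = as.character(groups),
    replicates_per_group = as.integer(replicates_per_group),
    de_fraction = as.numeric(de_fraction),
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd),
    gc_content = as.numeric(gc_content),
    plant_rate_target = as.numeric(plant_rate_target),
    plant_rate_background = as.numeric(plant_rate_background),
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L || cfg$n_promoters < 1L || cfg$promoter_length < 1L)
    stopf("n_genes, n_promoters and promoter_length must be positive")
  if (length(cfg$groups) < 2L || anyDuplicated(cfg$groups))
    stopf("groups must be >= 2 distinct labels (first one is the reference)")
  if (cfg$replicates_per_group < 2L)
    stopf("replicates_per_group must be >= 2")
  if (is.na(cfg$de_fraction) || cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stopf("de_fraction must lie in [0, 1]")
  if (cfg$effect_size < 0) stopf("effect_size must be >= 0")
  if (cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (is.na(cfg$gc_content) || cfg$gc_content < 0 || cfg$gc_content > 1)
    stopf("gc_content must lie in [0, 1]")
  if (cfg$plant_rate_target < 0 || cfg$plant_rate_background < 0)
    stopf("plant rates must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config (", config_hash(x), ")\n", sep = "")
  cat(sprintf("  %d genes, %d promoters x %d bp (GC %.2f)\n",
              x$n_genes, x$n_promoters, x$promoter_length, x$gc_content))
  cat(sprintf("  groups: %s, %d replicates each\n",
              paste(x$groups, collapse = "/"), x$replicates_per_group))
  cat(sprintf("  DE fraction %.3f, effect %.2f log2, noise SD %.2f\n",
              x$de_fraction, x$effect_size, x$noise_sd))
  cat(sprintf("  plant rates: target %.2f, background %.2f; seed %d\n",
              x$plant_rate_target, x$plant_rate_background, x$seed))
  invisible(x)
}

# Shared gene-id scheme: promoters use the first n_promoters ids so the FASTA
# joins the expression matrix on gene_id.
gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# Count of true-DE genes: round-half-to-even (base R round), recorded exactly
# in the truth table and asserted in tests.
n_true_de <- function(cfg) as.integer(round(cfg$de_fraction * cfg$n_genes))
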