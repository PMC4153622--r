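#' Generate a synthetic log2 expression matrix with planted DE structure
#'
#' Emulates a summarized array experiment over ordered population-doubling
#' (PD) groups: per-gene baseline log2 intensities are drawn N(8, 2) (a
#' typical array log-intensity range), a fixed fraction of genes (the true-DE
#' set, `round(de_fraction * n_genes)` genes, round-half-to-even) receives a
#' +/- `effect_size` log2 shift in every non-reference group (one random sign
#' per gene, recorded), and i.i.d. N(0, noise_sd) noise is added to every
#' observation.
#'
#' @param cfg a [sim_config()]
#' @return list with
#'   \item{matrix}{numeric genes x samples matrix, log2 scale, dimnames set}
#'   \item{samples}{data.frame (sample_id, group, replicate)}
#'   \item{truth}{data.frame: gene_id, is_de, and one true_log2fc_<group>
#'     column per non-reference group}
#' @examples
#' sim <- generate_expression(sim_config(n_genes = 20, seed = 1))
#' dim(sim$matrix)
#' head(sim$truth)
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  groups <- cfg$groups
  reps <- cfg$replicates_per_group
  ids <- gene_ids(cfg$n_genes)
  n_de <- n_true_de(cfg)

  samples <- data.frame(
    sample_id = paste0(rep(groups, each = reps), "_r", seq_len(reps)),
    group = rep(groups, each = reps),
    replicate = rep(seq_len(reps), times = length(groups)),
    stringsAsFactors = FALSE
  )

  out <- with_seed(cfg$seed + 2L, {
    baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 2)
    de_idx <- if (n_de > 0L) sample.int(cfg$n_genes, n_de) else integer(0)
    sign <- integer(cfg$n_genes)
    sign[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    shift <- sign * cfg$effect_size

    mat <- matrix(0, nrow = cfg$n_genes, ncol = nrow(samples),
                  dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- baseline
      if (samples$group[j] != groups[1]) mu <- mu + shift
      mat[, j] <- mu + stats::rnorm(cfg$n_genes, sd = cfg$noise_sd)
    }
    list(mat = mat, de_idx = de_idx, shift = shift)
  })

  truth <- data.frame(gene_id = ids,
                      is_de = seq_len(cfg$n_genes) %in% out$de_idx,
                      stringsAsFactors = FALSE)
  for (g in groups[-1]) truth[[paste0("true_log2fc_", g)]] <- out$shift
  list(matrix = out$mat, samples = samples, truth = truth)
}

#' Write / read an expression matrix with its sample sheet
#'
#' TSV round-trip: the matrix file has `gene_id` as first column and sample
#' ids as header; the companion sample sheet maps sample_id to group and
#' replicate.  Both carry a `config_hash` header comment when `hash` is given.
#'
#' @param sim output of [generate_expression()] (or a list with `matrix` and
#'   `samples`)
#' @param matrix_path,samples_path output TSV paths
#' @param hash optional config hash to stamp into the headers
#' @return paths, invisibly
#' @export
write_expression <- function(sim, matrix_path, samples_path, hash = NULL) {
  df <- data.frame(gene_id = rownames(sim$matrix),
                   as.data.frame(sim$matrix, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_stamped(df, matrix_path, hash)
  write_tsv_stamped(sim$samples, samples_path, hash)
  invisible(c(matrix_path, samples_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(matrix_path, samples_path) {
  df <- read_tsv_plain(matrix_path)
  samples <- read_tsv_plain(samples_path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  storage.mode(mat) <- "double"
  if (anyNA(mat) || any(!is.finite(mat)))
    stopf("expression matrix contains missing or non-finite values")
  if (!setequal(colnames(mat), samples$sample_id))
    stopf("sample sheet does not match matrix columns")
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  list(matrix = mat, samples = samples)
}
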