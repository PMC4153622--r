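make_matrix <- function(values_by_group, reps = NULL) {
  # values_by_group: named list group -> genes x reps matrix (or vector)
  mats <- lapply(values_by_group, function(v) {
    if (is.null(dim(v))) matrix(v, nrow = 1) else v
  })
  samples <- data.frame(
    sample_id = unlist(lapply(names(mats), function(g)
      paste0(g, "_r", seq_len(ncol(mats[[g]]))))),
    group = rep(names(mats), vapply(mats, ncol, integer(1))),
    replicate = unlist(lapply(mats, function(m) seq_len(ncol(m)))),
    stringsAsFactors = FALSE
  )
  mat <- do.call(cbind, mats)
  colnames(mat) <- samples$sample_id
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  list(matrix = mat, samples = samples)
}

test_that("log2 fold change is the mean difference on the log2 scale", {
  d <- make_matrix(list(PD38 = c(4, 4, 4), PD47 = c(4, 4, 4)))
  expect_equal(unname(log2_fold_change(d$matrix, d$samples, "PD47", "PD38")), 0)
  d <- make_matrix(list(PD38 = c(8, 8, 8), PD47 = c(9, 9, 9)))
  expect_equal(unname(log2_fold_change(d$matrix, d$samples, "PD47", "PD38")), 1)
  d <- make_matrix(list(PD38 = c(8, 8, 8), PD47 = c(8.1, 8.5, 8.3)))
  expect_equal(unname(log2_fold_change(d$matrix, d$samples, "PD47", "PD38")),
               0.3, tolerance = 1e-12)
  # swapping group and reference negates exactly
  expect_identical(log2_fold_change(d$matrix, d$samples, "PD47", "PD38"),
                   -log2_fold_change(d$matrix, d$samples, "PD38", "PD47"))
  expect_error(log2_fold_change(d$matrix, d$samples, "PD99", "PD38"),
               "no samples")
})

test_that("per-gene t-test matches formula oracles and conventions", {
  d <- make_matrix(list(PD38 = c(8, 8.1, 7.9), PD47 = c(10, 10.1, 9.9)))
  p <- de_test(d$matrix, d$samples, "PD47", "PD38")
  expect_lt(p, 0.01)
  expect_equal(unname(p), oracle_pooled_p(c(10, 10.1, 9.9), c(8, 8.1, 7.9)),
               tolerance = 1e-12)
  expect_equal(unname(de_test(d$matrix, d$samples, "PD47", "PD38",
                              welch = TRUE)),
               oracle_welch_p(c(10, 10.1, 9.9), c(8, 8.1, 7.9)),
               tolerance = 1e-12)

  # identical samples on both sides: p = 1 by convention
  d <- make_matrix(list(PD38 = c(5, 5, 5), PD47 = c(5, 5, 5)))
  expect_identical(unname(de_test(d$matrix, d$samples, "PD47", "PD38")), 1)
  # zero variance, unequal means: p = 0 by convention
  d <- make_matrix(list(PD38 = c(5, 5, 5), PD47 = c(6, 6, 6)))
  expect_identical(unname(de_test(d$matrix, d$samples, "PD47", "PD38")), 0)
  # n = 2 vs 2, distinct values: p strictly inside (0, 1)
  d <- make_matrix(list(PD38 = c(1, 2), PD47 = c(4, 7)))
  p <- unname(de_test(d$matrix, d$samples, "PD47", "PD38"))
  expect_gt(p, 0); expect_lt(p, 1)

  # vectorised path equals per-gene stats::t.test on random data
  set.seed(21)
  d <- make_matrix(list(PD38 = matrix(rnorm(150), 50), PD47 = matrix(rnorm(150), 50)))
  p <- de_test(d$matrix, d$samples, "PD47", "PD38")
  pw <- de_test(d$matrix, d$samples, "PD47", "PD38", welch = TRUE)
  for (i in c(1, 17, 50)) {
    expect_equal(unname(p[i]),
                 t.test(d$matrix[i, 4:6], d$matrix[i, 1:3],
                        var.equal = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(unname(pw[i]),
                 t.test(d$matrix[i, 4:6], d$matrix[i, 1:3])$p.value,
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  q <- adjust_fdr(p)
  expect_true(all(q >= p))
  expect_false(is.unsorted(q[order(p)]))  # order-preserving step-up
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("DE calls apply strict double thresholds and directions", {
  lfc <- c(g1 = 0.4, g2 = -0.5, g3 = 2.0, g4 = 0.41, g5 = -0.2)
  q <- c(g1 = 0.001, g2 = 0.01, g3 = 0.2, g4 = 0.049, g5 = 0.001)
  res <- call_de(lfc, q)
  expect_identical(res$is_de, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(res$direction, c("none", "down", "none", "up", "none"))
  # boundary alpha is strict too
  expect_false(call_de(c(g = 1), c(g = 0.05))$is_de)
  # invariant to gene ordering
  perm <- c(3, 5, 1, 2, 4)
  res_p <- call_de(lfc[perm], q[perm])
  expect_identical(res_p$is_de[match(res$gene_id, res_p$gene_id)], res$is_de)
  expect_error(call_de(lfc, q[c(2, 1, 3, 4, 5)]), "differ")
})

test_that("null simulation is calibrated: ~5% of raw p-values below 0.05", {
  sim <- generate_expression(sim_config(n_genes = 5000, effect_size = 0,
                                        de_fraction = 0, seed = 101))
  p <- de_test(sim$matrix, sim$samples, "PD47", "PD38")
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 5000))
})

test_that("de_table assembles per-contrast calls consistent with its parts", {
  sim <- generate_expression(sim_config(n_genes = 300, noise_sd = 0.1,
                                        effect_size = 2, de_fraction = 0.2,
                                        seed = 14))
  de <- de_table(sim$matrix, sim$samples)
  expect_setequal(unique(de$contrast), c("PD47_vs_PD38", "PD54_vs_PD38"))
  d47 <- de[de$contrast == "PD47_vs_PD38", ]
  expect_equal(d47$log2fc,
               unname(log2_fold_change(sim$matrix, sim$samples, "PD47", "PD38")))
  expect_identical(d47$is_de,
                   (d47$q < 0.05) & (abs(d47$log2fc) > 0.4))
  expect_true(all(d47$q >= d47$p))
  # raw-p reading calls at least as many genes
  de_raw <- de_table(sim$matrix, sim$samples, use_raw_p = TRUE)
  expect_gte(sum(de_raw$is_de), sum(de$is_de))
})

test_that("overlap fraction is |a intersect b| / |a|", {
  a <- paste0("g", 1:5)
  expect_equal(overlap_fraction(a, c(paste0("g", 1:4), "g9")), 0.8)
  expect_equal(overlap_fraction(a, c(a, "g99")), 1.0)
  expect_equal(overlap_fraction(a, paste0("x", 1:5)), 0.0)
  expect_error(overlap_fraction(character(0), a), "empty")
})
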