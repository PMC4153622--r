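test_that("promoter generation honours length, base and GC contracts", {
  p <- generate_promoters(sim_config(n_promoters = 3, promoter_length = 1000,
                                     seed = 1))
  expect_length(p, 3L)
  expect_true(all(nchar(p) == 1000L))
  expect_false(anyDuplicated(names(p)) > 0)

  gc_only <- generate_promoters(sim_config(n_promoters = 2, gc_content = 1,
                                           promoter_length = 200, seed = 2))
  expect_true(all(grepl("^[GC]+$", gc_only)))

  # empirical GC within 3 binomial SDs of the target
  cfg <- sim_config(n_promoters = 2000, gc_content = 0.4, seed = 7)
  p <- generate_promoters(cfg)
  n_bases <- sum(nchar(p))
  gc_frac <- sum(nchar(gsub("[AT]", "", paste(p, collapse = "")))) / n_bases
  se <- sqrt(0.4 * 0.6 / n_bases)
  expect_lt(abs(gc_frac - 0.4), 3 * se)

  expect_error(sim_config(n_promoters = 0), "positive")
})

test_that("identical configs give byte-identical outputs", {
  cfg <- sim_config(n_genes = 50, n_promoters = 20, promoter_length = 100,
                    seed = 33)
  expect_identical(generate_promoters(cfg), generate_promoters(cfg))
  expect_identical(generate_expression(cfg), generate_expression(cfg))
  f1 <- tempfile(); f2 <- tempfile()
  write_promoters(generate_promoters(cfg), f1)
  write_promoters(generate_promoters(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("motif planting writes findable sites and exact truth counts", {
  cfg0 <- sim_config(n_promoters = 10, promoter_length = 200,
                     plant_rate_target = 0, plant_rate_background = 0,
                     seed = 4)
  p <- generate_promoters(cfg0)
  pl <- plant_motif(p, iupac_motif("TF", "ACGT"), names(p)[1:5], cfg0)
  expect_identical(unclass(pl$promoters), unclass(p))  # zero rate: unchanged
  expect_true(all(pl$planted == 0L))

  # planted sites are findable (>= because of chance background matches)
  cfg <- sim_config(n_promoters = 50, promoter_length = 1000,
                    plant_rate_target = 2, plant_rate_background = 0,
                    seed = 8)
  p <- generate_promoters(cfg)
  pl <- plant_motif(p, iupac_motif("TF", "ACGT"), names(p), cfg)
  occ <- count_occurrences(pl$promoters, "ACGT", strand_mode = "forward")
  expect_true(all(occ[, 1] >= pl$planted))
  expect_true(all(nchar(pl$promoters) == nchar(p)))  # length preserved

  # Poisson total: 100 targets at rate 3 within 3 Poisson SDs of 300
  cfg <- sim_config(n_promoters = 100, promoter_length = 1000,
                    plant_rate_target = 3, plant_rate_background = 0,
                    seed = 12)
  p <- generate_promoters(cfg)
  pl <- plant_motif(p, iupac_motif("TF", "TGACGTCA"), names(p), cfg)
  expect_lt(abs(sum(pl$planted) - 300), 3 * sqrt(300))

  expect_error(plant_motif(p, iupac_motif("TF", strrep("A", 1000)),
                           names(p), cfg), "smaller")
  expect_error(plant_motif(p, iupac_motif("TF", "ACGT"), "nope", cfg),
               "subset")
})

test_that("expression simulation plants the recorded DE structure", {
  # effect 0: truth has no fold changes
  sim0 <- generate_expression(sim_config(n_genes = 50, effect_size = 0,
                                         seed = 3))
  expect_true(all(sim0$truth$true_log2fc_PD47 == 0))

  # noiseless limit: sample log2FC equals the recorded truth exactly
  sim <- generate_expression(sim_config(n_genes = 100, noise_sd = 0,
                                        effect_size = 1, de_fraction = 0.2,
                                        seed = 5))
  lfc <- log2_fold_change(sim$matrix, sim$samples, "PD54", "PD38")
  expect_equal(unname(lfc), sim$truth$true_log2fc_PD54, tolerance = 1e-12)
  expect_setequal(unique(abs(sim$truth$true_log2fc_PD54)), c(0, 1))

  # exact true-DE count under the round-half-to-even rule
  sim <- generate_expression(sim_config(n_genes = 5000, de_fraction = 0.1,
                                        seed = 6))
  expect_identical(sum(sim$truth$is_de), 500L)
  expect_identical(nrow(sim$truth), 5000L)  # one truth record per gene
  expect_identical(
    sum(generate_expression(sim_config(n_genes = 10, de_fraction = 0.25,
                                       seed = 1))$truth$is_de), 2L)
  expect_identical(
    sum(generate_expression(sim_config(n_genes = 14, de_fraction = 0.25,
                                       seed = 1))$truth$is_de), 4L)

  expect_error(sim_config(de_fraction = 1.2), "de_fraction")
})

test_that("Ct table generation inverts the efficiency model", {
  # fold 2 at E = 2, no noise: test-group Ct exactly one cycle lower
  ct <- generate_ct_table(c(tg = 2), reference_genes = "ref",
                         efficiencies = 2, noise_sd = 0, seed = 1)
  m <- tapply(ct$Ct[ct$gene_id == "tg"], ct$group[ct$gene_id == "tg"], mean)
  expect_equal(unname(m["PD38"] - m["PD54"]), 1, tolerance = 1e-12)

  # closed form: delta Ct = log(fold)/log(E)
  ct <- generate_ct_table(c(tg = 1.5), reference_genes = "ref",
                         efficiencies = 1.9, noise_sd = 0, seed = 1)
  m <- tapply(ct$Ct[ct$gene_id == "tg"], ct$group[ct$gene_id == "tg"], mean)
  expect_equal(unname(m["PD38"] - m["PD54"]), log(1.5) / log(1.9),
               tolerance = 1e-12)

  # all folds 1, no noise: downstream NRQ identically 1
  ct <- generate_ct_table(c(a = 1, b = 1), reference_genes = c("r1", "r2"),
                         efficiencies = 2, noise_sd = 0, seed = 2)
  nrq <- normalize_nrq(ct, reference_genes = c("r1", "r2"))
  expect_equal(nrq$nrq, rep(1, nrow(nrq)), tolerance = 1e-12)

  expect_error(generate_ct_table(c(tg = -1), reference_genes = "ref"),
               "positive")
  expect_error(generate_ct_table(c(tg = 2), reference_genes = "ref",
                                 efficiencies = 2.5), "1, 2")
})
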