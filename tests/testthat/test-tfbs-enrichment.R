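toy_occ <- function(counts, motif = "ACGT") {
  matrix(counts, ncol = 1,
         dimnames = list(paste0("p", seq_along(counts)), motif))
}

test_that("background stats are the sample mean and n-1 SD per motif", {
  bg <- background_stats(toy_occ(0:4))
  expect_equal(bg$mean, 2)
  expect_equal(bg$sd, sqrt(2.5))
  expect_equal(bg$upper, 2 + sqrt(2.5))
  bg <- background_stats(toy_occ(c(2, 2, 2)))
  expect_equal(bg$sd, 0)
  # permutation invariance
  occ <- toy_occ(c(5, 1, 3, 0, 2))
  expect_equal(background_stats(occ)[, -1],
               background_stats(occ[c(4, 2, 5, 1, 3), , drop = FALSE])[, -1])
  expect_error(background_stats(toy_occ(3)), "undefined")
})

test_that("candidate targets use the strict mean +/- SD outlier rule", {
  occ <- toy_occ(0:4)
  expect_setequal(candidate_targets(occ)[["ACGT"]], c("p1", "p5"))
  # constant counts: SD 0, thresholds at the mean, strict -> empty
  expect_length(candidate_targets(toy_occ(c(2, 2, 2)))[["ACGT"]], 0L)
  # counts exactly at mean +/- SD are not candidates
  occ <- toy_occ(c(1, 2, 3))       # mean 2, sd 1: thresholds 1 and 3
  expect_length(candidate_targets(occ)[["ACGT"]], 0L)
})

test_that("TF-target correlation counts |r| above threshold, both signs", {
  mat <- rbind(tf = 1:9,
               same = 1:9,
               anti = 10 - (1:9),
               flat = c(5, 5, 5, 5, 5, 5, 5, 5, 4.9),
               noise = c(2, 9, 4, 7, 1, 8, 3, 6, 5))
  samples <- data.frame(sample_id = paste0("s", 1:9),
                        group = rep(c("PD38", "PD47", "PD54"), each = 3),
                        replicate = rep(1:3, 3))
  colnames(mat) <- samples$sample_id
  res <- correlate_tf_targets(mat, samples, "tf",
                              c("same", "anti", "flat", "noise", "missing"))
  expect_equal(unname(res$r["same"]), 1)
  expect_equal(unname(res$r["anti"]), -1)
  expect_identical(res$n_skipped, 1L)
  expect_setequal(res$correlated, c("same", "anti"))
  expect_identical(res$n_correlated, 2L)
  expect_error(correlate_tf_targets(mat, samples, "absent", "same"), "absent")

  # group-mean mode collapses replicates before correlating
  res_gm <- correlate_tf_targets(mat, samples, "tf", "same", mode = "group_mean")
  expect_equal(unname(res_gm$r["same"]), 1)
})

test_that("TF ranking sorts by correlated targets with documented ties", {
  rep_df <- data.frame(tf_gene_id = c("TFC", "TFA", "TFB", "TFD"),
                       n_correlated = c(3, 5, 3, 1),
                       p = c(0.2, 0.9, 0.1, 0.5))
  r <- rank_tfs(rep_df)
  expect_identical(r$tf_gene_id, c("TFA", "TFB", "TFC", "TFD"))
  expect_identical(r$rank, 1:4)
  # tie on n_correlated and p: lexicographic id
  rep_df$p <- 0.5
  r <- rank_tfs(rep_df)
  expect_identical(r$tf_gene_id[2:3], c("TFB", "TFC"))
  expect_identical(rank_tfs(rep_df[1, , drop = FALSE])$rank, 1L)
  # invariant to input order
  r2 <- rank_tfs(rep_df[c(3, 1, 4, 2), ])
  expect_identical(r2$tf_gene_id, r$tf_gene_id)
})

test_that("Fisher enrichment builds conserved tables and sane odds ratios", {
  universe <- paste0("p", 1:550)
  de <- paste0("p", 1:50)
  # proportional table: 5/45 DE vs 50/450 non-DE -> OR 1, p 1
  tgt <- list(m1 = c(paste0("p", 1:5), paste0("p", 51:100)),
              m2 = paste0("p", 1:10),           # DE-heavy
              m3 = paste0("p", 101:140))        # disjoint from DE: a = 0
  res <- enrichment_test(tgt, de, universe)
  expect_equal(res$odds_ratio[1], 1)
  expect_equal(res$p[1], 1, tolerance = 1e-12)
  expect_identical(res$a[3], 0L)
  expect_equal(res$odds_ratio[3], 0)
  expect_false(res$enriched[3])
  # margins conserved: a+b = |DE|, c+d = |universe| - |DE| for every motif
  expect_true(all(res$a + res$b == 50L))
  expect_true(all(res$c + res$d == 500L))

  # derived table cross-checked against the hypergeometric tail-sum oracle
  expect_equal(
    enrichment_test(list(m = c(paste0("d", 1:10), paste0("n", 1:10))),
                    de_genes = paste0("d", 1:50),
                    universe = c(paste0("d", 1:50), paste0("n", 1:450)))$p,
    oracle_fisher_p(10, 40, 10, 440), tolerance = 1e-12)

  # conventions and errors
  expect_equal(enrichment_test(tgt, character(0), universe)$p, rep(1, 3))
  expect_error(enrichment_test(tgt, de, character(0)), "empty")
  expect_error(enrichment_test(tgt, c(de, "zz"), universe), "subset")
})

test_that("Fisher p equals the oracle on random small tables", {
  set.seed(31)
  for (i in 1:100) {
    a <- sample(0:20, 1); b <- sample(0:20, 1)
    cc <- sample(0:20, 1); d <- sample(0:20, 1)
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    expect_equal(fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value,
                 oracle_fisher_p(a, b, cc, d), tolerance = 1e-9,
                 info = paste(a, b, cc, d))
  }
})

test_that("permutation enrichment flags a planted count excess", {
  set.seed(17)
  occ <- toy_occ(c(rpois(50, 5), rpois(450, 0.5)), motif = "m")
  de <- paste0("p", 1:50)
  res <- enrichment_test(list(m = paste0("p", 1:50)), de, rownames(occ),
                         method = "permutation", occ = occ, n_perm = 500,
                         seed = 5)
  expect_lt(res$p, 0.01)
  # null labels: permutation p is not extreme
  res0 <- enrichment_test(list(m = paste0("p", 1:50)),
                          sample(rownames(occ), 50), rownames(occ),
                          method = "permutation", occ = occ, n_perm = 500,
                          seed = 5)
  expect_gt(res0$p, 0.01)
})

test_that("candidate calling is idempotent under promoter permutation", {
  cfg <- sim_config(n_promoters = 100, promoter_length = 500, seed = 19)
  p <- generate_promoters(cfg)
  occ <- count_occurrences(p, c("CCAAT", "CANNTG"))
  cand <- candidate_targets(occ)
  perm <- sample(nrow(occ))
  cand_p <- candidate_targets(occ[perm, , drop = FALSE])
  for (m in names(cand)) expect_setequal(cand[[m]], cand_p[[m]])
})
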