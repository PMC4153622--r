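# Pool of realistic degenerate binding motifs (IUPAC), in the style of
# core promoter-binding TF families (E2F-, NF-Y-, SP1-, AP-1-, CREB-like,
# etc.).  Used when a run does not supply its own TF -> motif table; TF gene
# ids are drawn from the simulated genes.
MOTIF_POOL <- c(
  "TTTSSCGC",   # E2F-like
  "CCAAT",      # NF-Y-like CCAAT box
  "GGGCGG",     # SP1-like GC box
  "TGASTCA",    # AP-1-like TPA response element
  "TGACGTCA",   # CREB-like CRE
  "CACGTG",     # MYC-like E box
  "GGGRNYYYCC", # NF-kB-like
  "RRRCWWGYYY", # p53-like half site
  "CCWWWWWWGG", # SRF-like CArG box
  "GGAWR",      # ETS-like core
  "TTGCGCAA",   # C/EBP-like
  "RTAAAYA",    # forkhead-like
  "WGATAR",     # GATA-like
  "CANNTG",     # bHLH E-box, degenerate core
  "TAATKR",     # homeodomain-like
  "GGGGTCAAAG", # NFAT-like
  "TTCYNRGAA",  # STAT-like
  "RCGCANGCGY", # NRF1-like
  "YYANWTT",    # TATA-adjacent AT-rich
  "SCGGAAGY"    # ELK/ETS-like
)

#' Generate a synthetic TF -> motif table
#'
#' Assigns degenerate binding motifs from a built-in pool of realistic
#' TF-family-style patterns to transcription-factor gene ids sampled from the
#' simulated genes, so the scan stage can join TF expression to motifs.
#'
#' @param cfg a [sim_config()] (supplies gene ids and the seed)
#' @param n_tfs number of TF rows (default 15; patterns recycle beyond the
#'   pool size)
#' @param tf_gene_id optional explicit TF gene ids (overrides sampling)
#' @return a [motif_table()] data.frame
#' @export
make_tf_motifs <- function(cfg, n_tfs = 15L, tf_gene_id = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(tf_gene_id)) {
    tf_gene_id <- with_seed(cfg$seed + 3L,
      sample(gene_ids(cfg$n_genes), n_tfs))
  }
  pats <- rep_len(MOTIF_POOL, length(tf_gene_id))
  motif_table(tf_gene_id, pats)
}

#' Run the full senescence TFBS pipeline on synthetic data
#'
#' Executes the stages in study order: simulate inputs (promoters,
#' expression, TF motifs), call differential expression per non-reference PD
#' group, keep the motifs of differentially expressed TFs that pass the
#' variant-count eligibility filter, count motif occurrences over all
#' promoters, call candidate targets by the mean +/- SD outlier rule,
#' correlate candidate-target expression with TF expression, rank TFs by
#' correlated-target count, and test TFBS enrichment in DE promoters versus
#' all promoters.  All tables are written to `out_dir` stamped with the
#' config hash; `summary.json` records the counts at every filter step.
#'
#' @param cfg a [sim_config()]
#' @param out_dir output directory (created if needed)
#' @param motifs optional [motif_table()]; default [make_tf_motifs()]
#' @param n_tfs TF count for the default motif table
#' @param fc_thresh,alpha,use_raw_p DE thresholds, see [de_table()]
#' @param corr_threshold,corr_mode correlation settings, see
#'   [correlate_tf_targets()]
#' @param strand_mode,overlap,max_variants scan settings, see [scan_motif()]
#' @param enrich_method,n_perm enrichment settings, see [enrichment_test()]
#' @param target_mode `"candidates"` (mean +/- SD outlier sets; the study's
#'   pipeline order) or `"any_site"` (promoters with >= 1 match)
#' @param restrict_to_de_tfs scan only motifs of DE transcription factors
#'   (default TRUE, the study's order of operations)
#' @return invisibly, a list: `summary` (the summary.json content), `de`,
#'   `occ`, `report` (ranked enrichment table), `paths`
#' @examples
#' \donttest{
#' run <- run_pipeline(sim_config(n_genes = 300, n_promoters = 200, seed = 42),
#'                     out_dir = tempfile("senotf_run_"))
#' run$summary$counts
#' }
#' @export
run_pipeline <- function(cfg, out_dir,
                         motifs = NULL, n_tfs = 15L,
                         fc_thresh = 0.4, alpha = 0.05, use_raw_p = FALSE,
                         corr_threshold = 0.8,
                         corr_mode = c("replicate", "group_mean"),
                         strand_mode = c("both", "forward"),
                         overlap = c("allowed", "disallowed"),
                         max_variants = 1000L,
                         enrich_method = c("fisher", "permutation"),
                         n_perm = 10000L,
                         target_mode = c("candidates", "any_site"),
                         restrict_to_de_tfs = TRUE) {
  corr_mode <- match.arg(corr_mode)
  strand_mode <- match.arg(strand_mode)
  overlap <- match.arg(overlap)
  enrich_method <- match.arg(enrich_method)
  target_mode <- match.arg(target_mode)
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  settings <- list(cfg = unclass(cfg), n_tfs = n_tfs, fc_thresh = fc_thresh,
                   alpha = alpha, use_raw_p = use_raw_p,
                   corr_threshold = corr_threshold, corr_mode = corr_mode,
                   strand_mode = strand_mode, overlap = overlap,
                   max_variants = max_variants, enrich_method = enrich_method,
                   target_mode = target_mode,
                   restrict_to_de_tfs = restrict_to_de_tfs)
  hash <- config_hash(settings)
  yaml::write_yaml(c(settings, list(config_hash = hash)),
                   file.path(out_dir, "config.yaml"))

  # --- simulate -------------------------------------------------------------
  promoters <- generate_promoters(cfg)
  sim <- generate_expression(cfg)
  if (is.null(motifs)) motifs <- make_tf_motifs(cfg, n_tfs)
  write_promoters(promoters, file.path(out_dir, "promoters.fa"))
  write_expression(sim, file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "samples.tsv"), hash)
  write_tsv_stamped(sim$truth, file.path(out_dir, "truth.tsv"), hash)
  write_tsv_stamped(motifs, file.path(out_dir, "motifs.tsv"), hash)

  # --- differential expression ---------------------------------------------
  de <- de_table(sim$matrix, sim$samples, reference = cfg$groups[1],
                 fc_thresh = fc_thresh, alpha = alpha, use_raw_p = use_raw_p)
  write_tsv_stamped(de, file.path(out_dir, "de_table.tsv"), hash)
  de_sets <- split(de$gene_id[de$is_de], de$contrast[de$is_de])
  de_genes <- unique(de$gene_id[de$is_de])
  universe <- names(promoters)
  de_promoters <- intersect(de_genes, universe)

  # --- motif filter: DE TFs, then eligibility ------------------------------
  tf_de <- if (restrict_to_de_tfs) motifs$tf_gene_id %in% de_genes
           else rep(TRUE, nrow(motifs))
  kept <- motifs[tf_de & motifs$eligible, , drop = FALSE]

  counts <- list(
    n_genes = cfg$n_genes, n_promoters = length(universe),
    n_de = lapply(split(de$is_de, de$contrast), sum),
    n_de_union = length(de_genes), n_de_promoters = length(de_promoters),
    n_tfs_input = nrow(motifs), n_tfs_de = sum(tf_de),
    n_motifs_eligible = nrow(kept)
  )

  report <- data.frame(tf_gene_id = character(0), motif = character(0),
                       n_candidates = integer(0), n_correlated = integer(0),
                       a = integer(0), b = integer(0), c = integer(0),
                       d = integer(0), odds_ratio = numeric(0),
                       p = numeric(0), q = numeric(0),
                       enriched = logical(0), rank = integer(0),
                       stringsAsFactors = FALSE)
  occ <- NULL

  if (nrow(kept) > 0L && length(de_promoters) > 0L) {
    scan <- count_occurrences(promoters, kept, strand_mode = strand_mode,
                              overlap = overlap, max_variants = max_variants,
                              return_matches = TRUE)
    occ <- scan$counts
    occ_df <- data.frame(gene_id = rownames(occ),
                         as.data.frame(occ, check.names = FALSE),
                         check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_stamped(occ_df, file.path(out_dir, "occurrence_matrix.tsv"),
                      hash, meta = c(paste0("strand_mode=", strand_mode),
                                     paste0("overlap=", overlap)))
    write_tsv_stamped(scan$matches, file.path(out_dir, "matches.tsv"), hash)

    bg <- background_stats(occ)
    cand <- candidate_targets(occ, bg)
    targets <- if (target_mode == "candidates") cand
               else apply(occ > 0, 2, function(z) rownames(occ)[z],
                          simplify = FALSE)
    enr <- enrichment_test(targets, de_promoters, universe, alpha = alpha,
                           method = enrich_method, occ = occ,
                           n_perm = n_perm, seed = cfg$seed + 4L)
    corr <- vapply(seq_len(nrow(kept)), function(i) {
      correlate_tf_targets(sim$matrix, sim$samples, kept$tf_gene_id[i],
                           cand[[colnames(occ)[i]]],
                           threshold = corr_threshold,
                           mode = corr_mode)$n_correlated
    }, integer(1))
    report <- data.frame(tf_gene_id = kept$tf_gene_id,
                         motif = colnames(occ),
                         n_candidates = lengths(cand)[colnames(occ)],
                         n_correlated = corr,
                         stringsAsFactors = FALSE)
    report <- cbind(report, enr[match(report$motif, enr$motif),
                                c("a", "b", "c", "d", "odds_ratio",
                                  "p", "q", "enriched")])
    report <- rank_tfs(report)
  }
  write_tsv_stamped(report, file.path(out_dir, "enrichment_report.tsv"), hash)

  counts$n_candidates <- if (nrow(report)) {
    stats::setNames(as.list(report$n_candidates), report$motif)
  } else list()
  counts$n_enriched <- sum(report$enriched)

  summary <- list(
    config_hash = hash, settings = settings, counts = counts,
    top_tfs = if (nrow(report))
      utils::head(report[, c("rank", "tf_gene_id", "motif",
                             "n_correlated", "q", "enriched")], 5L)
      else list(),
    enriched_motifs = report$motif[report$enriched]
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  invisible(list(summary = summary, de = de, de_sets = de_sets, occ = occ,
                 report = report, truth = sim$truth,
                 paths = file.path(out_dir,
                   c("config.yaml", "promoters.fa", "expression.tsv",
                     "samples.tsv", "truth.tsv", "motifs.tsv", "de_table.tsv",
                     "enrichment_report.tsv", "summary.json"))))
}

#' Human-readable summary of a pipeline run directory
#'
#' Pure function of the run directory: reads `summary.json` and formats the
#' filter counts, the top-ranked TFs, and the enriched motifs (possibly
#' none) as markdown lines.
#'
#' @param run_dir directory written by [run_pipeline()]
#' @return character vector of report lines (also printed)
#' @export
pipeline_report <- function(run_dir) {
  path <- file.path(run_dir, "summary.json")
  if (!file.exists(path)) stopf("no summary.json in '%s'", run_dir)
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  cnt <- s$counts
  lines <- c(
    "# Senescence TFBS pipeline report",
    paste0("config hash: ", s$config_hash),
    "",
    "## Filter counts",
    sprintf("- genes: %d; promoters: %d", cnt$n_genes, cnt$n_promoters),
    vapply(names(cnt$n_de), function(k)
      sprintf("- DE genes (%s): %d", k, cnt$n_de[[k]]), character(1)),
    sprintf("- DE genes (union): %d; with promoters: %d",
            cnt$n_de_union, cnt$n_de_promoters),
    sprintf("- TF motifs in: %d; of DE TFs: %d; eligible: %d",
            cnt$n_tfs_input, cnt$n_tfs_de, cnt$n_motifs_eligible),
    sprintf("- motifs enriched in DE promoters (q < alpha): %d",
            cnt$n_enriched),
    ""
  )
  if (length(s$top_tfs) && NROW(s$top_tfs) > 0) {
    tt <- as.data.frame(s$top_tfs)
    lines <- c(lines, "## Top-ranked TFs (by correlated targets)",
               sprintf("- rank %d: %s (%s), %d correlated targets, q = %.3g%s",
                       tt$rank, tt$tf_gene_id, tt$motif, tt$n_correlated,
                       tt$q, ifelse(tt$enriched, " [enriched]", "")))
  } else {
    lines <- c(lines, "No motifs reached the enrichment stage.")
  }
  if (!length(s$enriched_motifs)) {
    lines <- c(lines, "", "Zero motifs enriched in DE promoters.")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
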