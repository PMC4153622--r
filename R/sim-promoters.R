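#' Generate synthetic promoter sequences
#'
#' Draws `n_promoters` i.i.d. sequences of `promoter_length` bases emulating
#' fixed-width upstream promoter windows (one record per gene).  Bases are
#' independent with P(G) = P(C) = gc_content/2 and P(A) = P(T) =
#' (1 - gc_content)/2.  Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()]
#' @return named character vector (class `promoter_collection`); names are
#'   gene ids shared with [generate_expression()]
#' @examples
#' p <- generate_promoters(sim_config(n_promoters = 3, seed = 1))
#' nchar(p)
#' @export
generate_promoters <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_promoters
  len <- cfg$promoter_length
  gc <- cfg$gc_content
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- with_seed(cfg$seed, {
    codes <- sample(utf8ToInt("ACGT"), n * len, replace = TRUE, prob = prob)
    big <- intToUtf8(codes)
    substring(big, (seq_len(n) - 1L) * len + 1L, seq_len(n) * len)
  })
  names(seqs) <- gene_ids(n)
  class(seqs) <- "promoter_collection"
  seqs
}

#' @export
print.promoter_collection <- function(x, ...) {
  cat(sprintf("Promoter collection: %d sequences, lengths %d..%d bp\n",
              length(x), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Plant motif occurrences into promoters
#'
#' Creates ground truth for the enrichment stage: each promoter receives a
#' Poisson-distributed number of concrete motif instances (rate
#' `plant_rate_target` for promoters in `target_ids`, `plant_rate_background`
#' otherwise), written at uniformly chosen non-overlapping positions on the
#' forward strand.  Each planted instance is an independently sampled concrete
#' variant of the degenerate pattern.  If a drawn count cannot be placed
#' without overlap the count is reduced and the actual number recorded.
#' Sequence lengths never change.  Chance background matches may add to the
#' planted count when scanning, so scans report `>=` the planted truth.
#'
#' @param promoters a `promoter_collection`
#' @param motif an [iupac_motif()] (eligibility is not required: variants are
#'   sampled lazily, never enumerated)
#' @param target_ids promoter ids to plant at the target rate
#' @param cfg a [sim_config()] supplying the rates and seed
#' @return list with `promoters` (modified collection) and `planted`
#'   (named integer vector of exact planted counts per promoter)
#' @export
plant_motif <- function(promoters, motif, target_ids, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!inherits(motif, "iupac_motif")) motif <- iupac_motif("TF", motif)
  ids <- names(promoters)
  if (!all(target_ids %in% ids))
    stopf("target_ids must be a subset of promoter ids")
  w <- nchar(motif$pattern)
  if (any(w >= nchar(promoters)))
    stopf("motif length must be smaller than every promoter length")
  chars <- iupac_chars(motif$pattern)
  sets <- IUPAC_SETS[chars]
  is_target <- ids %in% target_ids
  rate <- ifelse(is_target, cfg$plant_rate_target, cfg$plant_rate_background)

  out <- unclass(promoters)
  planted <- integer(length(ids))
  names(planted) <- ids
  # seed offset 1: keeps the planting stream distinct from promoter generation
  # under the same config seed
  with_seed(cfg$seed + 1L, {
    k_wanted <- stats::rpois(length(ids), rate)
    for (i in which(k_wanted > 0L)) {
      len <- nchar(out[i])
      starts <- integer(0)
      tries <- 0L
      while (length(starts) < k_wanted[i] && tries < 50L * k_wanted[i]) {
        cand <- sample.int(len - w + 1L, 1L)
        if (!any(abs(cand - starts) < w)) starts <- c(starts, cand)
        tries <- tries + 1L
      }
      if (length(starts)) {
        s <- out[i]
        for (st in starts) {
          inst <- paste(vapply(sets, function(b) b[sample.int(length(b), 1L)],
                               character(1)), collapse = "")
          substr(s, st, st + w - 1L) <- inst
        }
        out[i] <- s
      }
      planted[i] <- length(starts)
    }
  })
  class(out) <- "promoter_collection"
  list(promoters = out, planted = planted)
}

#' Write / read promoters as FASTA
#'
#' Standard FASTA I/O through Biostrings; record ids are gene ids (no
#' description), so promoter and expression data join on `gene_id`.
#'
#' @param promoters a `promoter_collection`
#' @param path FASTA file path
#' @return `write_promoters` the path, invisibly; `read_promoters` a
#'   `promoter_collection`
#' @export
write_promoters <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(unclass(promoters))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_promoters
#' @export
read_promoters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(seqs))) stopf("duplicate promoter ids in %s", path)
  if (any(nchar(seqs) == 0L)) stopf("empty promoter sequence in %s", path)
  class(seqs) <- "promoter_collection"
  seqs
}
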