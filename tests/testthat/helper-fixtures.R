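# Shared builders for tests. Fixtures are generated in code; the heavier
# simulated runs are memoised so several test files can share one run.

# A tfe_matrix from a bare count matrix (one chromosome, plus strand).
mk_tfe_matrix <- function(counts, stage = NULL, spikein = NULL) {
  n <- nrow(counts)
  if (is.null(spikein)) spikein <- rep(FALSE, n)
  regions <- data.frame(
    tfe_id = sprintf("TFE%05d", seq_len(n)), chrom = "chr1",
    start = seq_len(n) * 200, end = seq_len(n) * 200 + 10, strand = "+",
    summit = seq_len(n) * 200, count = as.integer(rowSums(counts)),
    is_spikein = spikein, stringsAsFactors = FALSE
  )
  if (is.null(stage)) stage <- rep("S1", ncol(counts))
  samples <- data.frame(sample_id = paste0("s", seq_len(ncol(counts))),
                        stage = stage, stringsAsFactors = FALSE)
  dimnames(counts) <- list(regions$tfe_id, samples$sample_id)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, regions = regions, samples = samples,
                 unassigned = 0L),
            class = "tfe_matrix")
}

mk_events <- function(pos, strand = "+", chrom = "chr1", umi = NULL,
                      sample_id = "s1", is_spikein = FALSE) {
  n <- length(pos)
  if (is.null(umi)) umi <- sprintf("UMI%04d", seq_len(n))
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             strand = rep_len(strand, n), umi = rep_len(umi, n),
             sample_id = rep_len(sample_id, n),
             is_spikein = rep_len(is_spikein, n), stringsAsFactors = FALSE)
}

# Independent brute-force single-linkage clustering: a cluster is a maximal
# set of positions chainable by pairwise gaps <= max_gap.
brute_force_tfes <- function(events, min_count, max_gap) {
  out <- list()
  for (g in unique(paste(events$chrom, events$strand))) {
    idx <- paste(events$chrom, events$strand) == g
    pos <- events$pos[idx]
    strand <- events$strand[idx][1]
    remaining <- seq_along(pos)
    while (length(remaining)) {
      in_cl <- remaining[1]
      repeat {
        outside <- setdiff(remaining, in_cl)
        grow <- outside[vapply(outside, function(i) {
          any(abs(pos[i] - pos[in_cl]) <= max_gap)
        }, logical(1))]
        if (!length(grow)) break
        in_cl <- c(in_cl, grow)
      }
      remaining <- setdiff(remaining, in_cl)
      cl <- sort(pos[in_cl])
      if (length(cl) >= min_count) {
        tab <- table(cl)
        modes <- as.numeric(names(tab)[tab == max(tab)])
        out[[length(out) + 1]] <- data.frame(
          chrom = events$chrom[idx][1], start = min(cl), end = max(cl) + 1,
          strand = strand,
          summit = if (strand == "+") min(modes) else max(modes),
          count = length(cl))
      }
    }
  }
  if (!length(out)) return(NULL)
  d <- do.call(rbind, out)
  d[order(d$chrom, d$start, d$strand), ]
}

# Memoised simulated runs shared across test files.
.fixture_env <- new.env(parent = emptyenv())

small_experiment <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(seed = 11, n_chromosomes = 2, chromosome_length = 4e5,
                      n_coding_genes = 120, n_noncoding_genes = 60,
                      n_spikeins = 30, n_markers_per_stage = 4,
                      samples_per_stage = 3)
    .fixture_env$small <- simulate_experiment(cfg)
  }
  .fixture_env$small
}

# Full study-scale run at the generator defaults (the conditions the
# acceptance checks are stated for).
full_pipeline_run <- function() {
  if (is.null(.fixture_env$full)) {
    dir <- file.path(tempdir(), "tfeseq-full-run")
    .fixture_env$full <- run_pipeline(run_config(sim = sim_config(seed = 101)),
                                      dir, quiet = TRUE)
  }
  .fixture_env$full
}
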