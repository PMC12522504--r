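# The synthetic-data generator: determinism, gene structure, expression
# program, capture/duplication model.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 3, n_chromosomes = 2, chromosome_length = 2.5e5,
         n_coding_genes = 60, n_noncoding_genes = 30, n_spikeins = 15,
         n_markers_per_stage = 2, samples_per_stage = 3),
    list(...))
  do.call(sim_config, args)
}

test_that("reference generation is byte-deterministic for a fixed seed", {
  r1 <- generate_reference(small_cfg())
  r2 <- generate_reference(small_cfg())
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$units, r2$units)
  expect_identical(r1$spikeins, r2$spikeins)
  r3 <- generate_reference(small_cfg(seed = 4))
  expect_false(identical(as.character(r1$genome), as.character(r3$genome)))
})

test_that("degenerate config without coding genes yields only noncoding models", {
  cfg <- small_cfg(n_coding_genes = 0L)
  ref <- generate_reference(cfg)
  expect_true(all(ref$models$genes$biotype == "noncoding"))
  expect_true(all(is.na(ref$models$genes$cds_start)))
})

test_that("a genome too small for the gene load raises a capacity error", {
  expect_error(generate_reference(small_cfg(chromosome_length = 2e4)),
               "too small")
})

test_that("every gene model is structurally valid", {
  ref <- generate_reference(small_cfg())
  g <- ref$models$genes
  ex <- ref$models$exons
  for (i in seq_len(nrow(g))) {
    e <- ex[ex$gene_id == g$gene_id[i], ]
    expect_gte(nrow(e), 2L)
    expect_true(all(diff(e$start) > 0))
    expect_true(all(e$end[-nrow(e)] <= e$start[-1]))  # disjoint
    if (g$biotype[i] == "coding") {
      # CDS strictly inside the exon span with nonempty UTRs on both sides
      expect_true(g$cds_start[i] > g$span_start[i])
      expect_true(g$cds_end[i] < g$span_end[i])
      expect_true(any(e$start <= g$cds_start[i] & g$cds_start[i] < e$end))
      expect_true(any(e$start < g$cds_end[i] & g$cds_end[i] <= e$end))
    }
    expect_equal(g$tss[i],
                 if (g$strand[i] == "+") e$start[1] else e$end[nrow(e)] - 1)
  }
  # gene bodies do not overlap within a chromosome
  for (ch in unique(g$chrom)) {
    d <- g[g$chrom == ch, ]
    d <- d[order(d$span_start), ]
    expect_true(all(d$span_end[-nrow(d)] <= d$span_start[-1]))
  }
})

test_that("molecule counts are Poisson-like when overdispersion is zero", {
  cfg <- small_cfg(overdispersion = 0, samples_per_stage = 3)
  ref <- generate_reference(cfg)
  cnt <- simulate_counts(ref)
  # empirical CV^2 ~ 1/mu: simulate one housekeeping-like mean at n = 10000
  mu <- 80
  withr::with_seed(5, {
    draws <- matrix(rpois(10000, mu), ncol = 1)
  })
  expect_lt(abs(var(draws[, 1]) / mean(draws[, 1]) - 1), 0.05)
  # and the generator's own draws match their configured means
  gv <- cnt$molecules[, cnt$samples$stage == "GV", drop = FALSE]
  mu_gv <- cnt$truth$mean_molecules[, "GV"]
  big <- mu_gv > 50
  expect_lt(max(abs(rowMeans(gv)[big] - mu_gv[big]) /
                  sqrt(mu_gv[big] / ncol(gv))), 5)
})

test_that("marker genes have zero expected molecules outside their stage", {
  cnt <- simulate_counts(small_experiment()$reference)
  cls <- cnt$truth$classes
  mm <- cnt$truth$mean_molecules
  for (st in colnames(mm)) {
    rows <- cls$class == paste0("marker:", st)
    expect_true(any(rows))
    expect_true(all(mm[rows, setdiff(colnames(mm), st)] == 0))
    expect_true(all(mm[rows, st] > 0))
  }
})

test_that("maternal decay has its largest drops after MII and at the EGA stage", {
  cnt <- small_experiment()$counts
  cls <- cnt$truth$classes
  mm <- cnt$truth$mean_molecules[cls$class == "maternal", , drop = FALSE]
  tot <- colSums(mm)
  ratios <- tot[-1] / tot[-length(tot)]
  worst <- order(ratios)[1:2]
  expect_setequal(names(ratios)[worst], c("2c", "16c"))
  # zygotic means rise at the EGA stage
  zz <- colSums(cnt$truth$mean_molecules[cls$class == "zygotic", ])
  expect_gt(zz["16c"], 3 * zz["8c"])
})

test_that("equal stage content multipliers equalize expected stage totals", {
  cfg <- small_cfg(stage_content_multiplier = rep(1, 7))
  cnt <- simulate_counts(generate_reference(cfg))
  tot <- colSums(cnt$truth$mean_molecules)
  expect_equal(unname(tot), rep(unname(tot[1]), length(tot)), tolerance = 1e-9)
})

test_that("unknown stage labels in content/decay vectors are rejected", {
  expect_error(sim_config(stage_content_multiplier = c(1, 1)), "per stage")
  expect_error(sim_config(maternal_decay = rep(1, 3)), "per stage")
})

test_that("identity regime: events per gene-sample equal molecule counts", {
  cfg <- small_cfg(capture_efficiency = 1, pcr_duplicate_rate = 0,
                   tss_jitter_sd = 0)
  ref <- generate_reference(cfg)
  cnt <- simulate_counts(ref)
  aln <- simulate_alignments(cnt, ref)
  gen <- aln$events[!aln$events$is_spikein, ]
  key <- paste(gen$chrom, gen$pos, gen$strand)
  ukey <- paste(ref$units$chrom, ref$units$tss, ref$units$strand)
  per_gene <- table(factor(key, levels = ukey), gen$sample_id)
  expect_identical(
    matrix(as.integer(per_gene), nrow = nrow(ref$units)),
    matrix(as.integer(cnt$molecules[, colnames(per_gene)]),
           nrow = nrow(ref$units)))
})

test_that("dedup recovers the pre-duplication event stream exactly", {
  aln <- small_experiment()$alignments
  expect_gt(nrow(aln$events), nrow(aln$predup))
  dd <- dedup_events(aln$events)
  key <- function(e) paste(e$sample_id, e$chrom, e$strand, e$pos, e$umi)
  expect_identical(sort(key(dd)), sort(unique(key(aln$predup))))
})

test_that("minus-strand genes emit events at the model's rightmost base", {
  cfg <- small_cfg(tss_jitter_sd = 0, capture_efficiency = 1)
  ref <- generate_reference(cfg)
  cnt <- simulate_counts(ref)
  aln <- simulate_alignments(cnt, ref)
  minus <- ref$units[ref$units$strand == "-", ][1, ]
  ev <- aln$events[aln$events$chrom == minus$chrom &
                     aln$events$strand == "-" &
                     abs(aln$events$pos - minus$tss) < 50, ]
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$pos == minus$span_end - 1))
})

test_that("expected event counts follow molecules x eta x (1 + dup rate)", {
  exp <- small_experiment()
  cfg <- exp$reference$config
  n_mol <- sum(exp$counts$molecules) + nrow(exp$counts$samples) *
    sum(exp$reference$spikeins$molecules)
  expected <- n_mol * cfg$capture_efficiency * (1 + cfg$pcr_duplicate_rate)
  # binomial capture + Poisson duplication: conservative 3-SE band
  se <- sqrt(n_mol * cfg$capture_efficiency * (1 + cfg$pcr_duplicate_rate)^2 * 2)
  expect_lt(abs(nrow(exp$alignments$events) - expected), 3 * se)
})

test_that("spike-in dedup counts per sample estimate capture efficiency", {
  exp <- small_experiment()
  cfg <- exp$reference$config
  dd <- dedup_events(exp$alignments$events)
  sp_tot <- table(dd$sample_id[dd$is_spikein])
  eta_hat <- as.numeric(sp_tot) / cfg$spikein_molecules_per_sample
  expect_true(all(abs(eta_hat - cfg$capture_efficiency) < 0.02))
})
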