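# TFE quantification: 5'-end extraction, UMI dedup, region calling and the
# count matrix.

test_that("the 5' end is the strand-appropriate extreme aligned base", {
  expect_equal(extract_five_prime(data.frame(start = 100, end = 150), "+"), 100)
  expect_equal(extract_five_prime(data.frame(start = 100, end = 150), "-"), 149)
  # spliced: enumerate aligned bases, take the maximum on the minus strand
  blocks <- data.frame(start = c(100, 180), end = c(120, 200))
  aligned <- c(100:119, 180:199)
  expect_equal(extract_five_prime(blocks, "-"), max(aligned))
  expect_equal(extract_five_prime(blocks, "+"), min(aligned))
  expect_error(extract_five_prime(data.frame(start = 10, end = 10), "+"),
               "no aligned bases")
})

test_that("dedup keeps one event per (sample, chrom, strand, pos, UMI) tuple", {
  ev <- mk_events(rep(100, 3), umi = "ACGT")
  expect_equal(nrow(dedup_events(ev)), 1)
  ev2 <- mk_events(c(100, 100), umi = c("ACGT", "ACGA"))
  expect_equal(nrow(dedup_events(ev2)), 2)
  # no cross-sample collapse
  ev3 <- rbind(mk_events(100, umi = "ACGT", sample_id = "s1"),
               mk_events(100, umi = "ACGT", sample_id = "s2"))
  expect_equal(nrow(dedup_events(ev3)), 2)
})

test_that("dedup equals the distinct-tuple oracle and ignores input order", {
  withr::with_seed(9, {
    ev <- mk_events(sample(1:50, 400, replace = TRUE),
                    strand = sample(c("+", "-"), 400, replace = TRUE),
                    umi = sample(c("AA", "CC", "GG"), 400, replace = TRUE),
                    sample_id = sample(c("s1", "s2"), 400, replace = TRUE))
    dd <- dedup_events(ev)
    tuples <- unique(paste(ev$sample_id, ev$chrom, ev$strand, ev$pos, ev$umi))
    expect_equal(nrow(dd), length(tuples))
    shuffled <- ev[sample(nrow(ev)), ]
  })
  expect_identical(dedup_events(shuffled), dd)
})

test_that("region calling clusters by gap, filters by pooled count, places summits", {
  ev <- mk_events(c(rep(100, 3), rep(130, 2), 400),
                  umi = sprintf("U%d", 1:6))
  r <- call_tfes(ev, min_count = 2, max_gap = 50)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 100)
  expect_equal(r$end, 131)
  expect_equal(r$summit, 100)
  expect_equal(r$count, 5L)

  # a single event with min_count 1 becomes a width-1 region
  r1 <- call_tfes(mk_events(250), min_count = 1)
  expect_equal(c(r1$start, r1$end, r1$summit), c(250, 251, 250))

  # identical positions on both strands give two strand-specific TFEs
  ev2 <- rbind(mk_events(c(100, 110), umi = c("A", "B")),
               mk_events(c(100, 110), strand = "-", umi = c("A", "B")))
  r2 <- call_tfes(ev2, min_count = 2)
  expect_equal(nrow(r2), 2)
  expect_setequal(r2$strand, c("+", "-"))

  # summit tie-break is the farthest-5' mode per strand
  tie <- c(100, 100, 120, 120)
  expect_equal(call_tfes(mk_events(tie, umi = sprintf("U%d", 1:4)),
                         min_count = 1)$summit, 100)
  expect_equal(call_tfes(mk_events(tie, strand = "-", umi = sprintf("U%d", 1:4)),
                         min_count = 1)$summit, 120)

  expect_equal(nrow(call_tfes(mk_events(numeric(0)))), 0)
})

test_that("region calling matches brute-force clustering on random instances", {
  withr::with_seed(14, {
    for (rep in 1:200) {
      n <- sample(5:40, 1)
      ev <- mk_events(sample(1:300, n, replace = TRUE),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      umi = sprintf("U%03d", seq_len(n)))
      max_gap <- sample(c(0, 5, 20, 60), 1)
      min_count <- sample(1:3, 1)
      got <- call_tfes(ev, min_count = min_count, max_gap = max_gap)
      want <- brute_force_tfes(ev, min_count, max_gap)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(got[, c("chrom", "start", "end", "strand", "summit", "count")],
                     want, ignore_attr = TRUE)
      }
    }
  })
})

test_that("region calling is invariant under event permutation", {
  withr::with_seed(15, {
    ev <- mk_events(sample(1:500, 100, replace = TRUE),
                    umi = sprintf("U%03d", 1:100))
    r1 <- call_tfes(ev)
    r2 <- call_tfes(ev[sample(nrow(ev)), ])
  })
  expect_identical(r1, r2)
})

test_that("the count matrix assigns events by half-open interval and strand", {
  samples <- data.frame(sample_id = c("s1", "s2"), stage = c("GV", "GV"))
  ev <- mk_events(c(100, 105, 110, 130), umi = sprintf("U%d", 1:4))
  r <- call_tfes(ev, min_count = 2, max_gap = 60)
  x <- build_count_matrix(r, ev, samples)
  expect_equal(unname(x$counts[, "s1"]), 4L)
  expect_equal(x$unassigned, 0L)

  # one bp past the region end is unassigned (half-open boundary)
  past <- rbind(ev, mk_events(r$end, umi = "PAST"))
  x2 <- build_count_matrix(r, past, samples)
  expect_equal(unname(x2$counts[, "s1"]), 4L)
  expect_equal(x2$unassigned, 1L)

  # unknown sample errors
  bad <- mk_events(100, sample_id = "ghost")
  expect_error(build_count_matrix(r, bad, samples), "ghost")
})

test_that("the count matrix equals the double-loop oracle and conserves events", {
  withr::with_seed(16, {
    samples <- data.frame(sample_id = sprintf("s%d", 1:5),
                          stage = rep(c("GV", "MII"), c(3, 2)))
    ev <- mk_events(sample(1:2000, 200, replace = TRUE),
                    strand = sample(c("+", "-"), 200, replace = TRUE),
                    umi = sprintf("U%03d", 1:200),
                    sample_id = sample(samples$sample_id, 200, replace = TRUE))
    regions <- call_tfes(ev, min_count = 4, max_gap = 30)
  })
  x <- build_count_matrix(regions, ev, samples)
  oracle <- matrix(0L, nrow(regions), nrow(samples))
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(samples))) {
      oracle[i, j] <- sum(ev$chrom == regions$chrom[i] &
                            ev$strand == regions$strand[i] &
                            ev$sample_id == samples$sample_id[j] &
                            ev$pos >= regions$start[i] &
                            ev$pos < regions$end[i])
    }
  }
  expect_equal(unname(x$counts), oracle)
  expect_equal(sum(x$counts) + x$unassigned, nrow(ev))
})

test_that("the caller recovers nearly all true TSS loci as single TFEs", {
  exp <- small_experiment()
  dd <- dedup_events(exp$alignments$events)
  regions <- call_tfes(dd)
  m <- match_tfes_to_truth(regions, exp$counts$truth)
  cls <- exp$counts$truth$classes
  # loci with enough pooled events to be callable at all
  gen <- dd[!dd$is_spikein, ]
  near <- paste(gen$chrom, gen$strand)
  per_unit <- vapply(seq_len(nrow(cls)), function(i) {
    sum(near == paste(cls$chrom[i], cls$strand[i]) &
          abs(gen$pos - cls$tss[i]) <= 60)
  }, numeric(1))
  callable <- cls$unit_id[per_unit >= 2]
  hits <- table(m$unit_id)
  expect_gte(mean(callable %in% names(hits)), 0.99)
  expect_true(all(hits[names(hits) %in% callable] == 1))
})
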