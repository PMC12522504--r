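# Technical-noise model, excess-variability test, variable-TFE selection,
# correlation, and the consecutive-stage NB Wald test.

test_that("the noise fit is exact on noiseless points and degenerate inputs", {
  mu <- exp(seq(log(2), log(2000), length.out = 40))
  fit <- fit_technical_noise(mu, 2 / mu + 0.1)
  expect_lt(abs(fit$a0 - 0.1), 1e-6)
  expect_lt(abs(fit$a1 - 2), 1e-6)
  expect_equal(cv2_tech(fit, 10), 2 / 10 + 0.1, tolerance = 1e-6)

  # constant CV^2 over a wide mean range: a0 -> c, a1 -> 0
  fit2 <- fit_technical_noise(mu, rep(0.25, 40))
  expect_lt(abs(fit2$a0 - 0.25), 1e-6)
  expect_lt(abs(fit2$a1), 1e-4)

  expect_error(fit_technical_noise(mu[1:5], (2 / mu + 0.1)[1:5]), ">= 10")
})

test_that("the noise fit recovers (a0, a1) = (0, 1) under Poisson spike-ins", {
  n <- 12
  mu <- exp(seq(log(5), log(2000), length.out = 40))
  withr::with_seed(31, {
    ests <- t(replicate(60, {
      counts <- matrix(rpois(40 * n, rep(mu, n)), ncol = n)
      m <- normalized_moments(counts, rep(1, n))
      fit <- fit_technical_noise(m$mean, m$cv2)
      c(fit$a0, fit$a1)
    }))
  })
  se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1]) - 0) , 3 * se[1] + 1e-3)
  expect_lt(abs(mean(ests[, 2]) - 1), 3 * se[2] + 0.02)
})

test_that("variability p values behave at the extremes", {
  fit <- structure(list(a0 = 0.01, a1 = 1, method = "exact", n_points = 40),
                   class = "noise_fit")
  expect_equal(variability_test(100, 0, fit, 10), 1)
  expect_lt(variability_test(100, 5, fit, 10), 1e-10)
  expect_error(variability_test(10, 0.1, structure(
    list(a0 = -1, a1 = 0.1, method = "x", n_points = 40),
    class = "noise_fit"), 10), "non-positive")
  expect_error(variability_test(10, 0.1, fit, 2), ">= 3")
})

test_that("top-variable selection is filter, sort, slice with stable ties", {
  res <- data.frame(tfe_id = sprintf("T%02d", 1:6),
                    mean = 10, cv2 = c(5, 3, 3, 8, 1, 2),
                    p = 0.001, padj = c(0.01, 0.01, 0.01, 0.2, 0.01, 0.01))
  # fewer significant than K -> all returned, highest CV^2 first
  expect_equal(select_top_variable(res, k = 100),
               c("T01", "T02", "T03", "T06", "T05"))
  # equal CV^2 breaks ties by id, deterministically
  expect_equal(select_top_variable(res, k = 3), c("T01", "T02", "T03"))
  # random fixture equals the naive filter-sort-slice oracle
  withr::with_seed(41, {
    r2 <- data.frame(tfe_id = sprintf("T%03d", 1:200), mean = 1,
                     cv2 = round(rexp(200), 2), p = 0.01,
                     padj = runif(200, 0, 0.1))
  })
  sig <- r2[r2$padj < 0.05, ]
  oracle <- sig$tfe_id[order(-sig$cv2, sig$tfe_id)][1:20]
  expect_equal(select_top_variable(r2, k = 20), oracle)
})

test_that("pairwise correlations are Pearson on finite values", {
  withr::with_seed(27, {
    counts <- matrix(rpois(40, 40) + 1L, ncol = 4)
  })
  x <- mk_tfe_matrix(counts, stage = rep("GV", 4),
                     spikein = rep(c(TRUE, FALSE), c(3, 7)))
  nz <- log2_normalize(x, pseudocount = 1)
  cc <- pairwise_correlation(nz)
  expect_equal(diag(cc), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(cc >= -1 & cc <= 1))
  expect_equal(cc, t(cc))
  # duplicated / negated columns
  v <- nz$values
  expect_equal(cor(v[, 1], v[, 1]), 1)
  # textbook formula on a hand matrix
  h <- matrix(c(1, 2, 4, 8, 2, 1, 7, 3, 5, 5, 5, 6), ncol = 3)
  manual <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  nz$values <- h
  colnames(nz$values) <- paste0("h", 1:3)
  cc2 <- pairwise_correlation(nz)
  expect_equal(cc2[1, 2], manual(h[, 1], h[, 2]))
  expect_equal(cc2[1, 3], manual(h[, 1], h[, 3]))
  # sentinels are refused; zero-variance samples flagged as NA
  nz$values[1, 1] <- -Inf
  expect_error(pairwise_correlation(nz), "pseudocount")
  nz$values <- h
  nz$values[, 2] <- 7
  colnames(nz$values) <- paste0("h", 1:3)
  expect_warning(cc3 <- pairwise_correlation(nz), "zero-variance")
  expect_true(is.na(cc3[1, 2]))
})

test_that("BH adjustment matches the naive step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  naive_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  withr::with_seed(51, {
    for (i in 1:20) {
      p <- runif(sample(1:100, 1))
      expect_equal(bh_adjust(p), naive_bh(p))
    }
  })
})

de_fixture <- function(counts_e, counts_l, n = 4) {
  samples <- data.frame(sample_id = c(paste0("e", 1:n), paste0("l", 1:n)),
                        stage = rep(c("E", "L"), each = n))
  mk_tfe_matrix(cbind(counts_e, counts_l), stage = samples$stage)
}

unit_sf <- function(x) stats::setNames(rep(1, ncol(x$counts)),
                                       colnames(x$counts))

test_that("identical groups give zero fold change and p near 1", {
  cnt <- matrix(rep(c(30L, 100L, 5L), 4), ncol = 4)
  x <- de_fixture(cnt, cnt)
  de <- nb_wald_contrast(x, unit_sf(x), "L", "E")
  expect_equal(de$lfc, rep(0, 3))
  expect_true(all(de$p > 0.99))
  expect_true(all(de$direction == "ns"))
})

test_that("the Wald test is group-swap equivariant", {
  withr::with_seed(61, {
    ce <- matrix(rnbinom(50 * 4, mu = 80, size = 8), ncol = 4)
    cl <- matrix(rnbinom(50 * 4, mu = 120, size = 8), ncol = 4)
  })
  x <- de_fixture(ce, cl)
  d1 <- nb_wald_contrast(x, unit_sf(x), "L", "E")
  d2 <- nb_wald_contrast(x, unit_sf(x), "E", "L")
  expect_equal(d1$lfc, -d2$lfc)
  expect_equal(d1$p, d2$p)
})

test_that("jointly scaling one sample's counts and factor changes nothing", {
  withr::with_seed(62, {
    ce <- matrix(rnbinom(40 * 4, mu = 60, size = 6), ncol = 4)
    cl <- matrix(rnbinom(40 * 4, mu = 90, size = 6), ncol = 4)
  })
  x <- de_fixture(ce, cl)
  d1 <- nb_wald_contrast(x, unit_sf(x), "L", "E")
  x2 <- x
  x2$counts[, 3] <- x2$counts[, 3] * 5L
  sf <- unit_sf(x); sf[3] <- 5
  d2 <- nb_wald_contrast(x2, sf, "L", "E")
  expect_equal(d1$lfc, d2$lfc, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
})

test_that("consecutive contrasts come in fixed developmental order", {
  stages <- c("GV", "MII", "2c", "4c", "8c", "16c", "Blc")
  cc <- consecutive_contrasts(stages)
  expect_equal(cc$name, c("MII|GV", "2c|MII", "4c|2c", "8c|4c",
                          "16c|8c", "Blc|16c"))
  exp <- small_experiment()
  dd <- dedup_events(exp$alignments$events)
  x <- build_count_matrix(call_tfes(dd), dd, exp$counts$samples)
  de <- run_consecutive_de(x, stages = stages)
  expect_equal(names(de), cc$name)
})
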