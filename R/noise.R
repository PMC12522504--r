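# Technical-noise modelling on spike-ins (CV^2 vs mean), the excess-
# variability test, variable-TFE selection and sample correlation.

#' Per-row mean and CV^2 of normalized counts
#'
#' @param counts integer matrix (rows = TFEs).
#' @param size_factors per-sample size factors.
#' @return data.frame with `mean` and `cv2` (unbiased sample variance).
#' @export
normalized_moments <- function(counts, size_factors) {
  q <- sweep(counts, 2, size_factors, "/")
  mu <- rowMeans(q)
  data.frame(mean = mu, cv2 = row_vars(q) / mu^2)
}

#' Fit the spike-in technical-noise model CV^2(mu) = a1/mu + a0
#'
#' A gamma generalized linear model with identity link regresses spike-in
#' CV^2 on 1/mu. If the IRLS fit fails to converge, ordinary least squares
#' on (1/mu, CV^2) is used instead and the fallback is recorded.
#'
#' @param mu spike-in normalized means (> 0).
#' @param cv2 matching squared coefficients of variation.
#' @param min_spikeins minimum usable points (default 10).
#' @return object of class `noise_fit`: `a0`, `a1`, `n_points`, `method`
#'   ("gamma-glm" or "ols").
#' @export
fit_technical_noise <- function(mu, cv2, min_spikeins = 10L) {
  ok <- is.finite(mu) & is.finite(cv2) & mu > 0 & cv2 > 0
  if (sum(ok) < min_spikeins) {
    stopf("need >= %d spike-ins with positive mean and CV^2, got %d",
          min_spikeins, sum(ok))
  }
  d <- data.frame(x = 1 / mu[ok], y = cv2[ok])
  ls <- stats::coef(stats::lm(y ~ x, data = d))
  fit <- tryCatch({
    # AIC evaluation warns (NaN) when residual deviance is ~0; convergence
    # is checked explicitly below, so warnings can be muffled
    g <- suppressWarnings(
      stats::glm(y ~ x, data = d, family = stats::Gamma(link = "identity"),
                 start = pmax(ls, c(1e-8, 1e-8)),
                 control = stats::glm.control(maxit = 100)))
    if (!g$converged) stop("IRLS did not converge")
    list(a0 = unname(stats::coef(g)[1]), a1 = unname(stats::coef(g)[2]),
         method = "gamma-glm")
  }, error = function(e) {
    warnf("gamma GLM failed (%s); falling back to OLS", conditionMessage(e))
    list(a0 = unname(ls[1]), a1 = unname(ls[2]), method = "ols")
  })
  structure(list(a0 = fit$a0, a1 = fit$a1, n_points = sum(ok),
                 method = fit$method),
            class = "noise_fit")
}

#' @export
print.noise_fit <- function(x, ...) {
  cat(sprintf("Technical noise fit (%s, %d spike-ins): CV2_tech(mu) = %.4g/mu + %.4g\n",
              x$method, x$n_points, x$a1, x$a0))
  invisible(x)
}

#' Predicted technical CV^2 at a mean
#' @param fit a `noise_fit`.
#' @param mu normalized mean(s).
#' @export
cv2_tech <- function(fit, mu) fit$a1 / mu + fit$a0

#' Test a TFE for variability in excess of technical noise
#'
#' The statistic T = (n - 1) CV^2 / CV^2_tech(mu) is referred to the upper
#' tail of a chi-square distribution with n - 1 degrees of freedom: under
#' purely technical noise the observed CV^2 fluctuates around the spike-in
#' prediction, and biological variability inflates T.
#'
#' @param mu observed normalized mean(s) (> 0).
#' @param cv2 observed CV^2.
#' @param fit a [fit_technical_noise()] result.
#' @param n_samples number of samples behind each CV^2 (>= 3).
#' @return vector of upper-tail p values.
#' @export
variability_test <- function(mu, cv2, fit, n_samples) {
  if (n_samples < 3L) stopf("need >= 3 samples")
  tech <- cv2_tech(fit, mu)
  if (any(!is.finite(tech) | tech <= 0)) stopf("non-positive technical CV^2 prediction")
  stats::pchisq((n_samples - 1) * cv2 / tech, df = n_samples - 1,
                lower.tail = FALSE)
}

#' Variable-TFE testing over a count matrix
#'
#' Fits the technical-noise model on spike-in rows and tests every
#' non-spike-in TFE with positive total count for excess variability;
#' p values are BH-adjusted.
#'
#' @param x a `tfe_matrix`.
#' @param size_factors size factors (computed from spike-ins when NULL).
#' @return data.frame: `tfe_id`, `mean`, `cv2`, `p`, `padj`, plus the
#'   `noise_fit` as attribute "fit".
#' @export
test_variable_tfes <- function(x, size_factors = NULL) {
  stopifnot(inherits(x, "tfe_matrix"))
  if (is.null(size_factors)) size_factors <- spikein_size_factors(x)
  sp <- x$regions$is_spikein
  msp <- normalized_moments(x$counts[sp, , drop = FALSE], size_factors)
  fit <- fit_technical_noise(msp$mean, msp$cv2)
  keep <- !sp & rowSums(x$counts) > 0
  m <- normalized_moments(x$counts[keep, , drop = FALSE], size_factors)
  p <- variability_test(m$mean, m$cv2, fit, ncol(x$counts))
  res <- data.frame(tfe_id = x$regions$tfe_id[keep], mean = m$mean,
                    cv2 = m$cv2, p = p, padj = bh_adjust(p),
                    row.names = NULL)
  attr(res, "fit") <- fit
  res
}

#' Select the top-K most variable significant TFEs
#'
#' Filters adjusted p < alpha, sorts by CV^2 descending (ties by TFE id)
#' and returns the first K ids (all, if fewer pass).
#'
#' @param results a [test_variable_tfes()] data.frame.
#' @param k maximum TFEs (default 20000).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return character vector of TFE ids.
#' @export
select_top_variable <- function(results, k = 20000L, alpha = 0.05) {
  if (k < 1L) stopf("k must be >= 1")
  sig <- results[results$padj < alpha, ]
  sig <- sig[order(-sig$cv2, sig$tfe_id), ]
  utils::head(sig$tfe_id, k)
}

#' Pairwise Pearson correlation of samples
#'
#' Computed over the given TFE rows of a pseudocount-normalized value
#' matrix; sentinel (`-Inf`) values are not accepted. Zero-variance samples
#' produce NA entries (flagged with a warning), never a silent 0.
#'
#' @param norm a `tfe_norm` with `pseudocount > 0`.
#' @param tfe_ids rows to use (default all).
#' @return symmetric sample x sample correlation matrix.
#' @export
pairwise_correlation <- function(norm, tfe_ids = NULL) {
  stopifnot(inherits(norm, "tfe_norm"))
  v <- norm$values
  if (!is.null(tfe_ids)) v <- v[match(tfe_ids, norm$regions$tfe_id), , drop = FALSE]
  if (any(!is.finite(v))) {
    stopf("values contain sentinels; use a pseudocount > 0 normalization")
  }
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) warnf("zero-variance sample(s): %s; correlations set to NA",
                           paste(colnames(v)[sds == 0], collapse = ", "))
  suppressWarnings(stats::cor(v))
}
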