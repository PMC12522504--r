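# Spike-in-anchored normalization: median-of-ratios size factors on
# spike-in rows, log2 normalized values, relative poly(A) content per
# stage, and the value <-> molecule-copies calibration.

#' Spike-in median-of-ratios size factors
#'
#' Median-of-ratios computed on spike-in rows only: per sample, the median
#' over usable spike-ins of count / geometric mean of that spike-in's
#' counts; the factors are rescaled to geometric mean 1. A spike-in is
#' usable when its count is positive in every sample.
#'
#' @param x a `tfe_matrix` with flagged spike-in rows.
#' @return named numeric vector of positive size factors, geometric mean 1.
#' @export
spikein_size_factors <- function(x) {
  stopifnot(inherits(x, "tfe_matrix"))
  sp <- x$counts[x$regions$is_spikein, , drop = FALSE]
  if (any(colSums(sp) == 0)) {
    stopf("sample(s) with all-zero spike-ins: %s",
          paste(colnames(sp)[colSums(sp) == 0], collapse = ", "))
  }
  usable <- rowSums(sp == 0) == 0L
  if (sum(usable) < 2L) stopf("fewer than 2 spike-ins with positive counts in all samples")
  sp <- sp[usable, , drop = FALSE]
  loggeo <- rowMeans(log(sp))
  # median of log ratios (as in the median-of-ratios estimator), so an even
  # number of spike-ins averages the two middle ratios geometrically
  sf <- exp(apply(log(sp) - loggeo, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Log2 spike-in-normalized values
#'
#' value = log2((count + pseudocount) / (size_factor x S_ref)), where S_ref
#' is the mean total spike-in UMI count across samples. On this scale a
#' value of 0 corresponds to one spike-in-input-equivalent of molecules, so
#' [value_to_copies()] converts values to absolute copies. With
#' `pseudocount = 0` zero counts map to `-Inf`, the below-threshold
#' sentinel: it compares below any finite expression threshold, and values
#' are strictly increasing in counts within a sample.
#'
#' @param x a `tfe_matrix`.
#' @param size_factors as from [spikein_size_factors()]; computed when NULL.
#' @param pseudocount added to counts before the log (default 0; use 1 for
#'   correlation/clustering inputs).
#' @return object of class `tfe_norm`: list with `values` (TFE x sample
#'   matrix), `size_factors`, `s_ref`, `pseudocount`, `regions`, `samples`.
#' @export
log2_normalize <- function(x, size_factors = NULL, pseudocount = 0) {
  stopifnot(inherits(x, "tfe_matrix"))
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  if (is.null(size_factors)) size_factors <- spikein_size_factors(x)
  s_ref <- mean(colSums(x$counts[x$regions$is_spikein, , drop = FALSE]))
  if (!is.finite(s_ref) || s_ref <= 0) stopf("no spike-in counts to anchor S_ref")
  values <- log2(sweep(x$counts + pseudocount, 2, size_factors * s_ref, "/"))
  structure(list(values = values, size_factors = size_factors, s_ref = s_ref,
                 pseudocount = pseudocount, regions = x$regions,
                 samples = x$samples),
            class = "tfe_norm")
}

#' @export
print.tfe_norm <- function(x, ...) {
  cat(sprintf("tfe_norm: %d TFEs x %d samples; S_ref = %.1f spike-in UMIs, pseudocount %g\n",
              nrow(x$values), ncol(x$values), x$s_ref, x$pseudocount))
  invisible(x)
}

#' Relative poly(A) RNA content per stage
#'
#' Per sample, the endogenous (non-spike-in) mapped total is divided by the
#' spike-in total; the ratios are averaged by developmental stage and
#' divided by the reference-stage average, which is set to 1.
#'
#' @param x a `tfe_matrix`.
#' @param reference_stage stage set to 1 (default the sheet's first stage).
#' @return data.frame with `stage` and `content` columns, stage order as in
#'   the sheet.
#' @export
relative_rna_content <- function(x, reference_stage = NULL) {
  stopifnot(inherits(x, "tfe_matrix"))
  sp <- colSums(x$counts[x$regions$is_spikein, , drop = FALSE])
  if (any(sp == 0)) {
    stopf("zero spike-in total in sample(s): %s",
          paste(colnames(x$counts)[sp == 0], collapse = ", "))
  }
  gen <- colSums(x$counts[!x$regions$is_spikein, , drop = FALSE])
  ratio <- gen / sp
  stages <- unique(x$samples$stage)
  if (is.null(reference_stage)) reference_stage <- stages[1]
  if (!reference_stage %in% stages) stopf("unknown reference stage '%s'", reference_stage)
  avg <- vapply(stages, function(st) {
    mean(ratio[x$samples$sample_id[x$samples$stage == st]])
  }, numeric(1))
  data.frame(stage = stages, content = unname(avg / avg[reference_stage]),
             row.names = NULL)
}

#' Convert log2 normalized values to molecule copies (and back)
#'
#' With M spike-in molecules loaded per sample, a log2 normalized value v
#' estimates 2^v x M molecule copies; with the default synthetic input
#' M = 9216, v = -10 corresponds to exactly 9 copies. The sentinel `-Inf`
#' (zero counts) has no copy estimate and is an error.
#'
#' @param v finite log2 normalized value(s).
#' @param molecules_per_sample spike-in molecules loaded per sample (M).
#' @return estimated molecule copies.
#' @export
value_to_copies <- function(v, molecules_per_sample) {
  if (molecules_per_sample <= 0) stopf("molecules_per_sample must be > 0")
  if (any(!is.finite(v))) stopf("no copy estimate for sentinel (zero-count) values")
  2^v * molecules_per_sample
}

#' @rdname value_to_copies
#' @param copies molecule copies (> 0).
#' @export
copies_to_value <- function(copies, molecules_per_sample) {
  if (molecules_per_sample <= 0) stopf("molecules_per_sample must be > 0")
  if (any(copies <= 0)) stopf("copies must be > 0")
  log2(copies / molecules_per_sample)
}
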