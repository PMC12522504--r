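# Differential expression between consecutive developmental stages:
# negative binomial Wald test on spike-in size-factor-normalized counts.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()] after validating the input).
#' @param p p values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stopf("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Consecutive-stage contrasts in developmental order
#'
#' @param stages ordered stage labels.
#' @return data.frame with `later`, `earlier`, `name` ("later|earlier"),
#'   one row per adjacent pair.
#' @export
consecutive_contrasts <- function(stages) {
  if (length(stages) < 2L) stopf("need >= 2 stages")
  data.frame(later = stages[-1], earlier = stages[-length(stages)],
             name = paste(stages[-1], stages[-length(stages)], sep = "|"),
             stringsAsFactors = FALSE)
}

#' Negative binomial Wald test for one stage contrast
#'
#' For every TFE, counts are normalized by the per-sample size factors and
#' group means are formed for the later and earlier stage; zero group means
#' are replaced by half of the smallest positive normalized count in the
#' contrast so fold changes stay finite. The log2 fold change is
#' later vs earlier. A per-TFE NB dispersion is estimated by the method of
#' moments on normalized counts pooled within groups (floored at 1e-8), and
#' the Wald standard error follows from the NB mean-variance relation by
#' the delta method. Because the dispersion uses only n1 + n2 - 2 residual
#' degrees of freedom, the two-sided p value refers the Wald statistic to a
#' t distribution with that df (a normal reference is anticonservative at
#' typical replicate numbers).
#' Directions are assigned after BH adjustment across the contrast's TFEs:
#' up/down means adjusted p < alpha with positive/negative fold change.
#'
#' @param x a `tfe_matrix`.
#' @param size_factors per-sample size factors.
#' @param later,earlier stage labels of the contrast (later developmental
#'   stage first).
#' @param alpha adjusted-p cutoff for direction calls (default 0.05).
#' @return data.frame of class `de_table`: `tfe_id`, `base_mean`, `lfc`,
#'   `se`, `stat`, `p`, `padj`, `direction`.
#' @export
nb_wald_contrast <- function(x, size_factors, later, earlier, alpha = 0.05) {
  stopifnot(inherits(x, "tfe_matrix"))
  sL <- x$samples$sample_id[x$samples$stage == later]
  sE <- x$samples$sample_id[x$samples$stage == earlier]
  if (length(sL) < 2L || length(sE) < 2L) {
    stopf("need >= 2 samples per stage (%s: %d, %s: %d)",
          later, length(sL), earlier, length(sE))
  }
  qL <- sweep(x$counts[, sL, drop = FALSE], 2, size_factors[sL], "/")
  qE <- sweep(x$counts[, sE, drop = FALSE], 2, size_factors[sE], "/")
  nL <- length(sL); nE <- length(sE)
  cL <- mean(1 / size_factors[sL]); cE <- mean(1 / size_factors[sE])
  mL <- rowMeans(qL); mE <- rowMeans(qE)
  vL <- row_vars(qL); vE <- row_vars(qE)

  qpos <- c(qL[qL > 0], qE[qE > 0])
  delta <- if (length(qpos)) min(qpos) / 2 else 0.5
  mL2 <- ifelse(mL == 0, delta, mL)
  mE2 <- ifelse(mE == 0, delta, mE)
  lfc <- log2(mL2 / mE2)

  # method-of-moments dispersion pooled over the two groups
  aL <- ifelse(mL > 0, (vL - mL * cL) / mL^2, NA_real_)
  aE <- ifelse(mE > 0, (vE - mE * cE) / mE^2, NA_real_)
  w <- cbind(ifelse(is.na(aL), 0, nL - 1), ifelse(is.na(aE), 0, nE - 1))
  a <- rowSums(cbind(ifelse(is.na(aL), 0, aL), ifelse(is.na(aE), 0, aE)) * w)
  a <- ifelse(rowSums(w) > 0, a / rowSums(w), 0)
  a <- pmax(a, 1e-8)

  # plug-in NB variance of each group mean; an all-zero group contributes
  # no variance (the offset enters the point estimate only)
  var_mL <- (mL * cL + a * mL^2) / nL
  var_mE <- (mE * cE + a * mE^2) / nE
  se <- sqrt(var_mL / mL2^2 + var_mE / mE2^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(stat), df = nL + nE - 2L)
  padj <- bh_adjust(p)
  direction <- ifelse(padj < alpha & lfc > 0, "up",
                      ifelse(padj < alpha & lfc < 0, "down", "ns"))
  structure(data.frame(tfe_id = x$regions$tfe_id,
                       base_mean = (mL + mE) / 2, lfc = lfc, se = se,
                       stat = stat, p = p, padj = padj,
                       direction = direction, row.names = NULL),
            class = c("de_table", "data.frame"),
            contrast = c(later = later, earlier = earlier))
}

#' Wald tests for all consecutive-stage contrasts
#'
#' Runs [nb_wald_contrast()] for each adjacent stage pair in developmental
#' order (e.g. MII|GV, 2c|MII, ..., Blc|16c). TFEs with zero total count
#' across all samples are removed first.
#'
#' @param x a `tfe_matrix`.
#' @param size_factors size factors (spike-in median-of-ratios when NULL).
#' @param stages ordered stage labels (default: order of appearance in the
#'   sample sheet).
#' @param alpha adjusted-p cutoff.
#' @return named list of `de_table`s, one per contrast, in order.
#' @export
run_consecutive_de <- function(x, size_factors = NULL, stages = NULL,
                               alpha = 0.05) {
  stopifnot(inherits(x, "tfe_matrix"))
  if (is.null(size_factors)) size_factors <- spikein_size_factors(x)
  if (is.null(stages)) stages <- unique(x$samples$stage)
  keep <- rowSums(x$counts) > 0
  xs <- x
  xs$counts <- x$counts[keep, , drop = FALSE]
  xs$regions <- x$regions[keep, , drop = FALSE]
  cons <- consecutive_contrasts(stages)
  out <- lapply(seq_len(nrow(cons)), function(i) {
    nb_wald_contrast(xs, size_factors, cons$later[i], cons$earlier[i], alpha)
  })
  names(out) <- cons$name
  out
}
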