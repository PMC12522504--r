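# Ground-truth matching helpers for benchmarking the pipeline on
# synthetic data.

#' Match called TFEs to true TSS loci
#'
#' Assigns each non-spike-in TFE to the nearest simulated transcription
#' unit on the same chromosome and strand whose true TSS lies within
#' `max_dist` bp of the TFE summit.
#'
#' @param regions a [call_tfes()] result.
#' @param truth the `truth` element of a [simulate_counts()] object.
#' @param max_dist maximum summit-to-TSS distance (default 60, the caller's
#'   default gap).
#' @return data.frame: `tfe_id`, `unit_id` (NA when unmatched), `distance`.
#' @export
match_tfes_to_truth <- function(regions, truth, max_dist = 60L) {
  cls <- truth$classes
  unit_id <- rep(NA_character_, nrow(regions))
  distance <- rep(NA_real_, nrow(regions))
  grp_r <- paste(regions$chrom, regions$strand, sep = "\r")
  grp_u <- paste(cls$chrom, cls$strand, sep = "\r")
  for (g in unique(grp_r)) {
    iu <- which(grp_u == g)
    if (!length(iu)) next
    ir <- which(grp_r == g)
    ord <- order(cls$tss[iu])
    tss <- cls$tss[iu][ord]
    ids <- cls$unit_id[iu][ord]
    k <- findInterval(regions$summit[ir], tss)
    lo <- pmax(k, 1L)
    hi <- pmin(k + 1L, length(tss))
    dlo <- abs(regions$summit[ir] - tss[lo])
    dhi <- abs(regions$summit[ir] - tss[hi])
    best <- ifelse(dlo <= dhi, lo, hi)
    d <- pmin(dlo, dhi)
    ok <- d <= max_dist
    unit_id[ir[ok]] <- ids[best[ok]]
    distance[ir[ok]] <- d[ok]
  }
  data.frame(tfe_id = regions$tfe_id, unit_id = unit_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Sensitivity and false-discovery proportion of marker recovery
#'
#' Compares a [call_stage_markers()] result against the planted
#' `marker:<stage>` classes of the ground truth, restricted to the stages
#' the marker set covers. A called marker TFE is a true positive when it
#' matches a unit planted as a marker of the same stage.
#'
#' @param markers a `marker_set`.
#' @param matching a [match_tfes_to_truth()] data.frame.
#' @param truth the ground truth of a [simulate_counts()] object.
#' @return list with `sensitivity`, `fdp`, `n_called`, `n_planted` (planted
#'   units with at least one matched TFE count once).
#' @export
marker_recovery <- function(markers, matching, truth) {
  cls <- truth$classes
  tp <- 0L; called <- 0L; planted <- 0L; recovered <- 0L
  for (st in names(markers)) {
    planted_units <- cls$unit_id[cls$class == paste0("marker:", st)]
    called_ids <- markers[[st]]$tfe_id
    called_units <- matching$unit_id[match(called_ids, matching$tfe_id)]
    tp <- tp + sum(!is.na(called_units) & called_units %in% planted_units)
    called <- called + length(called_ids)
    planted <- planted + length(planted_units)
    recovered <- recovered + sum(planted_units %in% called_units)
  }
  list(sensitivity = if (planted) recovered / planted else NA_real_,
       fdp = if (called) 1 - tp / called else 0,
       n_called = called, n_planted = planted)
}
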