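# TFE quantification: deduplicated 5'-end events -> strand-specific TFE
# regions -> TFE x sample UMI count matrix.

#' 5' end of an aligned record
#'
#' Returns the read's 5'-end reference position from its aligned blocks:
#' the leftmost aligned base on the plus strand, the rightmost on the minus
#' strand. Spliced alignments (several blocks) are respected.
#'
#' @param blocks data.frame with 0-based half-open `start`, `end` columns,
#'   one row per aligned block.
#' @param strand "+" or "-".
#' @return 0-based reference position of the 5' end.
#' @export
extract_five_prime <- function(blocks, strand) {
  if (nrow(blocks) == 0L || any(blocks$end <= blocks$start)) {
    stopf("alignment has no aligned bases")
  }
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  if (strand == "+") min(blocks$start) else max(blocks$end) - 1L
}

#' Collapse PCR duplicates of 5'-end events
#'
#' One event survives per distinct (sample, chrom, strand, pos, UMI) tuple;
#' reads sharing all five keys are PCR duplicates of one molecule. There is
#' no cross-sample collapsing. The result is sorted by (chrom, pos, strand,
#' sample, UMI) and therefore independent of input order.
#'
#' @param events data.frame with columns `chrom`, `pos`, `strand`, `umi`,
#'   `sample_id`, `is_spikein`.
#' @return data.frame of deduplicated events (same columns).
#' @export
dedup_events <- function(events) {
  check_events(events)
  key <- paste(events$sample_id, events$chrom, events$strand, events$pos,
               events$umi, sep = "\r")
  out <- events[!duplicated(key),
                c("chrom", "pos", "strand", "umi", "sample_id", "is_spikein")]
  out <- out[order(out$chrom, out$pos, out$strand, out$sample_id, out$umi), ]
  rownames(out) <- NULL
  out
}

check_events <- function(events, dedup = FALSE) {
  need <- c("chrom", "pos", "strand", "umi", "sample_id", "is_spikein")
  miss <- setdiff(need, names(events))
  if (length(miss)) stopf("events lack column(s): %s", paste(miss, collapse = ", "))
  if (any(is.na(events$umi) | events$umi == "")) stopf("events with missing UMI")
  if (any(events$pos < 0)) stopf("negative event positions")
  if (!all(events$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  invisible(events)
}

#' Call TFE regions from pooled deduplicated 5'-end events
#'
#' Per (chromosome, strand), event positions are single-linkage clustered:
#' positions at most `max_gap` bp apart join one cluster. Clusters whose
#' pooled event count (over all samples) is below `min_count` are dropped.
#' Each surviving cluster becomes a TFE region `[min pos, max pos + 1)` with
#' a summit at the modal event position; modal ties resolve to the
#' farthest-5' mode (leftmost on "+", rightmost on "-"). Identical event
#' sets on opposite strands yield two separate TFEs. TFE ids are ordinals in
#' (chrom, start, strand) order.
#'
#' @param events deduplicated events (see [dedup_events()]).
#' @param min_count minimum pooled event count to keep a region (default 2).
#' @param max_gap maximum bp gap joining neighbouring events (default 60).
#' @return data.frame of class `tfe_regions`: `tfe_id`, `chrom`, `start`,
#'   `end`, `strand`, `summit`, `count`, `is_spikein`. Empty input gives an
#'   empty data.frame.
#' @export
call_tfes <- function(events, min_count = 2L, max_gap = 60L) {
  if (min_count < 1L) stopf("min_count must be >= 1")
  if (max_gap < 0L) stopf("max_gap must be >= 0")
  check_events(events)
  if (nrow(events) == 0L) {
    return(empty_regions())
  }
  grp <- paste(events$chrom, events$strand, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(events)), grp), function(idx) {
    pos <- sort(events$pos[idx])
    cl <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
    sp <- split(pos, cl)
    keep <- vapply(sp, length, integer(1)) >= min_count
    sp <- sp[keep]
    if (!length(sp)) return(NULL)
    strand <- events$strand[idx[1]]
    data.frame(
      chrom = events$chrom[idx[1]],
      start = vapply(sp, min, numeric(1)),
      end = vapply(sp, max, numeric(1)) + 1,
      strand = strand,
      summit = vapply(sp, modal_position, numeric(1), strand = strand),
      count = vapply(sp, length, integer(1)),
      is_spikein = events$is_spikein[idx[1]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty_regions())
  out <- out[order(out$chrom, out$start, out$strand), ]
  out$tfe_id <- sprintf("TFE%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  structure(out[, c("tfe_id", "chrom", "start", "end", "strand", "summit",
                    "count", "is_spikein")],
            class = c("tfe_regions", "data.frame"))
}

empty_regions <- function() {
  structure(data.frame(tfe_id = character(0), chrom = character(0),
                       start = numeric(0), end = numeric(0),
                       strand = character(0), summit = numeric(0),
                       count = integer(0), is_spikein = logical(0)),
            class = c("tfe_regions", "data.frame"))
}

# Modal position; ties go to the farthest-5' mode for the strand.
modal_position <- function(pos, strand) {
  tab <- table(pos)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  if (strand == "+") min(modes) else max(modes)
}

#' Count deduplicated events per TFE region and sample
#'
#' Cell (t, s) holds the number of deduplicated events of sample s whose
#' strand matches region t and whose position lies in t's half-open
#' interval. Events falling in no region are tallied in the `unassigned`
#' attribute (conservation: matrix total + unassigned = number of events).
#'
#' @param regions a [call_tfes()] result (regions disjoint per strand).
#' @param events deduplicated events.
#' @param samples sample sheet data.frame with `sample_id`, `stage`.
#' @return object of class `tfe_matrix`: list with integer matrix `counts`
#'   (TFE x sample), `regions`, `samples`, and attribute-like field
#'   `unassigned`.
#' @export
build_count_matrix <- function(regions, events, samples) {
  check_events(events)
  check_samples(samples)
  extra <- setdiff(unique(events$sample_id), samples$sample_id)
  if (length(extra)) {
    stopf("events carry sample(s) absent from the sample sheet: %s",
          paste(extra, collapse = ", "))
  }
  region_of <- rep(NA_integer_, nrow(events))
  grp_e <- paste(events$chrom, events$strand, sep = "\r")
  grp_r <- paste(regions$chrom, regions$strand, sep = "\r")
  for (g in unique(grp_e)) {
    ir <- which(grp_r == g)
    if (!length(ir)) next
    ir <- ir[order(regions$start[ir])]
    ie <- which(grp_e == g)
    k <- findInterval(events$pos[ie], regions$start[ir])
    hit <- k >= 1L & events$pos[ie] < regions$end[ir][pmax(k, 1L)]
    region_of[ie[hit]] <- ir[k[hit]]
  }
  assigned <- !is.na(region_of)
  counts <- table(factor(region_of[assigned], levels = seq_len(nrow(regions))),
                  factor(events$sample_id[assigned], levels = samples$sample_id))
  counts <- matrix(as.integer(counts), nrow(regions), nrow(samples),
                   dimnames = list(regions$tfe_id, samples$sample_id))
  structure(list(counts = counts, regions = as.data.frame(regions),
                 samples = samples, unassigned = sum(!assigned)),
            class = "tfe_matrix")
}

check_samples <- function(samples) {
  if (!all(c("sample_id", "stage") %in% names(samples))) {
    stopf("sample sheet needs columns sample_id and stage")
  }
  if (anyDuplicated(samples$sample_id)) stopf("duplicated sample ids")
  invisible(samples)
}

#' @export
print.tfe_matrix <- function(x, ...) {
  cat(sprintf("tfe_matrix: %d TFEs (%d spike-in) x %d samples, %d stages; %d unassigned events\n",
              nrow(x$counts), sum(x$regions$is_spikein), ncol(x$counts),
              length(unique(x$samples$stage)), x$unassigned))
  invisible(x)
}
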