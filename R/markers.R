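# Stage medians, stage-exclusive marker calling, row scaling and k-means
# temporal clustering.

#' Per-stage median of log2 normalized values
#'
#' Medians are taken over the samples of each stage; sentinel values
#' (`-Inf`, zero counts) participate as minus infinity, so a stage whose
#' lower middle value is a sentinel gets a sentinel median.
#'
#' @param norm a `tfe_norm`.
#' @param stages ordered stage labels (default sheet order).
#' @return TFE x stage matrix of medians.
#' @export
stage_medians <- function(norm, stages = NULL) {
  stopifnot(inherits(norm, "tfe_norm"))
  if (is.null(stages)) stages <- unique(norm$samples$stage)
  out <- matrix(NA_real_, nrow(norm$values), length(stages),
                dimnames = list(norm$regions$tfe_id, stages))
  for (st in stages) {
    cols <- norm$samples$sample_id[norm$samples$stage == st]
    if (!length(cols)) stopf("stage '%s' has no samples", st)
    out[, st] <- apply(norm$values[, cols, drop = FALSE], 1, stats::median)
  }
  out
}

#' Call stage-exclusive marker TFEs
#'
#' A TFE is a marker of stage S when (i) its median log2 normalized value
#' exceeds `expr_threshold` in S (strictly) and is strictly below the
#' threshold in every other stage, and (ii) it is significantly
#' upregulated (adjusted p < alpha, log2 fold change > `lfc_threshold`)
#' against the stage immediately preceding S. The first stage has no
#' predecessor and is instead tested against the second stage
#' (upregulation there shows as a significant negative fold change in the
#' second-vs-first contrast). Exclusivity makes marker sets pairwise
#' disjoint by construction.
#'
#' @param medians a [stage_medians()] matrix (all stages as columns).
#' @param de_tables named list of `de_table`s as from
#'   [run_consecutive_de()].
#' @param stages stages to call markers for (default `c("GV", "MII",
#'   "16c", "Blc")`, the stages with distinctive profiles; any subset of
#'   the median columns is accepted).
#' @param expr_threshold expressed/not-expressed cutoff on the log2
#'   normalized scale (default -10, about nine molecule copies at the
#'   default spike-in input).
#' @param lfc_threshold minimum log2 fold change (default 3).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param stage_order full developmental stage order (default the median
#'   columns).
#' @return object of class `marker_set`: named list per stage with
#'   `tfe_id` and `contrast`.
#' @export
call_stage_markers <- function(medians, de_tables,
                               stages = c("GV", "MII", "16c", "Blc"),
                               expr_threshold = -10, lfc_threshold = 3,
                               alpha = 0.05, stage_order = colnames(medians)) {
  stages <- intersect(stage_order, stages)
  if (!length(stages)) stopf("no requested stage present in the median matrix")
  out <- lapply(stages, function(st) {
    i <- match(st, stage_order)
    if (i == 1L) {
      contrast <- paste(stage_order[2], st, sep = "|")
      tab <- de_tables[[contrast]]
      if (is.null(tab)) stopf("missing DE contrast '%s'", contrast)
      de_ok <- tab$tfe_id[tab$padj < alpha & tab$lfc < -lfc_threshold]
    } else {
      contrast <- paste(st, stage_order[i - 1L], sep = "|")
      tab <- de_tables[[contrast]]
      if (is.null(tab)) stopf("missing DE contrast '%s'", contrast)
      de_ok <- tab$tfe_id[tab$padj < alpha & tab$lfc > lfc_threshold]
    }
    excl <- medians[, st] > expr_threshold &
      rowSums(medians[, setdiff(stage_order, st), drop = FALSE] >=
                expr_threshold) == 0L
    list(tfe_id = intersect(rownames(medians)[excl], de_ok),
         contrast = contrast)
  })
  names(out) <- stages
  structure(out, class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("Stage-exclusive marker TFEs:\n")
  for (st in names(x)) {
    cat(sprintf("  %-4s %5d markers (contrast %s)\n", st,
                length(x[[st]]$tfe_id), x[[st]]$contrast))
  }
  invisible(x)
}

#' Row z-scoring
#'
#' Subtracts the row mean and divides by the row sample standard
#' deviation. Constant rows become all-zero with a warning.
#'
#' @param m numeric matrix with >= 2 finite values per row.
#' @return scaled matrix of the same shape.
#' @export
scale_rows <- function(m) {
  if (any(rowSums(is.finite(m)) < 2L)) stopf("each row needs >= 2 finite values")
  mu <- rowMeans(m)
  sd <- sqrt(row_vars(m))
  flat <- sd == 0
  if (any(flat)) {
    warnf("%d constant row(s) scaled to zero", sum(flat))
    sd[flat] <- 1
  }
  (m - mu) / sd
}

#' Seeded restarted k-means for temporal profiles
#'
#' Lloyd's algorithm from random row-sampled centers, restarted
#' `restarts` times from one seeded RNG stream; the assignment with the
#' lowest total within-cluster sum of squares (WCSS) is kept. An empty
#' cluster is repaired by reseeding its center at the point farthest from
#' its current center. Deterministic for a fixed seed.
#'
#' @param m numeric matrix (rows are profiles, e.g. row-scaled values).
#' @param k number of clusters (default 6).
#' @param restarts random restarts (default 1000).
#' @param max_iter Lloyd iterations per restart (default 20).
#' @param seed RNG seed.
#' @return object of class `tfe_clusters`: `cluster` (named labels 1..k),
#'   `centers` (k x ncol), `wcss`, `restarts`, `wcss_trace` (per-iteration
#'   WCSS of the winning restart).
#' @export
kmeans_profiles <- function(m, k = 6L, restarts = 1000L, max_iter = 20L,
                            seed = 1L) {
  n <- nrow(m)
  if (k > n) stopf("k (%d) exceeds number of rows (%d)", k, n)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- m[sample.int(n, k), , drop = FALSE]
      run <- lloyd(m, centers, max_iter)
      if (is.null(best) || run$wcss < best$wcss) best <- run
    }
    names(best$cluster) <- rownames(m)
    structure(list(cluster = best$cluster, centers = best$centers,
                   wcss = best$wcss, restarts = restarts,
                   wcss_trace = best$trace),
              class = "tfe_clusters")
  })
}

lloyd <- function(m, centers, max_iter) {
  k <- nrow(centers)
  rs <- rowSums(m^2)
  trace <- numeric(0)
  cl <- NULL
  for (it in seq_len(max_iter)) {
    d <- outer(rs, rowSums(centers^2), "+") - 2 * m %*% t(centers)
    new_cl <- max.col(-d, ties.method = "first")
    # repair empty clusters from the globally farthest point
    for (j in which(tabulate(new_cl, k) == 0L)) {
      far <- which.max(d[cbind(seq_len(nrow(m)), new_cl)])
      centers[j, ] <- m[far, ]
      new_cl[far] <- j
      d[, j] <- rs + sum(centers[j, ]^2) - 2 * m %*% centers[j, ]
    }
    wcss <- sum(d[cbind(seq_along(new_cl), new_cl)])
    trace <- c(trace, max(wcss, 0))
    if (!is.null(cl) && all(new_cl == cl)) break
    cl <- new_cl
    for (j in seq_len(k)) centers[j, ] <- colMeans(m[cl == j, , drop = FALSE])
  }
  # final WCSS against the final centers
  d <- outer(rs, rowSums(centers^2), "+") - 2 * m %*% t(centers)
  wcss <- max(sum(d[cbind(seq_along(cl), cl)]), 0)
  list(cluster = cl, centers = centers, wcss = wcss, trace = trace)
}

#' @export
print.tfe_clusters <- function(x, ...) {
  cat(sprintf("k-means profiles: k = %d, %d rows, WCSS = %.2f (best of %d restarts)\n",
              nrow(x$centers), length(x$cluster), x$wcss, x$restarts))
  print(table(cluster = x$cluster))
  invisible(x)
}
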