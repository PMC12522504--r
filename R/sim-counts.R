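#' Simulate per-gene molecule counts across staged samples
#'
#' Assigns each transcription unit an expression class and draws molecule
#' counts per sample. Maternal genes decay multiplicatively after the MII
#' stage (two major waves by default), zygotic genes switch on at the EGA
#' stage (16-cell by default), housekeeping and unannotated units are flat,
#' and marker genes are expressed in exactly one stage. Per-stage totals are
#' rescaled so that expected total molecules follow
#' `config$stage_content_multiplier` relative to the first stage. Counts are
#' negative binomial around the stage mean with biological CV^2 equal to
#' `config$overdispersion` (Poisson when 0).
#'
#' @param reference a [generate_reference()] object.
#' @param truth_seed seed for the expression program and count draws;
#'   defaults to `config$seed + 1`.
#' @return list of class `sim_counts`: `molecules` (integer unit x sample
#'   matrix), `samples` (sample sheet data.frame with `sample_id`, `stage`),
#'   and `truth` (ground truth: `classes` per unit, `mean_molecules`
#'   unit x stage matrix, `content_ratio` per stage, `spike_input`).
#' @export
simulate_counts <- function(reference, truth_seed = NULL) {
  stopifnot(inherits(reference, "sim_reference"))
  cfg <- reference$config
  if (is.null(truth_seed)) truth_seed <- cfg$seed + 1L
  with_seed(truth_seed, {
    units <- reference$units
    n <- nrow(units)
    stages <- cfg$stages
    ns <- length(stages)

    cls <- assign_classes(units, cfg)
    base <- stats::rlnorm(n, meanlog = log(cfg$mean_abundance),
                          sdlog = cfg$abundance_sdlog)
    base[grepl("^marker:", cls)] <- cfg$marker_molecules

    prof <- matrix(0, n, ns, dimnames = list(units$unit_id, stages))
    decay <- cumprod(cfg$maternal_decay)
    ega <- ega_stage_index(stages)
    zyg <- c(rep(0.02, ega - 1L), rep(1, ns - ega + 1L))
    for (i in seq_len(n)) {
      prof[i, ] <- switch(sub(":.*", "", cls[i]),
        maternal = decay,
        zygotic = zyg,
        housekeeping = rep(1, ns),
        unannotated = rep(1, ns),
        marker = as.numeric(stages == sub("^marker:", "", cls[i]))
      )
    }
    mu <- prof * base

    # enforce the configured per-stage total poly(A) content
    tot <- colSums(mu)
    scale <- (tot[1] * cfg$stage_content_multiplier / cfg$stage_content_multiplier[1]) / tot
    mu <- sweep(mu, 2, scale, "*")

    samples <- data.frame(
      sample_id = paste0(rep(stages, each = cfg$samples_per_stage), "_r",
                         rep(seq_len(cfg$samples_per_stage), ns)),
      stage = rep(stages, each = cfg$samples_per_stage),
      stringsAsFactors = FALSE
    )
    mu_s <- mu[, samples$stage, drop = FALSE]
    counts <- draw_counts(mu_s, cfg$overdispersion)
    dimnames(counts) <- list(units$unit_id, samples$sample_id)

    truth <- list(
      classes = data.frame(unit_id = units$unit_id, class = cls,
                           chrom = units$chrom, strand = units$strand,
                           tss = units$tss, annotated = units$annotated,
                           stringsAsFactors = FALSE),
      mean_molecules = mu,
      content_ratio = cfg$stage_content_multiplier / cfg$stage_content_multiplier[1],
      spike_input = reference$spikeins[, c("name", "molecules")]
    )
    structure(list(molecules = counts, samples = samples, truth = truth),
              class = "sim_counts")
  })
}

# The EGA stage: "16c" when present, otherwise the second-to-last stage.
ega_stage_index <- function(stages) {
  i <- match("16c", stages)
  if (is.na(i)) i <- max(2L, length(stages) - 1L)
  i
}

assign_classes <- function(units, cfg) {
  n <- nrow(units)
  cls <- rep(NA_character_, n)
  cls[!units$annotated] <- "unannotated"
  ann <- which(units$annotated)
  n_mark <- cfg$n_markers_per_stage * length(cfg$stages)
  if (n_mark > length(ann)) {
    stopf("not enough annotated genes for %d markers", n_mark)
  }
  mark_idx <- sample(ann, n_mark)
  cls[mark_idx] <- paste0("marker:", rep(cfg$stages, each = cfg$n_markers_per_stage))
  rest <- setdiff(ann, mark_idx)
  pr <- c(maternal = cfg$maternal_fraction, zygotic = cfg$zygotic_fraction,
          housekeeping = cfg$housekeeping_fraction)
  if (sum(pr) < 1) pr["housekeeping"] <- pr["housekeeping"] + (1 - sum(pr))
  nm <- round(pr / sum(pr) * length(rest))
  nm[3] <- length(rest) - sum(nm[1:2])
  cls[rest] <- sample(rep(names(pr), times = nm))
  cls
}

draw_counts <- function(mu, cv2_bio) {
  k <- matrix(0L, nrow(mu), ncol(mu))
  pos <- mu > 0
  if (cv2_bio == 0) {
    k[pos] <- stats::rpois(sum(pos), mu[pos])
  } else {
    k[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / cv2_bio)
  }
  k
}
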