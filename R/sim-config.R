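#' Configuration of the synthetic 5'-end sequencing experiment
#'
#' Builds and validates the configuration object consumed by
#' [generate_reference()], [simulate_counts()] and [simulate_alignments()].
#' The defaults describe a miniature experiment mimicking the
#' maternal-to-zygotic transition (MZT) of oocyte/preimplantation-embryo
#' transcriptomes: seven ordered developmental stages, maternal transcript
#' decay with two major degradation waves (after fertilization and at the
#' 16-cell stage), a zygotic transcription burst at the 16-cell stage
#' (embryonic genome activation, EGA), stage-exclusive marker genes,
#' transcription from unannotated TSSs, and spike-in RNA at a fixed molecule
#' input per sample.
#'
#' @param seed integer seed; all generator functions are deterministic given
#'   the config (derived seeds are used per step).
#' @param n_chromosomes,chromosome_length genome shape (bp).
#' @param n_coding_genes,n_noncoding_genes annotated gene counts.
#' @param n_spikeins number of spike-in reference sequences.
#' @param spikein_molecules_per_sample total spike-in molecules loaded per
#'   sample (M). The default 9216 makes a log2 normalized value of -10
#'   correspond to exactly 9 molecule copies (see [value_to_copies()]).
#' @param stages ordered character vector of stage labels.
#' @param samples_per_stage biological replicates per stage.
#' @param capture_efficiency fraction of molecules converted to a
#'   deduplicated event (eta).
#' @param pcr_duplicate_rate expected extra reads per captured molecule.
#' @param tss_jitter_sd SD (bp) of the positional jitter of read 5' ends
#'   around the true TSS.
#' @param maternal_fraction,zygotic_fraction,housekeeping_fraction class
#'   fractions among non-marker genes (must sum to <= 1; any remainder is
#'   assigned to the housekeeping class).
#' @param n_markers_per_stage stage-exclusive marker genes planted per stage.
#' @param stage_content_multiplier per-stage scalar on total poly(A) RNA
#'   molecules relative to the first stage; the default declines from the
#'   2-cell stage to a minimum at the 16-cell stage and recovers at the
#'   blastocyst, the qualitative shape of bulk poly(A) content across the MZT.
#' @param maternal_decay per-stage multiplicative decay factors applied
#'   cumulatively to maternal gene means; the defaults put the two largest
#'   drops at the 2-cell and 16-cell stages.
#' @param unannotated_tss_fraction fraction of transcription units placed in
#'   the genome but left out of the annotation (unannotated TSSs).
#' @param overdispersion biological squared coefficient of variation of
#'   molecule counts around stage means (0 gives Poisson molecule counts).
#' @param mean_abundance,abundance_sdlog log-normal molecule abundance of a
#'   gene at full activity (median `mean_abundance` molecules).
#' @param marker_molecules mean molecules of a marker gene in its own stage.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       chromosome_length = 1.6e6,
                       n_coding_genes = 1400L,
                       n_noncoding_genes = 600L,
                       n_spikeins = 50L,
                       spikein_molecules_per_sample = 9216,
                       stages = c("GV", "MII", "2c", "4c", "8c", "16c", "Blc"),
                       samples_per_stage = 4L,
                       capture_efficiency = 0.2,
                       pcr_duplicate_rate = 1,
                       tss_jitter_sd = 5,
                       maternal_fraction = 0.45,
                       zygotic_fraction = 0.2,
                       housekeeping_fraction = 0.35,
                       n_markers_per_stage = 20L,
                       stage_content_multiplier = c(1, 1, 0.8, 0.65, 0.55, 0.35, 0.75),
                       maternal_decay = c(1, 1, 0.35, 0.9, 0.9, 0.5, 1),
                       unannotated_tss_fraction = 0.1,
                       overdispersion = 0.1,
                       mean_abundance = 30,
                       abundance_sdlog = 1,
                       marker_molecules = 200) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.numeric(chromosome_length),
    n_coding_genes = as.integer(n_coding_genes),
    n_noncoding_genes = as.integer(n_noncoding_genes),
    n_spikeins = as.integer(n_spikeins),
    spikein_molecules_per_sample = as.numeric(spikein_molecules_per_sample),
    stages = as.character(stages),
    samples_per_stage = as.integer(samples_per_stage),
    capture_efficiency = capture_efficiency,
    pcr_duplicate_rate = pcr_duplicate_rate,
    tss_jitter_sd = tss_jitter_sd,
    maternal_fraction = maternal_fraction,
    zygotic_fraction = zygotic_fraction,
    housekeeping_fraction = housekeeping_fraction,
    n_markers_per_stage = as.integer(n_markers_per_stage),
    stage_content_multiplier = stage_content_multiplier,
    maternal_decay = maternal_decay,
    unannotated_tss_fraction = unannotated_tss_fraction,
    overdispersion = overdispersion,
    mean_abundance = mean_abundance,
    abundance_sdlog = abundance_sdlog,
    marker_molecules = marker_molecules
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  ns <- length(cfg$stages)
  if (ns < 1L || anyDuplicated(cfg$stages)) {
    stopf("stages must be a nonempty ordered list of distinct labels")
  }
  for (f in c("n_chromosomes", "n_spikeins", "samples_per_stage")) {
    if (!is_count(cfg[[f]])) stopf("%s must be a positive integer", f)
  }
  if (cfg$n_coding_genes < 0L || cfg$n_noncoding_genes < 0L) {
    stopf("gene counts must be non-negative")
  }
  if (cfg$n_coding_genes + cfg$n_noncoding_genes < 1L) {
    stopf("at least one gene is required")
  }
  if (!(cfg$capture_efficiency > 0 && cfg$capture_efficiency <= 1)) {
    stopf("capture_efficiency must be in (0, 1]")
  }
  if (cfg$pcr_duplicate_rate < 0) stopf("pcr_duplicate_rate must be >= 0")
  if (cfg$tss_jitter_sd < 0) stopf("tss_jitter_sd must be >= 0")
  if (cfg$overdispersion < 0) stopf("overdispersion must be >= 0")
  if (cfg$spikein_molecules_per_sample <= 0) {
    stopf("spikein_molecules_per_sample must be > 0")
  }
  fr <- c(cfg$maternal_fraction, cfg$zygotic_fraction, cfg$housekeeping_fraction,
          cfg$unannotated_tss_fraction)
  if (!all(vapply(fr, is_fraction, logical(1)))) {
    stopf("all class fractions must lie in [0, 1]")
  }
  if (cfg$maternal_fraction + cfg$zygotic_fraction + cfg$housekeeping_fraction > 1 + 1e-12) {
    stopf("maternal + zygotic + housekeeping fractions must sum to <= 1")
  }
  for (f in c("stage_content_multiplier", "maternal_decay")) {
    v <- cfg[[f]]
    if (length(v) != ns || any(!is.finite(v)) || any(v <= 0)) {
      stopf("%s must hold one positive value per stage", f)
    }
  }
  if (cfg$n_markers_per_stage < 0L) stopf("n_markers_per_stage must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic 5'-end experiment config\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp; %d coding + %d noncoding genes, %d spike-ins\n",
              x$n_chromosomes, format(x$chromosome_length, big.mark = ","),
              x$n_coding_genes, x$n_noncoding_genes, x$n_spikeins))
  cat(sprintf("  stages: %s (%d samples each)\n",
              paste(x$stages, collapse = " > "), x$samples_per_stage))
  cat(sprintf("  capture %.2f, PCR duplicate rate %.2f, TSS jitter sd %.1f bp, CV2_bio %.2f\n",
              x$capture_efficiency, x$pcr_duplicate_rate, x$tss_jitter_sd,
              x$overdispersion))
  invisible(x)
}
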