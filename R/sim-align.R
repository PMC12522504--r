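#' Simulate 5'-end alignment events with UMIs and PCR duplicates
#'
#' Each molecule is captured with probability `capture_efficiency`; a
#' captured molecule emits one primary event at the unit's true TSS plus
#' Normal positional jitter on the correct strand, tagged with a random UMI.
#' PCR duplication replicates whole (position, UMI, sample) tuples at the
#' configured expected rate. Spike-in molecules are handled identically on
#' their dedicated reference sequences.
#'
#' @param counts a [simulate_counts()] object.
#' @param reference the matching [generate_reference()] object.
#' @param align_seed seed; defaults to `config$seed + 2`.
#' @return list of class `sim_alignments` with `events` (the PCR-duplicated
#'   stream: data.frame chrom, pos, strand, umi, sample_id, is_spikein,
#'   read_id) and `predup` (the pre-duplication molecule-level stream).
#' @export
simulate_alignments <- function(counts, reference, align_seed = NULL) {
  stopifnot(inherits(counts, "sim_counts"), inherits(reference, "sim_reference"))
  cfg <- reference$config
  if (is.null(align_seed)) align_seed <- cfg$seed + 2L
  with_seed(align_seed, {
    units <- reference$units
    mol <- counts$molecules
    eta <- cfg$capture_efficiency

    # genomic units: binomial capture of integer molecules
    cap <- matrix(stats::rbinom(length(mol), size = as.vector(mol), prob = eta),
                  nrow(mol), ncol(mol))
    ui <- rep(rep(seq_len(nrow(mol)), ncol(mol)), as.vector(cap))
    si <- rep(rep(seq_len(ncol(mol)), each = nrow(mol)), as.vector(cap))
    gen <- data.frame(
      chrom = units$chrom[ui],
      pos = jitter_pos(units$tss[ui], cfg$tss_jitter_sd,
                       cfg$chromosome_length),
      strand = units$strand[ui],
      sample_id = counts$samples$sample_id[si],
      is_spikein = FALSE,
      stringsAsFactors = FALSE
    )

    # spike-ins: same fixed molecule input in every sample
    sp <- reference$spikeins
    nsamp <- nrow(counts$samples)
    spcap <- matrix(stats::rbinom(nrow(sp) * nsamp,
                                  size = rep(sp$molecules, nsamp), prob = eta),
                    nrow(sp), nsamp)
    pi <- rep(rep(seq_len(nrow(sp)), nsamp), as.vector(spcap))
    psi <- rep(rep(seq_len(nsamp), each = nrow(sp)), as.vector(spcap))
    spk <- data.frame(
      chrom = sp$name[pi],
      pos = jitter_pos(sp$tss[pi], cfg$tss_jitter_sd, sp$length[pi]),
      strand = "+",
      sample_id = counts$samples$sample_id[psi],
      is_spikein = TRUE,
      stringsAsFactors = FALSE
    )

    predup <- rbind(gen, spk)
    predup$umi <- random_umis(nrow(predup))
    extra <- stats::rpois(nrow(predup), cfg$pcr_duplicate_rate)
    events <- predup[rep(seq_len(nrow(predup)), 1L + extra), , drop = FALSE]
    events$read_id <- sprintf("read%08d", seq_len(nrow(events)))
    rownames(events) <- rownames(predup) <- NULL
    cols <- c("chrom", "pos", "strand", "umi", "sample_id", "is_spikein")
    structure(list(events = events[, c(cols, "read_id")],
                   predup = predup[, cols]),
              class = "sim_alignments")
  })
}

jitter_pos <- function(tss, sd, len) {
  p <- tss + if (sd > 0) round(stats::rnorm(length(tss), 0, sd)) else 0
  pmin(pmax(p, 0), len - 1)
}

#' Run the full generator: reference, counts and alignment events
#'
#' Convenience wrapper chaining [generate_reference()], [simulate_counts()]
#' and [simulate_alignments()] with seeds derived from `config$seed`.
#' @param config a [sim_config()].
#' @return list of class `sim_experiment` with `reference`, `counts`,
#'   `alignments`.
#' @export
simulate_experiment <- function(config) {
  reference <- generate_reference(config)
  counts <- simulate_counts(reference)
  alignments <- simulate_alignments(counts, reference)
  structure(list(reference = reference, counts = counts,
                 alignments = alignments),
            class = "sim_experiment")
}
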