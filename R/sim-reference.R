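#' Generate the synthetic genome, gene models and spike-in manifest
#'
#' Places non-overlapping transcription units on both strands of a random
#' genome. Every coding gene has >= 2 exons with a CDS strictly inside the
#' exon span and nonempty 5'/3' UTRs; noncoding genes have >= 2 exons. A
#' configurable fraction of units is expressed but omitted from the
#' annotation (unannotated TSSs). Spike-in references carry a reserved name
#' prefix and a fixed molecule input per sample.
#'
#' @param config a [sim_config()] object.
#' @param spikein_prefix reserved reference-name prefix for spike-ins.
#' @return A list of class `sim_reference` with elements
#'   `genome` (a [Biostrings::DNAStringSet] including spike-in sequences),
#'   `models` (a `gene_models` object for the annotated units only),
#'   `units` (data.frame of all transcription units incl. unannotated ones),
#'   `unit_exons` (data.frame of exons for all units, 0-based half-open),
#'   `spikeins` (manifest: name, length, tss, molecules per sample) and the
#'   `config`.
#' @export
generate_reference <- function(config, spikein_prefix = "spike_") {
  validate_sim_config(config)
  with_seed(config$seed, {
    n_ann <- config$n_coding_genes + config$n_noncoding_genes
    n_unann <- round(config$unannotated_tss_fraction * n_ann)
    n_units <- n_ann + n_unann

    biotype <- c(rep("coding", config$n_coding_genes),
                 rep("noncoding", config$n_noncoding_genes),
                 rep("noncoding", n_unann))
    annotated <- c(rep(TRUE, n_ann), rep(FALSE, n_unann))
    ord <- sample.int(n_units)
    biotype <- biotype[ord]
    annotated <- annotated[ord]

    units <- place_units(n_units, biotype, annotated, config)
    exons <- units$exons
    units <- units$units
    units$unit_id <- sprintf("gene%05d", seq_len(n_units))
    exons$unit_id <- units$unit_id[exons$unit_idx]
    exons$unit_idx <- NULL

    chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
    genome_seqs <- vapply(chrom_names, function(ch) {
      random_dna(config$chromosome_length)
    }, character(1))

    # spike-in mix spans ~3 decades like a typical dilution series, integer
    # molecule counts summing exactly to M (largest-remainder rounding)
    sp_names <- sprintf("%s%02d", spikein_prefix, seq_len(config$n_spikeins))
    w <- 2^seq(0, 10, length.out = config$n_spikeins)
    target <- w / sum(w) * config$spikein_molecules_per_sample
    mol <- floor(target)
    rem <- config$spikein_molecules_per_sample - sum(mol)
    if (rem > 0) {
      bump <- order(target - mol, decreasing = TRUE)[seq_len(rem)]
      mol[bump] <- mol[bump] + 1
    }
    sp_len <- 1000L
    sp_seqs <- vapply(sp_names, function(nm) random_dna(sp_len), character(1))
    spikeins <- data.frame(name = sp_names, length = sp_len, tss = 50L,
                           strand = "+", molecules = mol,
                           stringsAsFactors = FALSE)

    genome <- Biostrings::DNAStringSet(c(genome_seqs, sp_seqs))
    names(genome) <- c(chrom_names, sp_names)

    models <- units_to_gene_models(units[units$annotated, , drop = FALSE],
                                   exons[exons$unit_id %in%
                                           units$unit_id[units$annotated], ,
                                         drop = FALSE])

    structure(list(genome = genome, models = models, units = units,
                   unit_exons = exons, spikeins = spikeins,
                   spikein_prefix = spikein_prefix, config = config),
              class = "sim_reference")
  })
}

# Sequentially fill chromosomes with gene bodies separated by gaps large
# enough that upstream windows (500 bp class boundary, 400 bp promoters) of
# neighbouring units do not run into each other.
place_units <- function(n_units, biotype, annotated, config) {
  margin <- 1000
  gap_range <- c(700L, 1500L)
  chrom <- integer(n_units)
  res_units <- vector("list", n_units)
  res_exons <- vector("list", n_units)
  ch <- 1L
  cursor <- margin
  for (i in seq_len(n_units)) {
    repeat {
      gap <- sample(seq(gap_range[1], gap_range[2]), 1L)
      start <- cursor + gap
      st <- sample(c("+", "-"), 1L)
      g <- random_gene_structure(start, st, biotype[i] == "coding")
      if (g$span_end <= config$chromosome_length - margin) {
        cursor <- g$span_end
        chrom[i] <- ch
        break
      }
      ch <- ch + 1L
      cursor <- margin
      if (ch > config$n_chromosomes) {
        stopf(paste("genome too small: placed %d of %d units;",
                    "increase chromosome_length or n_chromosomes"),
              i - 1L, n_units)
      }
    }
    res_units[[i]] <- data.frame(
      chrom = sprintf("chr%d", chrom[i]), strand = st, biotype = biotype[i],
      annotated = annotated[i], span_start = g$span_start,
      span_end = g$span_end, tss = g$tss,
      cds_start = ifelse(is.null(g$cds), NA_real_, g$cds[1]),
      cds_end = ifelse(is.null(g$cds), NA_real_, g$cds[2]),
      stringsAsFactors = FALSE
    )
    res_exons[[i]] <- data.frame(unit_idx = i, start = g$exons$start,
                                 end = g$exons$end)
  }
  list(units = do.call(rbind, res_units), exons = do.call(rbind, res_exons))
}

# One random multi-exon gene starting at `start` (0-based). Coding genes get
# a CDS strictly inside the exon span with nonempty UTRs on both sides.
random_gene_structure <- function(start, strand, coding) {
  n_ex <- sample(2:4, 1L)
  widths <- sample(80:300, n_ex, replace = TRUE)
  introns <- if (n_ex > 1L) sample(100:800, n_ex - 1L, replace = TRUE) else integer(0)
  starts <- start + cumsum(c(0L, widths[-n_ex] + introns))
  ends <- starts + widths
  exons <- data.frame(start = starts, end = ends)
  span <- c(starts[1], ends[n_ex])
  tss <- if (strand == "+") span[1] else span[2] - 1
  cds <- NULL
  if (coding) {
    L <- sum(widths)
    utr5 <- sample(20:min(120, L - 60), 1L)
    utr3 <- sample(20:min(120, L - utr5 - 20), 1L)
    g1 <- tx_to_genome(exons, strand, utr5)
    g2 <- tx_to_genome(exons, strand, L - utr3 - 1L)
    cds <- c(min(g1, g2), max(g1, g2) + 1)
  }
  list(span_start = span[1], span_end = span[2], tss = tss,
       exons = exons, cds = cds)
}

# Map a 0-based transcript coordinate to its genomic base, strand-aware.
tx_to_genome <- function(exons, strand, t) {
  widths <- exons$end - exons$start
  if (strand == "-") {
    ord <- order(exons$start, decreasing = TRUE)
    exons <- exons[ord, , drop = FALSE]
    widths <- widths[ord]
  }
  cum <- cumsum(widths)
  i <- which(t < cum)[1]
  if (is.na(i)) stopf("transcript coordinate %d beyond transcript end", t)
  off <- t - c(0, cum)[i]
  if (strand == "+") exons$start[i] + off else exons$end[i] - 1 - off
}

units_to_gene_models <- function(units, exons) {
  genes <- data.frame(
    gene_id = units$unit_id, chrom = units$chrom, strand = units$strand,
    biotype = units$biotype, tss = units$tss,
    span_start = units$span_start, span_end = units$span_end,
    cds_start = units$cds_start, cds_end = units$cds_end,
    stringsAsFactors = FALSE
  )
  ex <- exons[, c("unit_id", "start", "end")]
  names(ex)[1] <- "gene_id"
  ex <- ex[order(match(ex$gene_id, genes$gene_id), ex$start), ]
  rownames(genes) <- rownames(ex) <- NULL
  structure(list(genes = genes, exons = ex), class = "gene_models")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf("Synthetic reference: %d sequences (%d chromosomes + %d spike-ins)\n",
              length(x$genome), x$config$n_chromosomes, nrow(x$spikeins)))
  cat(sprintf("  %d transcription units (%d annotated, %d unannotated)\n",
              nrow(x$units), sum(x$units$annotated), sum(!x$units$annotated)))
  invisible(x)
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d coding, %d noncoding), %d exons\n",
              nrow(x$genes), sum(x$genes$biotype == "coding"),
              sum(x$genes$biotype == "noncoding"), nrow(x$exons)))
  invisible(x)
}
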