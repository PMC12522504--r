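# Readers and writers for external formats. Internal coordinates are
# 0-based half-open throughout; GTF (1-based closed) is converted at the
# boundary. Standard formats go through rtracklayer / Biostrings.

#' Read gene models from a GTF file
#'
#' Parses exon (and CDS) features and assembles one gene-level model per
#' gene: the longest transcript by exonic length, ties broken by
#' lexicographic transcript_id. Coordinates are converted from GTF 1-based
#' closed to 0-based half-open. Genes with a CDS outside their exon union or
#' with missing strand are rejected with a message listing their ids.
#'
#' @param path GTF file with attributes `gene_id`, `transcript_id` and
#'   (optionally) `gene_biotype`; genes without CDS features are noncoding.
#' @return a `gene_models` object: list of `genes` (gene_id, chrom, strand,
#'   biotype, tss, span_start, span_end, cds_start, cds_end) and `exons`
#'   (gene_id, start, end), 0-based half-open.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    biotype = if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) {
      gr$gene_biotype
    } else {
      NA_character_
    },
    stringsAsFactors = FALSE
  )
  rejected <- character(0)
  out <- lapply(split(df, df$gene_id), function(d) {
    if (any(!d$strand %in% c("+", "-"))) {
      rejected <<- c(rejected, d$gene_id[1])
      return(NULL)
    }
    # longest transcript, ties by lexicographic transcript_id
    ex <- d[d$type == "exon", ]
    len <- tapply(ex$end - ex$start, ex$transcript_id, sum)
    tx <- names(len)[order(-len, names(len))][1]
    ex <- ex[ex$transcript_id == tx, ]
    ex <- ex[order(ex$start), ]
    cds <- d[d$type == "CDS" & d$transcript_id == tx, ]
    cds_start <- cds_end <- NA_real_
    coding <- nrow(cds) > 0L
    if (coding) {
      cds_start <- min(cds$start)
      cds_end <- max(cds$end)
      inside <- any(ex$start <= cds_start & cds_start < ex$end) &&
        any(ex$start < cds_end & cds_end <= ex$end)
      if (!inside) {
        rejected <<- c(rejected, d$gene_id[1])
        return(NULL)
      }
    }
    strand <- ex$strand[1]
    biotype <- if (!is.na(ex$biotype[1])) {
      ifelse(ex$biotype[1] %in% c("protein_coding", "coding"), "coding", "noncoding")
    } else {
      ifelse(coding, "coding", "noncoding")
    }
    data.frame(
      gene_id = d$gene_id[1], chrom = ex$chrom[1], strand = strand,
      biotype = biotype,
      tss = if (strand == "+") ex$start[1] else ex$end[nrow(ex)] - 1,
      span_start = ex$start[1], span_end = ex$end[nrow(ex)],
      cds_start = cds_start, cds_end = cds_end,
      exons = I(list(ex[, c("start", "end")])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (length(rejected)) {
    message("rejected ", length(rejected), " gene model(s): ",
            paste(utils::head(rejected, 10), collapse = ", "))
  }
  if (is.null(out) || nrow(out) == 0L) stopf("no usable gene models in %s", path)
  exons <- do.call(rbind, Map(function(gid, ex) {
    data.frame(gene_id = gid, start = ex$start, end = ex$end)
  }, out$gene_id, out$exons))
  genes <- out[, setdiff(names(out), "exons")]
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models as GTF
#'
#' Emits exon and CDS features (1-based closed) with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes, one transcript per gene.
#' @param models a `gene_models` object.
#' @param path output file.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  ex <- models$exons
  feats <- lapply(seq_len(nrow(g)), function(i) {
    e <- ex[ex$gene_id == g$gene_id[i], ]
    rows <- data.frame(start = e$start, end = e$end, type = "exon",
                       phase = NA_integer_)
    if (!is.na(g$cds_start[i])) {
      cs <- pmax(e$start, g$cds_start[i])
      ce <- pmin(e$end, g$cds_end[i])
      keep <- cs < ce
      if (any(keep)) {
        w <- (ce - cs)[keep]
        ord <- if (g$strand[i] == "+") order(cs[keep]) else order(-cs[keep])
        phase <- integer(length(w))
        phase[ord] <- (3L - cumsum(c(0L, w[ord][-length(w)])) %% 3L) %% 3L
        rows <- rbind(rows, data.frame(start = cs[keep], end = ce[keep],
                                       type = "CDS", phase = phase))
      }
    }
    rows$gene <- g$gene_id[i]
    rows$chrom <- g$chrom[i]
    rows$strand <- g$strand[i]
    rows$biotype <- ifelse(g$biotype[i] == "coding", "protein_coding",
                           g$biotype[i])
    rows
  })
  feats <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    feats$chrom,
    IRanges::IRanges(feats$start + 1L, feats$end),  # back to 1-based closed
    strand = feats$strand,
    type = feats$type, source = "tfeseq", phase = feats$phase,
    gene_id = feats$gene, transcript_id = paste0(feats$gene, ".t1"),
    gene_biotype = feats$biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read 5'-end events from the 7-column event TSV
#'
#' Expects a coordinate-sorted, tab-separated table with header columns
#' `chrom, pos, strand, umi, sample_id, is_spikein, read_id` (the spike-in
#' flag is recomputed from the reference-name prefix). Unsorted input is an
#' error naming the first offending record.
#'
#' @param path event TSV.
#' @param spikein_prefix reference-name prefix marking spike-in sequences.
#' @return events data.frame.
#' @export
read_events <- function(path, spikein_prefix = "spike_") {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(pos = "numeric"))
  need <- c("chrom", "pos", "strand", "umi", "sample_id")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stopf("event table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(is.na(ev$umi) | ev$umi == "")) stopf("record with missing UMI")
  bad <- which(c(FALSE, diff(ev$pos) < 0) &
                 c(FALSE, ev$chrom[-1] == ev$chrom[-nrow(ev)]))
  if (length(bad)) {
    stopf("input not coordinate-sorted at record %d (%s:%s)",
          bad[1], ev$chrom[bad[1]], ev$pos[bad[1]])
  }
  ev$is_spikein <- startsWith(ev$chrom, spikein_prefix)
  if (!"read_id" %in% names(ev)) ev$read_id <- sprintf("read%08d", seq_len(nrow(ev)))
  check_events(ev)
  ev
}

#' Write 5'-end events as a coordinate-sorted TSV
#' @param events events data.frame.
#' @param path output file.
#' @export
write_events <- function(events, path) {
  check_events(events)
  ev <- events[order(events$chrom, events$pos, events$strand,
                     events$sample_id, events$umi), ]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the TFE count matrix TSV
#'
#' The TSV carries one row per TFE with its region metadata (coordinates,
#' strand, summit, spike-in flag) followed by one integer column per sample.
#' Round-trips are lossless.
#'
#' @param x a `tfe_matrix`.
#' @param path file path.
#' @param samples sample sheet to attach on read.
#' @return `write_count_matrix` returns the path; `read_count_matrix` a
#'   `tfe_matrix`.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "tfe_matrix"))
  meta <- x$regions[, c("tfe_id", "chrom", "start", "end", "strand",
                        "summit", "is_spikein")]
  utils::write.table(cbind(meta, as.data.frame(x$counts)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, samples) {
  check_samples(samples)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(d) == 0L) stopf("empty count matrix: %s", path)
  meta_cols <- c("tfe_id", "chrom", "start", "end", "strand", "summit",
                 "is_spikein")
  miss <- setdiff(meta_cols, names(d))
  if (length(miss)) stopf("count matrix lacks column(s): %s",
                          paste(miss, collapse = ", "))
  cn <- setdiff(names(d), meta_cols)
  counts <- as.matrix(d[, cn, drop = FALSE])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- d$tfe_id
  counts <- counts[, samples$sample_id, drop = FALSE]
  regions <- d[, meta_cols]
  regions$count <- as.integer(rowSums(counts))
  structure(list(counts = counts, regions = regions, samples = samples,
                 unassigned = NA_integer_),
            class = "tfe_matrix")
}

#' Write strand-aware intervals as BED6
#'
#' 0-based half-open, with name, score and strand columns.
#' @param intervals data.frame with `chrom`, `start`, `end`, `strand` and
#'   optionally `name`, `score`.
#' @param path output file.
#' @param chrom_lengths optional named vector; intervals beyond a
#'   chromosome end are an error.
#' @export
write_intervals <- function(intervals, path, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[intervals$chrom]
    if (any(is.na(len)) || any(intervals$end > len) || any(intervals$start < 0)) {
      stopf("interval beyond chromosome end")
    }
  }
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end),
    strand = intervals$strand
  )
  gr$name <- if ("name" %in% names(intervals)) intervals$name else {
    rep(".", length(gr))
  }
  gr$score <- if ("score" %in% names(intervals)) intervals$score else {
    rep(0, length(gr))
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read BED6 intervals back into the internal 0-based frame
#' @param path BED file.
#' @export
read_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    stringsAsFactors = FALSE
  )
}

#' Write named sequences as wrapped FASTA
#' @param seqs a named [Biostrings::DNAStringSet] (or named character).
#' @param path output file.
#' @export
write_sequences <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a FASTA genome
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Read / write the sample sheet TSV (sample_id, stage)
#' @param path file path.
#' @param stages optional ordered stage vector; labels outside it are an
#'   error.
#' @export
read_sample_sheet <- function(path, stages = NULL) {
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  check_samples(s)
  if (!is.null(stages)) {
    bad <- setdiff(unique(s$stage), stages)
    if (length(bad)) stopf("unknown stage label(s): %s", paste(bad, collapse = ", "))
    s <- s[order(match(s$stage, stages)), ]
    rownames(s) <- NULL
  }
  s
}

#' @rdname read_sample_sheet
#' @param samples sample sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  check_samples(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
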