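# Strand-aware promoter windows around TFE summits and sequence export
# for external motif tools.

#' Promoter windows around TFE summits
#'
#' Anchored on the TFE summit p (0-based). On the plus strand the window is
#' `[p - up, p + down)`; on the minus strand `[p - down + 1, p + up + 1)`.
#' "Downstream" includes the anchor base itself, so an unclipped window has
#' length exactly `up + down` with `up` bases 5' of the anchor and `down`
#' bases from the anchor on. Windows are clipped to the chromosome and
#' flagged; a window entirely outside its chromosome is an error.
#'
#' @param regions a [call_tfes()] result (rows to extract windows for).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param up,down bases upstream / downstream of the summit (defaults 400
#'   and 100).
#' @return data.frame of class `promoter_windows`: `tfe_id`, `chrom`,
#'   `start`, `end`, `strand`, `anchor`, `clipped`.
#' @export
promoter_windows <- function(regions, chrom_lengths, up = 400L, down = 100L) {
  if (up < 0L) stopf("up must be >= 0")
  if (down < 1L) stopf("down must be >= 1 (the window contains its anchor)")
  len <- chrom_lengths[regions$chrom]
  if (any(is.na(len))) {
    stopf("chromosome length missing for: %s",
          paste(unique(regions$chrom[is.na(len)]), collapse = ", "))
  }
  p <- regions$summit
  plus <- regions$strand == "+"
  start <- ifelse(plus, p - up, p - down + 1)
  end <- ifelse(plus, p + down, p + up + 1)
  if (any(end <= 0 | start >= len)) stopf("promoter window entirely outside chromosome")
  cs <- pmax(start, 0)
  ce <- pmin(end, len)
  structure(data.frame(tfe_id = regions$tfe_id, chrom = regions$chrom,
                       start = cs, end = ce, strand = regions$strand,
                       anchor = p, clipped = cs != start | ce != end,
                       row.names = NULL),
            class = c("promoter_windows", "data.frame"))
}

#' Extract promoter sequences
#'
#' Slices each window from the genome; minus-strand windows are
#' reverse-complemented so every sequence reads 5' to 3' from the promoter
#' into the TSS. Names carry the TFE id and the window coordinates.
#'
#' @param windows a [promoter_windows()] data.frame.
#' @param genome a [Biostrings::DNAStringSet].
#' @return a named [Biostrings::DNAStringSet].
#' @export
extract_promoter_sequences <- function(windows, genome) {
  miss <- setdiff(unique(windows$chrom), names(genome))
  if (length(miss)) stopf("chromosome(s) missing from genome: %s",
                          paste(miss, collapse = ", "))
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(windows)), function(i) {
    s <- Biostrings::subseq(genome[[windows$chrom[i]]],
                            start = windows$start[i] + 1L,
                            end = windows$end[i])
    if (windows$strand[i] == "-") Biostrings::reverseComplement(s) else s
  }))
  names(seqs) <- sprintf("%s::%s:%d-%d(%s)", windows$tfe_id, windows$chrom,
                         windows$start, windows$end, windows$strand)
  seqs
}

#' Write promoter windows as BED6 and FASTA
#'
#' The BED carries the windows in genome coordinates; the FASTA the
#' strand-aware sequences — both directly consumable by motif-discovery
#' suites.
#'
#' @param windows a [promoter_windows()] data.frame.
#' @param genome a [Biostrings::DNAStringSet].
#' @param bed_path,fasta_path output files.
#' @export
write_promoters <- function(windows, genome, bed_path, fasta_path) {
  w <- windows
  w$name <- w$tfe_id
  write_intervals(w, bed_path,
                  chrom_lengths = stats::setNames(Biostrings::width(genome),
                                                  names(genome)))
  write_sequences(extract_promoter_sequences(windows, genome), fasta_path)
  invisible(c(bed = bed_path, fasta = fasta_path))
}
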