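# Genomic annotation of TFEs: nine positional categories, the fixed 9 -> 6
# merge, and stage-averaged annotation proportions.

#' The nine positional categories and the fixed merge to six
#' @export
annotation_categories <- function() {
  c("Coding5UTR", "CodingUpstream", "CodingCDS", "Coding3UTR",
    "Noncoding1stExon", "NoncodingUpstream", "NoncodingOtherExon",
    "Intron", "Unannotated")
}

#' @rdname annotation_categories
#' @export
merged_categories <- function() {
  c("UpstreamAnd5UTRCoding", "CDSAnd3UTRCoding",
    "UpstreamAnd1stExonNoncoding", "OtherExonsNoncoding",
    "Intron", "Unannotated")
}

#' Merge a positional category into the six-category scheme
#'
#' Fixed total map: coding 5'-UTR and coding upstream merge to "upstream and
#' 5'-UTR of coding"; coding CDS and 3'-UTR to "CDS and 3'-UTR of coding";
#' noncoding 1st exon and upstream to "upstream and 1st exon of noncoding";
#' the remaining categories map to themselves.
#'
#' @param category character vector of nine-category labels.
#' @return character vector of merged labels.
#' @export
merge_category <- function(category) {
  map <- c(
    Coding5UTR = "UpstreamAnd5UTRCoding",
    CodingUpstream = "UpstreamAnd5UTRCoding",
    CodingCDS = "CDSAnd3UTRCoding",
    Coding3UTR = "CDSAnd3UTRCoding",
    Noncoding1stExon = "UpstreamAnd1stExonNoncoding",
    NoncodingUpstream = "UpstreamAnd1stExonNoncoding",
    NoncodingOtherExon = "OtherExonsNoncoding",
    Intron = "Intron",
    Unannotated = "Unannotated"
  )
  bad <- setdiff(category, names(map))
  if (length(bad)) stopf("unknown category: %s", paste(bad, collapse = ", "))
  unname(map[category])
}

#' Classify TFEs against gene models
#'
#' Each TFE is labelled by its summit position against same-strand gene
#' models. Overlapping-gene ambiguity resolves toward the most
#' promoter-like label with the fixed priority Coding5UTR > CodingUpstream >
#' CodingCDS > Coding3UTR > Noncoding1stExon > NoncodingUpstream >
#' NoncodingOtherExon > Intron > Unannotated. "Upstream" means within
#' `upstream_bp` 5' of a model's TSS (outside the gene body); "intron" means
#' inside the gene span but in no exon. Unannotated is the fall-through.
#'
#' @param regions a [call_tfes()] result.
#' @param models a `gene_models` object.
#' @param upstream_bp upstream window size in bp (default 500).
#' @return character vector of nine-category labels, one per region
#'   (NA for spike-in regions).
#' @export
classify_tfes <- function(regions, models, upstream_bp = 500L) {
  if (upstream_bp <= 0) stopf("upstream_bp must be > 0")
  summit <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$summit + 1L, regions$summit + 1L),
    strand = regions$strand
  )
  sets <- category_ranges(models, upstream_bp)
  cat <- rep("Unannotated", nrow(regions))
  for (nm in rev(setdiff(annotation_categories(), "Unannotated"))) {
    hit <- IRanges::overlapsAny(summit, sets[[nm]], ignore.strand = FALSE)
    cat[hit] <- nm  # later (higher-priority) assignments overwrite
  }
  cat[regions$is_spikein] <- NA_character_
  cat
}

# Strand-aware GRanges per category, built once per gene-model set.
category_ranges <- function(models, upstream_bp) {
  g <- models$genes
  ex <- models$exons
  ex$strand <- g$strand[match(ex$gene_id, g$gene_id)]
  ex$chrom <- g$chrom[match(ex$gene_id, g$gene_id)]
  ex$biotype <- g$biotype[match(ex$gene_id, g$gene_id)]
  gr <- function(d) {
    if (is.null(d) || nrow(d) == 0L) return(GenomicRanges::GRanges())
    keep <- d$end > d$start
    d <- d[keep, , drop = FALSE]
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end),
                           strand = d$strand)
  }

  coding <- g$biotype == "coding"
  cex <- ex[ex$biotype == "coding", , drop = FALSE]
  i <- match(cex$gene_id, g$gene_id)
  # exonic pieces 5' of the CDS, inside the CDS span, and 3' of it
  utr5 <- data.frame(chrom = cex$chrom, strand = cex$strand,
                     start = ifelse(g$strand[i] == "+", cex$start,
                                    pmax(cex$start, g$cds_end[i])),
                     end = ifelse(g$strand[i] == "+",
                                  pmin(cex$end, g$cds_start[i]), cex$end))
  utr3 <- data.frame(chrom = cex$chrom, strand = cex$strand,
                     start = ifelse(g$strand[i] == "+",
                                    pmax(cex$start, g$cds_end[i]), cex$start),
                     end = ifelse(g$strand[i] == "+", cex$end,
                                  pmin(cex$end, g$cds_start[i])))
  cds <- data.frame(chrom = cex$chrom, strand = cex$strand,
                    start = pmax(cex$start, g$cds_start[i]),
                    end = pmin(cex$end, g$cds_end[i]))

  up <- function(sel) {
    d <- g[sel, , drop = FALSE]
    data.frame(chrom = d$chrom, strand = d$strand,
               start = ifelse(d$strand == "+", d$tss - upstream_bp, d$tss + 1),
               end = ifelse(d$strand == "+", d$tss, d$tss + 1 + upstream_bp))
  }

  nex <- ex[ex$biotype == "noncoding", , drop = FALSE]
  first <- unlist(lapply(split(seq_len(nrow(nex)), nex$gene_id), function(idx) {
    st <- nex$strand[idx[1]]
    idx[if (st == "+") which.min(nex$start[idx]) else which.max(nex$end[idx])]
  }), use.names = FALSE)
  n1 <- nex[first, , drop = FALSE]
  no <- nex[setdiff(seq_len(nrow(nex)), first), , drop = FALSE]

  span <- data.frame(chrom = g$chrom, strand = g$strand,
                     start = g$span_start, end = g$span_end)

  list(
    Coding5UTR = gr(utr5),
    CodingUpstream = gr(up(coding)),
    CodingCDS = gr(cds),
    Coding3UTR = gr(utr3),
    Noncoding1stExon = gr(n1),
    NoncodingUpstream = gr(up(!coding)),
    NoncodingOtherExon = gr(no),
    Intron = gr(span)
  )
}

#' Stage-averaged annotation proportions
#'
#' Per sample, non-spike-in TFE counts are summed by merged category and
#' divided by the sample's total (x 100); the per-sample percentages are
#' then averaged over the samples of each stage. Each stage's six
#' percentages sum to 100.
#'
#' @param x a `tfe_matrix`.
#' @param categories nine-category labels per TFE row (NA for spike-ins),
#'   as from [classify_tfes()].
#' @return data.frame, one row per stage (in sheet order), one column per
#'   merged category.
#' @export
annotation_proportions <- function(x, categories) {
  stopifnot(inherits(x, "tfe_matrix"))
  keep <- !x$regions$is_spikein
  if (any(is.na(categories[keep]))) stopf("every non-spike-in TFE must be classified")
  merged <- factor(merge_category(categories[keep]), levels = merged_categories())
  counts <- x$counts[keep, , drop = FALSE]
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stopf("sample(s) with zero total counts: %s",
          paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  pct <- apply(counts, 2, function(v) tapply(v, merged, sum, default = 0L))
  pct <- sweep(pct, 2, tot, "/") * 100
  stages <- unique(x$samples$stage)
  out <- t(vapply(stages, function(st) {
    rowMeans(pct[, x$samples$sample_id[x$samples$stage == st], drop = FALSE])
  }, numeric(length(merged_categories()))))
  data.frame(stage = stages, out, check.names = FALSE, row.names = NULL)
}
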