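# End-to-end orchestration: simulate -> quantify -> annotate -> normalize
# -> variable-TFE selection -> consecutive-stage DE -> markers -> temporal
# clustering -> promoter extraction, with a fixed output layout and a
# manifest of every written file.

#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' `alpha` 0.05 (BH-adjusted significance), `top_k` 20000 (variable TFEs),
#' `expr_threshold` -10 (log2 expressed cutoff), `lfc_threshold` 3 (marker
#' fold change), `up`/`down` 400/100 bp (promoter window),
#' `k`/`restarts`/`max_iter` 6/1000/20 (k-means), `min_count` 2 and
#' `max_gap` 60 (TFE calling), `upstream_bp` 500 (annotation),
#' `pseudocount` 1 (correlation/clustering values), `reference_stage` "GV"
#' (relative content), `marker_stages` (marker calling). Unknown keys are
#' rejected.
#'
#' @param sim a [sim_config()] for the synthetic input.
#' @param ... overrides of the defaults listed above.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), ...) {
  cfg <- list(
    sim = sim, seed = sim$seed,
    alpha = 0.05, top_k = 20000L, expr_threshold = -10, lfc_threshold = 3,
    up = 400L, down = 100L, k = 6L, restarts = 1000L, max_iter = 20L,
    min_count = 2L, max_gap = 60L, upstream_bp = 500L, pseudocount = 1,
    reference_stage = "GV", marker_stages = c("GV", "MII", "16c", "Blc"),
    spikein_prefix = "spike_"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline into an output directory
#'
#' Executes every stage in dependency order on a synthetic experiment and
#' writes the fixed output layout (genome FASTA, gene models GTF, event and
#' sample TSVs, TFE BED + count matrix, annotations and stage proportions,
#' normalized values and relative content, variable-TFE list and sample
#' correlations, per-contrast DE tables, marker sets, cluster assignments,
#' promoter BED + FASTA) plus `manifest.tsv` with the MD5 checksum and row
#' count of every output. A rerun with the same configuration reproduces
#' the outputs byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage logging.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  pth <- function(f) file.path(out_dir, f)

  # -- simulate ------------------------------------------------------------
  exp <- simulate_experiment(config$sim)
  ref <- exp$reference; cnt <- exp$counts; aln <- exp$alignments
  write_sequences(ref$genome, pth("genome.fa"))
  write_gene_models(ref$models, pth("annotation.gtf"))
  write_events(aln$events, pth("events.tsv"))
  write_sample_sheet(cnt$samples, pth("samples.tsv"))
  utils::write.table(cnt$truth$classes, pth("truth_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(stage = config$sim$stages, content = cnt$truth$content_ratio),
    pth("truth_content.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  log("simulate", "%d units, %d samples, %d read events",
      nrow(ref$units), nrow(cnt$samples), nrow(aln$events))

  # -- quantify ------------------------------------------------------------
  dedup <- dedup_events(aln$events)
  regions <- call_tfes(dedup, min_count = config$min_count,
                       max_gap = config$max_gap)
  mat <- build_count_matrix(regions, dedup, cnt$samples)
  write_intervals(transform(regions, name = tfe_id, score = count),
                  pth("tfes.bed"))
  write_count_matrix(mat, pth("counts.tsv"))
  log("quantify", "%d dedup events -> %d TFEs (%d spike-in), %d unassigned",
      nrow(dedup), nrow(regions), sum(regions$is_spikein), mat$unassigned)

  # -- annotate ------------------------------------------------------------
  categories <- classify_tfes(regions, ref$models,
                              upstream_bp = config$upstream_bp)
  utils::write.table(
    data.frame(tfe_id = regions$tfe_id, category = categories,
               merged = ifelse(is.na(categories), NA,
                               merge_category(ifelse(is.na(categories),
                                                     "Unannotated", categories)))),
    pth("annotations.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  props <- annotation_proportions(mat, categories)
  utils::write.table(props, pth("proportions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log("annotate", "proportions over %d stages x %d categories",
      nrow(props), ncol(props) - 1L)

  # -- normalize -----------------------------------------------------------
  sf <- spikein_size_factors(mat)
  norm0 <- log2_normalize(mat, sf, pseudocount = 0)
  norm1 <- log2_normalize(mat, sf, pseudocount = config$pseudocount)
  utils::write.table(
    data.frame(tfe_id = regions$tfe_id, round(norm1$values, 6),
               check.names = FALSE),
    pth("values.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  content <- relative_rna_content(mat, reference_stage = config$reference_stage)
  utils::write.table(content, pth("content.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log("normalize", "size factors in [%.3f, %.3f], S_ref = %.1f",
      min(sf), max(sf), norm0$s_ref)

  # -- hvt -----------------------------------------------------------------
  var_res <- test_variable_tfes(mat, sf)
  top <- select_top_variable(var_res, k = config$top_k, alpha = config$alpha)
  utils::write.table(var_res, pth("variable_tfes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(top, pth("top_variable.txt"))
  corr <- pairwise_correlation(norm1, top)
  utils::write.table(data.frame(sample_id = rownames(corr), round(corr, 6),
                                check.names = FALSE),
                     pth("correlation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log("hvt", "%d/%d TFEs selected (%s)", length(top), nrow(var_res),
      format(attr(var_res, "fit")$method))

  # -- de ------------------------------------------------------------------
  de <- run_consecutive_de(mat, sf, stages = config$sim$stages,
                           alpha = config$alpha)
  for (nm in names(de)) {
    utils::write.table(de[[nm]], pth(sprintf("de_%s.tsv", gsub("\\|", "_vs_", nm))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log("de", "%d consecutive contrasts", length(de))

  # -- markers -------------------------------------------------------------
  med <- stage_medians(norm0, stages = config$sim$stages)
  markers <- call_stage_markers(med, de, stages = config$marker_stages,
                                expr_threshold = config$expr_threshold,
                                lfc_threshold = config$lfc_threshold,
                                alpha = config$alpha,
                                stage_order = config$sim$stages)
  mk <- do.call(rbind, lapply(names(markers), function(st) {
    if (!length(markers[[st]]$tfe_id)) return(NULL)
    data.frame(stage = st, tfe_id = markers[[st]]$tfe_id,
               contrast = markers[[st]]$contrast)
  }))
  if (is.null(mk)) mk <- data.frame(stage = character(0), tfe_id = character(0),
                                    contrast = character(0))
  utils::write.table(mk, pth("markers.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log("markers", "%d marker TFEs over %s", nrow(mk),
      paste(names(markers), collapse = "/"))

  # -- cluster -------------------------------------------------------------
  sel <- match(top, regions$tfe_id)
  scaled <- scale_rows(norm1$values[sel, , drop = FALSE])
  clusters <- kmeans_profiles(scaled, k = config$k, restarts = config$restarts,
                              max_iter = config$max_iter, seed = config$seed)
  utils::write.table(
    data.frame(tfe_id = names(clusters$cluster), cluster = clusters$cluster),
    pth("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  log("cluster", "k = %d, WCSS = %.1f", config$k, clusters$wcss)

  # -- promoters -----------------------------------------------------------
  ega <- intersect(names(markers), "16c")
  prom_ids <- if (length(ega)) markers[["16c"]]$tfe_id else mk$tfe_id
  win <- promoter_windows(regions[match(prom_ids, regions$tfe_id), , drop = FALSE],
                          stats::setNames(Biostrings::width(ref$genome),
                                          names(ref$genome)),
                          up = config$up, down = config$down)
  write_promoters(win, ref$genome, pth("promoters.bed"), pth("promoters.fa"))
  log("promoters", "%d windows of %d bp", nrow(win), config$up + config$down)

  # -- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    bytes = file.size(file.path(out_dir, files))
  )
  utils::write.table(manifest, pth("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(reference = ref, counts = cnt, alignments = aln,
                 matrix = mat, categories = categories, proportions = props,
                 size_factors = sf, norm = norm0, norm_pseudo = norm1,
                 content = content, variable = var_res, top = top,
                 correlation = corr, de = de, medians = med,
                 markers = markers, clusters = clusters, windows = win,
                 manifest = manifest))
}
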