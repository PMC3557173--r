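# Pipeline orchestration: configuration, stage execution, report bundle.

#' Pipeline configuration
#'
#' Paths to the stage inputs plus every tunable parameter. Stages whose
#' input paths are NULL (or listed in \code{skip}) are skipped and their
#' report fields are NULL.
#'
#' @param out_dir run directory for all outputs (created if absent).
#' @param map_file genetic-map TSV (required).
#' @param genotype_file BC1 genotype TSV (segregation stage).
#' @param primer_file primer-pair TSV (anchoring stage).
#' @param template_file template-pool FASTA (anchoring stage).
#' @param qtl_file QTL TSV (integration stage).
#' @param marker_loci_file optional marker-to-locus TSV (duplication
#'   analysis and multi-locus cluster positions).
#' @param skip character vector of stage names to skip, among
#'   "segregation", "structure", "anchor", "integrate".
#' @param alpha,min_run segregation parameters.
#' @param gap_threshold,bin_width,min_loci,window map-structure
#'   parameters.
#' @param max_mismatch,min_product,max_product_est,max_product_bac
#'   anchoring parameters.
#' @param min_overlap,min_identity unigene-merge parameters.
#' @param max_interval QTL interval-width filter in cM.
#' @param seed integer seed recorded in the run log (the pipeline itself
#'   is deterministic given its inputs).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            map_file,
                            genotype_file = NULL,
                            primer_file = NULL,
                            template_file = NULL,
                            qtl_file = NULL,
                            marker_loci_file = NULL,
                            skip = character(),
                            alpha = 0.05, min_run = 3,
                            gap_threshold = 10, bin_width = 10,
                            min_loci = 5, window = 1.0,
                            max_mismatch = 3, min_product = 40,
                            max_product_est = 5000,
                            max_product_bac = 20000,
                            min_overlap = 40, min_identity = 0.95,
                            max_interval = 20, seed = 1) {
  stopifnot(alpha > 0, alpha <= 1, min_run >= 1, window > 0,
            min_loci >= 1, max_mismatch >= 0, min_product >= 1,
            min_identity > 0, min_identity <= 1, max_interval > 0)
  out <- as.list(environment())
  class(out) <- "pipeline_config"
  out
}

.stage_check <- function(stage, path, what) {
  if (!file.exists(path))
    stop(stage, ": ", what, " file not found: ", path, call. = FALSE)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full map-integration pipeline
#'
#' Executes, in order: map summary and gap detection; segregation tests
#' and SDR scanning; density binning, cluster calling and duplication
#' analysis; primer-pool anchoring with product-size comparison and
#' unigene selection; QTL integration and QTL clustering. Every stage
#' writes its table under \code{cfg$out_dir} (fixed filenames) and a
#' top-level \code{report.json} echoes the headline statistics.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  cat("", file = log_path)
  pars <- cfg[!vapply(cfg, is.null, logical(1))]
  for (nm in setdiff(names(pars), c("out_dir")))
    logline("param %s = %s", nm, paste(format(pars[[nm]]), collapse = ","))

  report <- list()
  run_stage <- function(stage, expr) {
    logline("stage %s: start", stage)
    out <- tryCatch(expr, error = function(e) {
      logline("stage %s: FAILED: %s", stage, conditionMessage(e))
      stop(stage, ": ", conditionMessage(e), call. = FALSE)
    })
    logline("stage %s: done", stage)
    out
  }
  skip <- function(stage) stage %in% cfg$skip

  # --- map summary ---
  .stage_check("summarize", cfg$map_file, "map")
  map <- run_stage("summarize", read_map(cfg$map_file))
  summ <- summarize_map(map)
  gaps <- detect_gaps(map, cfg$gap_threshold)
  jsonlite::write_json(
    list(n_loci = summ$n_loci, n_groups = summ$n_groups,
         total_length = summ$total_length,
         mean_interlocus = summ$mean_interlocus,
         mean_loci_per_group = summ$mean_loci_per_group,
         n_gaps = nrow(gaps)),
    file.path(cfg$out_dir, "map_summary.json"), auto_unbox = TRUE,
    digits = NA)
  .write_tsv(summ$per_group, file.path(cfg$out_dir, "map_per_group.tsv"))
  .write_tsv(gaps, file.path(cfg$out_dir, "gaps.tsv"))
  report$map <- list(n_loci = summ$n_loci, n_groups = summ$n_groups,
                     total_length = summ$total_length,
                     mean_interlocus = summ$mean_interlocus,
                     n_gaps = nrow(gaps))

  marker_to_loci <- NULL
  if (!is.null(cfg$marker_loci_file)) {
    .stage_check("structure", cfg$marker_loci_file, "marker-to-locus")
    marker_to_loci <- read.delim(cfg$marker_loci_file, comment.char = "#",
                                 stringsAsFactors = FALSE)
  }

  # --- segregation ---
  report$segregation <- NULL
  if (!is.null(cfg$genotype_file) && !skip("segregation")) {
    .stage_check("segregation", cfg$genotype_file, "genotype")
    seg <- run_stage("segregation", {
      geno <- read_genotypes(cfg$genotype_file)
      res <- classify_loci(geno, cfg$alpha)
      sdrs <- scan_sdrs(map, res[match(map$locus, res$locus), ],
                        cfg$min_run)
      types <- setNames(map$marker_type, map$locus)
      list(results = res, sdrs = sdrs,
           by_type = marker_type_summary(
             res[res$locus %in% map$locus, ], types))
    })
    .write_tsv(seg$results, file.path(cfg$out_dir, "distortion.tsv"))
    .write_tsv(seg$sdrs, file.path(cfg$out_dir, "sdrs.tsv"))
    .write_tsv(seg$by_type, file.path(cfg$out_dir, "distortion_by_type.tsv"))
    report$segregation <- list(
      n_tested = nrow(seg$results),
      n_distorted = sum(seg$results$status != "none"),
      n_toward_recurrent = sum(seg$results$status == "toward_recurrent"),
      n_toward_heterozygote =
        sum(seg$results$status == "toward_heterozygote"),
      n_sdrs = nrow(seg$sdrs))
  }

  # --- map structure ---
  report$structure <- NULL
  if (!skip("structure")) {
    st <- run_stage("structure", {
      dens <- bin_density(map, cfg$bin_width)
      clus <- detect_clusters(map, cfg$min_loci, cfg$window)
      dup <- if (!is.null(marker_to_loci))
        analyze_duplication(map, marker_to_loci) else NULL
      list(density = dens, clusters = clus, dup = dup)
    })
    .write_tsv(st$density, file.path(cfg$out_dir, "density.tsv"))
    .write_tsv(st$clusters[, setdiff(names(st$clusters), "loci")],
               file.path(cfg$out_dir, "clusters.tsv"))
    if (!is.null(st$dup))
      jsonlite::write_json(
        c(st$dup$summary, list(histogram = as.list(st$dup$histogram))),
        file.path(cfg$out_dir, "duplication.json"), auto_unbox = TRUE,
        digits = NA)
    report$structure <- list(
      n_clusters = nrow(st$clusters),
      n_cluster_loci = sum(st$clusters$n_loci),
      n_gene_islands = sum(st$clusters$kind == "gene_island"),
      n_retro_rich = sum(st$clusters$kind == "retro_rich"),
      duplication = st$dup$summary)
  }

  # --- anchoring ---
  anchors <- NULL
  report$anchor <- NULL
  if (!is.null(cfg$primer_file) && !is.null(cfg$template_file) &&
      !skip("anchor")) {
    .stage_check("anchor", cfg$primer_file, "primer")
    .stage_check("anchor", cfg$template_file, "template")
    anc <- run_stage("anchor", {
      primers <- read_primers(cfg$primer_file)
      pool <- read_templates(cfg$template_file)
      anchors <- anchor_pool(primers, pool, cfg$max_mismatch,
                             cfg$min_product, cfg$max_product_est,
                             cfg$max_product_bac)
      sizes <- compare_product_sizes(anchors)
      list(anchors = anchors, sizes = sizes, pool = pool)
    })
    anchors <- anc$anchors
    .write_tsv(anchors$hits, file.path(cfg$out_dir, "anchors.tsv"))
    write_anchors_gff(anchors, file.path(cfg$out_dir, "anchors.gff3"))
    .write_tsv(anc$sizes, file.path(cfg$out_dir, "product_sizes.tsv"))
    report$anchor <- c(anchors$summary,
                       attr(anc$sizes, "summary"))
  }

  # --- integration ---
  report$integration <- NULL
  if (!is.null(cfg$qtl_file) && !is.null(anchors) && !skip("integrate")) {
    .stage_check("integrate", cfg$qtl_file, "QTL")
    intg <- run_stage("integrate", {
      qtls <- read_qtl(cfg$qtl_file)
      clusters <- build_clusters(anchors, map, marker_to_loci)
      res <- integrate_qtl(qtls, map, clusters, cfg$max_interval)
      qclust <- cluster_qtl(qtls)
      # representative unigene per anchored marker with >= 1 member
      seq_by_id <- setNames(anc$pool$seq, anc$pool$id)
      uni <- lapply(clusters, function(cl) {
        select_unigene(seq_by_id[cl$members$template], cfg$min_overlap,
                       cfg$min_identity)
      })
      list(res = res, qclust = qclust, uni = uni, clusters = clusters)
    })
    .write_tsv(intg$res$records, file.path(cfg$out_dir, "integration.tsv"))
    .write_tsv(intg$res$summary, file.path(cfg$out_dir, "table2.tsv"))
    .write_tsv(intg$qclust, file.path(cfg$out_dir, "qtl_clusters.tsv"))
    uniseq <- Biostrings::DNAStringSet(
      vapply(intg$uni, function(u) u$seq, character(1)))
    names(uniseq) <- sprintf("%s provenance=%s n_members=%d",
                             names(intg$uni),
                             vapply(intg$uni, function(u) u$provenance,
                                    character(1)),
                             vapply(intg$uni, function(u) u$n_members,
                                    integer(1)))
    Biostrings::writeXStringSet(uniseq,
                                file.path(cfg$out_dir, "unigenes.fasta"))
    tot <- intg$res$summary[intg$res$summary$chromosome == "Total", ]
    report$integration <- list(
      n_qtl_retained = tot$qtl_total,
      n_qtl_excluded = length(intg$res$excluded),
      n_genes_assigned = tot$n_genes,
      n_qtl_clusters = nrow(intg$qclust),
      n_multi_trait_clusters = sum(intg$qclust$multi_trait))
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logline("pipeline complete")
  invisible(report)
}
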