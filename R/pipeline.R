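#' Run the full conservation pipeline
#'
#' Orchestrates every stage end to end: catalogue curation, proteome-based
#' species filtering, e-value filtering and best-hit selection, Hamming
#' anchoring and hit annotation, P1 / Hamming-distance / P1' distributions,
#' per-site metrics (conservation, coil prevalence, hydrophobicity
#' prevalence, destabilizing fraction), criterion-based selection,
#' reference-set validation (when reference ids are configured) and the
#' species dendrogram. Inputs may be file paths (the tab-separated/FASTA
#' formats of the `read_*` functions) or in-memory objects, e.g. the
#' components of [generate_corpus()].
#'
#' @param catalogue Catalogue path or tibble (`site_id`, `accession`,
#'   `gene`, `p1_pos`).
#' @param proteome FASTA path or named character vector of protein sequences.
#' @param hits Hit-table path or tibble.
#' @param lineage Lineage path or tibble.
#' @param proteome_sizes Proteome-size path or tibble.
#' @param q3 Q3-profile path or tibble (`site_id`, `q3`); optional — without
#'   it coil prevalence is `NA` and its criterion fails.
#' @param config A [selection_config()].
#' @param evalue_max E-value cut-off for hits (default 1e-16).
#' @param proteome_min Proteome-size threshold (strict, default 8000).
#' @param exclude_accessions Accessions dropped during curation.
#' @param out_dir Optional directory; when given, every table is written as
#'   tab-separated values plus the dendrogram in Newick format and a run log
#'   with parameter values.
#' @return List: `sites`, `curation_report`, `species_universe`,
#'   `annotated`, `p1_distribution`, `hd_distribution`,
#'   `p1prime_distribution`, `hydro_shift`, `metrics`, `criteria`,
#'   `selected`, `validation` (NULL without reference ids), `dendrogram`
#'   (NULL with < 2 species).
#' @export
run_pipeline <- function(catalogue, proteome, hits, lineage, proteome_sizes,
                         q3 = NULL, config = selection_config(),
                         evalue_max = 1e-16, proteome_min = 8000,
                         exclude_accessions = character(), out_dir = NULL) {
  if (is.character(hits) && length(hits) == 1L) hits <- read_hit_table(hits)
  if (is.character(lineage) && length(lineage) == 1L) {
    lineage <- read_lineage(lineage)
  }
  if (is.character(proteome_sizes) && length(proteome_sizes) == 1L) {
    proteome_sizes <- read_proteome_sizes(proteome_sizes)
  }
  if (is.character(q3) && length(q3) == 1L) q3 <- read_q3_profiles(q3)

  cur <- load_sites(catalogue, proteome, exclude_accessions)
  sites <- cur$sites

  universe <- filter_species(proteome_sizes, proteome_min)
  if (!length(universe)) {
    warning("no species passes the proteome filter; downstream tables are empty")
  }
  best <- best_hit_per_species(
    filter(hits, .data$taxon_id %in% universe, .data$site_id %in% sites$site_id),
    evalue_max
  )
  ann <- annotate_hits(sites, best, lineage)

  p1_dist <- p1_distribution(ann)
  hd_dist <- hd_distribution(ann)
  p1p_dist <- p1prime_distribution(ann)

  metrics <- if (length(universe) && nrow(ann)) {
    target_conservation(ann, universe, config$class_list)
  } else {
    tibble(site_id = character(), n_species = integer(),
           pct_species = numeric(), median_hd = numeric(),
           p1_d_fraction = numeric(), classes_present = list(),
           n_classes = integer(), no_d_hits = logical())
  }
  # make one metrics row per curated site, even with zero hits
  metrics <- left_join(select(sites, "site_id", "accession", "gene"),
                       metrics, by = "site_id")
  metrics$pct_species[is.na(metrics$pct_species)] <- 0
  metrics$n_species[is.na(metrics$n_species)] <- 0L
  metrics$classes_present[vapply(metrics$classes_present, is.null,
                                 logical(1))] <- list(character())

  # coil prevalence from the human Q3 profiles
  if (!is.null(q3)) {
    q3v <- setNames(q3$q3, q3$site_id)
    metrics$coil_prevalence <- vapply(seq_len(nrow(metrics)), function(i) {
      id <- metrics$site_id[i]
      if (is.na(q3v[id])) return(NA_real_)
      coil_prevalence(q3v[[id]],
                      sites$p1_window_pos[sites$site_id == id])
    }, numeric(1))
  } else {
    metrics$coil_prevalence <- NA_real_
  }

  # hydrophobicity prevalence: corpus-level shift over every ortholog window,
  # per-site median over the site's hits; human window value alongside
  shift <- NA_real_
  metrics$hydro_prevalence_median <- NA_real_
  if (nrow(ann)) {
    p1wp <- sites$p1_window_pos[match(ann$site_id, sites$site_id)]
    blocks <- hydro_block_values(ann$anchored_window, p1_window_pos = p1wp)
    shift <- hydro_shift(blocks)
    prev <- (blocks$central + shift) / (blocks$flank_mean + shift)
    med <- tapply(prev, ann$site_id, median, na.rm = TRUE)
    metrics$hydro_prevalence_median <- as.numeric(med[metrics$site_id])
    hshift_h <- shift
    metrics$hydro_prevalence_human <- hydro_prevalence(
      sites$window[match(metrics$site_id, sites$site_id)], hshift_h,
      p1_window_pos = sites$p1_window_pos[match(metrics$site_id,
                                                sites$site_id)])
  } else {
    metrics$hydro_prevalence_human <- NA_real_
  }

  destab <- if (nrow(ann)) {
    ann %>% group_by(.data$site_id) %>%
      summarise(destab_fraction = {
        def <- .data$p1prime_nature[.data$p1prime_nature != "undefined"]
        if (length(def)) mean(def == "destabilizing") else NA_real_
      }, .groups = "drop")
  } else {
    tibble(site_id = character(), destab_fraction = numeric())
  }
  metrics <- left_join(metrics, destab, by = "site_id")

  sel <- apply_criteria(metrics, config)
  validation <- if (length(config$reference_site_ids)) {
    validate_reference(metrics, config)
  } else NULL

  dendro <- NULL
  if (nrow(ann) && length(unique(ann$taxon_id)) >= 2L) {
    dendro <- cluster_species(species_matrix(ann, "octamer"))
  }

  result <- list(
    sites = sites, curation_report = cur$report,
    species_universe = universe, annotated = ann,
    p1_distribution = p1_dist, hd_distribution = hd_dist,
    p1prime_distribution = p1p_dist, hydro_shift = shift,
    metrics = metrics, criteria = sel$criteria, selected = sel$selected,
    validation = validation, dendrogram = dendro
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  result
}

# flatten the classes_present list column for tabular output
flatten_metrics <- function(metrics) {
  m <- metrics
  m$classes_present <- vapply(m$classes_present, paste, "", collapse = ";")
  m
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))
  w(result$sites, "curated_sites.tsv")
  w(result$curation_report, "curation_report.tsv")
  w(result$annotated, "annotated_hits.tsv")
  w(result$p1_distribution, "p1_distribution.tsv")
  w(result$hd_distribution, "hd_distribution.tsv")
  w(result$p1prime_distribution$residues, "p1prime_distribution.tsv")
  w(result$p1prime_distribution$nature, "p1prime_nature_totals.tsv")
  w(flatten_metrics(result$metrics), "target_metrics.tsv")
  w(result$criteria, "selection_matrix.tsv")
  w(flatten_metrics(result$selected), "selected_targets.tsv")
  if (!is.null(result$validation)) w(result$validation, "validation.tsv")
  if (!is.null(result$dendrogram)) {
    writeLines(result$dendrogram$newick,
               file.path(out_dir, "species_dendrogram.nwk"))
  }
  log <- c(
    paste0("casptrace ", as.character(utils::packageVersion("casptrace"))),
    paste0("n_sites_kept=", nrow(result$sites)),
    paste0("n_species_universe=", length(result$species_universe)),
    paste0("n_annotated_hits=", nrow(result$annotated)),
    paste0("hydro_shift=", result$hydro_shift),
    paste0("thresholds: median_hd<", config$median_hd_max,
           " coil>", config$coil_prev_min,
           " hydro<", config$hydro_prev_max,
           " pct_species>", config$pct_species_min,
           " all_classes=", config$require_all_classes,
           " destab>", config$destab_min,
           " destab_enabled=", config$destab_enabled)
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
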