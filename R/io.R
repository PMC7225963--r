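# Tab-separated readers for the pipeline's input tables. All tables carry a
# header row; taxon and site identifiers are always read as character.

#' Read a cleavage-site catalogue (site_id, accession, gene, p1_pos)
#' @param path Path to a tab-separated file with header.
#' @return Tibble.
#' @export
read_catalogue <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    site_id = "c", accession = "c", gene = "c", p1_pos = "i"
                  ))
}

#' Read an ortholog hit table (BLAST outfmt-6-like column subset)
#'
#' Expected columns: `site_id` (qseqid), `taxon_id` (staxids), `evalue`,
#' `subject_segment` (sseq); optional `qseq`, `sseq`, `qstart` for gapped
#' input.
#' @param path Path to a tab-separated file with header.
#' @return Tibble.
#' @export
read_hit_table <- function(path) {
  h <- readr::read_tsv(path, show_col_types = FALSE)
  h$site_id <- as.character(h$site_id)
  h$taxon_id <- as.character(h$taxon_id)
  h
}

#' Read a lineage table (taxon_id, species_name, class_label)
#' @param path Path to a tab-separated file with header.
#' @return Tibble.
#' @export
read_lineage <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Read a proteome-size table (taxon_id, n_proteins)
#' @param path Path to a tab-separated file with header.
#' @return Tibble.
#' @export
read_proteome_sizes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(taxon_id = "c", n_proteins = "d"))
}

#' Read Q3 secondary-structure profiles (site_id, q3)
#' @param path Path to a tab-separated file with header.
#' @return Tibble.
#' @export
read_q3_profiles <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(site_id = "c", q3 = "c"))
}

#' Write a synthetic corpus to disk in the pipeline's input formats
#'
#' Emits exactly the files the pipeline consumes: `proteome.fasta`,
#' `catalogue.tsv`, `hits.tsv`, `lineage.tsv`, `proteome_sizes.tsv`,
#' `q3.tsv`, plus the ground truth as `ground_truth_sites.tsv`,
#' `ground_truth_hits.tsv` and the planted aggregates in
#' `ground_truth_summary.tsv`.
#'
#' @param corpus Output of [generate_corpus()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteome = file.path(dir, "proteome.fasta"),
    catalogue = file.path(dir, "catalogue.tsv"),
    hits = file.path(dir, "hits.tsv"),
    lineage = file.path(dir, "lineage.tsv"),
    proteome_sizes = file.path(dir, "proteome_sizes.tsv"),
    q3 = file.path(dir, "q3.tsv"),
    truth_sites = file.path(dir, "ground_truth_sites.tsv"),
    truth_hits = file.path(dir, "ground_truth_hits.tsv"),
    truth_summary = file.path(dir, "ground_truth_summary.tsv")
  )
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(corpus$proteome), paths[["proteome"]])
  readr::write_tsv(corpus$catalogue, paths[["catalogue"]])
  readr::write_tsv(corpus$hits, paths[["hits"]])
  readr::write_tsv(corpus$lineage, paths[["lineage"]])
  readr::write_tsv(corpus$proteome_sizes, paths[["proteome_sizes"]])
  readr::write_tsv(corpus$q3, paths[["q3"]])
  gt <- corpus$ground_truth
  readr::write_tsv(gt$site_truth, paths[["truth_sites"]])
  readr::write_tsv(gt$hit_truth, paths[["truth_hits"]])
  readr::write_tsv(
    tibble(parameter = c("p1_d_fraction", "destab_fraction"),
           value = c(gt$p1_d_fraction, gt$destab_fraction)),
    paths[["truth_summary"]])
  invisible(paths)
}
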