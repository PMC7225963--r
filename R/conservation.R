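#' Hamming distance between two equal-length residue strings
#'
#' Counts positions where the two strings differ. A position matches only when
#' both characters are the same standard residue; gaps (`-`) and ambiguity
#' codes (X, B, Z, U, ...) differ from everything, including an identical
#' ambiguity character in the other string. For octamers the distance ranges
#' 0 (identical cleavage sites) to 8 (no residue matches).
#'
#' @param a,b Strings of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming() requires equal-length strings (", nchar(a), " vs ", nchar(b), ")")
  }
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  sum(!(x == y & x %in% .aa_codes()))
}

# vectorized over pairs of equal-length strings
hamming_vec <- function(a, b) {
  if (!length(a)) return(integer())
  mapply(hamming, a, b, USE.NAMES = FALSE)
}

#' Distribution of residues observed at the P1 position
#'
#' Tabulates the character found under the human P1 column in every ortholog
#' hit, including gap (`-`) and ambiguity categories. High retention of 'D'
#' here is the primary signature of conserved cleavage.
#'
#' @param hits Annotated hit tibble (uses column `p1_residue`) or a plain
#'   character vector of P1 characters.
#' @return Tibble `residue`, `n`, `percent` sorted by decreasing count.
#'   Percentages are of the total and sum to 100 within rounding.
#' @export
p1_distribution <- function(hits) {
  x <- if (is.data.frame(hits)) hits$p1_residue else hits
  tab <- sort(table(x), decreasing = TRUE)
  tibble(
    residue = names(tab),
    n = as.integer(tab),
    percent = 100 * as.integer(tab) / sum(tab)
  )
}

#' Joint distribution of P1-aspartate retention and octamer Hamming distance
#'
#' Cross-tabulates ortholog hits by whether the P1 column holds an aspartate
#' and by the octamer Hamming distance to the human site. Percentages are of
#' the grand total, so the aspartate rows sum to the 'D' share of
#' [p1_distribution()].
#'
#' @param hits Annotated hit tibble (uses `p1_residue`, `octamer_hd`).
#' @return Tibble `p1_is_d`, `octamer_hd`, `n`, `percent`.
#' @export
hd_distribution <- function(hits) {
  total <- nrow(hits)
  hits %>%
    mutate(p1_is_d = .data$p1_residue == "D") %>%
    count(.data$p1_is_d, .data$octamer_hd) %>%
    arrange(desc(.data$p1_is_d), .data$octamer_hd) %>%
    mutate(percent = 100 * .data$n / total)
}

#' Per-site conservation metrics
#'
#' Aggregates annotated, best-per-species hits into one row per cleavage
#' site: number and percentage of species in the universe with a hit, the
#' median octamer Hamming distance over hits that retain the P1 aspartate
#' (orthologous D-cuts), the fraction of hits retaining P1 'D', and the set
#' of vertebrate classes covered. Hits whose P1 is not aspartate still count
#' toward species and class coverage (presence of the ortholog is a search
#' outcome, not a P1 property); only the median Hamming distance is
#' restricted to D-cuts. Even-count medians are the mean of the two middle
#' values. A site with no D-cut hits gets `median_hd = NA` and is flagged —
#' it cannot pass selection.
#'
#' @param hits Annotated hit tibble from [annotate_hits()].
#' @param species_universe Character vector of taxon ids defining the species
#'   universe (normally the output of [filter_species()]); hits from other
#'   taxa are ignored.
#' @param class_list Class labels that count toward class coverage.
#' @return Tibble `site_id`, `n_species`, `pct_species`, `median_hd`,
#'   `p1_d_fraction`, `classes_present` (list column), `n_classes`,
#'   `no_d_hits`.
#' @export
target_conservation <- function(hits, species_universe,
                                class_list = vertebrate_classes()) {
  n_universe <- length(unique(species_universe))
  if (n_universe == 0L) stop("species_universe is empty")
  h <- filter(hits, .data$taxon_id %in% species_universe)
  h %>%
    group_by(.data$site_id) %>%
    summarise(
      n_species = n_distinct(.data$taxon_id),
      pct_species = 100 * n_distinct(.data$taxon_id) / n_universe,
      median_hd = if (any(.data$p1_residue == "D")) {
        median(.data$octamer_hd[.data$p1_residue == "D"])
      } else NA_real_,
      p1_d_fraction = mean(.data$p1_residue == "D"),
      classes_present = list(sort(unique(
        .data$class_label[.data$class_label %in% class_list]
      ))),
      .groups = "drop"
    ) %>%
    mutate(
      n_classes = lengths(.data$classes_present),
      no_d_hits = is.na(.data$median_hd)
    )
}
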