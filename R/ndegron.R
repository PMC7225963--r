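#' Arg/N-degron classification of N-terminal residues
#'
#' After caspase cleavage the P1' residue becomes the N-terminus of the
#' C-terminal fragment and determines its fate under the Arg/N-degron
#' pathway: primary destabilizing residues (R, K, H, L, F, Y, W, I) are
#' recognized directly, secondary ones (D, E, C) after arginylation by the
#' ATE1 arginyl-transferase, tertiary ones (N, Q) after deamidation followed
#' by arginylation. G, S, A, T, V, M and P are not recognized by the pathway
#' and count as stabilizing for this analysis (Nt-acetylation-dependent fates
#' are not modeled). The two natures partition the 20 standard residues.
#'
#' @return Tibble `residue`, `nature` (stabilizing/destabilizing),
#'   `mechanism` (primary/secondary/tertiary/stabilizing).
#' @export
ndegron_table <- function() {
  tbl <- tibble(
    residue = c("R", "K", "H", "L", "F", "Y", "W", "I",
                "D", "E", "C",
                "N", "Q",
                "G", "S", "A", "T", "V", "M", "P"),
    mechanism = c(rep("primary", 8), rep("secondary", 3), rep("tertiary", 2),
                  rep("stabilizing", 7))
  )
  tbl$nature <- ifelse(tbl$mechanism == "stabilizing",
                       "stabilizing", "destabilizing")
  stopifnot(setequal(tbl$residue, AA_STANDARD), !anyDuplicated(tbl$residue))
  tbl
}

#' Classify P1' residues as stabilizing or destabilizing
#'
#' Vectorized lookup into [ndegron_table()]. Gaps and ambiguity codes have no
#' defined N-degron fate and return `"undefined"`.
#'
#' @param residue Character vector of single characters.
#' @return Character vector over `{stabilizing, destabilizing, undefined}`.
#' @export
classify_p1prime <- function(residue) {
  tbl <- ndegron_table()
  nature <- tbl$nature[match(residue, tbl$residue)]
  ifelse(is.na(nature), "undefined", nature)
}

#' Fraction of ortholog hits with a destabilizing P1' residue
#'
#' Conservation of a destabilizing P1' across orthologs suggests the
#' C-terminal fragment is deliberately routed to N-degron degradation.
#' Undefined natures (gaps, ambiguity codes) are excluded from the
#' denominator so alignment gaps do not penalize a site.
#'
#' @param hits Annotated hit tibble (uses `p1prime_nature`) or a character
#'   vector of natures.
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when every nature
#'   is undefined.
#' @export
destab_fraction <- function(hits) {
  x <- if (is.data.frame(hits)) hits$p1prime_nature else hits
  def <- x[x != "undefined"]
  if (!length(def)) {
    warning("all P1' natures undefined")
    return(NA_real_)
  }
  mean(def == "destabilizing")
}

#' Distribution of residues at the P1' position
#'
#' Counts each residue observed at P1' together with its N-degron nature,
#' plus subtotals by nature.
#'
#' @param hits Annotated hit tibble (uses `p1prime_residue`) or a character
#'   vector of P1' characters.
#' @return List with `residues` (tibble `residue`, `nature`, `n`, `percent`)
#'   and `nature` (tibble `nature`, `n`, `percent`).
#' @export
p1prime_distribution <- function(hits) {
  x <- if (is.data.frame(hits)) hits$p1prime_residue else hits
  tab <- sort(table(x), decreasing = TRUE)
  residues <- tibble(
    residue = names(tab),
    nature = classify_p1prime(names(tab)),
    n = as.integer(tab),
    percent = 100 * as.integer(tab) / sum(tab)
  )
  nature <- residues %>%
    group_by(.data$nature) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    mutate(percent = 100 * .data$n / sum(.data$n)) %>%
    arrange(desc(.data$n))
  list(residues = residues, nature = nature)
}
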