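#' Configuration of the five-criterion target filter
#'
#' The final target list keeps a site only when all enabled criteria hold,
#' every comparison strict: median octamer Hamming distance over D-cut
#' orthologs `< median_hd_max`; coil prevalence `> coil_prev_min`; median
#' hydrophobicity prevalence `< hydro_prev_max`; percentage of the species
#' universe with an ortholog `> pct_species_min`; ortholog presence in every
#' class of `class_list` (when `require_all_classes`). A sixth criterion —
#' destabilizing P1' in `> destab_min` of orthologs — is computed and
#' reported in the validation table but disabled by default: most reference
#' targets with proven proapoptotic fragments fail it, so it is too
#' restrictive to impose.
#'
#' @param median_hd_max Exclusive upper bound on median Hamming distance
#'   (default 2).
#' @param coil_prev_min Exclusive lower bound on coil prevalence (default 1).
#' @param hydro_prev_max Exclusive upper bound on median hydrophobicity
#'   prevalence (default 1).
#' @param pct_species_min Exclusive lower bound on percent species coverage
#'   (default 96; on a 328-species universe this means at least 315 species).
#' @param require_all_classes Require presence in every class (default TRUE).
#' @param class_list Ordered class labels (default [vertebrate_classes()]).
#' @param destab_min Exclusive lower bound on the destabilizing fraction
#'   (default 0.5).
#' @param destab_enabled Whether the destabilizing criterion participates in
#'   selection (default FALSE).
#' @param reference_site_ids Site ids of the reference set for
#'   [validate_reference()].
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(median_hd_max = 2,
                             coil_prev_min = 1,
                             hydro_prev_max = 1,
                             pct_species_min = 96,
                             require_all_classes = TRUE,
                             class_list = vertebrate_classes(),
                             destab_min = 0.5,
                             destab_enabled = FALSE,
                             reference_site_ids = character()) {
  stopifnot(
    is.finite(median_hd_max), is.finite(coil_prev_min),
    is.finite(hydro_prev_max), is.finite(pct_species_min),
    is.finite(destab_min), length(class_list) >= 1L
  )
  structure(
    list(
      median_hd_max = median_hd_max,
      coil_prev_min = coil_prev_min,
      hydro_prev_max = hydro_prev_max,
      pct_species_min = pct_species_min,
      require_all_classes = isTRUE(require_all_classes),
      class_list = class_list,
      destab_min = destab_min,
      destab_enabled = isTRUE(destab_enabled),
      reference_site_ids = reference_site_ids
    ),
    class = "selection_config"
  )
}

# per-criterion verdicts; NA metric values fail their criterion
criteria_matrix <- function(metrics, config) {
  pass <- function(x) !is.na(x) & x
  tibble(
    site_id = metrics$site_id,
    pass_median_hd = pass(metrics$median_hd < config$median_hd_max),
    pass_coil = pass(metrics$coil_prevalence > config$coil_prev_min),
    pass_hydro = pass(metrics$hydro_prevalence_median < config$hydro_prev_max),
    pass_pct_species = pass(metrics$pct_species > config$pct_species_min),
    pass_classes = vapply(metrics$classes_present, function(cl) {
      all(config$class_list %in% cl)
    }, logical(1)),
    pass_destab = pass(metrics$destab_fraction > config$destab_min)
  )
}

#' Apply the conservation criteria to per-site metrics
#'
#' Evaluates every criterion for every site and selects the sites passing
#' all enabled ones. Undefined metrics (e.g. no D-cut orthologs, empty
#' blocks) fail their criterion. The pass/fail matrix is returned alongside
#' so the conjunction is auditable: a site is in `selected` exactly when its
#' enabled columns are all TRUE.
#'
#' @param metrics Tibble with `site_id`, `median_hd`, `coil_prevalence`,
#'   `hydro_prevalence_median`, `pct_species`, `classes_present` (list
#'   column), `destab_fraction`.
#' @param config A [selection_config()].
#' @return List with `selected` (metrics rows passing) and `criteria`
#'   (pass/fail matrix with a `selected` column).
#' @export
apply_criteria <- function(metrics, config = selection_config()) {
  cm <- criteria_matrix(metrics, config)
  sel <- cm$pass_median_hd & cm$pass_coil & cm$pass_hydro &
    cm$pass_pct_species
  if (config$require_all_classes) sel <- sel & cm$pass_classes
  if (config$destab_enabled) sel <- sel & cm$pass_destab
  cm$selected <- sel
  list(selected = metrics[sel, , drop = FALSE], criteria = cm)
}

#' Validate the selection criteria against a reference target set
#'
#' For each single criterion (median Hamming distance, coil prevalence,
#' hydrophobicity prevalence, destabilizing P1') counts how many of all
#' targets and how many of the reference targets — cleavages with proven
#' proapoptotic C-terminal fragments — pass it. A useful criterion should
#' retain most of the reference set.
#'
#' @param metrics Per-site metrics tibble (as for [apply_criteria()]).
#' @param config A [selection_config()] whose `reference_site_ids` are all
#'   present in `metrics`.
#' @return Tibble `criterion`, `n_targets_pass`, `pct_targets_pass`,
#'   `n_reference_pass`, `pct_reference_pass` (percentages rounded to two
#'   decimals).
#' @export
validate_reference <- function(metrics, config) {
  ref <- config$reference_site_ids
  if (!length(ref)) stop("config carries no reference_site_ids")
  missing <- setdiff(ref, metrics$site_id)
  if (length(missing)) {
    stop("reference site ids missing from metrics: ",
         paste(missing, collapse = ", "))
  }
  cm <- criteria_matrix(metrics, config)
  is_ref <- cm$site_id %in% ref
  cols <- c(
    median_hd = "pass_median_hd",
    coil_prevalence = "pass_coil",
    hydro_prevalence = "pass_hydro",
    destab_fraction = "pass_destab"
  )
  vv <- function(f) vapply(unname(cols), f, numeric(1), USE.NAMES = FALSE)
  tibble(
    criterion = names(cols),
    n_targets_pass = as.integer(vv(function(cl) sum(cm[[cl]]))),
    pct_targets_pass = round(100 * vv(function(cl) mean(cm[[cl]])), 2),
    n_reference_pass = as.integer(vv(function(cl) sum(cm[[cl]][is_ref]))),
    pct_reference_pass = round(100 * vv(function(cl) mean(cm[[cl]][is_ref])), 2)
  )
}
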