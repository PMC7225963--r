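#' Configuration for the synthetic ortholog corpus
#'
#' Defines a fully in-silico study: human proteins with planted cleavage
#' sites, a species panel organized into vertebrate classes, and ortholog
#' hits produced by a two-tier mutation process (a class-level divergence of
#' the human window shared by all species of the class, then independent
#' species-level substitutions), so that real class structure is planted and
#' recoverable by clustering. The P1 column is drawn per hit: aspartate with
#' probability `p1_retention_prob`, glutamate with `p1_to_E_prob`, a gap with
#' `gap_at_p1_prob`, any other residue with the remainder. P1' substitutions
#' preserve the stabilizing/destabilizing nature of the human residue,
#' mirroring the near-total conservation of fragment fate across orthologs;
#' exactly `round(destab_p1prime_fraction * n_sites)` sites carry a
#' destabilizing human P1' (stratified assignment, so the composition
#' parameter is exact). E-values are a decreasing function of the planted
#' substitution count plus noise — only their ordering matters. Decoy species
#' with small proteomes exercise the proteome-representation filter.
#'
#' @param seed Integer seed; a fixed seed makes the corpus byte-identical
#'   across runs.
#' @param n_sites Number of planted cleavage sites (one per protein).
#' @param n_species_per_class Named integer vector, species per class; all of
#'   these pass the proteome filter.
#' @param protein_length Length of each synthetic human protein.
#' @param p1_retention_prob,p1_to_E_prob,gap_at_p1_prob Marginal per-hit
#'   probabilities of D / E / '-' at the P1 column.
#' @param octamer_sub_rate Named per-class substitution rate for the free
#'   octamer positions (class-level divergence).
#' @param flank_sub_rate Corpus-mean class-level substitution rate outside
#'   the octamer; each class's flank rate is this value scaled by its
#'   relative octamer rate, so flank divergence tracks lineage divergence.
#' @param species_octamer_sub_rate,species_flank_sub_rate Species-level
#'   substitution rates on top of the class divergence.
#' @param hit_dropout_prob Probability a species yields no hit for a site.
#' @param extra_hit_rate Poisson mean of redundant extra hits per species
#'   (worse e-values; removed by best-hit selection).
#' @param weak_hit_prob Probability the species' best hit lands above the
#'   e-value cut-off (lost to filtering).
#' @param n_decoy_species Species with under-represented proteomes.
#' @param proteome_size_range,decoy_size_range Uniform ranges for annotated
#'   protein counts of panel and decoy species.
#' @param coil_fraction Named probabilities of 'C' per window third
#'   (left/central/right) in the Q3 strings.
#' @param helix_share Among non-coil Q3 characters, probability of 'H'.
#' @param destab_p1prime_fraction Fraction of sites with a destabilizing
#'   human P1' residue.
#' @param background_freqs Optional named residue frequencies for background
#'   sequence; default uniform.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_sites = 100L,
    n_species_per_class = c(Mammalia = 120L, Aves = 90L, Actinopterygii = 80L,
                            Reptilia = 20L, Amphibia = 10L,
                            Chondrichthyes = 6L, Coelacanthimorpha = 2L),
    protein_length = 200L,
    p1_retention_prob = 0.92,
    p1_to_E_prob = 0.05,
    gap_at_p1_prob = 0.002,
    octamer_sub_rate = c(Mammalia = 0.04, Aves = 0.06, Actinopterygii = 0.11,
                         Reptilia = 0.07, Amphibia = 0.09,
                         Chondrichthyes = 0.13, Coelacanthimorpha = 0.10),
    flank_sub_rate = 0.10,
    species_octamer_sub_rate = 0.02,
    species_flank_sub_rate = 0.04,
    hit_dropout_prob = 0.02,
    extra_hit_rate = 0.3,
    weak_hit_prob = 0.01,
    n_decoy_species = 20L,
    proteome_size_range = c(9000L, 60000L),
    decoy_size_range = c(500L, 8000L),
    coil_fraction = c(left = 0.55, central = 0.65, right = 0.55),
    helix_share = 0.75,
    destab_p1prime_fraction = 0.2,
    background_freqs = NULL) {
  probs <- c(p1_retention_prob, p1_to_E_prob, gap_at_p1_prob,
             octamer_sub_rate, flank_sub_rate, species_octamer_sub_rate,
             species_flank_sub_rate, hit_dropout_prob, weak_hit_prob,
             coil_fraction, helix_share, destab_p1prime_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p1_retention_prob + p1_to_E_prob + gap_at_p1_prob > 1) {
    stop("P1 outcome probabilities exceed 1")
  }
  if (is.null(names(n_species_per_class)) ||
      !all(names(n_species_per_class) %in% names(octamer_sub_rate))) {
    stop("every class needs an octamer substitution rate")
  }
  if (!setequal(names(coil_fraction), c("left", "central", "right"))) {
    stop("coil_fraction needs left/central/right entries")
  }
  if (is.null(background_freqs)) {
    background_freqs <- setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# sample background residues
sample_aa <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# substitute positions of a character vector at a given rate with a random
# *different* standard residue
mutate_chars <- function(ch, idx, rate, freqs) {
  if (!length(idx) || rate <= 0) return(ch)
  hitpos <- idx[runif(length(idx)) < rate]
  for (p in hitpos) {
    repl <- sample_aa(1L, freqs)
    while (repl == ch[p]) repl <- sample_aa(1L, freqs)
    ch[p] <- repl
  }
  ch
}

# nature-preserving substitution of the P1' character
mutate_p1prime <- function(current, rate, nd) {
  if (runif(1) >= rate) return(current)
  same <- nd$residue[nd$nature == nd$nature[match(current, nd$residue)]]
  same <- setdiff(same, current)
  if (!length(same)) return(current)
  sample(same, 1L)
}

#' Generate a synthetic corpus of sites, species and ortholog hits
#'
#' Produces every input the pipeline consumes — proteome FASTA sequences,
#' cleavage-site catalogue, ortholog hit table, lineage table, proteome-size
#' table, Q3 secondary-structure strings — plus a ground-truth record of what
#' was planted, for parameter-recovery studies. All randomness flows through
#' `config$seed`; a fixed seed reproduces the corpus exactly.
#'
#' @param config A [synthetic_config()].
#' @return List with `proteome` (named character vector), `catalogue`,
#'   `hits`, `lineage`, `proteome_sizes`, `q3` (tibbles) and `ground_truth`
#'   (list: the config, per-site truth, per-hit truth, aggregate planted
#'   values).
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nd <- ndegron_table()
  destab_set <- nd$residue[nd$nature == "destabilizing"]
  stab_set <- c("G", "S", "A", "T", "V", "M", "P")
  stab_w <- c(G = 33, S = 26, A = 15, T = 3, V = 3, M = 2, P = 1)

  classes <- names(config$n_species_per_class)
  n_panel <- sum(config$n_species_per_class)
  panel <- tibble(
    taxon_id = sprintf("tax%04d", seq_len(n_panel)),
    class_label = rep(classes, config$n_species_per_class)
  ) %>%
    group_by(.data$class_label) %>%
    mutate(species_name = paste0(.data$class_label, "_sp", row_number())) %>%
    ungroup()
  decoys <- if (config$n_decoy_species > 0) tibble(
    taxon_id = sprintf("tax9%03d", seq_len(config$n_decoy_species)),
    class_label = sample(classes, config$n_decoy_species, replace = TRUE),
    species_name = paste0("decoy_sp", seq_len(config$n_decoy_species))
  ) else tibble(taxon_id = character(), class_label = character(),
                species_name = character())
  lineage <- bind_rows(panel, decoys)[, c("taxon_id", "species_name",
                                          "class_label")]
  proteome_sizes <- tibble(
    taxon_id = lineage$taxon_id,
    n_proteins = c(
      round(runif(n_panel, config$proteome_size_range[1],
                  config$proteome_size_range[2])),
      if (config$n_decoy_species > 0)
        round(runif(config$n_decoy_species, config$decoy_size_range[1],
                    config$decoy_size_range[2]))
    )
  )

  # --- human proteins with planted sites ------------------------------------
  n_sites <- config$n_sites
  n_destab <- round(config$destab_p1prime_fraction * n_sites)
  destab_site <- rep(FALSE, n_sites)
  destab_site[sample.int(n_sites, n_destab)] <- TRUE

  L <- config$protein_length
  proteome <- character(n_sites)
  names(proteome) <- sprintf("SYN%05d", seq_len(n_sites))
  catalogue <- tibble(
    site_id = sprintf("site%03d", seq_len(n_sites)),
    accession = names(proteome),
    gene = sprintf("GENE%03d", seq_len(n_sites)),
    p1_pos = integer(n_sites)
  )
  windows <- character(n_sites)
  p1prime_planted <- character(n_sites)
  for (i in seq_len(n_sites)) {
    ch <- sample_aa(L, config$background_freqs)
    p1 <- sample(35:(L - 35), 1L)
    oct <- sample_aa(8L, config$background_freqs)
    oct[4] <- "D"
    if (runif(1) < 0.5) oct[1] <- "D"     # DxxD-flavoured motif
    oct[5] <- if (destab_site[i]) sample(destab_set, 1L) else {
      sample(stab_set, 1L, prob = stab_w[stab_set])
    }
    ch[(p1 - 3L):(p1 + 4L)] <- oct
    proteome[i] <- paste(ch, collapse = "")
    catalogue$p1_pos[i] <- p1
    windows[i] <- substr(proteome[i], p1 - 29L, p1 + 30L)
    p1prime_planted[i] <- oct[5]
  }

  # --- Q3 strings ------------------------------------------------------------
  third <- rep(c("left", "central", "right"), each = 20L)
  q3 <- tibble(
    site_id = catalogue$site_id,
    q3 = vapply(seq_len(n_sites), function(i) {
      coil <- runif(60) < config$coil_fraction[third]
      other <- ifelse(runif(60) < config$helix_share, "H", "E")
      paste(ifelse(coil, "C", other), collapse = "")
    }, "")
  )

  # --- ortholog hits ----------------------------------------------------------
  oct_idx <- 27:34
  free_oct_idx <- c(27:29, 32:34)
  flank_idx <- setdiff(1:60, oct_idx)
  p_other <- 1 - config$p1_retention_prob - config$p1_to_E_prob -
    config$gap_at_p1_prob
  hit_chunks <- vector("list", n_sites * length(classes))
  truth_chunks <- vector("list", n_sites * length(classes))
  chunk <- 0L
  for (i in seq_len(n_sites)) {
    human <- strsplit(windows[i], "")[[1]]
    for (cl in classes) {
      cls_rate <- config$octamer_sub_rate[[cl]]
      # flank divergence tracks overall lineage divergence: per-class flank
      # rate scales with the class's relative octamer rate
      mean_rate <- mean(config$octamer_sub_rate[classes])
      flank_rate <- if (mean_rate > 0) {
        config$flank_sub_rate * cls_rate / mean_rate
      } else 0
      anc <- mutate_chars(human, free_oct_idx, cls_rate,
                          config$background_freqs)
      anc <- mutate_chars(anc, flank_idx, min(flank_rate, 1),
                          config$background_freqs)
      anc[31] <- mutate_p1prime(anc[31], cls_rate, nd)
      sp_tab <- panel[panel$class_label == cl, ]
      n_sp <- nrow(sp_tab)
      taxon <- character(0); ev_out <- numeric(0); subj_out <- character(0)
      t_taxon <- character(0); t_p1 <- character(0); t_hd <- integer(0)
      t_p1p <- character(0); t_weak <- logical(0); t_off <- integer(0)
      for (s in seq_len(n_sp)) {
        if (runif(1) < config$hit_dropout_prob) next
        ch <- mutate_chars(anc, free_oct_idx, config$species_octamer_sub_rate,
                           config$background_freqs)
        ch <- mutate_chars(ch, flank_idx, config$species_flank_sub_rate,
                           config$background_freqs)
        ch[31] <- mutate_p1prime(ch[31], config$species_octamer_sub_rate, nd)
        u <- runif(1)
        ch[30] <- if (u < config$p1_retention_prob) "D"
        else if (u < config$p1_retention_prob + config$p1_to_E_prob) "E"
        else if (u < 1 - p_other) "-"
        else sample(setdiff(AA_STANDARD, c("D", "E")), 1L)
        oct_hd <- sum(!(ch[oct_idx] == human[oct_idx] &
                          ch[oct_idx] %in% AA_STANDARD))
        total_subs <- sum(ch != human)
        lpad <- sample(0:15, 1L); rpad <- sample(0:15, 1L)
        subject <- paste(c(sample_aa(lpad, config$background_freqs), ch,
                           sample_aa(rpad, config$background_freqs)),
                         collapse = "")
        ev <- if (runif(1) < config$weak_hit_prob) {
          10^runif(1, -15, -8)
        } else {
          min(10^(-28 + 0.9 * total_subs + rnorm(1, 0, 0.4)), 1e-17)
        }
        taxon <- c(taxon, sp_tab$taxon_id[s])
        ev_out <- c(ev_out, ev)
        subj_out <- c(subj_out, subject)
        n_extra <- rpois(1, config$extra_hit_rate)
        for (k in seq_len(n_extra)) {
          ech <- mutate_chars(ch, 1:60, 0.05, config$background_freqs)
          taxon <- c(taxon, sp_tab$taxon_id[s])
          ev_out <- c(ev_out, ev * 10^runif(1, 1, 6))
          subj_out <- c(subj_out, paste(ech, collapse = ""))
        }
        t_taxon <- c(t_taxon, sp_tab$taxon_id[s])
        t_p1 <- c(t_p1, ch[30]); t_hd <- c(t_hd, oct_hd)
        t_p1p <- c(t_p1p, ch[31]); t_weak <- c(t_weak, ev > 1e-16)
        t_off <- c(t_off, lpad)
      }
      chunk <- chunk + 1L
      hit_chunks[[chunk]] <- tibble(
        site_id = catalogue$site_id[i], taxon_id = taxon,
        evalue = ev_out, subject_segment = subj_out
      )
      truth_chunks[[chunk]] <- tibble(
        site_id = catalogue$site_id[i], taxon_id = t_taxon,
        planted_p1 = t_p1, planted_octamer_hd = t_hd,
        planted_p1prime = t_p1p, weak = t_weak, anchor_offset_true = t_off
      )
    }
  }
  hits <- bind_rows(hit_chunks)
  hit_truth <- bind_rows(truth_chunks)
  # decoy species reuse the human window verbatim; the proteome filter must
  # remove them before any statistic
  if (nrow(decoys) > 0) {
    decoy_hits <- tidyr::expand_grid(site_id = catalogue$site_id,
                                     taxon_id = decoys$taxon_id) %>%
      mutate(evalue = 1e-25,
             subject_segment = windows[match(.data$site_id,
                                             catalogue$site_id)])
    hits <- bind_rows(hits, decoy_hits)
  }

  site_truth <- tibble(
    site_id = catalogue$site_id,
    octamer = substr(windows, 27, 34),
    window = windows,
    p1prime_residue = p1prime_planted,
    p1prime_nature = classify_p1prime(p1prime_planted)
  )
  usable <- hit_truth[!hit_truth$weak, ]
  ground_truth <- list(
    config = config,
    site_truth = site_truth,
    hit_truth = hit_truth,
    p1_d_fraction = mean(usable$planted_p1 == "D"),
    destab_fraction = mean(
      site_truth$p1prime_nature[match(usable$site_id,
                                      site_truth$site_id)] == "destabilizing"),
    hd_table = table(usable$planted_octamer_hd[usable$planted_p1 == "D"]),
    species_universe = panel$taxon_id
  )
  list(proteome = proteome, catalogue = catalogue, hits = hits,
       lineage = lineage, proteome_sizes = proteome_sizes, q3 = q3,
       ground_truth = ground_truth)
}

#' Compare pipeline estimates against the planted corpus truth
#'
#' Runs the recovery comparison: the P1-aspartate fraction, the D-cut octamer
#' Hamming-distance distribution (total-variation distance between estimated
#' and planted histograms), and the destabilizing P1' fraction, each against
#' the values actually planted in the corpus.
#'
#' @param corpus Output of [generate_corpus()].
#' @param annotated Annotated best-per-species hits for that corpus,
#'   restricted to the species universe (e.g. from [run_pipeline()] or
#'   [annotate_hits()] after [best_hit_per_species()]).
#' @return Tibble `parameter`, `planted`, `estimated`, `abs_error`.
#' @export
recover_parameters <- function(corpus, annotated) {
  gt <- corpus$ground_truth
  ann <- filter(annotated, .data$taxon_id %in% gt$species_universe)
  est_p1d <- mean(ann$p1_residue == "D")
  est_destab <- destab_fraction(ann)
  est_hd <- table(ann$octamer_hd[ann$p1_residue == "D"])
  lev <- sort(unique(c(names(gt$hd_table), names(est_hd))))
  p <- as.numeric(gt$hd_table[lev]); p[is.na(p)] <- 0
  q <- as.numeric(est_hd[lev]); q[is.na(q)] <- 0
  tv <- sum(abs(p / sum(p) - q / sum(q))) / 2
  tibble(
    parameter = c("p1_d_fraction", "destab_fraction", "hd_distribution_tv"),
    planted = c(gt$p1_d_fraction, gt$destab_fraction, 0),
    estimated = c(est_p1d, est_destab, tv),
    abs_error = c(abs(est_p1d - gt$p1_d_fraction),
                  abs(est_destab - gt$destab_fraction), tv)
  )
}
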