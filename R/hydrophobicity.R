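#' Cyclohexane-to-water side-chain transfer free-energy scale
#'
#' Per-residue hydrophobicity indices: the free energy (kcal/mol, pH 7)
#' required to transfer the amino-acid side chain from cyclohexane to water
#' (Radzicka & Wolfenden 1988 measurements). Negative values are hydrophilic
#' (arginine, -14.92, is the hydrophilic extreme), positive hydrophobic
#' (isoleucine/leucine, +4.92, the hydrophobic extreme). Proline has no free
#' side-chain analog and was not measured; it carries an alanine-like
#' aliphatic estimate of +1.81. The median of the 20 values is 0.40, with
#' glycine (0.94) the standard reference residue nearest the median.
#'
#' @return Named numeric vector over the 20 standard residues (kcal/mol).
#' @export
hydro_scale <- function() {
  s <- c(
    A = 1.81,  R = -14.92, N = -6.64, D = -8.72, C = 1.28,
    Q = -5.54, E = -6.81,  G = 0.94,  H = -4.66, I = 4.92,
    L = 4.92,  K = -5.55,  M = 2.35,  F = 2.98,  P = 1.81,
    S = -3.40, T = -2.57,  W = 2.33,  Y = -0.14, V = 4.04
  )
  # guard the anchors the analysis depends on
  stopifnot(
    length(s) == 20L, setequal(names(s), AA_STANDARD),
    s[["R"]] == -14.92, s[["I"]] == 4.92, s[["G"]] == 0.94,
    abs(median(s) - 0.4) < 1e-12
  )
  s
}

#' Sum of hydrophobicity indices over a residue segment
#'
#' Scores a segment (typically the central 20 residues with P1 aspartate in
#' the middle) by summing per-residue transfer free energies. Negative sums
#' mean a hydrophilic, likely surface-exposed segment. Gap and ambiguity
#' characters carry no measurable side chain and contribute the scale median
#' (0.4 kcal/mol), a neutral placeholder.
#'
#' @param segment Residue string (non-empty).
#' @param scale Named residue-to-kcal/mol mapping; default [hydro_scale()].
#' @return Sum in kcal/mol.
#' @export
hydro_sum <- function(segment, scale = hydro_scale()) {
  if (!nchar(segment)) stop("empty segment")
  ch <- strsplit(segment, "")[[1]]
  v <- scale[ch]
  v[is.na(v)] <- median(scale)
  sum(v)
}

#' Central and flank hydrophobicity block sums per window
#'
#' For each window, the hydrophobicity sum of the central 20-residue block
#' (`central`) and the mean of the left and right block sums (`flank_mean`),
#' the `(c, (l+r)/2)` pairs on which [hydro_shift()] and [hydro_prevalence()]
#' operate.
#'
#' @param windows Character vector of residue windows.
#' @param scale Hydrophobicity scale.
#' @param p1_window_pos P1 position within each window (recycled).
#' @return Tibble with columns `central` and `flank_mean` (kcal/mol).
#' @export
hydro_block_values <- function(windows, scale = hydro_scale(),
                               p1_window_pos = 30L) {
  p1 <- rep_len(p1_window_pos, length(windows))
  res <- vapply(seq_along(windows), function(i) {
    ch <- strsplit(windows[i], "")[[1]]
    blk <- window_blocks(length(ch), p1[i])
    sum_blk <- function(b) {
      sel <- blk == b
      if (!any(sel)) NA_real_ else hydro_sum(paste(ch[sel], collapse = ""), scale)
    }
    c(central = sum_blk("central"),
      flank_mean = mean(c(sum_blk("left"), sum_blk("right")), na.rm = TRUE))
  }, c(central = 0, flank_mean = 0))
  out <- as_tibble(t(res))
  out$flank_mean[is.nan(out$flank_mean)] <- NA_real_
  out
}

#' Positivity shift for hydrophobicity prevalence
#'
#' Hydrophobicity block sums can be negative or zero, so the prevalence ratio
#' is computed on shifted values. The shift is the absolute value of the
#' smallest central or mean-flank block sum observed over the whole corpus,
#' plus 1; adding it makes every shifted value at least 1 and rules out
#' division by zero. The shift is a corpus-level constant: it must be
#' computed once on all windows entering the analysis and reused for every
#' prevalence.
#'
#' @param blocks Tibble from [hydro_block_values()] on the corpus (columns
#'   `central`, `flank_mean`), or a numeric vector of block values.
#' @return The shift (numeric, >= 1).
#' @export
hydro_shift <- function(blocks) {
  v <- if (is.data.frame(blocks)) c(blocks$central, blocks$flank_mean) else blocks
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty corpus")
  abs(min(v)) + 1
}

#' Hydrophobicity prevalence of the cleavage-site region
#'
#' The coil-prevalence ratio applied to shifted hydrophobicity block sums:
#' `(c + shift) / ((l + r)/2 + shift)` with `c`, `l`, `r` the central, left
#' and right 20-residue block sums. Values below 1 mean the cleavage-site
#' block is more hydrophilic than its flanks — the geometry expected of an
#' exposed loop presented to the caspase.
#'
#' @param windows Character vector of residue windows.
#' @param shift Corpus-level shift from [hydro_shift()].
#' @param scale Hydrophobicity scale.
#' @param p1_window_pos P1 position within each window (recycled).
#' @return Numeric vector of prevalence values (strictly positive).
#' @export
hydro_prevalence <- function(windows, shift, scale = hydro_scale(),
                             p1_window_pos = 30L) {
  b <- hydro_block_values(windows, scale, p1_window_pos)
  (b$central + shift) / (b$flank_mean + shift)
}

#' Rank correlation between cleavage-site hydrophobicity and cleavage rate
#'
#' Kendall rank correlation (tau-b, tie-corrected, two-sided) between the
#' central-block hydrophobicity sum of each human site and its measured
#' cleavage rate. A negative tau means hydrophilic sites are cut faster.
#'
#' @param hydro Numeric vector of hydrophobicity sums.
#' @param rate Numeric vector of cleavage rates (same length, >= 3 pairs).
#' @return Tibble `tau`, `p_value`, `n`. Constant input yields `NA` with a
#'   warning.
#' @export
hydro_rate_correlation <- function(hydro, rate) {
  stopifnot(length(hydro) == length(rate))
  ok <- !is.na(hydro) & !is.na(rate)
  hydro <- hydro[ok]; rate <- rate[ok]
  if (length(hydro) < 3L) stop("need at least 3 pairs")
  if (length(unique(hydro)) < 2L || length(unique(rate)) < 2L) {
    warning("constant input: correlation undefined")
    return(tibble(tau = NA_real_, p_value = NA_real_, n = length(hydro)))
  }
  ct <- suppressWarnings(
    cor.test(hydro, rate, method = "kendall", exact = FALSE)
  )
  tibble(tau = unname(ct$estimate), p_value = ct$p.value, n = length(hydro))
}
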