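# Partition window positions into three 20-residue blocks relative to P1:
# left [P1-29, P1-10], central [P1-9, P1+10] (P1 at its 10th position),
# right [P1+11, P1+30]. Truncated windows keep whatever part of each block
# exists; statistics normalize by actual block length.
window_blocks <- function(len, p1_window_pos) {
  rel <- seq_len(len) - p1_window_pos
  ifelse(rel >= -9L & rel <= 10L, "central",
         ifelse(rel < -9L, "left", "right"))
}

#' Coil prevalence of the cleavage-site region
#'
#' Caspases cut in locally unfolded segments, so a cleavage site sitting in a
#' coil between two structured flanks should be especially accessible. With
#' `c`, `l`, `r` the percentage of coil (`C`) characters in the central, left
#' and right 20-residue blocks of the Q3 string, the prevalence is
#' `2c / (l + r)`: 1 means the site region is no more coiled than its flanks,
#' values above 1 mean coil enrichment at the site. Fully structured flanks
#' around a coiled center have no finite ratio and return `Inf` (they pass
#' any "> 1" threshold); an all-structured window returns 1.
#'
#' @param q3 Q3 secondary-structure string over `{H, E, C}`, aligned 1:1 with
#'   the residue window.
#' @param p1_window_pos Position of P1 within the window (30 for full
#'   windows). Truncated windows renormalize each block by its actual length.
#' @return Coil prevalence (non-negative, possibly `Inf`).
#' @export
coil_prevalence <- function(q3, p1_window_pos = 30L) {
  ch <- strsplit(q3, "")[[1]]
  if (!all(ch %in% c("H", "E", "C"))) {
    stop("q3 string may contain only H, E, C")
  }
  blk <- window_blocks(length(ch), p1_window_pos)
  pct <- function(b) {
    sel <- blk == b
    if (!any(sel)) NA_real_ else 100 * mean(ch[sel] == "C")
  }
  cc <- pct("central")
  if (is.na(cc)) stop("central block is empty")
  flank <- mean(c(pct("left"), pct("right")), na.rm = TRUE)
  if (is.nan(flank)) stop("both flanking blocks are empty")
  if (flank == 0) {
    return(if (cc > 0) Inf else 1)
  }
  cc / flank
}

#' Positional frequencies of secondary-structure states
#'
#' Column-wise frequency of H/E/C over a set of Q3 profiles, the numeric
#' matrix behind a sequence-logo display of structure around the cleavage
#' site.
#'
#' @param q3 Character vector of Q3 strings (or tibble with a `q3` column).
#' @param span Window positions to tabulate; default the central 20-residue
#'   block (positions 21-40) of full windows.
#' @return Matrix `length(span) x 3` with columns `H`, `E`, `C`; every row
#'   sums to 1.
#' @export
structure_frequency_matrix <- function(q3, span = 21:40) {
  x <- if (is.data.frame(q3)) q3$q3 else q3
  if (!length(x)) stop("no profiles supplied")
  if (any(nchar(x) < max(span))) stop("all profiles must cover the span")
  m <- t(vapply(x, function(s) strsplit(s, "")[[1]][span],
                character(length(span)), USE.NAMES = FALSE))
  freq <- vapply(c("H", "E", "C"), function(st) colMeans(m == st),
                 numeric(length(span)))
  rownames(freq) <- span
  freq
}
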