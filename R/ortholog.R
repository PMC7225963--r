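#' Select species with a well-represented proteome
#'
#' Ortholog absence is only meaningful when the species' proteome is well
#' annotated, so species are kept only when their protein count strictly
#' exceeds the threshold (default 8000 annotated proteins).
#'
#' @param proteome_sizes Tibble with columns `taxon_id`, `n_proteins`, or a
#'   named numeric vector (names = taxon ids).
#' @param threshold Minimum protein count (strict inequality). Default 8000.
#' @return Character vector of taxon ids passing the filter.
#' @export
filter_species <- function(proteome_sizes, threshold = 8000) {
  if (is.data.frame(proteome_sizes)) {
    ids <- as.character(proteome_sizes$taxon_id)
    counts <- proteome_sizes$n_proteins
  } else {
    ids <- names(proteome_sizes)
    counts <- unname(proteome_sizes)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("protein counts must be non-negative")
  }
  ids[counts > threshold]
}

#' Keep the single best ortholog hit per species and site
#'
#' Ortholog searches return several hits per species (duplicated database
#' entries from different experiments). Hits with an e-value above the cut-off
#' are removed, then exactly one hit is retained per (site, species): the one
#' with the smallest e-value. Ties break deterministically on longer subject
#' segment, then lexicographically smallest segment, so the result is
#' independent of input row order.
#'
#' @param hits Tibble with at least `site_id`, `taxon_id`, `evalue`,
#'   `subject_segment`.
#' @param evalue_max E-value cut-off; hits with `evalue > evalue_max` are
#'   dropped. Default `1e-16`.
#' @return Tibble with one row per (site_id, taxon_id).
#' @export
best_hit_per_species <- function(hits, evalue_max = 1e-16) {
  hits %>%
    filter(.data$evalue <= evalue_max) %>%
    arrange(.data$site_id, .data$taxon_id, .data$evalue,
            desc(nchar(.data$subject_segment)), .data$subject_segment) %>%
    distinct(.data$site_id, .data$taxon_id, .keep_all = TRUE)
}

#' Anchor the human window in an ortholog segment by minimum Hamming distance
#'
#' Slides the human query window over every offset of the subject segment
#' (including partial overhangs; positions outside the subject are read as
#' `'-'`) and picks the placement minimizing the Hamming distance, i.e. the
#' count of window positions whose subject character is not an identical
#' standard residue. Ties prefer a placement whose implied P1 character is
#' 'D' (the aspartate is the anchor), then the leftmost offset.
#'
#' @param human_window Human query window (string).
#' @param subject_segment Ortholog segment (string, non-empty).
#' @param p1_window_pos 1-based position of P1 within the window (30 for full
#'   windows).
#' @return List with `anchor_offset` (0-based offset of the window within the
#'   subject; negative when the window overhangs the subject start),
#'   `anchored_window` (subject text under the window, '-'-padded),
#'   `p1_residue` (character under window position `p1_window_pos`) and `hd`
#'   (the minimized window Hamming distance).
#' @export
anchor_p1 <- function(human_window, subject_segment, p1_window_pos = 30L) {
  w <- nchar(human_window)
  s <- nchar(subject_segment)
  if (s < 1L) stop("subject_segment must be non-empty")
  stopifnot(p1_window_pos >= 1L, p1_window_pos <= w)
  gap <- utf8ToInt("-")
  win <- utf8ToInt(human_window)
  subj <- c(rep.int(gap, w - 1L), utf8ToInt(subject_segment), rep.int(gap, w - 1L))
  n_off <- s + w - 1L
  # row i = placement with 0-based offset (i - w); column j = window position j
  idx <- rep(seq_len(n_off), times = w) + rep(seq_len(w) - 1L, each = n_off)
  m <- matrix(subj[idx], nrow = n_off)
  ok <- (m == rep(win, each = n_off)) & (m %in% .aa_codes())
  hd <- w - .rowSums(ok, n_off, w)
  cand <- which(hd == min(hd))
  if (length(cand) > 1L) {
    with_d <- cand[m[cand, p1_window_pos] == utf8ToInt("D")]
    if (length(with_d)) cand <- with_d
  }
  row <- cand[1L]
  list(
    anchor_offset = row - w,
    anchored_window = intToUtf8(m[row, ]),
    p1_residue = intToUtf8(m[row, p1_window_pos]),
    hd = hd[row]
  )
}

# Project BLAST-style aligned query/subject strings onto window coordinates:
# non-gap query columns advance the window position; the subject character in
# that column (possibly '-') lands there. Subject insertions (query '-') are
# skipped.
project_alignment <- function(qseq, sseq, qstart, window_len) {
  out <- rep("-", window_len)
  qc <- strsplit(qseq, "")[[1]]
  sc <- strsplit(sseq, "")[[1]]
  if (length(qc) != length(sc)) stop("qseq and sseq must have equal length")
  qpos <- qstart - 1L
  for (k in seq_along(qc)) {
    if (qc[k] != "-") {
      qpos <- qpos + 1L
      if (qpos >= 1L && qpos <= window_len) out[qpos] <- sc[k]
    }
  }
  paste(out, collapse = "")
}

#' Annotate ortholog hits with anchored cleavage-site features
#'
#' For every (already best-per-species) hit, locates the human window inside
#' the subject segment with [anchor_p1()], reads off the orthologous octamer,
#' the P1 and P1' characters, computes the octamer Hamming distance to the
#' human octamer, classifies the P1' residue under the Arg/N-degron pathway,
#' and attaches the vertebrate class from the lineage table. When the hit
#' table carries aligned `qseq`/`sseq` strings (gapped input), alignment
#' columns are honored instead of the Hamming scan.
#'
#' @param sites Curated sites tibble from [load_sites()].
#' @param hits Tibble with `site_id`, `taxon_id`, `evalue`,
#'   `subject_segment` (optionally `qseq`, `sseq`, `qstart`).
#' @param lineage Optional tibble `taxon_id`, `species_name`, `class_label`.
#'   Taxa absent from it are flagged `"unclassified"` (excluded from
#'   class-coverage statistics only).
#' @return Tibble of annotated hits: site/taxon identifiers, `evalue`,
#'   `anchor_offset`, `anchored_window`, `p1_residue`, `ortho_octamer`,
#'   `octamer_hd`, `p1prime_residue`, `p1prime_nature`, `class_label`,
#'   `species_name`.
#' @export
annotate_hits <- function(sites, hits, lineage = NULL) {
  missing_sites <- setdiff(unique(hits$site_id), sites$site_id)
  if (length(missing_sites)) {
    stop("hits reference unknown site ids: ",
         paste(head(missing_sites, 5), collapse = ", "))
  }
  h <- inner_join(hits,
                  select(sites, "site_id", "octamer", "window", "p1_window_pos"),
                  by = "site_id")
  n <- nrow(h)
  anchored <- character(n)
  offset <- integer(n)
  gapped <- all(c("qseq", "sseq") %in% names(h))
  qstart <- if ("qstart" %in% names(h)) h$qstart else rep(1L, n)
  for (i in seq_len(n)) {
    if (gapped && !is.na(h$qseq[i]) && !is.na(h$sseq[i])) {
      anchored[i] <- project_alignment(h$qseq[i], h$sseq[i], qstart[i],
                                       nchar(h$window[i]))
      offset[i] <- NA_integer_
    } else {
      a <- anchor_p1(h$window[i], h$subject_segment[i], h$p1_window_pos[i])
      anchored[i] <- a$anchored_window
      offset[i] <- a$anchor_offset
    }
  }
  p1wp <- h$p1_window_pos
  ortho_oct <- vapply(seq_len(n), function(i) {
    octamer_at(anchored[i], p1wp[i])
  }, "")
  out <- mutate(
    select(h, -"window"),
    anchor_offset = offset,
    anchored_window = anchored,
    p1_residue = substr(anchored, p1wp, p1wp),
    ortho_octamer = ortho_oct,
    octamer_hd = hamming_vec(.data$octamer, ortho_oct),
    p1prime_residue = ifelse(p1wp + 1L <= nchar(anchored),
                             substr(anchored, p1wp + 1L, p1wp + 1L), "-"),
    p1prime_nature = classify_p1prime(.data$p1prime_residue)
  )
  out$p1_residue[out$p1_residue == ""] <- "-"
  if (!is.null(lineage)) {
    out <- left_join(out,
                     select(lineage, "taxon_id", "species_name", "class_label"),
                     by = "taxon_id")
    out$class_label[is.na(out$class_label)] <- "unclassified"
  } else {
    out$species_name <- NA_character_
    out$class_label <- "unclassified"
  }
  out[setdiff(names(out), c("qseq", "sseq", "qstart"))]
}
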