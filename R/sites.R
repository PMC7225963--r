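#' Extract the 60-residue query window around a cleavage position
#'
#' The ortholog-search query for a cleavage site is the octamer plus 26
#' flanking residues on each side: protein positions `[p1_pos - 29,
#' p1_pos + 30]`, 60 residues in total, with P1 at window position 30
#' (1-based). Sites closer than 29 residues to a terminus keep a truncated
#' window; the returned start offset and P1 window position record the
#' truncation.
#'
#' @param sequence Protein sequence (single string).
#' @param p1_pos 1-based index of the P1 residue in `sequence`.
#' @return List with `window` (string), `start` (1-based offset of the window
#'   in the protein) and `p1_window_pos` (1-based position of P1 inside the
#'   window; 30 for full windows).
#' @export
extract_window <- function(sequence, p1_pos) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  len <- nchar(sequence)
  if (length(p1_pos) != 1L || is.na(p1_pos) || p1_pos < 1L || p1_pos > len) {
    stop("p1_pos (", p1_pos, ") out of range for sequence of length ", len)
  }
  p1_pos <- as.integer(p1_pos)
  start <- max(1L, p1_pos - 29L)
  end <- min(len, p1_pos + 30L)
  list(
    window = substr(sequence, start, end),
    start = start,
    p1_window_pos = p1_pos - start + 1L
  )
}

# Octamer P4..P4' around p1_pos; positions outside the protein become '-'.
octamer_at <- function(sequence, p1_pos) {
  len <- nchar(sequence)
  pos <- (p1_pos - 3L):(p1_pos + 4L)
  ch <- rep("-", 8L)
  inb <- pos >= 1L & pos <= len
  if (any(inb)) {
    ch[inb] <- strsplit(substr(sequence, pos[inb][1], pos[inb][length(pos[inb])]),
                        "")[[1]]
  }
  paste(ch, collapse = "")
}

#' Load and curate a human cleavage-site catalogue
#'
#' Applies the curation rules for the human catalogue: only sites whose P1
#' residue is aspartate are retained, duplicate (accession, p1_pos) rows
#' collapse to one, rows referencing accessions absent from the proteome or
#' with out-of-bounds positions are skipped, and accessions on an explicit
#' exclusion list (obsolete identifiers, readthroughs) are dropped. Every
#' decision is recorded in a curation report.
#'
#' @param catalogue Path to a tab-separated file with header columns
#'   `site_id`, `accession`, `gene`, `p1_pos`, or a data frame with those
#'   columns.
#' @param proteome Path to a protein FASTA file, a named character vector of
#'   sequences, or a `Biostrings::AAStringSet`. Names are matched on their
#'   first whitespace-delimited token.
#' @param exclude_accessions Character vector of accessions to drop.
#' @return List with `sites` (tibble of curated sites: `site_id`,
#'   `accession`, `gene`, `p1_pos`, `octamer`, `window`, `window_start`,
#'   `p1_window_pos`, `truncated`) and `report` (tibble with one row per
#'   input row: `site_id`, `accession`, `p1_pos`, `status`, `reason`).
#' @export
load_sites <- function(catalogue, proteome, exclude_accessions = character()) {
  cat_tbl <- if (is.character(catalogue) && length(catalogue) == 1L) {
    read_catalogue(catalogue)
  } else {
    as_tibble(catalogue)
  }
  need <- c("site_id", "accession", "gene", "p1_pos")
  if (!all(need %in% names(cat_tbl))) {
    stop("catalogue must have columns: ", paste(need, collapse = ", "))
  }
  seqs <- as_protein_vector(proteome)

  cat_tbl <- mutate(cat_tbl,
                    site_id = as.character(.data$site_id),
                    accession = as.character(.data$accession),
                    p1_pos = as.integer(.data$p1_pos))

  n <- nrow(cat_tbl)
  status <- rep("kept", n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    acc <- cat_tbl$accession[i]
    if (acc %in% exclude_accessions) {
      status[i] <- "dropped"; reason[i] <- "excluded accession"; next
    }
    if (!acc %in% names(seqs)) {
      status[i] <- "dropped"; reason[i] <- "accession not in FASTA"; next
    }
    p1 <- cat_tbl$p1_pos[i]
    if (is.na(p1) || p1 < 1L || p1 > nchar(seqs[[acc]])) {
      status[i] <- "dropped"; reason[i] <- "p1_pos out of bounds"; next
    }
    if (substr(seqs[[acc]], p1, p1) != "D") {
      status[i] <- "dropped"; reason[i] <- "non-D P1"; next
    }
  }

  # collapse duplicates among the survivors (first occurrence wins)
  keep_idx <- which(status == "kept")
  if (length(keep_idx)) {
    key <- paste(cat_tbl$accession[keep_idx], cat_tbl$p1_pos[keep_idx])
    dup <- duplicated(key)
    status[keep_idx[dup]] <- "dropped"
    reason[keep_idx[dup]] <- "duplicate (accession, p1_pos)"
  }

  report <- tibble(
    site_id = cat_tbl$site_id,
    accession = cat_tbl$accession,
    p1_pos = cat_tbl$p1_pos,
    status = status,
    reason = reason
  )

  kept <- cat_tbl[status == "kept", , drop = FALSE]
  sites <- lapply(seq_len(nrow(kept)), function(i) {
    seq <- seqs[[kept$accession[i]]]
    w <- extract_window(seq, kept$p1_pos[i])
    tibble(
      site_id = kept$site_id[i],
      accession = kept$accession[i],
      gene = as.character(kept$gene[i]),
      p1_pos = kept$p1_pos[i],
      octamer = octamer_at(seq, kept$p1_pos[i]),
      window = w$window,
      window_start = w$start,
      p1_window_pos = w$p1_window_pos,
      truncated = nchar(w$window) < 60L
    )
  })
  sites <- if (length(sites)) bind_rows(sites) else tibble(
    site_id = character(), accession = character(), gene = character(),
    p1_pos = integer(), octamer = character(), window = character(),
    window_start = integer(), p1_window_pos = integer(), truncated = logical()
  )
  list(sites = sites, report = report)
}

as_protein_vector <- function(proteome) {
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome)) {
    aa <- Biostrings::readAAStringSet(proteome)
    seqs <- as.character(aa)
    names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
    return(seqs)
  }
  if (methods::is(proteome, "AAStringSet")) {
    seqs <- as.character(proteome)
    names(seqs) <- vapply(strsplit(names(proteome), "\\s+"), `[`, "", 1L)
    return(seqs)
  }
  if (is.character(proteome) && !is.null(names(proteome))) {
    return(proteome)
  }
  stop("proteome must be a FASTA path, a named character vector, or an AAStringSet")
}
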