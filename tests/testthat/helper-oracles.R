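# Independent brute-force oracles, deliberately written with naive loops and
# substr() so they share no code path with the package implementations.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

naive_hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  d <- 0L
  for (k in seq_len(nchar(a))) {
    x <- substr(a, k, k)
    y <- substr(b, k, k)
    if (!(x == y && x %in% AA20)) d <- d + 1L
  }
  d
}

# Hamming distance of the window placed at every 0-based offset of the
# subject (overhangs read '-'); returns the vector indexed by offset
# -(w-1) .. (s-1).
naive_anchor_scan <- function(window, subject) {
  w <- nchar(window)
  s <- nchar(subject)
  offs <- (-(w - 1L)):(s - 1L)
  vapply(offs, function(off) {
    txt <- vapply(seq_len(w), function(j) {
      p <- off + j
      if (p >= 1L && p <= s) substr(subject, p, p) else "-"
    }, "")
    naive_hamming(window, paste(txt, collapse = ""))
  }, integer(1))
}

# O(m^2) Goodman-Kruskal gamma over two rank vectors (ties dropped)
brute_gamma <- function(x, y) {
  m <- length(x)
  con <- dis <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      sx <- sign(x[i] - x[j])
      sy <- sign(y[i] - y[j])
      if (sx == 0L || sy == 0L) next
      if (sx == sy) con <- con + 1L else dis <- dis + 1L
    }
  }
  (con - dis) / (con + dis)
}

# brute-force Baker's Gamma from two hclust trees via their co-cluster ranks
brute_bakers_gamma <- function(ha, hb) {
  ranks <- function(hc) {
    n <- length(hc$labels)
    members <- lapply(seq_len(n), function(i) i)
    r <- matrix(NA_integer_, n, n, dimnames = list(hc$labels, hc$labels))
    groups <- as.list(-seq_len(n))
    cl <- vector("list", n - 1L)
    for (k in seq_len(n - 1L)) {
      get <- function(v) if (v < 0) -v else cl[[v]]
      a <- get(hc$merge[k, 1]); b <- get(hc$merge[k, 2])
      for (i in a) for (j in b) { r[i, j] <- k; r[j, i] <- k }
      cl[[k]] <- c(a, b)
    }
    r
  }
  ra <- ranks(ha)
  rb <- ranks(hb)[ha$labels, ha$labels]
  ut <- upper.tri(ra)
  brute_gamma(ra[ut], rb[ut])
}

# random dendrogram on n labelled leaves
rand_hclust <- function(n, labels = letters[seq_len(n)]) {
  d <- matrix(runif(n * n), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  stats::hclust(stats::as.dist(d), method = "average")
}

# hand-built caterpillar hclust (((l1,l2),l3),l4): merges in the given order
caterpillar4 <- function(labels) {
  structure(
    list(
      merge = matrix(c(-1L, 1L, 2L, -2L, -3L, -4L), ncol = 2),
      height = c(1, 2, 3),
      order = 1:4,
      labels = labels,
      method = "average"
    ),
    class = "hclust"
  )
}

# random residue string
rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# minimal curated-site tibble for annotate_hits tests
toy_site <- function(window, site_id = "s1", p1_window_pos = 30L) {
  tibble::tibble(
    site_id = site_id,
    accession = "ACC1",
    gene = "G1",
    p1_pos = 100L,
    octamer = substr(window, p1_window_pos - 3L, p1_window_pos + 4L),
    window = window,
    window_start = 71L,
    p1_window_pos = p1_window_pos,
    truncated = nchar(window) < 60L
  )
}

# per-site metrics row for selection tests
toy_metrics <- function(site_id, median_hd = 0, coil = 1.5, hydro = 0.8,
                        pct = 98, classes = vertebrate_classes(),
                        destab = 0.6) {
  tibble::tibble(
    site_id = site_id,
    median_hd = median_hd,
    coil_prevalence = coil,
    hydro_prevalence_median = hydro,
    pct_species = pct,
    classes_present = list(classes),
    destab_fraction = destab
  )
}
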