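#' Build a species-by-site character matrix from annotated hits
#'
#' Rows are species, columns are cleavage sites; each cell holds that
#' species' orthologous octamer (or anchored 60-residue window, or the
#' numeric octamer Hamming distance). Missing (species, site) combinations
#' become runs of `'-'` (or `NA` for the numeric variant). The concatenated
#' rows are the profiles on which species are clustered.
#'
#' @param hits Annotated, best-per-species hit tibble.
#' @param type `"octamer"` (default), `"window"`, or `"hd"`.
#' @return For the character types, a character matrix (rownames = taxon
#'   ids, colnames = site ids) with equal string widths within each column;
#'   for `"hd"`, a numeric matrix.
#' @export
species_matrix <- function(hits, type = c("octamer", "window", "hd")) {
  type <- match.arg(type)
  taxa <- sort(unique(hits$taxon_id))
  sites <- sort(unique(hits$site_id))
  if (type == "hd") {
    m <- matrix(NA_real_, length(taxa), length(sites),
                dimnames = list(taxa, sites))
    m[cbind(match(hits$taxon_id, taxa), match(hits$site_id, sites))] <-
      hits$octamer_hd
    return(m)
  }
  col <- if (type == "octamer") hits$ortho_octamer else hits$anchored_window
  m <- matrix(NA_character_, length(taxa), length(sites),
              dimnames = list(taxa, sites))
  m[cbind(match(hits$taxon_id, taxa), match(hits$site_id, sites))] <- col
  for (j in seq_along(sites)) {
    width <- max(nchar(m[, j]), 1L, na.rm = TRUE)
    m[is.na(m[, j]), j] <- strrep("-", width)
    m[, j] <- formatC(m[, j], width = width, flag = "-")
    m[, j] <- gsub(" ", "-", m[, j], fixed = TRUE)
  }
  m
}

# pairwise distances: character matrices -> normalized Hamming distance over
# columns where both species are non-missing ('-'); numeric matrices ->
# mean absolute difference / 8 over shared non-NA columns.
species_distances <- function(mat) {
  taxa <- rownames(mat)
  n <- length(taxa)
  if (n < 2L) stop("need at least 2 species")
  if (is.numeric(mat)) {
    obs <- !is.na(mat)
    D <- matrix(0, n, n, dimnames = list(taxa, taxa))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      comp <- obs[i, ] & obs[j, ]
      if (!any(comp)) {
        stop("no comparable columns between ", taxa[i], " and ", taxa[j])
      }
      D[i, j] <- D[j, i] <- mean(abs(mat[i, comp] - mat[j, comp])) / 8
    }
    return(as.dist(D))
  }
  chars <- t(vapply(seq_len(n), function(i) {
    strsplit(paste(mat[i, ], collapse = ""), "")[[1]]
  }, character(sum(nchar(mat[1, ])))))
  miss <- chars == "-"
  std <- matrix(chars %in% AA_STANDARD, nrow = n)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- !miss[i, ] & !miss[j, ]
    if (!any(comp)) {
      stop("no comparable columns between ", taxa[i], " and ", taxa[j])
    }
    match_ij <- chars[i, comp] == chars[j, comp] & std[i, comp]
    D[i, j] <- D[j, i] <- 1 - mean(match_ij)
  }
  as.dist(D)
}

#' Cluster species on their cleavage-site profiles
#'
#' Agglomerative hierarchical clustering of species on the normalized
#' Hamming distance between their concatenated cleavage-site strings
#' (columns where either species lacks the site are excluded pairwise).
#' The eight-residue sites are variable enough to recover vertebrate classes
#' even though they are far too short for finer phylogenetics.
#'
#' @param mat Matrix from [species_matrix()].
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"average"` (UPGMA on the profile distances).
#' @return Object of class `casp_dendro`: list with `hclust`, `dist` and
#'   `newick` (branch lengths from merge heights).
#' @export
cluster_species <- function(mat, linkage = "average") {
  D <- species_distances(mat)
  hc <- hclust(D, method = linkage)
  structure(
    list(hclust = hc, dist = D,
         newick = ape::write.tree(ape::as.phylo(hc))),
    class = "casp_dendro"
  )
}

#' @export
print.casp_dendro <- function(x, ...) {
  cat("Species dendrogram:", length(x$hclust$labels), "leaves,",
      x$hclust$method, "linkage\n")
  invisible(x)
}

# n x n matrix of merge steps at which each leaf pair first co-clusters
merge_rank_matrix <- function(hc) {
  n <- length(hc$labels)
  r <- matrix(NA_integer_, n, n, dimnames = list(hc$labels, hc$labels))
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    ch <- lapply(hc$merge[k, ], function(v) {
      if (v < 0) -v else members[[v]]
    })
    r[ch[[1]], ch[[2]]] <- k
    r[ch[[2]], ch[[1]]] <- k
    members[[k]] <- c(ch[[1]], ch[[2]])
  }
  r
}

# Goodman-Kruskal gamma from two integer vectors via a contingency table and
# 2-D suffix/prefix sums (pairs tied in either vector are dropped).
gk_gamma <- function(x, y) {
  tab <- unclass(table(x, y))
  R <- nrow(tab); Cc <- ncol(tab)
  if (R < 2L || Cc < 2L) return(NA_real_)
  suff <- tab[R:1, , drop = FALSE]
  suff <- apply(suff, 2, cumsum)[R:1, , drop = FALSE]       # sums over i' >= i
  gt <- t(apply(suff[, Cc:1, drop = FALSE], 1, cumsum))[, Cc:1, drop = FALSE]
  # gt[i, j] = sum_{i' >= i, j' >= j}; concordant partner for cell (i, j)
  con_part <- matrix(0, R, Cc)
  con_part[-R, -Cc] <- gt[-1, -1]
  lt <- t(apply(suff, 1, cumsum))                           # sum_{i' >= i, j' <= j}
  dis_part <- matrix(0, R, Cc)
  dis_part[-R, -1] <- lt[-1, -Cc]
  C <- sum(tab * con_part)
  D <- sum(tab * dis_part)
  if (C + D == 0) return(NA_real_)
  (C - D) / (C + D)
}

#' Baker's Gamma correlation between two dendrograms
#'
#' For every unordered leaf pair, records in each tree the rank of the merge
#' step at which the pair first co-clusters, then computes the
#' Goodman-Kruskal gamma ((concordant - discordant) / (concordant +
#' discordant)) over all pairs of leaf pairs. 1 means the two hierarchies
#' nest leaf pairs in the same order; pairs tied in either tree count as
#' neither concordant nor discordant.
#'
#' @param tree_a,tree_b `hclust` objects or [cluster_species()] results on
#'   the same leaf set (>= 3 leaves).
#' @return Gamma in `[-1, 1]`.
#' @export
bakers_gamma <- function(tree_a, tree_b) {
  as_hc <- function(t) {
    if (inherits(t, "casp_dendro")) t$hclust
    else if (inherits(t, "hclust")) t
    else stop("expected an hclust or casp_dendro")
  }
  a <- as_hc(tree_a); b <- as_hc(tree_b)
  if (length(a$labels) < 3L) stop("need at least 3 leaves")
  if (!setequal(a$labels, b$labels) ||
      length(a$labels) != length(b$labels)) {
    stop("trees must share an identical leaf set")
  }
  ra <- merge_rank_matrix(a)
  rb <- merge_rank_matrix(b)[a$labels, a$labels]
  ut <- upper.tri(ra)
  gk_gamma(ra[ut], rb[ut])
}
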