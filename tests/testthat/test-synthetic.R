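small_config <- function(...) {
  synthetic_config(
    n_sites = 12L,
    n_species_per_class = c(Mammalia = 6L, Aves = 5L, Actinopterygii = 4L),
    octamer_sub_rate = c(Mammalia = 0.04, Aves = 0.07, Actinopterygii = 0.12),
    n_decoy_species = 3L,
    ...
  )
}

test_that("a fixed seed reproduces the corpus exactly", {
  c1 <- generate_corpus(small_config(seed = 7L))
  c2 <- generate_corpus(small_config(seed = 7L))
  expect_identical(c1$proteome, c2$proteome)
  expect_identical(c1$hits, c2$hits)
  expect_identical(c1$q3, c2$q3)
  expect_identical(c1$ground_truth$hit_truth, c2$ground_truth$hit_truth)
  c3 <- generate_corpus(small_config(seed = 8L))
  expect_false(identical(c1$hits, c3$hits))
})

test_that("the zero-noise limit yields identical orthologs and exact recovery", {
  cfg <- synthetic_config(
    seed = 3L, n_sites = 12L,
    n_species_per_class = c(Mammalia = 6L, Aves = 5L, Actinopterygii = 4L),
    n_decoy_species = 3L,
    p1_retention_prob = 1, p1_to_E_prob = 0, gap_at_p1_prob = 0,
    octamer_sub_rate = c(Mammalia = 0, Aves = 0, Actinopterygii = 0),
    flank_sub_rate = 0, species_octamer_sub_rate = 0,
    species_flank_sub_rate = 0, hit_dropout_prob = 0, weak_hit_prob = 0,
    extra_hit_rate = 0,
    coil_fraction = c(left = 1, central = 1, right = 1)
  )
  corp <- generate_corpus(cfg)
  universe <- filter_species(corp$proteome_sizes)
  expect_equal(length(universe), 15L)
  cur <- load_sites(corp$catalogue, corp$proteome)
  best <- best_hit_per_species(
    dplyr::filter(corp$hits, taxon_id %in% universe))
  ann <- annotate_hits(cur$sites, best, corp$lineage)
  expect_true(all(ann$octamer_hd == 0L))
  expect_true(all(ann$p1_residue == "D"))
  rec <- recover_parameters(corp, ann)
  expect_true(all(rec$abs_error == 0))
})

test_that("generated tables are valid pipeline inputs via their file formats", {
  corp <- generate_corpus(small_config(seed = 5L))
  dir <- tempfile("corpus")
  paths <- write_corpus(corp, dir)
  expect_true(all(file.exists(paths)))
  hits <- read_hit_table(paths[["hits"]])
  expect_identical(hits[c("site_id", "taxon_id", "subject_segment")],
                   corp$hits[c("site_id", "taxon_id", "subject_segment")])
  # e-values survive the text round trip to within write precision
  expect_equal(hits$evalue, corp$hits$evalue, tolerance = 1e-12)
  lin <- read_lineage(paths[["lineage"]])
  expect_identical(lin, corp$lineage)
  res <- run_pipeline(paths[["catalogue"]], paths[["proteome"]],
                      paths[["hits"]], paths[["lineage"]],
                      paths[["proteome_sizes"]], paths[["q3"]],
                      config = selection_config(
                        class_list = c("Mammalia", "Aves", "Actinopterygii")))
  expect_equal(nrow(res$sites), 12L)
  expect_true(nrow(res$annotated) > 0)
})

test_that("decoy species are removed by the proteome filter, not by accident", {
  corp <- generate_corpus(small_config(seed = 9L))
  universe <- filter_species(corp$proteome_sizes)
  decoys <- setdiff(corp$proteome_sizes$taxon_id, universe)
  expect_equal(length(decoys), 3L)
  expect_true(any(corp$hits$taxon_id %in% decoys))   # they do produce hits
})

test_that("class-structured divergence is recovered by species clustering", {
  # distinctly separated class rates: low in mammals, high in fish
  cfg <- synthetic_config(
    seed = 17L,
    n_sites = 120L,
    n_species_per_class = c(Mammalia = 4L, Aves = 4L, Reptilia = 4L,
                            Amphibia = 4L, Actinopterygii = 4L,
                            Chondrichthyes = 4L, Coelacanthimorpha = 4L),
    octamer_sub_rate = c(Mammalia = 0.03, Aves = 0.05, Reptilia = 0.07,
                         Amphibia = 0.09, Actinopterygii = 0.11,
                         Chondrichthyes = 0.13, Coelacanthimorpha = 0.15),
    n_decoy_species = 0L,
    hit_dropout_prob = 0, weak_hit_prob = 0, extra_hit_rate = 0
  )
  corp <- generate_corpus(cfg)
  cur <- load_sites(corp$catalogue, corp$proteome)
  ann <- annotate_hits(cur$sites, best_hit_per_species(corp$hits),
                       corp$lineage)
  dn_oct <- cluster_species(species_matrix(ann, "octamer"))
  # cutting at the number of classes recovers the planted classes exactly
  grp <- stats::cutree(dn_oct$hclust, k = 7)
  lin <- corp$lineage
  cls <- lin$class_label[match(names(grp), lin$taxon_id)]
  expect_equal(length(unique(paste(grp, cls))), 7L)
  # the octamer tree recapitulates the tree built from whole 60-mer windows
  dn_win <- cluster_species(species_matrix(ann, "window"))
  expect_gt(bakers_gamma(dn_oct, dn_win), 0.8)
})
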