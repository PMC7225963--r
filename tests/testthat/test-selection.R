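test_that("apply_criteria enforces every strict inequality", {
  cfg <- selection_config()
  m <- toy_metrics("ok")
  expect_equal(apply_criteria(m, cfg)$selected$site_id, "ok")

  # median HD exactly at the bound fails (strict < 2)
  expect_equal(nrow(apply_criteria(toy_metrics("x", median_hd = 2), cfg)$selected), 0L)
  # one class missing fails
  expect_equal(nrow(apply_criteria(
    toy_metrics("x", classes = vertebrate_classes()[-1]), cfg)$selected), 0L)
  # boundary values fail on every other criterion too
  expect_equal(nrow(apply_criteria(toy_metrics("x", coil = 1), cfg)$selected), 0L)
  expect_equal(nrow(apply_criteria(toy_metrics("x", hydro = 1), cfg)$selected), 0L)
  expect_equal(nrow(apply_criteria(toy_metrics("x", pct = 96), cfg)$selected), 0L)
  # NA metrics fail their criterion
  expect_equal(nrow(apply_criteria(toy_metrics("x", median_hd = NA_real_),
                                   cfg)$selected), 0L)
})

test_that("the destabilizing criterion is reported but off by default", {
  m <- toy_metrics("x", destab = 0.1)
  res <- apply_criteria(m, selection_config())
  expect_equal(res$selected$site_id, "x")
  expect_false(res$criteria$pass_destab)
  res2 <- apply_criteria(m, selection_config(destab_enabled = TRUE))
  expect_equal(nrow(res2$selected), 0L)
})

test_that("the pass/fail matrix conjunction reproduces the selected set", {
  set.seed(71)
  m <- dplyr::bind_rows(lapply(1:50, function(i) {
    toy_metrics(paste0("s", i),
                median_hd = sample(0:4, 1),
                coil = runif(1, 0, 3),
                hydro = runif(1, 0, 2),
                pct = runif(1, 90, 100),
                classes = sample(vertebrate_classes(),
                                 sample(5:7, 1)),
                destab = runif(1))
  }))
  cfg <- selection_config()
  res <- apply_criteria(m, cfg)
  cm <- res$criteria
  manual <- cm$pass_median_hd & cm$pass_coil & cm$pass_hydro &
    cm$pass_pct_species & cm$pass_classes
  expect_equal(res$selected$site_id, cm$site_id[manual])
  expect_equal(cm$selected, manual)
})

test_that("relaxing any single threshold never removes a selected site", {
  set.seed(72)
  m <- dplyr::bind_rows(lapply(1:80, function(i) {
    toy_metrics(paste0("s", i),
                median_hd = runif(1, 0, 4),
                coil = runif(1, 0, 3),
                hydro = runif(1, 0, 2),
                pct = runif(1, 90, 100),
                classes = sample(vertebrate_classes(), sample(5:7, 1)),
                destab = runif(1))
  }))
  base_cfg <- selection_config(destab_enabled = TRUE)
  base <- apply_criteria(m, base_cfg)$selected$site_id
  relaxed <- list(
    selection_config(median_hd_max = 3, destab_enabled = TRUE),
    selection_config(coil_prev_min = 0.5, destab_enabled = TRUE),
    selection_config(hydro_prev_max = 1.5, destab_enabled = TRUE),
    selection_config(pct_species_min = 92, destab_enabled = TRUE),
    selection_config(destab_min = 0.2, destab_enabled = TRUE),
    selection_config(require_all_classes = FALSE, destab_enabled = TRUE)
  )
  for (cfg in relaxed) {
    wider <- apply_criteria(m, cfg)$selected$site_id
    expect_true(all(base %in% wider))
  }
})

test_that("validate_reference counts criterion passes for the reference set", {
  m <- dplyr::bind_rows(
    toy_metrics("r1", median_hd = 0),
    toy_metrics("r2", median_hd = 3),
    toy_metrics("o1", median_hd = 1),
    toy_metrics("o2", median_hd = 5)
  )
  cfg <- selection_config(reference_site_ids = c("r1", "r2"))
  v <- validate_reference(m, cfg)
  row <- v[v$criterion == "median_hd", ]
  expect_equal(row$n_targets_pass, 2L)
  expect_equal(row$pct_targets_pass, 50)
  expect_equal(row$n_reference_pass, 1L)
  expect_equal(row$pct_reference_pass, 50)
  # all metrics passing every criterion
  m2 <- dplyr::bind_rows(toy_metrics("r1"), toy_metrics("r2"))
  v2 <- validate_reference(m2, cfg)
  expect_true(all(v2$pct_reference_pass == 100))
  # errors
  expect_error(validate_reference(m, selection_config()), "no reference")
  expect_error(
    validate_reference(m, selection_config(reference_site_ids = "nope")),
    "nope")
})
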