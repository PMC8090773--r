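test_that("grid enumeration follows the product formula", {
  single <- grid_spec(10, 4, 0, subgroup_size = 20, n_pairs = 1)
  expect_identical(enumerate_grid(single),
                   list(n_cells = 1L, n_cca_fits = 2L))
  g <- grid_spec(c(5, 10), 4, c(0, 2, 4), subgroup_size = 20, n_pairs = 7)
  e <- enumerate_grid(g, n_measures = 2, n_scenarios = 2, n_procedures = 2)
  expect_identical(e$n_cells, 2L * 3L * 2L * 2L * 2L)
  expect_identical(e$n_cca_fits, e$n_cells * 7L * 2L)
})

test_that("svr arithmetic and preset grids match the study design", {
  expect_equal(compute_svr(468, 468), 1)
  tj <- grid_preset("tianjin")
  expect_identical(tj$dims_x, as.integer(seq(50, 450, 50)))
  expect_identical(tj$overlaps, as.integer(seq(0, 450, 50)))
  expect_identical(tj$subgroup_size, 468L)
  hcp <- grid_preset("hcp")
  expect_identical(hcp$dims_x, as.integer(seq(35, 315, 35)))
  expect_identical(hcp$dim_y, 35L)
  expect_error(grid_spec(30, 4, 0, subgroup_size = 20), "subgroup_size - 1")
})

test_that("moderate-scenario construction removes the dominant block", {
  d <- generate_correlated_sets(generator_spec(400, 150, 26, rho = 0.85,
                                               n_dominant = 3, seed = 41))
  rf <- reference_fit(d$X, d$Y, dim_y = 20)
  ms <- make_moderate_scenario(d$Y, rf$fit$loadings_y, "drop_top_k", k = 3)
  expect_setequal(ms$removed, d$truth$dominant_vars)
  expect_identical(ncol(ms$table$values), 23L)
  # removing the dominant block weakens the first mode substantially
  rf2 <- reference_fit(d$X, ms$table, dim_y = 20)
  expect_gte(rf$fit$ccc - rf2$fit$ccc, 0.15)
  # retain-below-threshold with a permissive cutoff keeps everything
  keep_all <- make_moderate_scenario(d$Y, rf$fit$loadings_y,
                                     "retain_below_threshold",
                                     threshold = 1.0)
  expect_identical(keep_all$table$values, d$Y$values)
  expect_error(make_moderate_scenario(d$Y, rf$fit$loadings_y,
                                      "retain_below_threshold",
                                      threshold = 0),
               "every variable")
  expect_error(make_moderate_scenario(d$Y, rf$fit$loadings_y, "drop_top_k",
                                      k = 26), "at least one")
})

test_that("guideline verdict applies the CCC floor and dimensionality cap", {
  ok <- advise_stability(0.85, 9, dim_x = 50, dim_y = 50, sample_size = 468)
  expect_false(any(ok$flags))
  weak <- advise_stability(0.60, 9, dim_x = 50, dim_y = 50,
                           sample_size = 468)
  expect_true(weak$flags[["weak_correlation"]])
  expect_match(weak$recommendation, "not recommended")
  high <- advise_stability(0.85, 9, dim_x = 468, dim_y = 50,
                           sample_size = 468)
  expect_true(high$flags[["dimensionality_too_high"]])
  expect_match(high$recommendation, "report the SVR")
})

test_that("small sweeps are deterministic and count their fits", {
  d <- generate_correlated_sets(generator_spec(60, 15, 8, rho = 0.7,
                                               seed = 43))
  g <- grid_spec(c(3, 6), 3, c(0, 10), subgroup_size = 30, n_pairs = 3,
                 n_perm = 20, master_seed = 5)
  r1 <- run_grid(d$X, d$Y, g, "main")
  r2 <- run_grid(d$X, d$Y, g, "main")
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 4L)
  expect_identical(attr(r1, "n_fits"),
                   enumerate_grid(g)$n_cca_fits)
  expect_true(all(is.na(r1$skipped)))
  expect_equal(r1$pct_both_sig + r1$pct_both_insig + r1$pct_mixed,
               rep(100, 4), tolerance = 1e-9)
  # svr column is reported to 2 decimals
  expect_identical(r1$svr, rep(c(10, 5), 2))
})

test_that("infeasible cells are recorded as skipped, never aborting", {
  d <- generate_correlated_sets(generator_spec(40, 10, 6, rho = 0.6,
                                               seed = 44))
  g <- grid_spec(3, 3, c(0, 10), subgroup_size = 25, n_pairs = 2,
                 n_perm = 10, master_seed = 6)
  r <- run_grid(d$X, d$Y, g, "main")   # overlap 0 needs 50 > 40 subjects
  expect_identical(nrow(r), 2L)
  expect_match(r$skipped[r$overlap == 0], "infeasible")
  expect_true(is.na(r$ccc_mean[r$overlap == 0]))
  expect_true(is.na(r$skipped[r$overlap == 10]))
})

test_that("main and control procedures agree in the stable regime", {
  d <- generate_correlated_sets(generator_spec(120, 30, 10, rho = 0.85,
                                               n_dominant = 3, seed = 45))
  g <- grid_spec(6, 6, 0, subgroup_size = 60, n_pairs = 25, n_perm = 30,
                 master_seed = 7)
  rm_ <- run_grid(d$X, d$Y, g, "main")
  rc <- run_grid(d$X, d$Y, g, "control")
  expect_lt(abs(rm_$ccc_absdiff_mean - rc$ccc_absdiff_mean), 0.02)
  expect_gt(rc$loadcorr_y_mean, 0.8)
  expect_gt(rm_$loadcorr_y_mean, 0.8)
})

test_that("sweep records append to a long-format CSV", {
  d <- generate_correlated_sets(generator_spec(40, 8, 5, rho = 0.6,
                                               seed = 46))
  g <- grid_spec(3, 3, 0, subgroup_size = 20, n_pairs = 2, n_perm = 10)
  r <- run_grid(d$X, d$Y, g, "main", scenario = "strong")
  path <- withr::local_tempfile(fileext = ".csv")
  write_run_records(r, path)
  write_run_records(r, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 2L)
  expect_identical(back$scenario, c("strong", "strong"))
})
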