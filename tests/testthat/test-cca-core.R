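test_that("PCA scores are re-standardized and ordered by explained variance", {
  z <- zs(rand_mat(60, 8, seed = 1))
  pcs <- reduce_pca(z, 5)
  expect_lt(max(abs(colMeans(pcs$scores))), 1e-8)
  expect_lt(max(abs(apply(pcs$scores, 2, var) - 1)), 1e-8)
  expect_true(all(diff(pcs$explained_variance_ratio) <= 1e-12))
  expect_error(reduce_pca(z, 9), "out of range")
})

test_that("leading PC direction matches an independent eigendecomposition", {
  z <- zs(rand_mat(200, 3, seed = 7))
  pcs <- reduce_pca(z, 3)
  ev <- eigen(cov(z), symmetric = TRUE)  # independent route to the same basis
  for (j in 1:3) {
    alignment <- abs(sum(pcs$rotation[, j] * ev$vectors[, j]))
    expect_equal(alignment, 1, tolerance = 1e-8)
  }
  expect_equal(pcs$scale^2, ev$values[1:3], tolerance = 1e-8)
})

test_that("CCA on full-rank PC scores equals CCA on the raw variables", {
  zx <- zs(rand_mat(50, 6, seed = 2))
  zy <- zs(rand_mat(50, 4, seed = 3))
  direct <- fit_cca(zx, zy)$ccc
  reduced <- fit_cca(reduce_pca(zx, 6), reduce_pca(zy, 4))$ccc
  expect_equal(reduced, direct, tolerance = 1e-8)
})

test_that("projection of training rows reproduces the training scores", {
  z <- zs(rand_mat(40, 6, seed = 4))
  pcs <- reduce_pca(z, 3)
  expect_equal(project_pc(pcs, z), pcs$scores, tolerance = 1e-10)
})

test_that("degenerate and 1-D cases reduce to known answers", {
  x <- rand_mat(30, 1, seed = 5)
  expect_equal(fit_cca(x, x)$ccc, 1, tolerance = 1e-10)
  y <- rand_mat(30, 1, seed = 6)
  expect_equal(fit_cca(x, y)$ccc, abs(cor(x, y)[1]), tolerance = 1e-10)
  expect_error(fit_cca(x[1:2, , drop = FALSE], y[1:2, , drop = FALSE]),
               "more than 2")
})

test_that("solver matches the brute-force weight search on p = 2 sets", {
  for (s in 1:6) {
    X <- rand_mat(10, 2, seed = s)
    Y <- rand_mat(10, 2, seed = s + 50)
    expect_lt(abs(fit_cca(X, Y)$ccc - brute_force_ccc_2d(X, Y)), 1e-3)
  }
})

test_that("solver agrees with the textbook QR solution when well-conditioned", {
  X <- rand_mat(120, 5, seed = 8)
  Y <- rand_mat(120, 4, seed = 9)
  expect_equal(fit_cca(X, Y)$ccc, stats::cancor(X, Y)$cor[1],
               tolerance = 1e-8)
})

test_that("ccc is invariant under invertible linear transforms of a set", {
  X <- rand_mat(40, 5, seed = 10)
  Y <- rand_mat(40, 4, seed = 11)
  base <- fit_cca(X, Y)$ccc
  set.seed(12)
  A <- matrix(rnorm(25), 5, 5) + diag(5)
  B <- matrix(rnorm(16), 4, 4) + diag(4)
  expect_equal(fit_cca(X %*% A, Y)$ccc, base, tolerance = 1e-8)
  expect_equal(fit_cca(X, Y %*% B)$ccc, base, tolerance = 1e-8)
})

test_that("first-mode ccc is non-decreasing along a nested PC ladder", {
  d <- generate_correlated_sets(generator_spec(120, 40, 10, rho = 0.6,
                                               seed = 13))
  px <- reduce_pca(zscore(d$X), 40)
  py <- reduce_pca(zscore(d$Y), 8)
  ladder <- vapply(c(2, 5, 10, 20, 30, 40), function(k)
    fit_cca(px$scores[, 1:k, drop = FALSE], py)$ccc, 0)
  expect_true(all(diff(ladder) >= -1e-10))
})

test_that("ccc reaches 1 whenever the dimensionalities exhaust the sample", {
  # k_x + k_y >= n forces the whitened subspaces to intersect inside the
  # (n-1)-dimensional centered data space
  d <- generate_correlated_sets(generator_spec(30, 25, 10, rho = 0.3,
                                               seed = 14))
  f <- fit_cca(reduce_pca(zscore(d$X), 20), reduce_pca(zscore(d$Y), 10))
  expect_equal(f$ccc, 1, tolerance = 1e-8)
})

test_that("result invariants hold: correlation identity, ranges, sign rule", {
  d <- generate_correlated_sets(generator_spec(150, 12, 9, rho = 0.85,
                                               n_dominant = 2, seed = 15))
  f <- fit_cca(reduce_pca(zscore(d$X), 8), reduce_pca(zscore(d$Y), 6),
               x_original = d$X, y_original = d$Y)
  expect_lt(abs(cor(f$U1, f$V1) - f$ccc), 1e-8)
  expect_true(f$ccc >= 0 && f$ccc <= 1)
  expect_true(all(abs(c(f$loadings_x, f$loadings_y)) <= 1 + 1e-12))
  expect_equal(var(f$U1), 1, tolerance = 1e-8)
  expect_equal(var(f$V1), 1, tolerance = 1e-8)
  # sign convention: top-|loading| Y variable is positive
  expect_gt(f$loadings_y[which.max(abs(f$loadings_y))], 0)
  expect_true(all(diff(f$all_ccc) <= 1e-12))
})

test_that("loadings are Pearson correlations with the canonical variable", {
  set.seed(16)
  u <- rnorm(5000)
  tab <- subject_table(cbind(same = u, indep = rnorm(5000),
                             anti = -u + rnorm(5000, sd = 0.01)))
  l <- compute_loadings(tab, u)
  expect_equal(unname(l["same"]), 1, tolerance = 1e-10)
  expect_lt(abs(l["indep"]), 0.05)
  expect_lt(l["anti"], -0.99)
  expect_warning(l0 <- compute_loadings(cbind(flat = rep(1, 10), v = 1:10),
                                        1:10), "flat")
  expect_identical(unname(l0["flat"]), 0)
})

test_that("loadings follow the closed-form attenuation of the factor model", {
  # single latent, loading norm r: population cor(x_j, latent) = r_j/sqrt(r_j^2+s^2)
  d <- generate_correlated_sets(generator_spec(4000, 6, 6, rho = 0.8,
                                               seed = 17))
  lat <- d$truth$latent[, 1]
  obs <- drop(cor(d$X$values, lat))
  expect_equal(unname(obs), unname(d$truth$loadings_x[, 1]),
               tolerance = 0.06)
})

test_that("permutation p honors the add-one floor and determinism", {
  d <- generate_correlated_sets(generator_spec(200, 5, 5, rho = 0.9,
                                               seed = 18))
  zx <- zs(d$X$values); zy <- zs(d$Y$values)
  pt <- permutation_test_ccc(zx, zy, n_perm = 100, seed = 3)
  expect_identical(pt$p_value, 1 / 101)
  expect_true(all(pt$null_ccc < pt$ccc))
  pt2 <- permutation_test_ccc(zx, zy, n_perm = 100, seed = 3)
  expect_identical(pt$null_ccc, pt2$null_ccc)
  pt3 <- permutation_test_ccc(zx, zy, n_perm = 100, seed = 4)
  expect_false(identical(pt$null_ccc, pt3$null_ccc))
  expect_error(permutation_test_ccc(zx, zy, n_perm = 0), "n_perm")
})

test_that("bootstrap flags strong loadings and spares pure noise", {
  d <- generate_correlated_sets(generator_spec(400, 6, 6, rho = 0.8,
                                               seed = 19))
  zx <- zscore(d$X); zy <- zscore(d$Y)
  ls <- bootstrap_loading_significance(d$Y, reduce_pca(zx, 4),
                                       reduce_pca(zy, 4), which = "y",
                                       n_boot = 200, seed = 20)
  expect_s3_class(ls, "loading_significance")
  strongest <- which.max(abs(ls$loading))
  expect_true(ls$significant[strongest])
  expect_true(all(ls$ci_low <= ls$ci_high))
  expect_error(bootstrap_loading_significance(d$Y, zx, zy, n_boot = 50),
               "n_boot")
})

test_that("bootstrap significance of a pure-noise variable is near alpha", {
  hits <- vapply(1:150, function(r) {
    d <- generate_correlated_sets(generator_spec(120, 4, 4, rho = 0.7,
                                                 seed = r))
    noise <- subject_table(cbind(d$Y$values,
                                 noise_v = rnorm(120)))
    ls <- bootstrap_loading_significance(noise, zs(d$X$values),
                                         zs(d$Y$values), which = "y",
                                         n_boot = 100, seed = r + 7000)
    ls$significant[ls$variable == "noise_v"]
  }, TRUE)
  # percentile CIs at n_boot = 100 are approximate; generous band around 0.05
  expect_gt(mean(hits), 0.001)
  expect_lt(mean(hits), 0.17)
})

test_that("held-out projection reproduces the discovery fit on itself", {
  d <- generate_correlated_sets(generator_spec(150, 10, 6, rho = 0.7,
                                               seed = 21))
  pipe <- fit_cca_pipeline(d$X, d$Y, kx = 6, ky = 4)
  ph <- project_heldout(pipe, d$X, d$Y)
  expect_equal(ph$pseudo_ccc, pipe$fit$ccc, tolerance = 1e-8)
  bad <- subject_table(d$Y$values[, -1, drop = FALSE])
  expect_error(project_heldout(pipe, d$X, bad), "missing")
})

test_that("held-out pseudo-ccc is centered at zero without shared structure", {
  vals <- vapply(1:30, function(r) {
    d <- generate_correlated_sets(generator_spec(300, 6, 5, rho = 0,
                                                 seed = r))
    idx <- 1:150
    pipe <- fit_cca_pipeline(d$X[idx, ], d$Y[idx, ], kx = 4, ky = 3)
    project_heldout(pipe, d$X[-idx, ], d$Y[-idx, ])$pseudo_ccc
  }, 0)
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("held-out significance transfers at high SVR under strong correlation", {
  agree <- vapply(1:60, function(r) {
    d <- generate_correlated_sets(generator_spec(240, 10, 6, rho = 0.8,
                                                 seed = r + 500))
    idx <- 1:120
    pipe <- fit_cca_pipeline(d$X[idx, ], d$Y[idx, ], kx = 6, ky = 4)
    disc <- permutation_test_ccc(pipe$pcs_x, pipe$pcs_y, n_perm = 50,
                                 seed = r)$p_value < 0.05
    held <- project_heldout(pipe, d$X[-idx, ], d$Y[-idx, ])$p_value < 0.05
    disc == held
  }, TRUE)
  expect_gte(mean(agree), 0.95)
})
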