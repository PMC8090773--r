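#' PCA reduction with re-standardized scores
#'
#' Projects a standardized table onto its top `k` principal components and
#' re-standardizes the scores to unit variance ("double standardization":
#' raw variables are z-scored before PCA and the PC scores are z-scored
#' again before entering CCA).
#'
#' @param standardized A z-scored [subject_table] or matrix (see
#'   [zscore()]).
#' @param k Number of components to keep; `1 <= k <= min(p, n - 1)`.
#' @return An object of class `pc_scores` with elements `scores` (n x k,
#'   each column mean 0 / variance 1), `rotation` (p x k basis from
#'   standardized variables to raw scores), `center` (column means removed
#'   before projection), `scale` (per-PC standard deviations used for
#'   re-standardization), `explained_variance_ratio` and `var_names`.
#' @seealso [project_pc()] to place new subjects on the same components.
#' @export
reduce_pca <- function(standardized, k) {
  v <- as_values(standardized)
  if (anyNA(v)) stop("reduce_pca requires a complete table")
  kmax <- min(ncol(v), nrow(v) - 1L)
  if (k < 1 || k > kmax)
    stop("k = ", k, " out of range; must be in [1, ", kmax, "]")
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  sdev <- pc$sdev[seq_len(k)]
  if (any(sdev < .Machine$double.eps))
    stop("requested components beyond the rank of the data")
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, sdev, "/")
  structure(list(scores = scores,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center,
                 scale = sdev,
                 explained_variance_ratio = pc$sdev[seq_len(k)]^2 /
                   sum(pc$sdev^2),
                 var_names = colnames(v)),
            class = "pc_scores")
}

#' Project new standardized subjects onto fitted components
#'
#' @param pcs A `pc_scores` object from [reduce_pca()].
#' @param newdata A table/matrix of new subjects, already standardized with
#'   the training center/scale, with the same variables in the same order.
#' @return Matrix of re-standardized PC scores (using the training scale).
#' @export
project_pc <- function(pcs, newdata) {
  stopifnot(inherits(pcs, "pc_scores"))
  v <- as_values(newdata)
  if (ncol(v) != nrow(pcs$rotation))
    stop("newdata has ", ncol(v), " variables; expected ",
         nrow(pcs$rotation))
  raw <- sweep(v, 2, pcs$center, "-") %*% pcs$rotation
  sweep(raw, 2, pcs$scale, "/")
}

# Internal: score matrix from pc_scores / subject_table / matrix.
score_matrix <- function(x) {
  if (inherits(x, "pc_scores")) x$scores else as_values(x)
}

# Internal: whitening basis of a centered matrix by eigendecomposition of
# its covariance; directions with relative eigenvalue below `tol` are
# dropped (this is what keeps the solver stable in the rank-deficient
# SVR ~ 1 regime instead of crashing).  Returns the centered data, the
# whitened data (identity covariance) and the basis W with Xc %*% W = Xw.
whiten <- function(m, tol = 1e-10) {
  mc <- sweep(m, 2, colMeans(m), "-")
  ev <- eigen(crossprod(mc) / (nrow(mc) - 1), symmetric = TRUE)
  keep <- ev$values > tol * max(ev$values[1], .Machine$double.eps)
  W <- ev$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ev$values[keep]), sum(keep))
  list(mc = mc, W = W, white = mc %*% W)
}

#' First-mode canonical correlation analysis
#'
#' Solves CCA by singular-value decomposition of the cross-covariance of
#' the two whitened score sets.  Whitening uses an eigendecomposition with
#' relative tolerance `tol` for discarding null directions, so
#' rank-deficient inputs (dimensionality close to the sample size) are
#' handled without failure.  All canonical correlations are computed but
#' only the first mode is assessed downstream.
#'
#' Sign convention: the SVD already gives `cor(U1, V1) >= 0`; in addition,
#' if the largest-|loading| Y-variable has a negative loading, both sides
#' are flipped jointly so runs are comparable and deterministic.
#'
#' @param xp,yp `pc_scores` objects (or plain matrices) over the same
#'   subjects in the same order.
#' @param x_original,y_original Optional [subject_table]s of the original
#'   (pre-PCA) variables used for loading computation; when omitted the
#'   loadings are computed against the score columns themselves.
#' @param tol Relative eigenvalue tolerance of the whitening step.
#' @return An object of class `cca_result`: `ccc` (first-mode canonical
#'   correlation in `[0, 1]`), `A1`/`B1` (weight vectors over the score
#'   columns), `U1`/`V1` (unit-variance canonical variables),
#'   `loadings_x`/`loadings_y` (per-variable correlations with `U1`/`V1`),
#'   `all_ccc` (every canonical correlation) and `n_modes_available`.
#'   `p_value` is `NA` until filled by [permutation_test_ccc()].
#' @export
fit_cca <- function(xp, yp, x_original = NULL, y_original = NULL,
                    tol = 1e-10) {
  X <- score_matrix(xp); Y <- score_matrix(yp)
  if (nrow(X) != nrow(Y))
    stop("the two sets cover different numbers of subjects")
  n <- nrow(X)
  if (n <= 2) stop("CCA needs more than 2 subjects")

  wx <- whiten(X, tol); wy <- whiten(Y, tol)
  K <- crossprod(wx$white, wy$white) / (n - 1)
  sv <- svd(K)
  ccc <- min(max(sv$d[1], 0), 1)
  A1 <- drop(wx$W %*% sv$u[, 1])
  B1 <- drop(wy$W %*% sv$v[, 1])
  U1 <- drop(wx$mc %*% A1)
  V1 <- drop(wy$mc %*% B1)

  lx <- compute_loadings(if (is.null(x_original)) X else x_original, U1)
  ly <- compute_loadings(if (is.null(y_original)) Y else y_original, V1)
  j <- which.max(abs(ly))
  if (length(j) == 1 && ly[j] < 0) {
    B1 <- -B1; V1 <- -V1; ly <- -ly
    A1 <- -A1; U1 <- -U1; lx <- -lx   # keep cor(U1, V1) >= 0
  }
  structure(list(ccc = ccc, A1 = A1, B1 = B1, U1 = U1, V1 = V1,
                 loadings_x = lx, loadings_y = ly, p_value = NA_real_,
                 all_ccc = pmin(pmax(sv$d, 0), 1),
                 n_modes_available = length(sv$d)),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("First-mode CCA: ccc =", format(x$ccc, digits = 4))
  if (!is.na(x$p_value))
    cat(", permutation p =", format(x$p_value, digits = 3))
  cat(" (", x$n_modes_available, " modes available)\n", sep = "")
  invisible(x)
}

#' Canonical loadings of original variables
#'
#' The loading of a variable is its Pearson correlation with the canonical
#' variable of its set.  Zero-variance variables get a loading of 0 with a
#' warning.
#'
#' @param original A [subject_table] or matrix over the same subjects as
#'   the CCA fit.
#' @param canonical_variable Numeric vector (one canonical variable, e.g.
#'   `U1` or `V1`).
#' @return Named numeric vector of loadings in `[-1, 1]`.
#' @export
compute_loadings <- function(original, canonical_variable) {
  v <- as_values(original)
  if (nrow(v) != length(canonical_variable))
    stop("canonical variable length does not match the number of subjects")
  sdev <- apply(v, 2, stats::sd)
  zero <- sdev < .Machine$double.eps
  out <- rep(0, ncol(v))
  names(out) <- colnames(v)
  if (any(!zero))
    out[!zero] <- drop(stats::cor(v[, !zero, drop = FALSE],
                                  canonical_variable))
  if (any(zero))
    warning("zero-variance variable(s) given loading 0: ",
            paste(colnames(v)[zero], collapse = ", "))
  out
}

#' Permutation test for the first-mode canonical correlation
#'
#' The rows of the Y-set are permuted uniformly at random `n_perm` times
#' and the largest canonical correlation recomputed each time.  The
#' p-value uses the add-one estimator
#' `p = (1 + #permuted >= observed) / (n_perm + 1)`, which cannot reach 0
#' at small permutation counts (the workflow default is 100 permutations to
#' limit compute; more than 1000 is preferable when affordable).
#'
#' @param xp,yp `pc_scores` objects or matrices over the same subjects.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the null draw is deterministic under it.
#' @param tol Whitening tolerance passed through to the solver.
#' @return A list with `p_value`, the observed `ccc` and the vector of
#'   permuted `null_ccc` values.
#' @export
permutation_test_ccc <- function(xp, yp, n_perm = 100, seed = 1,
                                 tol = 1e-10) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- score_matrix(xp); Y <- score_matrix(yp)
  if (nrow(X) != nrow(Y))
    stop("the two sets cover different numbers of subjects")
  n <- nrow(X)
  # whitening bases are invariant under row permutation of Y, so they are
  # computed once and each permutation costs only a thin SVD
  wx <- whiten(X, tol); wy <- whiten(Y, tol)
  first_sv <- function(yw) svd(crossprod(wx$white, yw) / (n - 1))$d[1]
  observed <- min(max(first_sv(wy$white), 0), 1)
  null_ccc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      first_sv(wy$white[sample.int(n), , drop = FALSE]), 0)
  })
  null_ccc <- pmin(pmax(null_ccc, 0), 1)
  p <- (1 + sum(null_ccc >= observed)) / (n_perm + 1)
  list(p_value = p, ccc = observed, null_ccc = null_ccc)
}

#' Bootstrap significance of canonical loadings
#'
#' Resamples subjects with replacement, refits the first CCA mode per
#' resample, computes the loadings of the original variables against the
#' resampled canonical variable, sign-aligns each resampled loading vector
#' to the point-estimate loadings (flips it when their correlation is
#' negative), and forms per-variable percentile confidence intervals.  A
#' variable is flagged significant when its interval excludes 0.
#'
#' The resampling scheme (subject-level draws, percentile intervals, sign
#' alignment by correlation with the original loading vector) is a
#' standard-practice reconstruction and is configurable through the
#' arguments.
#'
#' @param original [subject_table] of the original variables of one set
#'   (the set whose loadings are tested), over the fitted subjects.
#' @param xp,yp `pc_scores` objects or matrices entering the CCA.
#' @param which `"x"` or `"y"`: which set `original` belongs to.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param alpha Significance level of the percentile interval.
#' @param seed Integer seed.
#' @param tol Whitening tolerance.
#' @return An object of class `loading_significance`: a data.frame with
#'   columns `variable`, `loading`, `ci_low`, `ci_high`, `significant`,
#'   and attributes `n_boot`, `alpha`, `n_redrawn`.
#' @export
bootstrap_loading_significance <- function(original, xp, yp,
                                           which = c("y", "x"),
                                           n_boot = 200, alpha = 0.05,
                                           seed = 1, tol = 1e-10) {
  which <- match.arg(which)
  if (n_boot < 100) stop("n_boot must be >= 100")
  X <- score_matrix(xp); Y <- score_matrix(yp)
  ov <- as_values(original)
  n <- nrow(X)
  if (nrow(ov) != n)
    stop("original table does not cover the fitted subjects")

  fit0 <- fit_cca(X, Y, tol = tol)
  cv0 <- if (which == "x") fit0$U1 else fit0$V1
  load0 <- compute_loadings(ov, cv0)

  boot <- matrix(NA_real_, n_boot, ncol(ov))
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(10L)) {
        idx <- sample.int(n, n, replace = TRUE)
        ok <- all(apply(ov[idx, , drop = FALSE], 2, stats::sd) >
                    .Machine$double.eps)
        if (ok) break
        n_redrawn <- n_redrawn + 1L
        if (attempt == 10L)
          stop("degenerate bootstrap resample persisted over 10 redraws")
      }
      fb <- fit_cca(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                    tol = tol)
      cvb <- if (which == "x") fb$U1 else fb$V1
      lb <- compute_loadings(ov[idx, , drop = FALSE], cvb)
      if (stats::cor(lb, load0) < 0) lb <- -lb
      boot[b, ] <- lb
    }
  })
  ci <- apply(boot, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  out <- data.frame(variable = colnames(ov), loading = unname(load0),
                    ci_low = ci[1, ], ci_high = ci[2, ],
                    significant = ci[1, ] > 0 | ci[2, ] < 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("loading_significance", "data.frame"),
            n_boot = n_boot, alpha = alpha, n_redrawn = n_redrawn)
}

#' Fit the full single-sample CCA pipeline
#'
#' Convenience wrapper tying the stages together on one (discovery) sample:
#' z-scoring of both sets, PCA reduction with re-standardization, and the
#' first-mode CCA with loadings against the original variables.  The
#' returned object carries every transform needed to project held-out
#' subjects ([project_heldout()]).
#'
#' @param X,Y [subject_table]s over the same subjects (QC-clean).
#' @param kx,ky Number of principal components for each set.
#' @param tol Whitening tolerance.
#' @return An object of class `cca_pipeline`: the `fit` (a `cca_result`),
#'   the `pcs_x`/`pcs_y` bases, the z-scoring parameters and the variable
#'   names of both sets.
#' @export
fit_cca_pipeline <- function(X, Y, kx, ky, tol = 1e-10) {
  stopifnot(inherits(X, "subject_table"), inherits(Y, "subject_table"))
  if (nrow(X$values) != nrow(Y$values))
    stop("X and Y cover different numbers of subjects")
  zx <- zscore(X); zy <- zscore(Y)
  pcs_x <- reduce_pca(zx, kx); pcs_y <- reduce_pca(zy, ky)
  fit <- fit_cca(pcs_x, pcs_y, x_original = X, y_original = Y, tol = tol)
  structure(list(fit = fit, pcs_x = pcs_x, pcs_y = pcs_y,
                 x_center = attr(zx, "center"), x_scale = attr(zx, "scale"),
                 y_center = attr(zy, "center"), y_scale = attr(zy, "scale"),
                 x_vars = X$var_names, y_vars = Y$var_names),
            class = "cca_pipeline")
}

#' Apply discovery canonical weights to held-out subjects
#'
#' Standardizes held-out subjects with the discovery means/SDs, projects
#' them through the discovery PCA bases and canonical weight vectors, and
#' correlates the resulting pseudo-canonical variables.  Significance is
#' the standard correlation test at the held-out sample size.
#'
#' @param pipeline A `cca_pipeline` fitted on the discovery sample.
#' @param heldout_x,heldout_y [subject_table]s of held-out subjects with
#'   exactly the discovery variables.
#' @return A list with `pseudo_ccc` (signed Pearson correlation of the
#'   projected canonical variables), `p_value`, `n` and the projected
#'   `U`/`V` vectors.
#' @export
project_heldout <- function(pipeline, heldout_x, heldout_y) {
  stopifnot(inherits(pipeline, "cca_pipeline"))
  hx <- as_values(heldout_x); hy <- as_values(heldout_y)
  check_vars <- function(got, want, set) {
    if (!identical(colnames(got), want)) {
      miss <- setdiff(want, colnames(got))
      extra <- setdiff(colnames(got), want)
      stop("held-out ", set, " variables differ from discovery",
           if (length(miss)) paste0("; missing: ",
                                    paste(miss, collapse = ", ")) else "",
           if (length(extra)) paste0("; unexpected: ",
                                     paste(extra, collapse = ", ")) else "")
    }
  }
  check_vars(hx, pipeline$x_vars, "X")
  check_vars(hy, pipeline$y_vars, "Y")
  zx <- sweep(sweep(hx, 2, pipeline$x_center, "-"), 2, pipeline$x_scale, "/")
  zy <- sweep(sweep(hy, 2, pipeline$y_center, "-"), 2, pipeline$y_scale, "/")
  U <- drop(project_pc(pipeline$pcs_x, zx) %*% pipeline$fit$A1)
  V <- drop(project_pc(pipeline$pcs_y, zy) %*% pipeline$fit$B1)
  ct <- stats::cor.test(U, V)
  list(pseudo_ccc = unname(ct$estimate), p_value = ct$p.value,
       n = length(U), U = U, V = V)
}
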