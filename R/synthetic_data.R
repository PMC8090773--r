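#' Specification for the paired-set synthetic generator
#'
#' Defines a population in which two variable sets (an "imaging-like" set X
#' and a "subject-measure-like" set Y) share `n_modes` latent modes of
#' co-variation with prescribed population canonical correlations.  The
#' generator gives an analytic ground truth: for mode m with canonical
#' correlation `rho[m]`, each set carries a loading vector along one latent
#' factor, and the loading norm is solved in closed form (see
#' [generate_correlated_sets()]).
#'
#' A few "dominant" Y-variables (think gender/height/weight) can be given
#' very large loadings on the first mode; removing them converts a strong
#' first-mode correlation into a moderate one, which is how the
#' strong/moderate study scenarios are constructed.
#'
#' @param n_subjects Number of subjects (rows).
#' @param p_x,p_y Number of variables in the X (imaging-like) and Y
#'   (subject-measure-like) sets.
#' @param rho Vector of population first/second/... -mode canonical
#'   correlations, each in `[0, 1]`, strictly decreasing.
#' @param n_modes Number of shared latent modes; defaults to `length(rho)`.
#' @param n_dominant Number of dominant Y-variables (0 allowed); they are
#'   appended as the last columns of Y with names `dominant_1`, ... and
#'   `dominant_1` is dichotomized (gender-like).
#' @param dominant_strength Target absolute correlation of each dominant
#'   variable with the first-mode latent, in (0, 1].  The default 0.80 is
#'   calibrated so that, at `rho[1] = 0.85` with 3 dominant variables and a
#'   full sample of ~468 subjects analyzed at a subject-to-variable ratio
#'   of 9, the strong scenario shows a sample first-mode CCC near 0.87 and
#'   removing the dominant block leaves a moderate-regime sample CCC near
#'   0.64 (population residual ~0.46).
#' @param noise_sd Standard deviation of the independent per-variable noise;
#'   must be positive unless all `rho` are 0 or 1 (noise-free edge cases).
#' @param within_cor Optional within-set equicorrelation of the noise
#'   component, in `[0, 1)`.  Nonzero values add a set-specific common
#'   factor to the noise; the population canonical correlations are then
#'   only approximately `rho`.
#' @param seed Integer seed; the same spec and seed give bit-identical data.
#'
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_subjects, p_x, p_y, rho, n_modes = length(rho),
                           n_dominant = 0, dominant_strength = 0.80,
                           noise_sd = 1, within_cor = 0, seed = 1) {
  rho <- as.numeric(rho)
  if (length(rho) != n_modes)
    stop("rho must have one entry per mode (n_modes = ", n_modes, ")")
  if (any(rho < 0 | rho > 1))
    stop("all rho must lie in [0, 1]")
  if (n_modes > 1 && any(diff(rho) >= 0))
    stop("rho must be strictly decreasing across modes")
  if (n_subjects < 1 || p_x < 1 || p_y < 1 || n_modes < 1)
    stop("n_subjects, p_x, p_y and n_modes must all be >= 1")
  if (n_dominant < 0 || n_dominant > p_y)
    stop("n_dominant must be in [0, p_y]")
  if (n_dominant > 0 &&
      (dominant_strength <= 0 || dominant_strength > 1))
    stop("dominant_strength must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd == 0 && !all(rho %in% c(0, 1)))
    stop("noise_sd = 0 is only meaningful when every rho is 0 or 1")
  if (within_cor < 0 || within_cor >= 1)
    stop("within_cor must be in [0, 1)")
  if (n_modes > min(p_x, p_y))
    stop("n_modes cannot exceed min(p_x, p_y)")
  if (n_dominant > 0 && p_y - n_dominant < n_modes)
    stop("p_y - n_dominant must leave room for ", n_modes,
         " regular mode directions")
  structure(list(n_subjects = n_subjects, p_x = p_x, p_y = p_y,
                 n_modes = n_modes, rho = rho, n_dominant = n_dominant,
                 dominant_strength = dominant_strength, noise_sd = noise_sd,
                 within_cor = within_cor, seed = as.integer(seed)),
            class = "generator_spec")
}

# Loading norm for a single-latent mode: with loading vector a (orthogonal
# across modes) and independent noise variance s^2 per column, the squared
# multiple correlation between the latent and the set is
#   R^2 = |a|^2 / (|a|^2 + s^2).
# The population canonical correlation of the mode is R_x * R_y; the split is
# symmetric (R_x = R_y = sqrt(rho)), so R^2 = rho and
#   |a|^2 = s^2 * rho / (1 - rho).
mode_norm <- function(rho, noise_sd) {
  if (rho >= 1) return(if (noise_sd == 0) 1 else Inf)
  noise_sd * sqrt(rho / (1 - rho))
}

#' Generate paired variable sets with known canonical structure
#'
#' Draws `n_modes` independent standard-normal latent scores per subject.
#' Mode m contributes a rank-one loading pattern to each set along a random
#' direction (directions are mutually orthogonal within a set), scaled so
#' that the population canonical correlation of the mode equals `rho[m]`:
#' with independent noise of sd `noise_sd`, the loading-vector norm is
#' `noise_sd * sqrt(rho / (1 - rho))` per set (symmetric split, see
#' [generator_spec()]).  Dominant Y-variables load only on mode 1 with
#' per-variable coefficient `noise_sd * g / sqrt(1 - g^2)` where
#' `g = dominant_strength`, so their population correlation with the mode-1
#' latent is exactly `g`; the remaining mode-1 "budget" is spread over a
#' random direction in the regular Y-columns.  `dominant_1` is dichotomized
#' at zero (its coefficient is pre-boosted by `sqrt(pi/2)` so the
#' point-biserial correlation with the latent is still `g`).
#'
#' @param spec A [generator_spec].
#' @return A list with elements `X` and `Y` ([subject_table]s without
#'   missing values) and `truth`, a list holding the population canonical
#'   correlations (`rho`), the loading matrices (`lambda_x`, `lambda_y`),
#'   the population variable-latent correlations (`loadings_x`,
#'   `loadings_y`), the latent scores (`latent`) and the dominant variable
#'   names (`dominant_vars`).
#' @export
generate_correlated_sets <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_subjects; M <- spec$n_modes; s <- spec$noise_sd
  p_x <- spec$p_x; p_y <- spec$p_y; n_dom <- spec$n_dominant
  p_reg <- p_y - n_dom

  with_seed(spec$seed, {
    Z <- matrix(stats::rnorm(n * M), n, M)

    # X loadings: orthonormal random directions, one per mode, scaled to the
    # closed-form norm.
    Qx <- qr.Q(qr(matrix(stats::rnorm(p_x * M), p_x, M)))
    lambda_x <- Qx %*% diag(vapply(spec$rho, mode_norm, 0, noise_sd = s),
                            M, M)

    # Y loadings: mode-1 budget B = |b|^2 split between dominant columns and
    # a random regular direction; modes >= 2 live on regular directions
    # orthogonal to the mode-1 regular direction.
    Qy <- qr.Q(qr(matrix(stats::rnorm(p_reg * M), p_reg, M)))
    lambda_y <- matrix(0, p_y, M)
    B <- mode_norm(spec$rho[1], s)^2
    if (n_dom > 0) {
      g <- spec$dominant_strength
      d <- if (g >= 1) 1 else s * g / sqrt(1 - g^2)
      D <- n_dom * d^2
      if (D > B + 1e-12)
        stop("dominant variables alone would imply a first-mode canonical ",
             "correlation above rho[1] = ", spec$rho[1],
             "; lower n_dominant or dominant_strength")
      lambda_y[p_reg + seq_len(n_dom), 1] <- d
      lambda_y[seq_len(p_reg), 1] <- Qy[, 1] * sqrt(max(B - D, 0))
    } else {
      lambda_y[seq_len(p_reg), 1] <- Qy[, 1] * sqrt(B)
    }
    if (M > 1)
      for (m in 2:M)
        lambda_y[seq_len(p_reg), m] <- Qy[, m] * mode_norm(spec$rho[m], s)

    draw_noise <- function(p) {
      E <- matrix(stats::rnorm(n * p), n, p)
      if (spec$within_cor > 0) {
        h <- stats::rnorm(n)
        E <- sqrt(1 - spec$within_cor) * E + sqrt(spec$within_cor) * h
      }
      s * E
    }
    X <- Z %*% t(lambda_x) + draw_noise(p_x)
    Y <- Z %*% t(lambda_y) + draw_noise(p_y)

    dom_names <- character(0)
    if (n_dom > 0) {
      dom_names <- sprintf("dominant_%d", seq_len(n_dom))
      # dichotomize dominant_1; boost its coefficient first so that
      # cor(1{W>0}, z) = sqrt(2/pi) * cor(W, z) still equals g.
      g1 <- min(spec$dominant_strength * sqrt(pi / 2), 0.999)
      d1 <- if (s == 0) 1 else s * g1 / sqrt(1 - g1^2)
      j1 <- p_reg + 1
      w <- Z[, 1] * d1 + Y[, j1] - Z[, 1] * lambda_y[j1, 1]
      Y[, j1] <- as.numeric(w > 0)
    }
    x_names <- sprintf("img_%04d", seq_len(p_x))
    y_names <- c(sprintf("sm_%03d", seq_len(p_reg)), dom_names)
    ids <- sprintf("sub_%05d", seq_len(n))

    col_sd <- function(L) sqrt(rowSums(L^2) + s^2)
    truth <- list(rho = spec$rho,
                  lambda_x = lambda_x, lambda_y = lambda_y,
                  loadings_x = lambda_x / col_sd(lambda_x),
                  loadings_y = lambda_y / col_sd(lambda_y),
                  latent = Z, noise_sd = s, dominant_vars = dom_names)
    list(X = subject_table(X, x_names, ids),
         Y = subject_table(Y, y_names, ids),
         truth = truth)
  })
}

#' Specification for a quality-control defect fixture
#'
#' Describes a subject-by-variable table seeded with exactly countable QC
#' defects: variables with many missing entries, near-constant variables,
#' variables excluded by name (HCP-style category lists), and otherwise
#' clean subjects carrying at least one missing cell in a clean variable
#' (so they survive variable filtering but are dropped by subject
#' filtering).
#'
#' @param n_subjects,n_vars Table dimensions.
#' @param n_heavy_missing Variables given more than `missing_threshold`
#'   missing entries.
#' @param n_low_variance Variables where more than `identical_threshold`
#'   subjects share a single value.
#' @param n_subjects_with_missing Clean subjects given missing entries
#'   confined to clean variables.
#' @param name_excluded Character vector of variable names to be excluded by
#'   list; these columns are generated clean and carry the given names.
#' @param seed Integer seed.
#' @return An object of class `qc_fixture_spec`.
#' @export
qc_fixture_spec <- function(n_subjects, n_vars, n_heavy_missing = 0,
                            n_low_variance = 0, n_subjects_with_missing = 0,
                            name_excluded = character(0), seed = 1) {
  if (n_heavy_missing + n_low_variance + length(name_excluded) > n_vars)
    stop("defect variable counts exceed n_vars")
  if (n_subjects_with_missing > n_subjects)
    stop("n_subjects_with_missing exceeds n_subjects")
  if (anyDuplicated(name_excluded))
    stop("name_excluded contains duplicates")
  structure(list(n_subjects = n_subjects, n_vars = n_vars,
                 n_heavy_missing = n_heavy_missing,
                 n_low_variance = n_low_variance,
                 n_subjects_with_missing = n_subjects_with_missing,
                 name_excluded = as.character(name_excluded),
                 seed = as.integer(seed)),
            class = "qc_fixture_spec")
}

#' Generate a table with exactly countable QC defects
#'
#' Builds a [subject_table] in which, measured by the counting rules of
#' [filter_variables()] and [filter_subjects()]: exactly
#' `spec$n_heavy_missing` variables have strictly more than
#' `missing_threshold` missing entries; exactly `spec$n_low_variance`
#' variables have strictly more than `identical_threshold` subjects sharing
#' one value (and no missing cells); and exactly
#' `spec$n_subjects_with_missing` subjects have missing values confined to
#' clean variables.  All other cells are complete draws from a continuous
#' distribution.  Deterministic under `spec$seed`.
#'
#' @param spec A [qc_fixture_spec].
#' @param missing_threshold,identical_threshold The thresholds the QC
#'   filters will be run with; both must be smaller than `spec$n_subjects`.
#' @return A [subject_table].
#' @export
generate_qc_fixture <- function(spec, missing_threshold = 200,
                                identical_threshold = 800) {
  stopifnot(inherits(spec, "qc_fixture_spec"))
  n <- spec$n_subjects; p <- spec$n_vars
  if (missing_threshold >= n || identical_threshold >= n)
    stop("thresholds must be smaller than n_subjects")
  if (missing_threshold + 1 > n)
    stop("cannot place more than missing_threshold missing entries")

  n_excl <- length(spec$name_excluded)
  i_excl <- seq_len(n_excl)
  i_heavy <- n_excl + seq_len(spec$n_heavy_missing)
  i_lowvar <- n_excl + spec$n_heavy_missing + seq_len(spec$n_low_variance)
  i_clean <- setdiff(seq_len(p), c(i_excl, i_heavy, i_lowvar))
  if (spec$n_subjects_with_missing > 0 && length(i_clean) == 0)
    stop("no clean variables left to host subject-level missing values")

  with_seed(spec$seed, {
    vals <- matrix(stats::rnorm(n * p), n, p)
    for (j in i_heavy)
      vals[sample.int(n, missing_threshold + 1), j] <- NA
    for (j in i_lowvar)
      vals[sample.int(n, identical_threshold + 1), j] <- 0
    if (spec$n_subjects_with_missing > 0) {
      subj <- sample.int(n, spec$n_subjects_with_missing)
      # round-robin over clean variables keeps each clean column far below
      # the missing threshold
      cols <- rep_len(i_clean, length(subj))
      vals[cbind(subj, cols)] <- NA
    }
    nm <- sprintf("var_%03d", seq_len(p))
    nm[i_excl] <- spec$name_excluded
    subject_table(vals, nm, sprintf("sub_%05d", seq_len(n)))
  })
}
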