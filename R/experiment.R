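#' Grid specification for a stability sweep
#'
#' A sweep crosses imaging-set dimensionalities (the SVR ladder) with
#' subject-overlap rates; each cell is evaluated over `n_pairs` subgroup
#' pairs with `n_perm` permutations per CCA.
#'
#' @param dims_x Vector of imaging-set dimensionalities (numbers of PCs).
#' @param dim_y Fixed subject-measure dimensionality.
#' @param overlaps Vector of exact subject-overlap counts.
#' @param subgroup_size Subjects per subgroup.
#' @param n_pairs Subgroup pairs per cell.
#' @param n_perm Permutations per CCA significance test.
#' @param master_seed Integer master seed; every pair, permutation and cell
#'   derives its own seed from it.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(dims_x, dim_y, overlaps, subgroup_size,
                      n_pairs = 100, n_perm = 100, master_seed = 1) {
  if (any(c(dims_x, dim_y) > subgroup_size - 1))
    stop("every dimensionality must be <= subgroup_size - 1")
  if (any(c(dims_x, dim_y) < 1)) stop("dimensionalities must be >= 1")
  if (any(overlaps < 0 | overlaps > subgroup_size))
    stop("overlaps must be in [0, subgroup_size]")
  structure(list(dims_x = as.integer(dims_x), dim_y = as.integer(dim_y),
                 overlaps = as.integer(overlaps),
                 subgroup_size = as.integer(subgroup_size),
                 n_pairs = as.integer(n_pairs), n_perm = as.integer(n_perm),
                 master_seed = as.integer(master_seed)),
            class = "grid_spec")
}

#' Preset grids
#'
#' `"tianjin"`: subgroup 468, imaging dimensionalities 50..450 by 50,
#' subject-measure dimensionality 50, overlaps 0..450 by 50.
#' `"hcp"`: subgroup 350, dimensionalities 35..315 by 35, overlaps 0..315
#' by 35; the subject-measure dimensionality defaults to the ladder
#' increment (35) and is exposed as a parameter.
#' Both default to scaled-down `n_pairs`/`n_perm`; pass `n_pairs = 1000`
#' for the full-scale sweep (a cluster-sized job).
#'
#' @param name `"tianjin"` or `"hcp"`.
#' @param n_pairs,n_perm,master_seed Passed to [grid_spec()].
#' @param dim_y Subject-measure dimensionality override.
#' @return A `grid_spec`.
#' @export
grid_preset <- function(name = c("tianjin", "hcp"), n_pairs = 100,
                        n_perm = 100, master_seed = 1, dim_y = NULL) {
  name <- match.arg(name)
  if (name == "tianjin")
    grid_spec(seq(50, 450, 50), if (is.null(dim_y)) 50 else dim_y,
              seq(0, 450, 50), 468, n_pairs, n_perm, master_seed)
  else
    grid_spec(seq(35, 315, 35), if (is.null(dim_y)) 35 else dim_y,
              seq(0, 315, 35), 350, n_pairs, n_perm, master_seed)
}

#' Cell and fit counts of a sweep
#'
#' @param grid A `grid_spec`.
#' @param n_measures Number of imaging measures swept (e.g. 2 for
#'   GMV + ReHo).
#' @param n_scenarios Number of correlation-strength scenarios.
#' @param n_procedures Number of procedures (main/control).
#' @return List with `n_cells` (product of grid factors) and `n_cca_fits`
#'   (`n_cells * n_pairs * 2`, two subgroups per pair).
#' @export
enumerate_grid <- function(grid, n_measures = 1, n_scenarios = 1,
                           n_procedures = 1) {
  n_cells <- length(grid$dims_x) * length(grid$overlaps) *
    n_measures * n_scenarios * n_procedures
  list(n_cells = as.integer(n_cells),
       n_cca_fits = as.integer(n_cells * grid$n_pairs * 2))
}

#' Subject-to-variable ratio
#'
#' The SVR is computed on the imaging-set dimensionality (the
#' subject-measure dimensionality is held fixed along the ladder); e.g.
#' 468 subjects over 50 PCs give 9.36, over 450 PCs give 1.04.
#'
#' @param subgroup_size Subjects per subgroup.
#' @param dim_x Imaging-set dimensionality.
#' @return `subgroup_size / dim_x` (reported to 2 decimals in sweep
#'   outputs).
#' @export
compute_svr <- function(subgroup_size, dim_x) {
  if (any(dim_x < 1)) stop("dim_x must be >= 1")
  subgroup_size / dim_x
}

#' Run a stability sweep
#'
#' For every combination of imaging dimensionality and subject overlap,
#' generates `n_pairs` subgroup pairs and fits the first CCA mode in both
#' subgroups of each pair.  Under the `"main"` procedure each subgroup is
#' z-scored and PCA-reduced on its own (so PC inconsistency between the
#' subgroups contributes to any instability); under the `"control"`
#' procedure z-scoring and PCA happen once on the whole group and only the
#' score rows are split, giving both subgroups perfectly corresponding
#' PCs.  Loadings are computed against the original variables in both
#' procedures.  Pairs are shared across the dimensionality ladder (the
#' top-k PC scores are nested), which is statistically equivalent to
#' redrawing them and considerably cheaper.
#'
#' Infeasible cells (overlap not achievable, dimensionality exceeding the
#' subgroup rank) are recorded as skipped with a reason, never aborting
#' the sweep.  The whole sweep is deterministic under
#' `grid$master_seed`.
#'
#' @param X,Y QC-clean [subject_table]s over the same subjects.
#' @param grid A [grid_spec()].
#' @param procedure `"main"` or `"control"`.
#' @param scenario Free-text label written into the records (e.g.
#'   `"strong"`, `"moderate"`).
#' @param alpha Significance threshold for Assessment 2.
#' @param verbose Log one line per cell.
#' @param return_outcomes Also return the raw [pair_outcome] lists (keyed
#'   `"dim<k>_ov<o>"`), for loading-profile analyses.
#' @return A data.frame with one row per grid cell: keys (`procedure`,
#'   `scenario`, `dim_x`, `dim_y`, `svr`, `overlap`), CCC magnitude
#'   summaries (`ccc_mean`, `ccc_sd` over the `2 * n_pairs` fits), the
#'   three assessments (see [summarize_stability()]), and a `skipped`
#'   reason column (`NA` for computed cells).  Attribute `n_fits` counts
#'   the CCA fits performed.  If `return_outcomes`, a list
#'   `(records, outcomes)`.
#' @export
run_grid <- function(X, Y, grid, procedure = c("main", "control"),
                     scenario = "strong", alpha = 0.05, verbose = FALSE,
                     return_outcomes = FALSE) {
  procedure <- match.arg(procedure)
  stopifnot(inherits(X, "subject_table"), inherits(Y, "subject_table"),
            inherits(grid, "grid_spec"))
  n <- nrow(X$values)
  if (nrow(Y$values) != n)
    stop("X and Y cover different numbers of subjects")
  size <- grid$subgroup_size
  kmax <- max(grid$dims_x)
  if (kmax > min(ncol(X$values), size - 1))
    stop("max(dims_x) exceeds what the X set / subgroup size supports")
  if (grid$dim_y > min(ncol(Y$values), size - 1))
    stop("dim_y exceeds what the Y set / subgroup size supports")

  if (procedure == "control") {
    gx <- reduce_pca(zscore(X), kmax)
    gy <- reduce_pca(zscore(Y), grid$dim_y)
  }

  n_fits <- 0L
  records <- list()
  all_outcomes <- list()

  for (oi in seq_along(grid$overlaps)) {
    ov <- grid$overlaps[oi]
    cell_seed <- mix_seed(grid$master_seed, oi)
    if (2 * size - ov > n) {
      for (k in grid$dims_x)
        records[[length(records) + 1L]] <- skipped_record(
          procedure, scenario, k, grid$dim_y, size, ov,
          sprintf("infeasible overlap: 2*%d - %d > %d", size, ov, n))
      next
    }
    outcomes <- rep(list(vector("list", grid$n_pairs)),
                    length(grid$dims_x))
    for (i in seq_len(grid$n_pairs)) {
      pr <- split_with_overlap(n, size, ov, seed = mix_seed(cell_seed, i))
      sides <- list(pr$idx_a, pr$idx_b)
      per_side <- vector("list", 2L)
      for (s in 1:2) {
        idx <- sides[[s]]
        ox <- X$values[idx, , drop = FALSE]
        oy <- Y$values[idx, , drop = FALSE]
        if (procedure == "main") {
          sx <- reduce_pca(zscore(ox), kmax)$scores
          sy <- reduce_pca(zscore(oy), grid$dim_y)$scores
        } else {
          sx <- gx$scores[idx, , drop = FALSE]
          sy <- gy$scores[idx, , drop = FALSE]
        }
        fits <- vector("list", length(grid$dims_x))
        for (di in seq_along(grid$dims_x)) {
          k <- grid$dims_x[di]
          sxk <- sx[, seq_len(k), drop = FALSE]
          fit <- fit_cca(sxk, sy, x_original = ox, y_original = oy)
          n_fits <- n_fits + 1L
          nd <- length(grid$dims_x)
          pt <- permutation_test_ccc(sxk, sy, n_perm = grid$n_perm,
                                     seed = mix_seed(cell_seed,
                                                     (i * 2L + s) * nd + di))
          fit$p_value <- pt$p_value
          fits[[di]] <- fit
        }
        per_side[[s]] <- fits
      }
      for (di in seq_along(grid$dims_x)) {
        fa <- per_side[[1]][[di]]; fb <- per_side[[2]][[di]]
        outcomes[[di]][[i]] <- pair_outcome(
          fa$ccc, fb$ccc, fa$p_value, fb$p_value,
          fa$loadings_x, fb$loadings_x, fa$loadings_y, fb$loadings_y)
      }
    }
    for (di in seq_along(grid$dims_x)) {
      k <- grid$dims_x[di]
      outs <- outcomes[[di]]
      cccs <- unlist(lapply(outs, function(o) c(o$ccc_a, o$ccc_b)))
      summ <- summarize_stability(outs, alpha)
      rec <- data.frame(procedure = procedure, scenario = scenario,
                        dim_x = k, dim_y = grid$dim_y,
                        svr = round(compute_svr(size, k), 2),
                        overlap = ov,
                        ccc_mean = mean(cccs), ccc_sd = stats::sd(cccs),
                        stringsAsFactors = FALSE)
      rec <- cbind(rec, as.data.frame(summ)[, c(
        "ccc_absdiff_mean", "ccc_absdiff_sd", "pct_both_sig",
        "pct_both_insig", "pct_mixed", "loadcorr_x_mean", "loadcorr_x_sd",
        "loadcorr_y_mean", "loadcorr_y_sd", "n_skipped_x", "n_skipped_y",
        "n_pairs")])
      rec$skipped <- NA_character_
      records[[length(records) + 1L]] <- rec
      if (return_outcomes)
        all_outcomes[[sprintf("dim%d_ov%d", k, ov)]] <- outs
      if (verbose)
        message(sprintf(
          "[%s/%s] dim_x=%d overlap=%d: ccc=%.3f |dCCC|=%.4f loadcorr_y=%.3f",
          procedure, scenario, k, ov, rec$ccc_mean, rec$ccc_absdiff_mean,
          rec$loadcorr_y_mean))
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "n_fits") <- n_fits
  if (return_outcomes) list(records = out, outcomes = all_outcomes) else out
}

skipped_record <- function(procedure, scenario, k, dim_y, size, ov,
                           reason) {
  data.frame(procedure = procedure, scenario = scenario, dim_x = k,
             dim_y = dim_y, svr = round(compute_svr(size, k), 2),
             overlap = ov, ccc_mean = NA_real_, ccc_sd = NA_real_,
             ccc_absdiff_mean = NA_real_, ccc_absdiff_sd = NA_real_,
             pct_both_sig = NA_real_, pct_both_insig = NA_real_,
             pct_mixed = NA_real_, loadcorr_x_mean = NA_real_,
             loadcorr_x_sd = NA_real_, loadcorr_y_mean = NA_real_,
             loadcorr_y_sd = NA_real_, n_skipped_x = NA_integer_,
             n_skipped_y = NA_integer_, n_pairs = 0L, skipped = reason,
             stringsAsFactors = FALSE)
}

#' Append sweep records to a long-format CSV
#'
#' @param records Output of [run_grid()].
#' @param path CSV path; created with a header if absent, appended to
#'   otherwise.
#' @return `path`, invisibly.
#' @export
write_run_records <- function(records, path) {
  new <- !file.exists(path)
  utils::write.table(records, path, sep = ",", row.names = FALSE,
                     col.names = new, append = !new, qmethod = "double")
  invisible(path)
}

#' Reference-configuration CCA fit
#'
#' Fits the pipeline on the full available sample at the reference SVR
#' (imaging dimensionality `round(n / svr_reference)`, subject-measure
#' dimensionality `min(50, p_y)` by default); its Y-loadings are the
#' reference loadings that scenario construction
#' ([make_moderate_scenario()]) works from, and its CCC is the input to
#' [advise_stability()].
#'
#' @param X,Y QC-clean [subject_table]s.
#' @param svr_reference Reference subject-to-variable ratio (default 9).
#' @param dim_y Subject-measure dimensionality.
#' @return A `cca_pipeline` (see [fit_cca_pipeline()]).
#' @export
reference_fit <- function(X, Y, svr_reference = 9,
                          dim_y = min(50, ncol(Y$values))) {
  n <- nrow(X$values)
  kx <- max(1L, min(round(n / svr_reference),
                    ncol(X$values), n - 1L))
  fit_cca_pipeline(X, Y, kx, dim_y)
}

#' Construct a moderate-correlation scenario
#'
#' Weakens the first-mode correlation by removing the subject-measure
#' variables that dominate it: either the `k` largest-|loading| variables
#' (`"drop_top_k"`), or everything except the variables with |loading|
#' below a threshold (`"retain_below_threshold"`).
#'
#' @param Y [subject_table] of subject measures.
#' @param reference_loadings Named loading vector from a reference
#'   configuration fit (see [reference_fit()]), one entry per Y variable.
#' @param mode `"drop_top_k"` or `"retain_below_threshold"`.
#' @param k Number of variables to drop (`drop_top_k`).
#' @param threshold Absolute-loading cutoff (`retain_below_threshold`).
#' @return List with the reduced `table` and the `removed` variable names.
#' @export
make_moderate_scenario <- function(Y, reference_loadings,
                                   mode = c("drop_top_k",
                                            "retain_below_threshold"),
                                   k = 3, threshold = 0.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(Y, "subject_table"))
  if (length(reference_loadings) != ncol(Y$values))
    stop("reference_loadings must have one entry per Y variable")
  al <- abs(reference_loadings)
  removed <- if (mode == "drop_top_k") {
    if (k >= ncol(Y$values))
      stop("k must leave at least one variable")
    Y$var_names[order(al, decreasing = TRUE)[seq_len(k)]]
  } else {
    out <- Y$var_names[al >= threshold]
    if (length(out) == ncol(Y$values))
      stop("threshold ", threshold, " would remove every variable")
    out
  }
  keep <- setdiff(Y$var_names, removed)
  list(table = subject_table(Y$values[, keep, drop = FALSE]),
       removed = removed)
}

#' Stability guideline verdict
#'
#' Encodes the practical guidelines distilled from the stability sweeps:
#' at a reference SVR of about 9, a first-mode CCC below 0.65 means the
#' stability of the CCA results cannot be guaranteed (CCC > 0.8 marks the
#' strong regime); and the dimensionality of each variable set should not
#' exceed two thirds (half, to be safer) of the sample size.  The CCC
#' should always be reported together with the SVR, and never interpreted
#' as an absolute correlation-strength measure, because overfitting
#' inflates it as the SVR drops.
#'
#' @param ccc_at_reference First-mode CCC observed at the reference SVR.
#' @param svr_reference The reference SVR (about 9).
#' @param dim_x,dim_y Dimensionality of each variable set as analyzed.
#' @param sample_size Number of subjects.
#' @return An object of class `guideline_verdict`: `svr`, `reference_ccc`,
#'   logical `flags` (`weak_correlation`, `dimensionality_too_high`) and a
#'   `recommendation` string.
#' @export
advise_stability <- function(ccc_at_reference, svr_reference = 9,
                             dim_x, dim_y, sample_size) {
  if (sample_size <= 0 || dim_x <= 0 || dim_y <= 0)
    stop("inputs must be positive")
  weak <- ccc_at_reference < 0.65
  too_high <- max(dim_x, dim_y) > (2 / 3) * sample_size
  rec <- c(
    if (weak)
      sprintf(paste0("First-mode CCC %.2f at SVR ~%.3g is below 0.65: the ",
                     "correlation is not strong enough for the CCA results ",
                     "to be stable; CCA is not recommended here."),
              ccc_at_reference, svr_reference)
    else
      sprintf(paste0("First-mode CCC %.2f at SVR ~%.3g clears the 0.65 ",
                     "floor%s."), ccc_at_reference, svr_reference,
              if (ccc_at_reference > 0.8)
                " and marks a strong-correlation regime" else ""),
    if (too_high)
      sprintf(paste0("Dimensionality max(%d, %d) exceeds 2/3 of the sample ",
                     "size %d: reduce each set (e.g. by PCA) to at most two ",
                     "thirds, or half to be safer, of the sample size."),
              dim_x, dim_y, sample_size)
    else
      sprintf("Dimensionality (%d, %d) is within 2/3 of the sample size %d.",
              dim_x, dim_y, sample_size),
    paste0("Always report the SVR (or the dimensionalities and sample ",
           "size) alongside the CCC; the CCC magnitude alone is inflated ",
           "by overfitting at low SVR and must not be read as an absolute ",
           "measure of correlation strength."))
  structure(list(svr = sample_size / dim_x,
                 reference_ccc = ccc_at_reference,
                 flags = c(weak_correlation = weak,
                           dimensionality_too_high = too_high),
                 recommendation = paste(rec, collapse = " ")),
            class = "guideline_verdict")
}

#' @export
print.guideline_verdict <- function(x, ...) {
  cat("Guideline verdict (SVR = ", format(x$svr, digits = 4), "):\n",
      sep = "")
  cat("  weak_correlation:        ", x$flags[["weak_correlation"]], "\n")
  cat("  dimensionality_too_high: ",
      x$flags[["dimensionality_too_high"]], "\n")
  cat(strwrap(x$recommendation, width = 76, prefix = "  "), sep = "\n")
  invisible(x)
}
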