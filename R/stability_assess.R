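#' Per-pair CCA outcome
#'
#' Bundles the quantities the three stability assessments need for one pair
#' of subgroups.
#'
#' @param ccc_a,ccc_b First-mode canonical correlations of the two
#'   subgroups.
#' @param p_a,p_b Permutation p-values.
#' @param loadings_x_a,loadings_x_b,loadings_y_a,loadings_y_b Loading
#'   vectors of the two subgroups, per set.
#' @return An object of class `pair_outcome`.
#' @export
pair_outcome <- function(ccc_a, ccc_b, p_a, p_b,
                         loadings_x_a, loadings_x_b,
                         loadings_y_a, loadings_y_b) {
  if (length(loadings_x_a) != length(loadings_x_b) ||
      length(loadings_y_a) != length(loadings_y_b))
    stop("loading vectors within a pair must have equal length per set")
  structure(list(ccc_a = ccc_a, ccc_b = ccc_b, p_a = p_a, p_b = p_b,
                 loadings_x_a = loadings_x_a, loadings_x_b = loadings_x_b,
                 loadings_y_a = loadings_y_a, loadings_y_b = loadings_y_b),
            class = "pair_outcome")
}

pick_loadings <- function(o, which) {
  if (which == "x") list(a = o$loadings_x_a, b = o$loadings_x_b)
  else list(a = o$loadings_y_a, b = o$loadings_y_b)
}

#' Assessment 1: similarity of canonical correlations
#'
#' The absolute difference of the two subgroups' first-mode canonical
#' correlations, summarized by its mean and sample SD across pairs.
#'
#' @param outcomes List of [pair_outcome]s (at least 2).
#' @return List with `mean` and `sd` of `|ccc_a - ccc_b|`.
#' @export
assess_ccc_similarity <- function(outcomes) {
  if (length(outcomes) < 2)
    stop("need at least 2 pair outcomes")
  d <- vapply(outcomes, function(o) abs(o$ccc_a - o$ccc_b), 0)
  list(mean = mean(d), sd = stats::sd(d))
}

#' Assessment 2: consistency of statistical significance
#'
#' Classifies each pair by whether both subgroups' canonical correlations
#' are significant (strict `p < alpha`), both insignificant, or mixed, and
#' reports the three percentages (they sum to 100).
#'
#' @param outcomes List of [pair_outcome]s.
#' @param alpha Significance threshold (strict inequality).
#' @return Named numeric vector `pct_both_sig`, `pct_both_insig`,
#'   `pct_mixed`.
#' @export
assess_significance_consistency <- function(outcomes, alpha = 0.05) {
  p <- vapply(outcomes, function(o) c(o$p_a, o$p_b), c(0, 0))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  sig <- p < alpha
  both_sig <- colSums(sig) == 2
  both_insig <- colSums(sig) == 0
  n <- length(outcomes)
  c(pct_both_sig = 100 * sum(both_sig) / n,
    pct_both_insig = 100 * sum(both_insig) / n,
    pct_mixed = 100 * sum(!both_sig & !both_insig) / n)
}

#' Assessment 3: similarity of loading vectors
#'
#' The canonical variables of two subgroups cannot be correlated directly
#' (the subjects differ), so mode similarity is measured on the loading
#' vectors, which live on the shared variable space: the absolute Pearson
#' correlation between the two subgroups' loading vectors, per pair,
#' summarized by mean and SD.  The absolute value removes the inherent
#' sign ambiguity of canonical directions.  Pairs in which either loading
#' vector is constant are skipped with a warning and counted.
#'
#' @param outcomes List of [pair_outcome]s; loading vectors of length >= 3.
#' @param which `"x"` or `"y"`: which set's loadings to compare.
#' @return List with `mean`, `sd` and `n_skipped`.
#' @export
assess_loading_similarity <- function(outcomes, which = c("x", "y")) {
  which <- match.arg(which)
  vals <- vapply(outcomes, function(o) {
    l <- pick_loadings(o, which)
    if (length(l$a) < 3)
      stop("loading vectors must have length >= 3")
    if (stats::sd(l$a) < .Machine$double.eps ||
        stats::sd(l$b) < .Machine$double.eps)
      return(NA_real_)
    abs(stats::cor(l$a, l$b))
  }, 0)
  n_skipped <- sum(is.na(vals))
  if (n_skipped > 0)
    warning(n_skipped, " pair(s) with constant loading vector skipped")
  vals <- vals[!is.na(vals)]
  list(mean = mean(vals), sd = stats::sd(vals), n_skipped = n_skipped)
}

#' Per-variable loading-difference profile
#'
#' For each variable, the mean and SD over pairs of the absolute loading
#' difference between the two subgroups, after sign alignment: a subgroup-B
#' loading vector is negated when its correlation with the subgroup-A
#' vector is negative (alignment is idempotent).
#'
#' @inheritParams assess_loading_similarity
#' @return data.frame with columns `variable`, `mean_absdiff`,
#'   `sd_absdiff`; attribute `n_skipped` counts degenerate pairs.
#' @export
loading_difference_profile <- function(outcomes, which = c("x", "y")) {
  which <- match.arg(which)
  diffs <- lapply(outcomes, function(o) {
    l <- pick_loadings(o, which)
    if (stats::sd(l$a) < .Machine$double.eps ||
        stats::sd(l$b) < .Machine$double.eps)
      return(NULL)
    b <- if (stats::cor(l$a, l$b) < 0) -l$b else l$b
    abs(l$a - b)
  })
  keep <- !vapply(diffs, is.null, TRUE)
  if (sum(keep) == 0) stop("no non-degenerate pairs")
  if (any(!keep))
    warning(sum(!keep), " pair(s) with constant loading vector skipped")
  m <- do.call(rbind, diffs[keep])
  vars <- names(pick_loadings(outcomes[[1]], which)$a)
  if (is.null(vars)) vars <- sprintf("v%03d", seq_len(ncol(m)))
  structure(data.frame(variable = vars,
                       mean_absdiff = colMeans(m),
                       sd_absdiff = apply(m, 2, stats::sd),
                       row.names = NULL, stringsAsFactors = FALSE),
            n_skipped = sum(!keep))
}

#' Consistency of bootstrap loading significance across paired subgroups
#'
#' Classifies each variable as consistently significant (significant in
#' both subgroups), consistently non-significant, or mixed.
#'
#' @param sig_a,sig_b `loading_significance` objects
#'   ([bootstrap_loading_significance()]) over the same variables.
#' @return A list with the per-variable data.frame `by_variable`
#'   (columns `variable`, `status`) and the aggregate `counts`.
#' @export
loading_significance_consistency <- function(sig_a, sig_b) {
  if (!identical(sig_a$variable, sig_b$variable))
    stop("the two significance tables cover different variables")
  status <- ifelse(sig_a$significant & sig_b$significant,
                   "consistently_significant",
                   ifelse(!sig_a$significant & !sig_b$significant,
                          "consistently_nonsignificant", "mixed"))
  counts <- c(consistently_significant =
                sum(status == "consistently_significant"),
              consistently_nonsignificant =
                sum(status == "consistently_nonsignificant"),
              mixed = sum(status == "mixed"))
  list(by_variable = data.frame(variable = sig_a$variable, status = status,
                                stringsAsFactors = FALSE),
       counts = counts)
}

#' Summarize all three stability assessments over one batch of pairs
#'
#' @param outcomes List of [pair_outcome]s.
#' @param alpha Significance threshold for Assessment 2.
#' @return One-row data.frame (class `stability_summary`) with the
#'   Assessment 1 mean/SD, the Assessment 2 percentages, the Assessment 3
#'   mean/SD per set, skip counts, and `n_pairs`.
#' @export
summarize_stability <- function(outcomes, alpha = 0.05) {
  a1 <- assess_ccc_similarity(outcomes)
  a2 <- assess_significance_consistency(outcomes, alpha)
  a3x <- suppressWarnings(assess_loading_similarity(outcomes, "x"))
  a3y <- suppressWarnings(assess_loading_similarity(outcomes, "y"))
  out <- data.frame(ccc_absdiff_mean = a1$mean, ccc_absdiff_sd = a1$sd,
                    pct_both_sig = a2[["pct_both_sig"]],
                    pct_both_insig = a2[["pct_both_insig"]],
                    pct_mixed = a2[["pct_mixed"]],
                    loadcorr_x_mean = a3x$mean, loadcorr_x_sd = a3x$sd,
                    loadcorr_y_mean = a3y$mean, loadcorr_y_sd = a3y$sd,
                    n_skipped_x = a3x$n_skipped, n_skipped_y = a3y$n_skipped,
                    n_pairs = length(outcomes))
  class(out) <- c("stability_summary", "data.frame")
  out
}
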