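#' Split subjects into two subgroups with an exact overlap
#'
#' Draws `overlap` shared subjects uniformly without replacement, then
#' `subgroup_size - overlap` further unique subjects for subgroup A from
#' the remainder, then the same number for subgroup B from what is left.
#' The overlap between the two index sets is therefore exact, not merely
#' expected.  With `overlap = 0` and `2 * subgroup_size = n_total` this is
#' a disjoint half split; with `overlap = subgroup_size` the two subgroups
#' are identical.
#'
#' @param n_total Total number of subjects (indices are `1..n_total`).
#' @param subgroup_size Size of each subgroup.
#' @param overlap Exact number of shared subjects,
#'   `0 <= overlap <= subgroup_size`.
#' @param seed Integer seed; the draw is deterministic under it.
#' @return An object of class `split_pair` with integer index vectors
#'   `idx_a`, `idx_b`, plus `overlap` and `seed`.
#' @export
split_with_overlap <- function(n_total, subgroup_size, overlap, seed = 1) {
  if (overlap < 0 || overlap > subgroup_size)
    stop("overlap must be in [0, subgroup_size]")
  if (2 * subgroup_size - overlap > n_total)
    stop("infeasible split: 2*", subgroup_size, " - ", overlap, " > ",
         n_total)
  with_seed(seed, {
    shared <- sample.int(n_total, overlap)
    rest <- setdiff(seq_len(n_total), shared)
    a_only <- rest[sample.int(length(rest), subgroup_size - overlap)]
    rest <- setdiff(rest, a_only)
    b_only <- rest[sample.int(length(rest), subgroup_size - overlap)]
    structure(list(idx_a = sort(c(shared, a_only)),
                   idx_b = sort(c(shared, b_only)),
                   overlap = as.integer(overlap),
                   seed = as.integer(seed)),
              class = "split_pair")
  })
}

#' @export
print.split_pair <- function(x, ...) {
  cat("split_pair: |A| =", length(x$idx_a), " |B| =", length(x$idx_b),
      " overlap =", x$overlap, "\n")
  invisible(x)
}

#' Generate many subgroup pairs at one overlap setting
#'
#' Per-pair seeds are derived from `master_seed` and the pair index via a
#' stable integer hash, so each pair is reproducible individually and the
#' list is independent of execution order.
#'
#' @inheritParams split_with_overlap
#' @param n_pairs Number of pairs.
#' @param master_seed Integer master seed.
#' @return A list of `split_pair` objects of length `n_pairs`.
#' @export
generate_pairs <- function(n_total, subgroup_size, overlap, n_pairs = 1000,
                           master_seed = 1) {
  lapply(seq_len(n_pairs), function(i)
    split_with_overlap(n_total, subgroup_size, overlap,
                       seed = mix_seed(master_seed, i)))
}

#' Serialize split pairs to JSON
#'
#' Subject indices are written 0-based for interoperability.
#'
#' @param pairs A list of `split_pair` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  payload <- lapply(pairs, function(p)
    list(idx_a = p$idx_a - 1L, idx_b = p$idx_b - 1L,
         overlap = p$overlap, seed = p$seed))
  jsonlite::write_json(payload, path, auto_unbox = FALSE)
  invisible(path)
}
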