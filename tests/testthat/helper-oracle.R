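# Brute-force CCA oracle for p = 2 per set: exhaustive search over unit-norm
# weight directions on an angle grid, independent of the SVD solver path.
brute_force_ccc_2d <- function(X, Y, grid_points = 2000) {
  th <- seq(0, pi, length.out = grid_points + 1)[seq_len(grid_points)]
  A <- rbind(cos(th), sin(th))
  U <- scale(X %*% A)
  V <- scale(Y %*% A)
  max(abs(crossprod(U, V) / (nrow(X) - 1)))
}

# Small standardized Gaussian matrix with a fixed seed.
rand_mat <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# Quick z-score of a plain matrix (column mean 0, sd 1).
zs <- function(m) scale(m)[, , drop = FALSE]
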