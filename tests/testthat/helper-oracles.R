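# Brute-force oracles, deliberately independent of the package's C++ paths.

# all-pairs minimum distance from each inside cell to the nearest outside
# cell centre, including the one-cell virtual ring beyond the grid edge
bf_dist_border <- function(mask_mat, cell_side) {
  nr <- nrow(mask_mat)
  nc <- ncol(mask_mat)
  cand <- NULL
  for (r in 0:(nr + 1)) {
    for (c in 0:(nc + 1)) {
      ingrid <- r >= 1 && r <= nr && c >= 1 && c <= nc
      if (!ingrid || !mask_mat[r, c]) cand <- rbind(cand, c(r, c))
    }
  }
  out <- matrix(0, nr, nc)
  for (r in 1:nr) {
    for (c in 1:nc) {
      if (!mask_mat[r, c]) next
      out[r, c] <- sqrt(min((cand[, 1] - r)^2 + (cand[, 2] - c)^2)) * cell_side
    }
  }
  out
}

# direct O(n^2) double-sum evaluation of global Moran's I, queen contiguity,
# row-standardised weights over inside cells
bf_morans_i <- function(vals_mat, mask_mat) {
  idx <- which(mask_mat, arr.ind = TRUE)
  x <- vals_mat[mask_mat]
  n <- length(x)
  mu <- mean(x)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (max(abs(idx[i, ] - idx[j, ])) == 1) W[i, j] <- 1
    }
  }
  rs <- rowSums(W)
  W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  z <- x - mu
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

# small all-inside square landscape with given prey matrix
square_landscape <- function(prey_mat, cell_side = 250) {
  landscape_grid(prey = prey_mat,
                 mask = matrix(TRUE, nrow(prey_mat), ncol(prey_mat)),
                 cell_side = cell_side)
}
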