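# Independent oracles used to cross-check the package implementation.
# These deliberately share no code with the package internals.

# Connected components of a 2D binary matrix by queue flood fill.
flood_count_2d <- function(m, connectivity = 8) {
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W)
  if (connectivity == 8) {
    nb <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (m[i, j] == 0 || seen[i, j]) next
    count <- count + 1
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nb))) {
        y <- p[1] + nb[q, 1]; x <- p[2] + nb[q, 2]
        if (y >= 1 && y <= H && x >= 1 && x <= W &&
            m[y, x] != 0 && !seen[y, x]) {
          seen[y, x] <- TRUE
          queue[[length(queue) + 1]] <- c(y, x)
        }
      }
    }
  }
  count
}

# Connected components of a 3D binary array, 26-connectivity.
flood_count_3d <- function(a) {
  d <- dim(a)
  seen <- array(FALSE, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  count <- 0
  idx <- which(a != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    count <- count + 1
    queue <- list(p0); seen[p0[1], p0[2], p0[3]] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nb))) {
        v <- p + nb[q, ]
        if (all(v >= 1) && all(v <= d) && a[v[1], v[2], v[3]] != 0 &&
            !seen[v[1], v[2], v[3]]) {
          seen[v[1], v[2], v[3]] <- TRUE
          queue[[length(queue) + 1]] <- v
        }
      }
    }
  }
  count
}

# Brute-force foreground-preserving pyramid: coarse pixel (i, j) at scale s
# is foreground iff any pixel of its 2^(s-1) block is foreground.
block_any_pyramid <- function(label, levels) {
  lapply(seq_len(levels), function(s) {
    f <- 2^(s - 1)
    H <- nrow(label) / f; W <- ncol(label) / f
    out <- matrix(0, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      block <- label[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)]
      out[i, j] <- as.numeric(any(block > 0))
    }
    out
  })
}

# Exhaustive voxel-loop confusion counts.
confusion_loop <- function(pred, truth) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  list(TP = tp, FP = fp, FN = fn)
}

# Rank-then-Pearson Spearman (average ranks for ties), written out longhand.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Small phantom spec used across tests (fast to generate).
tiny_phantom_spec <- function(seed = 5, ...) {
  phantom_spec(grid_shape = c(48, 48, 12), n_tubes = 3, n_dots = 5,
               tube_length_mm = c(4, 9), pvs_radius_mm = c(0.5, 1),
               n_sulci = 0, n_lacunes = 0, low_signal_fraction = 0,
               noise_sigma = 2, seed = seed, ...)
}
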