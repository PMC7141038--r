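# Independent connectivity oracles, written against the array API only:
# breadth-first flood fill implemented as vectorised wavefront dilation with
# coordinate arithmetic. Deliberately shares no code with the package's
# component labeling.

oracle_offsets <- function(connectivity, is3d) {
  zr <- if (is3d) -1:1 else 0
  g <- expand.grid(dy = -1:1, dx = -1:1, dz = zr)
  g <- g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ]
  manh <- abs(g$dy) + abs(g$dx) + abs(g$dz)
  keep <- switch(as.character(connectivity),
    "4" = manh == 1,
    "8" = rep(TRUE, nrow(g)),
    "6" = manh == 1,
    "18" = manh <= 2,
    "26" = rep(TRUE, nrow(g))
  )
  as.matrix(g[keep, , drop = FALSE])
}

# logical array marking the connected component of `mask` containing `seed`
# (a length-3 1-based coordinate)
oracle_flood <- function(mask, seed, connectivity) {
  d <- dim(mask)
  off <- oracle_offsets(connectivity, d[3] > 1)
  visited <- array(FALSE, dim = d)
  stopifnot(mask[seed[1], seed[2], seed[3]])
  frontier <- matrix(seed, ncol = 3)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  while (nrow(frontier) > 0) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = nrow(frontier)), , drop = FALSE]
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    lin <- (cand[, 3] - 1) * d[1] * d[2] + (cand[, 2] - 1) * d[1] + cand[, 1]
    new <- mask[lin] & !visited[lin]
    lin <- unique(lin[new])
    if (!length(lin)) break
    visited[lin] <- TRUE
    frontier <- cbind(
      (lin - 1) %% d[1] + 1,
      ((lin - 1) %/% d[1]) %% d[2] + 1,
      (lin - 1) %/% (d[1] * d[2]) + 1
    )
  }
  visited
}

# number of connected components of a logical array
oracle_n_components <- function(mask, connectivity) {
  left <- mask
  n <- 0L
  while (any(left)) {
    i <- which(left)[1]
    d <- dim(mask)
    seed <- c(
      (i - 1) %% d[1] + 1,
      ((i - 1) %/% d[1]) %% d[2] + 1,
      (i - 1) %/% (d[1] * d[2]) + 1
    )
    comp <- oracle_flood(left, seed, connectivity)
    left <- left & !comp
    n <- n + 1L
  }
  n
}

# random test masks: a few solid blobs plus scattered speckle, guaranteed
# non-empty and with a deterministic "largest blob" to act as the spheroid
random_blob_mask <- function(d, n_blobs = 3, speckle = 0.02) {
  mask <- array(FALSE, dim = d)
  # one dominant blob near the middle
  ctr <- pmax(2, round(d / 2 + runif(3, -2, 2)))
  ctr[d == 1] <- 1
  r0 <- max(2, round(min(d[d > 1]) / 4))
  mask <- mask | (spheromigrate:::dist2_from(d, ctr) <= r0^2)
  for (b in seq_len(n_blobs)) {
    c2 <- round(runif(3, 1, d))
    c2[d == 1] <- 1
    r2 <- runif(1, 1, max(2, min(d[d > 1]) / 6))
    mask <- mask | (spheromigrate:::dist2_from(d, c2) <= r2^2)
  }
  mask | (array(runif(prod(d)), dim = d) < speckle)
}

# per-class voxel F1 between estimated and true label arrays (codes 1:3)
class_f1 <- function(est, tru) {
  vapply(1:3, function(k) {
    tp <- sum(est == k & tru == k)
    fp <- sum(est == k & tru != k)
    fn <- sum(est != k & tru == k)
    if (2 * tp + fp + fn == 0) {
      return(NA_real_)
    }
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

# 90-degree in-plane rotation of a (row, col, plane) array
rotate90 <- function(arr) {
  d <- dim(arr)
  out <- array(arr[0], dim = c(d[2], d[1], d[3]))
  for (z in seq_len(d[3])) {
    out[, , z] <- t(arr[d[1]:1, , z])
  }
  out
}

quantify_quiet <- function(...) suppressMessages(quantify_stack(...))

# reduce a classed array to its bare data + dim
strip_attrs <- function(x) array(as.vector(unclass(x)), dim(x))

# wrap a plain logical array as the package's mask type
as_mask_for_test <- function(mask, spacing = 1) {
  spheromigrate:::as_foreground_mask(mask, spacing = spacing, threshold = 0.5)
}
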