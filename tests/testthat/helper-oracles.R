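# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the superposition oracle uses Horn's quaternion
# method (not SVD), the rolling-ball oracle a direct double loop, and the
# Yen oracle a per-threshold evaluation of the criterion from its
# definition.

canonical_filament <- function(n = 37, twist = -167, rise = 27, ...) {
  build_filament(helical_symmetry(twist, rise), n, ...)
}

tiled_37mer <- function() {
  tile_filament(canonical_filament(15), 3, 4, "pointed")
}

# Horn (1987) closed-form absolute orientation via the quaternion
# eigenvector of the 4x4 cross-covariance matrix.
horn_superpose <- function(P, Q) {
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  S <- crossprod(Pc, Qc)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  list(rotation = R, translation = as.vector(qbar - R %*% pbar),
       rmsd = rmsd)
}

# Direct (quadratic-time) grayscale opening with a ball structuring
# element: background under each pixel, then subtraction.
naive_rolling_ball <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  h <- sqrt(radius^2 - offs$dy^2 - offs$dx^2) - radius
  erode <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (k in seq_len(nrow(offs))) {
      y <- i + offs$dy[k]; x <- j + offs$dx[k]
      if (y >= 1 && y <= nr && x >= 1 && x <= nc) {
        v <- img[y, x] - h[k]
        if (v < erode[i, j]) erode[i, j] <- v
      }
    }
  }
  dil <- matrix(-Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (k in seq_len(nrow(offs))) {
      y <- i + offs$dy[k]; x <- j + offs$dx[k]
      if (y >= 1 && y <= nr && x >= 1 && x <= nc) {
        v <- erode[y, x] + h[k]
        if (v > dil[i, j]) dil[i, j] <- v
      }
    }
  }
  pmax(img - pmin(dil, img), 0)
}

# Yen threshold by exhaustive evaluation of the criterion at every
# candidate split of the histogram, straight from its definition:
# TC(t) = -log(S1 * S2) + 2 log(P1 * (1 - P1)).
yen_bruteforce <- function(image, nbins = 256) {
  rng <- range(image)
  brk <- seq(rng[1], rng[2], length.out = nbins + 1)
  cnt <- tabulate(findInterval(image, brk, rightmost.closed = TRUE),
                  nbins = nbins)
  p <- cnt / sum(cnt)
  centers <- (brk[-1] + brk[-(nbins + 1)]) / 2
  best <- -Inf; best_t <- centers[1]
  for (t in seq_len(nbins - 1)) {
    P1 <- sum(p[1:t])
    S1 <- sum(p[1:t]^2)
    S2 <- sum(p[(t + 1):nbins]^2)
    if (S1 <= 0 || S2 <= 0 || P1 <= 0 || P1 >= 1) next
    crit <- -log(S1 * S2) + 2 * log(P1 * (1 - P1))
    if (crit > best) { best <- crit; best_t <- centers[t] }
  }
  best_t
}

strand_means <- function(profile) {
  e <- profile$entries
  c(mean(e$twist_deg[e$strand == 0]), mean(e$twist_deg[e$strand == 1]))
}
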