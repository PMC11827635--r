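# Internal quaternion / rotation helpers. Quaternions are length-4 numeric
# vectors c(w, x, y, z), kept unit-norm; all angles in these helpers are
# radians unless the name says _deg.

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

matrix_to_quat <- function(m) {
  tr <- m[1, 1] + m[2, 2] + m[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (m[3, 2] - m[2, 3]) / s, (m[1, 3] - m[3, 1]) / s,
           (m[2, 1] - m[1, 2]) / s)
  } else if (m[1, 1] > m[2, 2] && m[1, 1] > m[3, 3]) {
    s <- sqrt(1 + m[1, 1] - m[2, 2] - m[3, 3]) * 2
    q <- c((m[3, 2] - m[2, 3]) / s, 0.25 * s, (m[1, 2] + m[2, 1]) / s,
           (m[1, 3] + m[3, 1]) / s)
  } else if (m[2, 2] > m[3, 3]) {
    s <- sqrt(1 + m[2, 2] - m[1, 1] - m[3, 3]) * 2
    q <- c((m[1, 3] - m[3, 1]) / s, (m[1, 2] + m[2, 1]) / s, 0.25 * s,
           (m[2, 3] + m[3, 2]) / s)
  } else {
    s <- sqrt(1 + m[3, 3] - m[1, 1] - m[2, 2]) * 2
    q <- c((m[2, 1] - m[1, 2]) / s, (m[1, 3] + m[3, 1]) / s,
           (m[2, 3] + m[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

quat_rotate_vec <- function(q, v) {
  qv <- quat_multiply(quat_multiply(q, c(0, v)), quat_conjugate(q))
  qv[2:4]
}

# Signed angle (degrees) wrapped into (-180, 180].
wrap_angle_deg <- function(deg) {
  w <- deg %% 360
  ifelse(w > 180, w - 360, w)
}

normalize_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Any unit vector perpendicular to u.
perpendicular_vec <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  normalize_vec(ref - sum(ref * u) * u)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Principal direction of an n x 3 point cloud, oriented along `orient`.
principal_axis <- function(pts, orient = NULL) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  u <- sv$v[, 1]
  if (!is.null(orient) && sum(u * orient) < 0) u <- -u
  list(axis = u, center = ctr)
}

# Local helix axis from a window of centroids. For points on a helix with
# constant rise the second differences c[i+1] - 2 c[i] + c[i-1] are purely
# transverse, so cross products of consecutive second differences recover
# the axis direction exactly (any per-step twist). Falls back to the
# principal direction for degenerate (straight / untwisted) windows, where
# that fallback is itself exact.
helix_axis <- function(pts, orient) {
  n <- nrow(pts)
  if (n >= 4) {
    s <- pts[3:n, , drop = FALSE] - 2 * pts[2:(n - 1), , drop = FALSE] +
      pts[1:(n - 2), , drop = FALSE]
    # remove the slowly varying backbone-curvature component; for straight
    # helices the subtracted mean is itself transverse, so exactness holds
    if (nrow(s) >= 3) s <- sweep(s, 2, colMeans(s))
    smag <- sqrt(rowSums(s^2))
    if (nrow(s) >= 2 && max(smag) > 1e-9) {
      acc <- c(0, 0, 0)
      for (i in seq_len(nrow(s) - 1)) {
        cr <- cross3(s[i, ], s[i + 1, ])
        if (sum(cr * orient) < 0) cr <- -cr
        acc <- acc + cr
      }
      if (sqrt(sum(acc^2)) > 1e-9 * max(smag)^2)
        return(normalize_vec(acc))
    }
  }
  principal_axis(pts, orient = orient)$axis
}

# Kasa algebraic circle fit on 2D points; exact for exact circle data.
# Falls back to the centroid when the design matrix is rank-deficient
# (collinear or coincident points, e.g. an untwisted lattice).
fit_circle_2d <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3) return(colMeans(xy))
  sol <- qr.coef(qrA, b)
  c(sol[1], sol[2])
}
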