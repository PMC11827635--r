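#' Helical symmetry parameters
#'
#' One-start helical symmetry of a two-strand actin-like filament: the signed
#' rotation and axial translation relating consecutive subunits along the
#' one-start (genetic) helix. The canonical F-actin lattice has a left-handed
#' one-start helix with twist close to -167 degrees and rise close to 27
#' Angstrom; the equivalent strand-level step (every second subunit) is
#' 26 degrees / 55 Angstrom.
#'
#' @param twist_deg Signed rotation per one-start step, degrees, in
#'   (-180, 180]. Negative for a left-handed one-start helix.
#' @param rise_ang Axial translation per one-start step, Angstrom; must be
#'   positive.
#' @return An object of class `helical_symmetry`.
#' @examples
#' helical_symmetry(-167, 27)
#' @export
helical_symmetry <- function(twist_deg, rise_ang) {
  stopifnot(is.numeric(twist_deg), length(twist_deg) == 1,
            is.numeric(rise_ang), length(rise_ang) == 1)
  if (!(twist_deg > -180 && twist_deg <= 180))
    stop("twist_deg must lie in (-180, 180]")
  if (rise_ang <= 0) stop("rise_ang must be positive")
  structure(list(twist_deg = twist_deg, rise_ang = rise_ang),
            class = "helical_symmetry")
}

#' Filament lattice model
#'
#' An ordered set of per-subunit rigid poses (centroid + orientation) of a
#' two-strand helical filament. Subunit 0 is the pointed end, the maximal
#' index the barbed end; strand membership is the parity of the protomer
#' index along the one-start helix.
#'
#' @param subunits Data frame with columns `index` (0-based consecutive
#'   integers), `strand` (`index %% 2`), centroid coordinates `x`, `y`, `z`
#'   (Angstrom) and unit-quaternion orientation `qw`, `qx`, `qy`, `qz`.
#' @return An object of class `filament_model`.
#' @export
filament_model <- function(subunits) {
  req <- c("index", "strand", "x", "y", "z", "qw", "qx", "qy", "qz")
  if (!all(req %in% names(subunits)))
    stop("subunits must have columns: ", paste(req, collapse = ", "))
  subunits <- subunits[order(subunits$index), req, drop = FALSE]
  rownames(subunits) <- NULL
  n <- nrow(subunits)
  if (n < 3) stop("a filament model needs at least 3 subunits")
  if (!identical(as.integer(subunits$index), seq_len(n) - 1L))
    stop("subunit indices must be consecutive integers starting at 0")
  if (!all(subunits$strand == subunits$index %% 2))
    stop("strand must equal index parity")
  qn <- sqrt(subunits$qw^2 + subunits$qx^2 + subunits$qy^2 + subunits$qz^2)
  if (any(abs(qn - 1) > 1e-6))
    stop("orientations must be unit quaternions")
  structure(list(subunits = subunits,
                 polarity = "index 0 = pointed end, max index = barbed end"),
            class = "filament_model")
}

#' @export
print.filament_model <- function(x, ...) {
  n <- nrow(x$subunits)
  cat(sprintf("<filament_model> %d subunits (%s)\n", n, x$polarity))
  invisible(x)
}

n_subunits <- function(model) nrow(model$subunits)

centroids <- function(model) {
  as.matrix(model$subunits[, c("x", "y", "z")])
}

subunit_quats <- function(model) {
  as.matrix(model$subunits[, c("qw", "qx", "qy", "qz")])
}

make_subunit_df <- function(cents, quats) {
  n <- nrow(cents)
  data.frame(index = seq_len(n) - 1L, strand = (seq_len(n) - 1L) %% 2L,
             x = cents[, 1], y = cents[, 2], z = cents[, 3],
             qw = quats[, 1], qx = quats[, 2], qy = quats[, 3],
             qz = quats[, 4])
}

#' Build a straight helical filament model
#'
#' Places `n_subunits` subunits on a straight one-start helix about the +z
#' axis (pointed end at the origin, barbed end toward +z): subunit i sits at
#' radius `radius` from the axis, rotated `i * twist_deg` and translated
#' `i * rise_ang` along it; orientations follow the same screw operation
#' applied to the seed orientation.
#'
#' @param symmetry A [helical_symmetry()].
#' @param n_subunits Number of subunits (>= 3).
#' @param radius Centroid distance from the filament axis, Angstrom.
#'   Twist measurements are invariant to it; rise exactly so.
#' @param seed_pose Optional list with elements `phase_deg` (azimuth of
#'   subunit 0) and/or `quat` (orientation of subunit 0, unit quaternion).
#' @return A [filament_model()].
#' @examples
#' fil <- build_filament(helical_symmetry(-167, 27), 37)
#' @export
build_filament <- function(symmetry, n_subunits, radius = 25,
                           seed_pose = NULL) {
  stopifnot(inherits(symmetry, "helical_symmetry"))
  if (n_subunits < 3) stop("n_subunits must be >= 3")
  twists <- rep(symmetry$twist_deg, n_subunits - 1)
  rises <- rep(symmetry$rise_ang, n_subunits - 1)
  build_filament_steps(twists, rises, radius = radius, seed_pose = seed_pose)
}

#' Build a filament from explicit per-step twist and rise values
#'
#' Generalisation of [build_filament()] used by the synthetic-data
#' generators: each one-start step i -> i+1 gets its own twist and rise, so
#' lattice-measurement round trips can be checked against stored per-step
#' ground truth.
#'
#' @param twist_deg_steps,rise_ang_steps Numeric vectors of equal length
#'   (n_subunits - 1): twist (degrees) and rise (Angstrom) of each step.
#' @inheritParams build_filament
#' @return A [filament_model()].
#' @export
build_filament_steps <- function(twist_deg_steps, rise_ang_steps,
                                 radius = 25, seed_pose = NULL) {
  stopifnot(length(twist_deg_steps) == length(rise_ang_steps))
  if (length(twist_deg_steps) < 2) stop("need at least 3 subunits (2 steps)")
  if (any(rise_ang_steps <= 0)) stop("all rise steps must be positive")
  phase0 <- 0
  q0 <- c(1, 0, 0, 0)
  if (!is.null(seed_pose)) {
    if (!is.null(seed_pose$phase_deg)) phase0 <- seed_pose$phase_deg
    if (!is.null(seed_pose$quat)) q0 <- quat_normalize(seed_pose$quat)
  }
  n <- length(twist_deg_steps) + 1
  phi <- (phase0 + c(0, cumsum(twist_deg_steps))) * pi / 180
  z <- c(0, cumsum(rise_ang_steps))
  cents <- cbind(radius * cos(phi), radius * sin(phi), z)
  quats <- t(vapply(phi - phase0 * pi / 180, function(a) {
    quat_multiply(quat_from_axis_angle(c(0, 0, 1), a), q0)
  }, numeric(4)))
  filament_model(make_subunit_df(cents, quats))
}

#' Bend a filament with twist-bend coupling
#'
#' Maps a (straight) filament model onto a circular arc of radius
#' 1/|curvature| in the plane perpendicular to `bend_plane_normal`,
#' preserving arc length along the axis, and optionally imposes a per-strand
#' twist asymmetry: strand 0's strand-level (i -> i+2) twist is shifted by
#' +asymmetry/2 per step and strand 1's by -asymmetry/2, so the measured
#' strand-mean twists differ by `strand_twist_asymmetry_deg`. For the
#' canonical left-handed lattice a negative asymmetry under-twists strand 0,
#' which the generators treat as the convex-side, decorated strand. With
#' zero curvature and zero asymmetry the model is returned unchanged.
#'
#' @param model A [filament_model()] (assumed straight; its global axis is
#'   taken as the bending backbone).
#' @param curvature Backbone curvature, 1/Angstrom. The total arc turn
#'   |curvature| * length must stay below pi.
#' @param bend_plane_normal Unit 3-vector normal to the bending plane; must
#'   not be parallel to the filament axis.
#' @param strand_twist_asymmetry_deg Difference (strand 0 minus strand 1)
#'   imposed on the strand-level twists, degrees.
#' @return A [filament_model()].
#' @export
bend_filament <- function(model, curvature, bend_plane_normal = c(1, 0, 0),
                          strand_twist_asymmetry_deg = 0) {
  stopifnot(inherits(model, "filament_model"))
  if (curvature == 0 && strand_twist_asymmetry_deg == 0) return(model)
  cents <- centroids(model)
  quats <- subunit_quats(model)
  n <- nrow(cents)
  u <- helix_axis(cents, orient = cents[n, ] - cents[1, ])
  # axis position: centre of the centroid circle in the transverse plane
  e1 <- perpendicular_vec(u)
  e2 <- cross3(u, e1)
  ctr2 <- fit_circle_2d(cbind(cents %*% e1, cents %*% e2))
  origin <- ctr2[1] * e1 + ctr2[2] * e2 + sum(cents[1, ] * u) * u
  s <- as.vector((cents %*% u) - sum(origin * u))
  total_len <- max(s) - min(s)
  if (abs(curvature) * total_len >= pi)
    stop("arc self-intersection: |curvature| * length must be < pi")
  m <- bend_plane_normal - sum(bend_plane_normal * u) * u
  if (sqrt(sum(m^2)) < 1e-9)
    stop("bend_plane_normal is parallel to the filament axis")
  m <- normalize_vec(m)
  e <- cross3(u, m)  # in-plane normal at s = 0; (u, e, m) right-handed

  # Per-subunit azimuthal adjustment realising the strand twist asymmetry:
  # subunit i (k-th on its strand) is rotated about the axis by +/- a/2 * k.
  a <- strand_twist_asymmetry_deg
  idx <- model$subunits$index
  k <- idx %/% 2
  dphi <- ifelse(idx %% 2 == 0, 1, -1) * (a / 2) * k * pi / 180

  radial <- sweep(cents, 2, origin) - outer(s, u)  # component perp. to axis
  # rotate radial offsets (and orientations) by dphi about u
  new_cents <- matrix(0, n, 3)
  new_quats <- matrix(0, n, 4)
  kappa <- curvature
  for (i in seq_len(n)) {
    qspin <- quat_from_axis_angle(u, dphi[i])
    r_i <- quat_rotate_vec(qspin, radial[i, ])
    alpha <- sum(r_i * e)
    beta <- sum(r_i * m)
    if (kappa == 0) {
      new_cents[i, ] <- origin + s[i] * u + alpha * e + beta * m
      q_tr <- c(1, 0, 0, 0)
    } else {
      theta <- s[i] * kappa
      arc <- origin + (sin(theta) / kappa) * u + ((1 - cos(theta)) / kappa) * e
      nu <- -sin(theta) * u + cos(theta) * e  # transported in-plane normal
      new_cents[i, ] <- arc + alpha * nu + beta * m
      # rotation mapping (u -> tangent, e -> nu): angle theta about -m,
      # since u x e = -m for the right-handed triple (u, e, m)... verified
      # numerically in tests via the orientation-method round trip.
      q_tr <- quat_from_axis_angle(m, -theta)
    }
    new_quats[i, ] <- quat_normalize(
      quat_multiply(q_tr, quat_multiply(qspin, quats[i, ])))
  }
  filament_model(make_subunit_df(new_cents, new_quats))
}

#' Least-squares rigid superposition of two filament models
#'
#' Kabsch-style singular-value-decomposition fit of the mobile model's
#' centroids onto the reference over a subset of protomer indices; rotation
#' is constrained to a proper rotation (no scaling or reflection).
#'
#' @param mobile,reference [filament_model()] objects sharing the subset
#'   indices.
#' @param subset Integer vector of protomer indices (0-based) used for the
#'   alignment; at least 3 non-collinear centroids.
#' @return An object of class `rigid_transform`: list with `rotation`
#'   (3 x 3 proper rotation), `translation` (3-vector, Angstrom) and `rmsd`
#'   (Angstrom over the subset).
#' @export
superpose <- function(mobile, reference, subset) {
  stopifnot(inherits(mobile, "filament_model"),
            inherits(reference, "filament_model"))
  subset <- as.integer(subset)
  if (length(subset) < 3) stop("subset must contain at least 3 indices")
  P <- centroids(mobile)[match(subset, mobile$subunits$index), , drop = FALSE]
  Q <- centroids(reference)[match(subset, reference$subunits$index), ,
                            drop = FALSE]
  if (anyNA(P) || anyNA(Q)) stop("subset indices missing from a model")
  kabsch(P, Q)
}

kabsch <- function(P, Q) {
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate geometry: alignment subset is collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  structure(list(rotation = R, translation = as.vector(qbar - R %*% pbar),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to a filament model
#'
#' @param model A [filament_model()].
#' @param transform A `rigid_transform` from [superpose()].
#' @return The transformed [filament_model()].
#' @export
apply_transform <- function(model, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  cents <- centroids(model) %*% t(transform$rotation)
  cents <- sweep(cents, 2, transform$translation, "+")
  qR <- matrix_to_quat(transform$rotation)
  quats <- t(apply(subunit_quats(model), 1, function(q) {
    quat_normalize(quat_multiply(qR, q))
  }))
  out <- model
  out$subunits[, c("x", "y", "z")] <- cents
  out$subunits[, c("qw", "qx", "qy", "qz")] <- quats
  out
}

#' Tile a filament model into an extended filament
#'
#' Superposes successive copies of a model end-over-end on a shared overlap
#' of terminal subunits, deletes the overlapping duplicates, and renumbers
#' from the pointed end. Three copies of a 15-subunit model with a
#' 4-subunit overlap yield the standard 37-subunit extended model used for
#' edge-free twist/rise measurement.
#'
#' @param model A [filament_model()] with n subunits.
#' @param n_copies Number of copies (>= 1).
#' @param overlap_subunits Number of shared terminal subunits used for the
#'   alignment, in `[3, n)`.
#' @param align_end `"pointed"` (each new copy's pointed-end subunits are
#'   aligned onto the growing barbed end) or `"barbed"` (the mirror image).
#' @return A [filament_model()] with `n + (n_copies - 1) * (n -
#'   overlap_subunits)` subunits.
#' @export
tile_filament <- function(model, n_copies, overlap_subunits,
                          align_end = c("pointed", "barbed")) {
  align_end <- match.arg(align_end)
  stopifnot(inherits(model, "filament_model"))
  n <- n_subunits(model)
  if (n_copies < 1) stop("n_copies must be >= 1")
  if (overlap_subunits < 3 || overlap_subunits >= n)
    stop("overlap_subunits must lie in [3, n)")
  if (n_copies == 1) return(model)
  k <- overlap_subunits
  cents <- centroids(model)
  quats <- subunit_quats(model)
  acc_c <- cents
  acc_q <- quats
  for (copy in seq_len(n_copies - 1)) {
    N <- nrow(acc_c)
    if (align_end == "pointed") {
      # align new copy's first k subunits onto the current last k
      tf <- kabsch(cents[seq_len(k), , drop = FALSE],
                   acc_c[(N - k + 1):N, , drop = FALSE])
      keep <- (k + 1):n
    } else {
      tf <- kabsch(cents[(n - k + 1):n, , drop = FALSE],
                   acc_c[seq_len(k), , drop = FALSE])
      keep <- seq_len(n - k)
    }
    moved <- sweep(cents %*% t(tf$rotation), 2, tf$translation, "+")
    qR <- matrix_to_quat(tf$rotation)
    movedq <- t(apply(quats, 1, function(q)
      quat_normalize(quat_multiply(qR, q))))
    if (align_end == "pointed") {
      acc_c <- rbind(acc_c, moved[keep, , drop = FALSE])
      acc_q <- rbind(acc_q, movedq[keep, , drop = FALSE])
    } else {
      acc_c <- rbind(moved[keep, , drop = FALSE], acc_c)
      acc_q <- rbind(movedq[keep, , drop = FALSE], acc_q)
    }
  }
  filament_model(make_subunit_df(acc_c, acc_q))
}

# Estimate and remove a circular-arc backbone from a filament's centroids
# (and transport orientations accordingly), so that azimuthal twist can be
# measured about a straight axis. The arc is estimated by quadratic fits of
# the two transverse coordinates against axial position; the fast helical
# wobble averages out of those fits. Models whose estimated total arc turn
# is below `min_turn` radians are returned unchanged, preserving exactness
# for straight lattices.
straighten_coords <- function(cents, quats, min_turn = 0.02) {
  n <- nrow(cents)
  if (n < 7) return(list(cents = cents, quats = quats, curvature = 0))
  u0 <- principal_axis(cents, orient = cents[n, ] - cents[1, ])$axis
  w1 <- perpendicular_vec(u0)
  w2 <- cross3(u0, w1)
  ctr <- colMeans(cents)
  # backbone estimate: running weighted mean whose transfer function nearly
  # annihilates the ~167 deg/step helical wobble, leaving the slow arc
  wts <- c(1, 2, 2, 2, 1) / 8
  if (n >= 7) {
    sm <- vapply(3:(n - 2), function(i) {
      colSums(cents[(i - 2):(i + 2), , drop = FALSE] * wts)
    }, numeric(3))
    bb <- t(sm)
  } else {
    bb <- cents
  }
  s0 <- as.vector(sweep(bb, 2, ctr) %*% u0)
  y1 <- as.vector(sweep(bb, 2, ctr) %*% w1)
  y2 <- as.vector(sweep(bb, 2, ctr) %*% w2)
  X <- cbind(1, s0, s0^2)
  co1 <- qr.coef(qr(X), y1)
  co2 <- qr.coef(qr(X), y2)
  kvec <- 2 * (co1[3] * w1 + co2[3] * w2)
  kappa <- sqrt(sum(kvec^2))
  s_all <- as.vector(sweep(cents, 2, ctr) %*% u0)
  span <- max(s_all) - min(s_all)
  # only straighten when the arc sagitta clearly dominates the residual
  # wobble leakage of the smoothed backbone fit (genuine arcs score >= 20
  # on this ratio, helical wobble that escapes the smoothing filter <= 8);
  # straight lattices of any twist, where direct measurement is exact,
  # must never be distorted by a spurious arc
  resid <- sqrt(mean((y1 - X %*% co1)^2 + (y2 - X %*% co2)^2))
  sagitta <- kappa * span^2 / 8
  if (kappa * span < min_turn || sagitta < 12 * resid)
    return(list(cents = cents, quats = quats, curvature = 0))
  e <- kvec / kappa                     # concave (centre-of-curvature) side
  u <- normalize_vec(u0 + co1[2] * w1 + co2[2] * w2)  # tangent at s = 0
  e <- normalize_vec(e - sum(e * u) * u)
  m <- cross3(e, u)                     # so that e == cross3(u, m)
  O <- ctr + co1[1] * w1 + co2[1] * w2  # backbone point at s = 0
  Ctr <- O + e / kappa                  # centre of the backbone arc
  out_c <- matrix(0, n, 3)
  out_q <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    V <- cents[i, ] - Ctr
    theta <- atan2(sum(V * u), -sum(V * e))
    rho <- sqrt(sum(V * u)^2 + sum(V * e)^2)
    alpha <- 1 / kappa - rho
    beta <- sum(V * m)
    out_c[i, ] <- O + (theta / kappa) * u + alpha * e + beta * m
    q_tr <- quat_from_axis_angle(m, theta)   # inverse transport
    out_q[i, ] <- quat_normalize(quat_multiply(q_tr, quats[i, ]))
  }
  list(cents = out_c, quats = out_q, curvature = kappa)
}

# Measure twist/rise across consecutive positions of a centroid sequence.
# `report_index` gives the protomer index attached to each step entry and
# `report_strand` the strand id. Twist is the signed rotation about the
# local axis (estimated from a sliding window of `window` centroids)
# carrying position j's azimuth onto position j+1's.
measure_steps <- function(cents, quats, window, method, report_index,
                          report_strand) {
  n <- nrow(cents)
  if (n < window) {
    warning("fewer subunits than window size; using the global axis",
            call. = FALSE)
    window <- n
  }
  overall <- cents[n, ] - cents[1, ]
  half <- (window - 1) %/% 2
  steps <- n - 1
  twist <- numeric(steps)
  rise <- numeric(steps)
  for (j in seq_len(steps)) {
    lo <- max(1, min(j - half + 1, n - window + 1))
    W <- cents[lo:(lo + window - 1), , drop = FALSE]
    u <- helix_axis(W, orient = overall)
    rise[j] <- sum((cents[j + 1, ] - cents[j, ]) * u)
    if (method == "azimuthal") {
      e1 <- perpendicular_vec(u)
      e2 <- cross3(u, e1)
      xy <- cbind(W %*% e1, W %*% e2)
      ctr <- fit_circle_2d(xy)
      p1 <- c(sum(cents[j, ] * e1), sum(cents[j, ] * e2)) - ctr
      p2 <- c(sum(cents[j + 1, ] * e1), sum(cents[j + 1, ] * e2)) - ctr
      if (sqrt(sum(p1^2)) < 1e-8 || sqrt(sum(p2^2)) < 1e-8) {
        twist[j] <- 0
      } else {
        twist[j] <- atan2(p1[1] * p2[2] - p1[2] * p2[1],
                          sum(p1 * p2)) * 180 / pi
      }
    } else {
      q_rel <- quat_multiply(quats[j + 1, ],
                             quat_conjugate(quats[j, ]))
      proj <- sum(q_rel[2:4] * u)
      ang <- 2 * atan2(proj, q_rel[1]) * 180 / pi
      twist[j] <- wrap_angle_deg(ang)
    }
  }
  data.frame(index = report_index, twist_deg = wrap_angle_deg(twist),
             rise_ang = rise, strand = report_strand)
}

new_lattice_profile <- function(entries, step_kind) {
  structure(list(step_kind = step_kind, entries = entries),
            class = "lattice_profile")
}

#' @export
print.lattice_profile <- function(x, ...) {
  cat(sprintf("<lattice_profile> %s steps, %d entries\n", x$step_kind,
              nrow(x$entries)))
  print(utils::head(x$entries))
  invisible(x)
}

#' Measure per-step one-start helical parameters
#'
#' For every one-start step i -> i+1: rise is the centroid displacement
#' projected on the local filament axis, and twist the signed rotation about
#' that axis carrying subunit i's azimuth onto subunit i+1's (degrees,
#' wrapped to (-180, 180]). The local axis is the principal direction of a
#' sliding window of centroids so that filament curvature does not bias the
#' measurement; the azimuthal method additionally fits the window's circle
#' centre in the transverse plane. For models shorter than the window the
#' global axis is used with a warning.
#'
#' @param model A [filament_model()] with at least 3 subunits.
#' @param window Sliding-window size (number of centroids) for the local
#'   axis estimate.
#' @param method `"azimuthal"` (default; twist from centroid azimuths about
#'   the local axis) or `"orientation"` (twist from the relative subunit
#'   orientation quaternions, projected on the local axis). Both agree
#'   exactly on noise-free generated lattices.
#' @return A `lattice_profile` with `step_kind = "one_start"`: one entry per
#'   step with `index` (0-based index of the step's first subunit),
#'   `twist_deg`, `rise_ang` and `strand` (parity of `index`).
#' @export
measure_lattice <- function(model, window = 7,
                            method = c("azimuthal", "orientation")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "filament_model"))
  n <- n_subunits(model)
  if (n < 3) stop("need at least 3 subunits")
  idx <- model$subunits$index[-n]
  st <- straighten_coords(centroids(model), subunit_quats(model))
  entries <- measure_steps(st$cents, st$quats, window, method, idx,
                           idx %% 2L)
  new_lattice_profile(entries, "one_start")
}

#' Measure per-strand helical parameters (i -> i+2 steps)
#'
#' Applies the same local-axis twist/rise measurement as
#' [measure_lattice()], but within each strand (subunits two one-start
#' indices apart). For a canonical one-start lattice the strand twist equals
#' twice the one-start twist wrapped into (-180, 180] (e.g. 2 x (-167) ->
#' +26 degrees) and the strand rise twice the one-start rise.
#'
#' @inheritParams measure_lattice
#' @param window Sliding-window size in strand subunits.
#' @return A `lattice_profile` with `step_kind = "strand"`; `index` is the
#'   protomer index of each step's first subunit.
#' @export
strand_profile <- function(model, window = 7,
                           method = c("azimuthal", "orientation")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "filament_model"))
  if (n_subunits(model) < 4) stop("need at least 4 subunits")
  st <- straighten_coords(centroids(model), subunit_quats(model))
  cents <- st$cents
  quats <- st$quats
  pieces <- lapply(0:1, function(s) {
    sel <- which(model$subunits$strand == s)
    if (length(sel) < 2) return(NULL)
    idx <- model$subunits$index[sel]
    measure_steps(cents[sel, , drop = FALSE], quats[sel, , drop = FALSE],
                  window, method, idx[-length(idx)], s)
  })
  entries <- do.call(rbind, pieces)
  entries <- entries[order(entries$index), ]
  rownames(entries) <- NULL
  new_lattice_profile(entries, "strand")
}

#' Retain the central entries of a lattice profile
#'
#' Edge subunits of a tiled or fitted model carry boundary artefacts; only a
#' central block of steps is kept for analysis. The retained block is
#' symmetric about the profile midpoint, with ties (odd number of discarded
#' entries) broken toward the pointed end.
#'
#' @param profile A `lattice_profile`.
#' @param n_central Number of entries to retain (default 10).
#' @return A `lattice_profile` with exactly `n_central` entries.
#' @export
trim_central <- function(profile, n_central = 10) {
  stopifnot(inherits(profile, "lattice_profile"))
  L <- nrow(profile$entries)
  if (L < n_central) stop("profile has fewer entries than n_central")
  start <- (L - n_central) %/% 2 + 1
  out <- profile
  out$entries <- profile$entries[start:(start + n_central - 1), ,
                                 drop = FALSE]
  rownames(out$entries) <- NULL
  out
}

#' Summarise a lattice profile
#'
#' Per-strand and overall mean, standard deviation and count of twist and
#' rise. Strands with no entries are omitted with a warning.
#'
#' @param profile A `lattice_profile`.
#' @return Data frame with columns `strand` (`"0"`, `"1"`, `"all"`), `n`,
#'   `twist_mean`, `twist_sd`, `rise_mean`, `rise_sd`.
#' @export
summarize_profile <- function(profile) {
  stopifnot(inherits(profile, "lattice_profile"))
  e <- profile$entries
  if (nrow(e) == 0) stop("empty profile")
  row_for <- function(label, d) {
    data.frame(strand = label, n = nrow(d),
               twist_mean = mean(d$twist_deg),
               twist_sd = stats::sd(d$twist_deg),
               rise_mean = mean(d$rise_ang),
               rise_sd = stats::sd(d$rise_ang))
  }
  out <- list()
  for (s in 0:1) {
    d <- e[e$strand == s, , drop = FALSE]
    if (nrow(d) == 0) {
      warning(sprintf("strand %d has no entries; omitted", s), call. = FALSE)
    } else {
      out[[length(out) + 1]] <- row_for(as.character(s), d)
    }
  }
  out[[length(out) + 1]] <- row_for("all", e)
  do.call(rbind, out)
}
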