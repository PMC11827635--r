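test_that("generated straight lattices reproduce their symmetry at every step", {
  fil <- canonical_filament(37)
  p <- measure_lattice(fil)
  expect_equal(nrow(p$entries), 36)
  expect_lt(max(abs(p$entries$twist_deg - (-167))), 1e-6)
  expect_lt(max(abs(p$entries$rise_ang - 27)), 1e-6)
  # both twist routes agree exactly on generator output
  po <- measure_lattice(fil, method = "orientation")
  expect_lt(max(abs(po$entries$twist_deg - p$entries$twist_deg)), 1e-9)

  z <- build_filament(helical_symmetry(0, 27), 8)
  pz <- measure_lattice(z, window = 5)
  expect_true(all(pz$entries$twist_deg == 0))
  expect_lt(max(abs(pz$entries$rise_ang - 27)), 1e-9)
})

test_that("per-step generator values round-trip through measurement", {
  set.seed(7)
  tw <- -167 + runif(24, -3, 3)
  fil <- build_filament_steps(tw, rep(27, 24))
  m <- measure_lattice(fil)
  expect_lt(max(abs(m$entries$twist_deg -
                      ((tw %% 360) - 360 * ((tw %% 360) > 180)))), 1e-6)
})

test_that("strand-level profile doubles the one-start step with wrapping", {
  fil <- canonical_filament(20, rise = 27.5)
  sp <- strand_profile(fil)
  expect_lt(max(abs(sp$entries$twist_deg - 26)), 1e-6)
  expect_lt(max(abs(sp$entries$rise_ang - 55)), 1e-6)

  z <- build_filament(helical_symmetry(0, 27), 10)
  sz <- strand_profile(z, window = 4)
  expect_true(all(sz$entries$twist_deg == 0))
  expect_lt(max(abs(sz$entries$rise_ang - 54)), 1e-9)

  # wrap property across a grid of one-start twists
  for (t1 in c(-179, -167, -150, -100, -30, 40, 100, 167)) {
    fil <- build_filament(helical_symmetry(t1, 27), 16)
    sp <- strand_profile(fil, window = 5)
    expected <- (2 * t1) %% 360
    if (expected > 180) expected <- expected - 360
    expect_lt(max(abs(sp$entries$twist_deg - expected)), 1e-6)
  }
})

test_that("tiling produces the closed-form subunit count and exact geometry", {
  f15 <- canonical_filament(15)
  t37 <- tile_filament(f15, 3, 4, "pointed")
  expect_equal(nrow(t37$subunits), 37)
  p <- trim_central(measure_lattice(t37), 10)
  expect_equal(nrow(p$entries), 10)
  expect_lt(max(abs(p$entries$twist_deg - (-167))), 1e-6)
  expect_lt(max(abs(p$entries$rise_ang - 27)), 1e-6)

  expect_identical(tile_filament(f15, 1, 4), f15)
  expect_equal(nrow(tile_filament(canonical_filament(10), 2, 3)$subunits),
               17)
  # count formula over a grid, both alignment ends
  for (n in c(6, 11, 15)) {
    fil <- canonical_filament(n)
    for (cpy in 1:4) for (k in c(3, min(5, n - 1))) {
      expect_equal(nrow(tile_filament(fil, cpy, k, "pointed")$subunits),
                   n + (cpy - 1) * (n - k))
      expect_equal(nrow(tile_filament(fil, cpy, k, "barbed")$subunits),
                   n + (cpy - 1) * (n - k))
    }
  }
  expect_error(tile_filament(f15, 2, 15), "overlap")
  expect_error(tile_filament(f15, 2, 2), "overlap")
})

test_that("superposition matches Horn's closed-form oracle", {
  fil <- canonical_filament(12)
  # self-alignment: identity
  tf <- superpose(fil, fil, 0:11)
  expect_lt(tf$rmsd, 1e-9)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)

  # apply-then-recover round trip
  rot90z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- apply_transform(fil, structure(
    list(rotation = rot90z, translation = c(10, 0, 0), rmsd = 0),
    class = "rigid_transform"))
  rec <- superpose(moved, fil, 0:11)
  expect_lt(rec$rmsd, 1e-9)
  expect_lt(max(abs(rec$rotation %*% rot90z - diag(3))), 1e-9)

  # noisy point sets against the independent oracle
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:20, 1)
    P <- matrix(rnorm(3 * n, sd = 10), n, 3)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, -pi, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    Q <- P %*% t(R) + matrix(rnorm(3 * n, sd = 0.5), n, 3)
    got <- actinlattice:::kabsch(P, Q)
    want <- horn_superpose(P, Q)
    expect_lt(abs(got$rmsd - want$rmsd), 1e-9)
    expect_lt(max(abs(got$rotation - want$rotation)), 1e-7)
  }

  # collinear subsets are rejected
  line <- build_filament(helical_symmetry(0, 27), 6, radius = 0)
  expect_error(superpose(line, line, 0:5), "degenerate|collinear")
})

test_that("bending maps the backbone onto the commanded arc", {
  t37 <- tiled_37mer()
  expect_identical(bend_filament(t37, 0, c(1, 0, 0), 0), t37)

  # arc radius check on an axis-only model (helical radius 0)
  ax_model <- build_filament(helical_symmetry(-167, 27), 37, radius = 0)
  bent <- bend_filament(ax_model, 1 / 2000, c(1, 0, 0), 0)
  cc <- as.matrix(bent$subunits[, c("x", "y", "z")])
  # least-squares circle in the bend plane
  fitc <- function(xy) {
    A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
    s <- qr.solve(A, xy[, 1]^2 + xy[, 2]^2)
    c(s[1], s[2], sqrt(s[3] + s[1]^2 + s[2]^2))
  }
  expect_lt(diff(range(cc[, 1])), 1e-9)     # stays in the bend plane
  f <- fitc(cc[, c(3, 2)])
  expect_lt(abs(f[3] - 2000), 1e-6)
  resid <- sqrt((cc[, 3] - f[1])^2 + (cc[, 2] - f[2])^2) - f[3]
  expect_lt(max(abs(resid)), 1e-6)

  expect_error(bend_filament(t37, 1 / 200, c(1, 0, 0), 0),
               "self-intersection")
})

test_that("commanded strand twist asymmetry is recovered", {
  t37 <- tiled_37mer()
  # straight lattice: azimuthal route is exact
  sb <- strand_profile(bend_filament(t37, 0, c(1, 0, 0), -2))
  m <- strand_means(sb)
  expect_lt(abs((m[1] - m[2]) - (-2)), 1e-6)
  # strand 0 (convex-side convention) is under-twisted in magnitude
  expect_lt(abs(m[1]), abs(m[2]))

  # curved lattices (bend radii >= 1000 A): orientation-frame route
  for (kappa in c(1 / 2000, 1 / 1000)) {
    sb <- strand_profile(bend_filament(t37, kappa, c(1, 0, 0), -2),
                         method = "orientation")
    m <- strand_means(sb)
    expect_lt(abs((m[1] - m[2]) - (-2)), 0.05)
  }

  # no asymmetry commanded: strands agree on a curved lattice
  sb <- strand_profile(bend_filament(t37, 1 / 2000, c(1, 0, 0), 0))
  m <- strand_means(sb)
  expect_lt(abs(m[1] - m[2]), 0.05)
})

test_that("central trimming is symmetric with the pointed-end tie rule", {
  p36 <- measure_lattice(tiled_37mer())
  expect_equal(trim_central(p36, 10)$entries$index, 13:22)

  ten <- trim_central(p36, 10)
  expect_identical(trim_central(ten, 10), ten)

  p14 <- ten
  p14$entries <- p36$entries[1:14, ]
  expect_equal(trim_central(p14, 10)$entries$index, 2:11)
  expect_error(trim_central(ten, 11), "fewer")
})

test_that("profile summaries match hand-computed means", {
  prof <- actinlattice:::new_lattice_profile(
    data.frame(index = 0:3, twist_deg = c(-167, -165, -169, -167),
               rise_ang = c(27, 28, 26, 27), strand = c(0L, 1L, 0L, 1L)),
    "one_start")
  s <- summarize_profile(prof)
  expect_equal(s$twist_mean[s$strand == "0"], -168)
  expect_equal(s$twist_mean[s$strand == "1"], -166)
  expect_equal(s$twist_mean[s$strand == "all"], -167)
  expect_equal(s$rise_mean[s$strand == "all"], 27)
  expect_equal(s$n[s$strand == "all"], 4)

  only0 <- prof
  only0$entries <- prof$entries[prof$entries$strand == 0, ]
  expect_warning(s0 <- summarize_profile(only0), "strand 1")
  expect_false("1" %in% s0$strand)
})

test_that("constructor preconditions are enforced", {
  expect_error(build_filament(helical_symmetry(-167, 27), 2), ">= 3")
  expect_error(helical_symmetry(-167, -1), "positive")
  expect_error(helical_symmetry(200, 27), "-180")
  # short model falls back to the global axis with a warning, not an error
  expect_warning(p3 <- measure_lattice(canonical_filament(3), window = 7),
                 "global axis")
  expect_equal(nrow(p3$entries), 2)
})
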