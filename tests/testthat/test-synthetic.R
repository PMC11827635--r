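test_that("generators are deterministic under a fixed config and seed", {
  cfg <- synthetic_config(seed = 13, lattice = list(n_subunits = 15L),
                          frames = list(n_frames = 2L))
  f1 <- generate_frame_series(cfg)
  f2 <- generate_frame_series(cfg)
  expect_identical(f1[[2]]$grid$values, f2[[2]]$grid$values)
  expect_identical(f1[[2]]$truth, f2[[2]]$truth)

  t1 <- generate_tirf_pair(cfg, list(rep(1L, 50)))
  t2 <- generate_tirf_pair(cfg, list(rep(1L, 50)))
  expect_identical(t1$pair$channel_b, t2$pair$channel_b)

  j1 <- generate_junction_image(cfg)
  j2 <- generate_junction_image(cfg)
  expect_identical(j1$pair$channel_a, j2$pair$channel_a)

  expect_error(synthetic_config(optics = list(nope = 1)), "unknown")
})

test_that("frame series couples curvature, asymmetry and decoration", {
  cfg <- synthetic_config(seed = 2, lattice = list(n_subunits = 15L),
                          frames = list(n_frames = 4L))
  fs <- generate_frame_series(cfg)
  expect_length(fs, 4)
  # curvature schedule increases; convex-strand truth strictly increases
  kappas <- vapply(fs, function(f) f$truth$kappa, numeric(1))
  expect_true(all(diff(kappas) > 0))
  s0 <- vapply(fs, function(f) mean(f$truth$occupancy[
    f$model$subunits$strand == 0]), numeric(1))
  s1 <- vapply(fs, function(f) mean(f$truth$occupancy[
    f$model$subunits$strand == 1]), numeric(1))
  expect_true(all(diff(s0) > 0))
  expect_true(all(s1 == cfg$frames$baseline_occupancy))

  # zero coupling: occupancies identical across frames
  cfg0 <- synthetic_config(seed = 2, lattice = list(n_subunits = 15L),
                           frames = list(n_frames = 3L, coupling = 0))
  fs0 <- generate_frame_series(cfg0)
  occs <- lapply(fs0, function(f) f$truth$occupancy)
  expect_identical(occs[[1]], occs[[2]])
  expect_identical(occs[[2]], occs[[3]])

  # flat curvature schedule: straight frames with symmetric strand twists
  cfgF <- synthetic_config(seed = 2, frames = list(n_frames = 3L,
                                                   kappa_max = 0,
                                                   asym_max_deg = 0))
  fsF <- generate_frame_series(cfgF)
  sp <- strand_profile(fsF[[3]]$model)
  m <- strand_means(sp)
  expect_lt(abs(m[1] - m[2]), 1e-6)

  expect_error(generate_frame_series(
    synthetic_config(frames = list(n_frames = 1L))), "2 frames")
})

test_that("volume library counts follow the closed-form formula", {
  base <- list(seed = 4, lattice = list(n_subunits = 9L),
               render = list(voxel_size = 8, blob_sigma = 6))
  cfg <- do.call(synthetic_config, c(base, list(
    library = list(orientations_deg = c(0, 120, 240),
                   curvatures = c(0, 1 / 2000), n_partial = 0L))))
  lib <- generate_volume_library(cfg)
  expect_length(lib$volumes, 3 * 2 * 2)
  expect_equal(sort(unique(lib$labels$pattern)), c("bare", "full"))

  cfg1 <- do.call(synthetic_config, c(base, list(
    library = list(orientations_deg = 0, curvatures = 0, n_partial = 0L))))
  expect_length(generate_volume_library(cfg1)$volumes, 2)

  cfg2 <- do.call(synthetic_config, c(base, list(
    library = list(orientations_deg = c(0, 90), curvatures = 0,
                   n_partial = 3L))))
  lib2 <- generate_volume_library(cfg2)
  expect_length(lib2$volumes, 2 * (2 + 3))
  part <- lib2$labels[grepl("partial", lib2$labels$pattern), ]
  expect_true(all(part$decorated_fraction > 0 &
                    part$decorated_fraction < 1))
  # recorded truth matches the labels
  for (id in part$id) {
    expect_equal(mean(lib2$truth[[id]]),
                 part$decorated_fraction[part$id == id])
  }
})

test_that("TIRF pairs carry consistent ground truth", {
  cfg <- synthetic_config(seed = 7, binding = list(n_sites = 80L),
                          optics = list(img_cols = 500L))

  # no bound sites: ligand channel is noise only, pipeline fraction ~ 0
  tp0 <- generate_tirf_pair(cfg, list(integer(80), integer(80)))
  expect_equal(sum(tp0$truth$ligand_mask), 0)
  q0 <- suppressWarnings(quantify_tirf_pair(tp0$pair))
  expect_lt(q0$fraction, 0.01)

  # fully bound filament
  tp1 <- generate_tirf_pair(cfg, list(rep(1L, 80), rep(1L, 80)))
  q1 <- quantify_tirf_pair(tp1$pair)
  expect_gte(q1$fraction, 0.95)

  # patchy simulator state: ligand truth colocalises with the filament
  st <- sample_lattice_states(synthetic_config(seed = 7, binding = list(
    n_sites = 80L, omega = 10, k_off = 25)), concentration = 0.5,
    n_filaments = 1)
  tp <- generate_tirf_pair(cfg, st)
  overlap <- sum(tp$truth$ligand_mask & tp$truth$actin_mask) /
    max(sum(tp$truth$ligand_mask), 1)
  expect_gte(overlap, 0.9)
})

test_that("junction images give the commanded FWHM ratio", {
  mid <- function(cfg) (cfg$junction$img_rows + 1) / 2
  ratio_for <- function(sa, sb, noise = 1, seed = 3) {
    cfg <- synthetic_config(seed = seed, junction = list(
      sigma_a_px = sa, sigma_b_px = sb, noise_sd = noise))
    jp <- generate_junction_image(cfg)
    pr <- line_profile(jp$pair, c(mid(cfg), 3),
                       c(mid(cfg), cfg$junction$img_cols - 2),
                       width_px = 5, step_px = 0.2)
    # the band centre falls between two pixel columns, so the noise-free
    # peak is a two-sample plateau; the global-maximum rule applies
    suppressWarnings(fwhm_ratio(pr)$ratio)
  }
  expect_lt(abs(ratio_for(3, 3) - 1), 0.05)
  expect_lt(abs(ratio_for(6, 3) - 2), 0.1)
  expect_lt(abs(ratio_for(6, 3, noise = 0) / 2 - 1), 0.01)
})
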