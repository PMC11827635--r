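#' Synthetic-data configuration
#'
#' One seeded configuration object drives every synthetic generator, so
#' each stage of the analysis can be exercised with known ground truth.
#' Defaults encode the study conditions the analyses assume: a 37-subunit
#' two-strand lattice at -167 deg / 27 A one-start symmetry, a ten-frame
#' variability series coupling curvature (up to a 2000 A bend radius),
#' strand twist asymmetry (-2 deg) and convex-strand decoration, a
#' cooperative binding lattice bracketing an apparent Kd near 1 uM, and
#' TIRF-like optics (0.1 um pixels, 0.15 um PSF sigma, Poisson + read
#' noise).
#'
#' @param seed Integer seed recorded in all outputs.
#' @param lattice,frames,render,binding,optics,library,junction Named lists
#'   overriding individual defaults (see the function source for the
#'   complete set).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, lattice = list(), frames = list(),
                             render = list(), binding = list(),
                             optics = list(), library = list(),
                             junction = list()) {
  merge_defaults <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown config fields: ",
                          paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    seed = as.integer(seed),
    lattice = merge_defaults(list(
      twist_deg = -167, rise_ang = 27, n_subunits = 37L, radius = 25), lattice),
    frames = merge_defaults(list(
      n_frames = 10L, kappa_max = 1 / 2000, asym_max_deg = -2,
      coupling = 0.9, baseline_occupancy = 0.1,
      bend_plane_normal = c(1, 0, 0)), frames),
    render = merge_defaults(list(
      voxel_size = 4, blob_sigma = 5, site_offset = 25), render),
    # lattice kinetics whose exact equilibrium curve, Hill-fitted over the
    # concentration grid below, shows apparent Kd ~0.92 uM and h ~2.7
    binding = merge_defaults(list(
      n_sites = 200L, k_on = 1, k_off = 8.4, omega = 3,
      concentrations = exp(seq(log(0.1), log(4), length.out = 8)),
      t_end = 10), binding),
    # binned-camera TIRF geometry: 0.2 um pixels, one lattice site per
    # 5 pixels, an effectively sub-pixel PSF (as after deconvolution) and
    # pure shot noise over a flat background, so segmentation truth is
    # unambiguous at half amplitude
    optics = merge_defaults(list(
      pixel_size_um = 0.2, psf_sigma_um = 0.05, read_noise_sd = 0,
      gain = 10, amp_a = 100, amp_b = 100, img_rows = 32L,
      img_cols = 1100L, px_per_site = 5L, line_halfwidth_px = 1L,
      n_filaments = 3L), optics),
    library = merge_defaults(list(
      orientations_deg = c(0, 120, 240), curvatures = c(0, 1 / 2000),
      n_partial = 2L), library),
    junction = merge_defaults(list(
      sigma_a_px = 3, sigma_b_px = 3, amp = 100, noise_sd = 1,
      img_rows = 96L, img_cols = 96L), junction))
  stopifnot(cfg$optics$read_noise_sd >= 0, cfg$optics$gain >= 0,
            cfg$junction$noise_sd >= 0)
  structure(cfg, class = "synthetic_config")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Curvature/occupancy-coupled synthetic frame series
#'
#' Emulates an ordered variability series: frame curvature increases
#' linearly from 0 to `kappa_max`, strand twist asymmetry scales with
#' curvature (twist-bend coupling, strand 0 under-twisted), and strand-0
#' (convex-side) site occupancies ramp from the baseline with the coupling
#' coefficient while strand 1 stays at baseline. Each frame carries its
#' rendered density map and a ground-truth record.
#'
#' @param config A [synthetic_config()].
#' @return List of frames; each frame is a list with `model`
#'   ([filament_model()]), `grid` ([density_grid()]) and `truth` (list:
#'   `occupancy` per subunit, `kappa`, `asymmetry_deg`, `frame`).
#' @export
generate_frame_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  fr <- config$frames
  if (fr$n_frames < 2) stop("need at least 2 frames")
  lat <- config$lattice
  rd <- config$render
  base_model <- build_filament(helical_symmetry(lat$twist_deg, lat$rise_ang),
                               lat$n_subunits, radius = lat$radius)
  idx <- base_model$subunits$index
  lapply(seq_len(fr$n_frames), function(f) {
    g <- (f - 1) / (fr$n_frames - 1)
    kappa <- fr$kappa_max * g
    asym <- fr$asym_max_deg * g
    model <- bend_filament(base_model, kappa, fr$bend_plane_normal, asym)
    occ <- ifelse(idx %% 2 == 0,
                  clamp01(fr$baseline_occupancy + fr$coupling * g),
                  fr$baseline_occupancy)
    grid <- render_density(model, occ, voxel_size = rd$voxel_size,
                           blob_sigma = rd$blob_sigma,
                           site_offset = rd$site_offset)
    list(model = model, grid = grid,
         truth = list(occupancy = occ, kappa = kappa, asymmetry_deg = asym,
                      frame = f, seed = config$seed))
  })
}

#' Synthetic decorated-filament volume library
#'
#' For every combination of complex orientation and filament curvature,
#' generates one bare filament, one fully decorated filament, and
#' `n_partial` partially decorated filaments with random binary decoration
#' patterns (decorated fraction strictly inside (0, 1)), mirroring the
#' construction of segmentation-training libraries for decorated
#' filaments. Total volume count is
#' `orientations x curvatures x (2 + n_partial)`.
#'
#' @param config A [synthetic_config()].
#' @return List with `volumes` (list of [density_grid()]), `labels` (data
#'   frame: `id`, `orientation_deg`, `curvature`, `pattern`,
#'   `decorated_fraction`) and `truth` (list of per-volume occupancy
#'   vectors).
#' @export
generate_volume_library <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lib <- config$library
  lat <- config$lattice
  rd <- config$render
  stopifnot(length(lib$orientations_deg) >= 1, length(lib$curvatures) >= 1,
            lib$n_partial >= 0)
  set.seed(config$seed)
  base_model <- build_filament(helical_symmetry(lat$twist_deg, lat$rise_ang),
                               lat$n_subunits, radius = lat$radius)
  n <- lat$n_subunits
  volumes <- list(); truth <- list(); labels <- list()
  id <- 0L
  for (orient in lib$orientations_deg) {
    # complex orientation: body-frame direction of the bound-complex anchor
    rot <- quat_from_axis_angle(c(0, 0, 1), orient * pi / 180)
    oriented <- base_model
    oriented$subunits[, c("qw", "qx", "qy", "qz")] <-
      t(apply(subunit_quats(base_model), 1, function(q)
        quat_normalize(quat_multiply(q, rot))))
    for (kappa in lib$curvatures) {
      model <- bend_filament(oriented, kappa,
                             config$frames$bend_plane_normal, 0)
      patterns <- c(list(bare = rep(0, n), full = rep(1, n)),
                    stats::setNames(lapply(seq_len(lib$n_partial), function(p) {
                      repeat {
                        occ <- as.numeric(stats::runif(n) < stats::runif(1, 0.2, 0.8))
                        fr <- mean(occ)
                        if (fr > 0 && fr < 1) return(occ)
                      }
                    }), if (lib$n_partial > 0)
                      paste0("partial", seq_len(lib$n_partial)) else NULL))
      for (pn in names(patterns)) {
        id <- id + 1L
        occ <- patterns[[pn]]
        volumes[[id]] <- render_density(model, occ,
                                        voxel_size = rd$voxel_size,
                                        blob_sigma = rd$blob_sigma,
                                        site_offset = rd$site_offset)
        truth[[id]] <- occ
        labels[[id]] <- data.frame(id = id, orientation_deg = orient,
                                   curvature = kappa, pattern = pn,
                                   decorated_fraction = mean(occ))
      }
    }
  }
  list(volumes = volumes, labels = do.call(rbind, labels), truth = truth)
}

# Separable Gaussian blur with reflected edges.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1, ceiling(4 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  pad_reflect <- function(v, r) c(rev(v[seq_len(r)]), v,
                                  rev(v[(length(v) - r + 1):length(v)]))
  conv1 <- function(v) stats::filter(pad_reflect(v, r), k,
                                     sides = 2)[(r + 1):(r + length(v))]
  img <- apply(img, 2, conv1)
  t(apply(t(img), 2, conv1))
}

#' Synthetic TIRF image pair from lattice binding states
#'
#' Forward model for the fraction-bound quantification: filaments are
#' horizontal one-pixel-wide lines (one lattice site per pixel) rendered
#' into channel A, bound sites into channel B; both channels are convolved
#' with a Gaussian PSF, scaled so the noise-free filament ridge reaches the
#' configured amplitude, and corrupted with Poisson shot noise (gain
#' photons per intensity unit; 0 disables) plus Gaussian read noise. Truth
#' masks are the half-amplitude supports of the noise-free renders.
#'
#' @param config A [synthetic_config()].
#' @param states List of binary occupancy vectors, one per filament (all of
#'   length `<= img_cols - 8`).
#' @param seed Seed for noise (defaults to `config$seed`).
#' @return List with `pair` ([image_pair()]), `truth` (list:
#'   `actin_mask`, `ligand_mask`, `bound_mask`, `bound_fraction`, `states`).
#' @export
generate_tirf_pair <- function(config, states, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"), length(states) >= 1)
  op <- config$optics
  nr <- op$img_rows; nc <- op$img_cols
  sig <- op$psf_sigma_um / op$pixel_size_um
  a <- matrix(0, nr, nc)
  b <- matrix(0, nr, nc)
  set.seed(seed)
  n_f <- length(states)
  rows <- round(seq(nr * 0.2, nr * 0.8, length.out = n_f)) +
    sample(-5:5, n_f, replace = TRUE)
  hw <- op$line_halfwidth_px
  for (i in seq_along(states)) {
    st <- rep(as.integer(states[[i]]), each = op$px_per_site)
    L <- length(st)
    if (L > nc - 8) stop("lattice longer than the image allows")
    c0 <- sample.int(nc - L - 6, 1) + 3
    r0 <- rows[i]
    rr <- max(1, r0 - hw):min(nr, r0 + hw)
    a[rr, c0:(c0 + L - 1)] <- 1
    b[rr, c0:(c0 + L - 1)] <- rep(st, each = length(rr))
  }
  # normalise so a blurred ridge of the configured thickness peaks at the
  # channel amplitude
  kr <- ceiling(4 * sig)
  kd <- stats::dnorm(-kr:kr, sd = sig)
  kd <- kd / sum(kd)
  kpeak <- sum(kd[abs(-kr:kr) <= hw])
  a_clean <- gaussian_blur(a, sig) * (op$amp_a / kpeak)
  b_clean <- gaussian_blur(b, sig) * (op$amp_b / kpeak)
  truth_a <- a_clean >= op$amp_a / 2
  truth_b <- b_clean >= op$amp_b / 2
  add_noise <- function(img) {
    out <- img
    if (op$gain > 0)
      out <- stats::rpois(length(img), lambda = op$gain * img) / op$gain
    out <- out + stats::rnorm(length(img), sd = op$read_noise_sd)
    matrix(pmax(out, 0), nrow(img), ncol(img))
  }
  pair <- image_pair(add_noise(a_clean), add_noise(b_clean),
                     pixel_size = op$pixel_size_um)
  list(pair = pair,
       truth = list(actin_mask = truth_a, ligand_mask = truth_b,
                    bound_mask = truth_a & truth_b,
                    bound_fraction = sum(truth_a & truth_b) / sum(truth_a),
                    states = states, seed = seed))
}

#' Synthetic bicellular-junction image pair
#'
#' A straight vertical junction band with Gaussian cross-section per
#' channel (sigma in pixels configurable per channel) plus Gaussian noise;
#' the ground truth records each channel's sigma, so measured FWHM ratios
#' can be scored against `sigma_a / sigma_b`.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed for noise (defaults to `config$seed`).
#' @return List with `pair` ([image_pair()]) and `truth` (list:
#'   `sigma_a_px`, `sigma_b_px`, `center_col`, `expected_ratio`).
#' @export
generate_junction_image <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  jc <- config$junction
  stopifnot(jc$sigma_a_px > 0, jc$sigma_b_px > 0)
  nr <- jc$img_rows; nc <- jc$img_cols
  cc <- (nc + 1) / 2
  cols <- seq_len(nc)
  band <- function(sigma) {
    prof <- jc$amp * exp(-(cols - cc)^2 / (2 * sigma^2))
    matrix(prof, nr, nc, byrow = TRUE)
  }
  set.seed(seed)
  noisy <- function(img) {
    matrix(pmax(img + stats::rnorm(length(img), sd = jc$noise_sd), 0),
           nrow(img), ncol(img))
  }
  pair <- image_pair(noisy(band(jc$sigma_a_px)), noisy(band(jc$sigma_b_px)),
                     pixel_size = config$optics$pixel_size_um)
  list(pair = pair,
       truth = list(sigma_a_px = jc$sigma_a_px, sigma_b_px = jc$sigma_b_px,
                    center_col = cc,
                    expected_ratio = jc$sigma_a_px / jc$sigma_b_px,
                    seed = seed))
}
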