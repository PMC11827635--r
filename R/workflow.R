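#' Simulated equilibrium lattice states for a concentration
#'
#' Runs the Gillespie simulator once per filament, starting from an
#' independent random state at the exact equilibrium coverage to shorten
#' burn-in, and returns the final binary states.
#'
#' @param config A [synthetic_config()] (its `binding` block sets the
#'   kinetics).
#' @param concentration Ligand concentration, uM.
#' @param n_filaments Number of independent filaments.
#' @param seed Integer seed.
#' @return List of binary occupancy vectors.
#' @export
sample_lattice_states <- function(config, concentration,
                                  n_filaments = config$optics$n_filaments,
                                  seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"), concentration > 0)
  bn <- config$binding
  kd <- bn$k_off / bn$k_on
  cov0 <- equilibrium_coverage_exact(bn$n_sites, concentration, kd,
                                     bn$omega)
  lapply(seq_len(n_filaments), function(j) {
    set.seed(seed + 7 * j)
    st <- as.integer(stats::runif(bn$n_sites) < cov0)
    lat <- binding_lattice(bn$n_sites, bn$k_on, bn$k_off, bn$omega,
                           concentration, state = st)
    simulate_lattice_binding(lat, bn$t_end, seed = seed + 13 * j)$state
  })
}

#' End-to-end TIRF fraction-bound concentration series
#'
#' For each configured concentration: simulates equilibrium lattice states,
#' renders a synthetic TIRF image pair, and runs the fraction-bound
#' pipeline (rolling-ball background subtraction, Yen thresholding, mask
#' conjunction). Returns measured and ground-truth fractions together with
#' Hill fits of the measured curve and of the exact transfer-matrix truth
#' curve, the generator-defined reference for parameter recovery.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return List with `curve` (data frame: `concentration`, `measured`,
#'   `truth_mask`, `coverage`), `fit_measured` and `fit_truth` (both
#'   [fit_hill()] results on measured fractions and on the exact
#'   equilibrium coverages respectively).
#' @export
tirf_binding_series <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  bn <- config$binding
  C <- bn$concentrations
  rows <- lapply(seq_along(C), function(i) {
    states <- sample_lattice_states(config, C[i],
                                    seed = seed + 1000L * i)
    tp <- generate_tirf_pair(config, states, seed = seed + i)
    q <- quantify_tirf_pair(tp$pair)
    data.frame(concentration = C[i], measured = q$fraction,
               truth_mask = tp$truth$bound_fraction,
               coverage = mean(unlist(states)))
  })
  curve <- do.call(rbind, rows)
  exact <- vapply(C, function(cc) {
    equilibrium_coverage_exact(bn$n_sites, cc, bn$k_off / bn$k_on,
                               bn$omega)
  }, numeric(1))
  list(curve = curve,
       fit_measured = fit_hill(data.frame(concentration = C,
                                          fraction_bound = curve$measured)),
       fit_truth = fit_hill(data.frame(concentration = C,
                                       fraction_bound = exact)))
}

#' Occupancy and geometry analysis of a synthetic frame series
#'
#' Runs the density-splitting occupancy measurement across a
#' curvature-coupled frame series, compares normalised intensities with
#' generator truth, and pairs the final (most curved) frame's strand-level
#' twist with its site occupancies.
#'
#' @param config A [synthetic_config()].
#' @param frames Optional pre-generated frame series (defaults to
#'   `generate_frame_series(config)`).
#' @return List with `trajectory` (per frame and strand mean normalised
#'   intensity), `site_table` (per frame/site normalised intensity vs truth
#'   occupancy), and `correlation` (geometry-occupancy association on the
#'   final frame, from [correlate_geometry_occupancy()]).
#' @export
frame_series_occupancy <- function(config,
                                   frames = generate_frame_series(config)) {
  rd <- config$render
  traj <- strand_occupancy_trajectory(frames, site_offset = rd$site_offset,
                                      radius = 15)
  per_frame <- lapply(frames, function(fr) {
    sp <- split_density(fr$grid, fr$model,
                        complex_anchors = fr$model$subunits$index,
                        radius = 15, site_offset = rd$site_offset)
    site_intensities(sp$sites)
  })
  gmax <- max(vapply(per_frame, function(s) max(s$integrated_intensity),
                     numeric(1)))
  site_table <- do.call(rbind, lapply(seq_along(frames), function(f) {
    s <- normalize_sites(per_frame[[f]], reference = gmax)
    s$frame <- f
    s$truth_occupancy <- frames[[f]]$truth$occupancy[s$index + 1]
    s
  }))
  last <- frames[[length(frames)]]
  prof <- strand_profile(last$model, method = "orientation")
  sites_last <- normalize_sites(per_frame[[length(frames)]],
                                reference = gmax)
  corr <- correlate_geometry_occupancy(prof, sites_last, "twist")
  list(trajectory = traj, site_table = site_table, correlation = corr)
}
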