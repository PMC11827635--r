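#' Cooperative binding lattice
#'
#' Parameters and state of a one-dimensional ligand-binding lattice on a
#' filament. Ligands bind single sites; a bridging cooperativity factor
#' `omega` rewards bound nearest neighbours, the mechanism by which a
#' coiled-coil bridge between adjacent actin-binding domains produces
#' cooperative, patch-forming filament decoration. Association at a site
#' with `b` bound neighbours proceeds at `k_on * C * omega^b`, dissociation
#' at `k_off * omega^-b`; the intrinsic dissociation constant is
#' `k_off / k_on` and each bound nearest-neighbour pair consequently carries
#' an equilibrium statistical weight of `omega^2`.
#'
#' @param n_sites Number of lattice sites (>= 1).
#' @param k_on Intrinsic association rate constant, per uM per s.
#' @param k_off Intrinsic dissociation rate, per s.
#' @param omega Dimensionless nearest-neighbour cooperativity factor
#'   (>= 0; 1 = independent sites).
#' @param concentration Free ligand concentration, uM.
#' @param state Optional initial binary occupancy vector (default all
#'   unbound).
#' @return An object of class `binding_lattice`.
#' @export
binding_lattice <- function(n_sites, k_on = 1, k_off = 1, omega = 1,
                            concentration = 1, state = NULL) {
  stopifnot(n_sites >= 1, k_on >= 0, k_off >= 0, omega >= 0,
            concentration >= 0)
  if (is.null(state)) state <- integer(n_sites)
  state <- as.integer(state)
  stopifnot(length(state) == n_sites, all(state %in% c(0L, 1L)))
  structure(list(n_sites = as.integer(n_sites), k_on = k_on, k_off = k_off,
                 omega = omega, concentration = concentration,
                 state = state),
            class = "binding_lattice")
}

bound_neighbour_counts <- function(state) {
  n <- length(state)
  left <- c(0L, state[-n])
  right <- c(state[-1], 0L)
  left + right
}

#' Event-driven stochastic simulation of lattice binding
#'
#' Continuous-time (Gillespie) simulation of the `binding_lattice` kinetic
#' scheme. Association rate at an empty site is
#' `k_on * C * omega^(bound neighbours)`, dissociation at an occupied site
#' `k_off * omega^(-bound neighbours)`; the scheme satisfies detailed
#' balance with respect to the 1D lattice-gas equilibrium used by
#' [equilibrium_coverage_exact()]. Reproducible under a fixed seed.
#'
#' @param lattice A [binding_lattice()].
#' @param t_end Simulated time, s.
#' @param seed Integer RNG seed.
#' @param max_events Safety cap on the number of events.
#' @return An object of class `binding_trajectory`: list with the final
#'   `state`, the event log `events` (data frame: `time`, `site`, `type`
#'   (+1 association / -1 dissociation), `nb_left`, `nb_right`), `t_end`,
#'   and the originating `lattice`.
#' @export
simulate_lattice_binding <- function(lattice, t_end, seed = 1,
                                     max_events = 2e6) {
  stopifnot(inherits(lattice, "binding_lattice"), t_end > 0)
  set.seed(seed)
  n <- lattice$n_sites
  state <- lattice$state
  omega <- lattice$omega
  kon_c <- lattice$k_on * lattice$concentration
  koff <- lattice$k_off

  site_rate <- function(i) {
    b <- (if (i > 1) state[i - 1] else 0L) + (if (i < n) state[i + 1] else 0L)
    if (state[i] == 0L) kon_c * omega^b else koff * omega^(-b)
  }
  rates <- vapply(seq_len(n), site_rate, numeric(1))

  cap <- 4096L
  ev_time <- numeric(cap); ev_site <- integer(cap)
  ev_type <- integer(cap); ev_l <- integer(cap); ev_r <- integer(cap)
  n_ev <- 0L
  t <- 0
  repeat {
    total <- sum(rates)
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t > t_end || n_ev >= max_events) break
    i <- sample.int(n, 1, prob = rates)
    n_ev <- n_ev + 1L
    if (n_ev > cap) {
      cap <- cap * 2L
      length(ev_time) <- cap; length(ev_site) <- cap
      length(ev_type) <- cap; length(ev_l) <- cap; length(ev_r) <- cap
    }
    ev_time[n_ev] <- t
    ev_site[n_ev] <- i
    ev_type[n_ev] <- if (state[i] == 0L) 1L else -1L
    ev_l[n_ev] <- if (i > 1) state[i - 1] else 0L
    ev_r[n_ev] <- if (i < n) state[i + 1] else 0L
    state[i] <- 1L - state[i]
    for (j in intersect(c(i - 1L, i, i + 1L), seq_len(n)))
      rates[j] <- site_rate(j)
  }
  events <- data.frame(time = ev_time[seq_len(n_ev)],
                       site = ev_site[seq_len(n_ev)],
                       type = ev_type[seq_len(n_ev)],
                       nb_left = ev_l[seq_len(n_ev)],
                       nb_right = ev_r[seq_len(n_ev)])
  structure(list(state = state, events = events, t_end = t_end,
                 lattice = lattice),
            class = "binding_trajectory")
}

#' Time-averaged coverage of a binding trajectory
#'
#' Time-weighted mean occupied fraction over `[from, t_end]`, with an
#' optional batch-means standard error (batches of equal duration; a
#' conservative estimate in the presence of autocorrelation).
#'
#' @param traj A `binding_trajectory`.
#' @param from Start of the averaging window, s (default: second half).
#' @param n_batches Number of batches for the standard error.
#' @return List with `coverage`, `se` and `n_batches`.
#' @export
trajectory_coverage <- function(traj, from = traj$t_end / 2,
                                n_batches = 20) {
  stopifnot(inherits(traj, "binding_trajectory"))
  n <- traj$lattice$n_sites
  ev <- traj$events
  # reconstruct occupancy count over time
  state <- traj$lattice$state
  occ0 <- sum(state)
  times <- c(0, ev$time, traj$t_end)
  occ <- occ0 + c(0, cumsum(ev$type))
  # piecewise-constant occ between times[k] and times[k+1]
  edges <- seq(from, traj$t_end, length.out = n_batches + 1)
  means <- numeric(n_batches)
  for (b in seq_len(n_batches)) {
    lo <- edges[b]; hi <- edges[b + 1]
    t0 <- pmax(times[-length(times)], lo)
    t1 <- pmin(times[-1], hi)
    dt <- pmax(t1 - t0, 0)
    means[b] <- sum(occ * dt) / (hi - lo)
  }
  cov <- mean(means) / n
  se <- stats::sd(means / n) / sqrt(n_batches)
  list(coverage = cov, se = se, n_batches = n_batches)
}

#' Exact equilibrium coverage of the 1D cooperative lattice
#'
#' Equilibrium occupied fraction of the nearest-neighbour lattice gas the
#' simulator embodies: each bound site carries weight `C / Kd_intrinsic`
#' and each bound nearest-neighbour pair weight `omega^2` (`omega` being
#' the kinetic cooperativity factor of [binding_lattice()], which both
#' accelerates association and slows dissociation). Computed either by
#' brute-force enumeration of all `2^n` configurations (small `n`) or by a
#' transfer-matrix recursion with running normalisation (any `n`); the two
#' agree to machine precision.
#'
#' @param n_sites Number of sites.
#' @param C Ligand concentration, uM.
#' @param Kd_intrinsic Intrinsic (single-site) dissociation constant, uM.
#' @param omega Kinetic cooperativity factor.
#' @param mode `"transfer"` (default) or `"brute"` (requires
#'   `n_sites <= 20`).
#' @param ring Logical; periodic boundary instead of the default free-ended
#'   chain.
#' @return Equilibrium coverage fraction in `[0, 1]`.
#' @export
equilibrium_coverage_exact <- function(n_sites, C, Kd_intrinsic, omega,
                                       mode = c("transfer", "brute"),
                                       ring = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_sites >= 1, C >= 0, Kd_intrinsic > 0, omega >= 0)
  x <- C / Kd_intrinsic
  w <- omega^2
  if (mode == "brute") {
    if (n_sites > 20) stop("brute-force mode requires n_sites <= 20")
    num <- 0; den <- 0
    for (cfg in 0:(2^n_sites - 1)) {
      s <- as.integer(intToBits(cfg))[seq_len(n_sites)]
      pairs <- if (n_sites > 1) sum(s[-1] * s[-n_sites]) else 0
      if (ring && n_sites > 2) pairs <- pairs + s[1] * s[n_sites]
      wt <- x^sum(s) * w^pairs
      num <- num + wt * sum(s)
      den <- den + wt
    }
    return(num / den / n_sites)
  }
  if (ring) {
    # fix the first site's state and close the ring explicitly
    total_num <- 0; total_den <- 0
    for (s1 in 0:1) {
      Z <- c(0, 0); N <- c(0, 0)
      Z[s1 + 1] <- x^s1
      N[s1 + 1] <- x^s1 * s1
      if (n_sites == 1) {
        total_num <- total_num + sum(N); total_den <- total_den + sum(Z)
        next
      }
      for (i in 2:n_sites) {
        Z2 <- c(0, 0); N2 <- c(0, 0)
        for (sp in 0:1) for (sn in 0:1) {
          wt <- x^sn * w^(sp * sn)
          Z2[sn + 1] <- Z2[sn + 1] + Z[sp + 1] * wt
          N2[sn + 1] <- N2[sn + 1] + (N[sp + 1] + Z[sp + 1] * sn) * wt
        }
        sc <- sum(Z2)
        Z <- Z2 / sc; N <- N2 / sc
        if (i == 2) { logZ <- log(sc) } else { logZ <- logZ + log(sc) }
      }
      # close ring: weight w^(s_n * s_1)
      for (sn in 0:1) {
        wt <- w^(sn * s1) * exp(logZ)
        total_num <- total_num + N[sn + 1] * wt
        total_den <- total_den + Z[sn + 1] * wt
      }
    }
    return(total_num / total_den / n_sites)
  }
  Z <- c(1, x); N <- c(0, x)
  if (n_sites > 1) {
    for (i in 2:n_sites) {
      Z2 <- c(0, 0); N2 <- c(0, 0)
      for (sp in 0:1) for (sn in 0:1) {
        wt <- x^sn * w^(sp * sn)
        Z2[sn + 1] <- Z2[sn + 1] + Z[sp + 1] * wt
        N2[sn + 1] <- N2[sn + 1] + (N[sp + 1] + Z[sp + 1] * sn) * wt
      }
      sc <- sum(Z2)
      Z <- Z2 / sc
      N <- N2 / sc
    }
  }
  sum(N) / sum(Z) / n_sites
}

#' Saturation binding curve from the lattice model
#'
#' Coverage (fraction of lattice sites bound) across a set of ligand
#' concentrations, from either the exact transfer-matrix equilibrium or the
#' stochastic simulator's equilibrium window.
#'
#' @param concentrations Positive concentrations, uM.
#' @param n_sites,k_on,k_off,omega Lattice parameters; see
#'   [binding_lattice()].
#' @param mode `"exact"` or `"simulate"`.
#' @param t_end Simulated time per concentration (simulate mode).
#' @param seed RNG seed (simulate mode).
#' @param replicate Replicate id stored with the curve.
#' @return A data frame of class `binding_curve_data`: `concentration`,
#'   `fraction_bound`, `replicate`.
#' @export
binding_curve <- function(concentrations, n_sites = 100, k_on = 1,
                          k_off = 1, omega = 1,
                          mode = c("exact", "simulate"), t_end = 200,
                          seed = 1, replicate = 1L) {
  mode <- match.arg(mode)
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  kd <- k_off / k_on
  frac <- vapply(seq_along(concentrations), function(i) {
    C <- concentrations[i]
    if (mode == "exact") {
      equilibrium_coverage_exact(n_sites, C, kd, omega)
    } else {
      # start near the expected coverage to shorten burn-in
      cov0 <- equilibrium_coverage_exact(n_sites, C, kd, omega)
      set.seed(seed + 7 * i)
      st <- as.integer(stats::runif(n_sites) < cov0)
      lat <- binding_lattice(n_sites, k_on, k_off, omega, C, state = st)
      traj <- simulate_lattice_binding(lat, t_end, seed = seed + 13 * i)
      trajectory_coverage(traj)$coverage
    }
  }, numeric(1))
  out <- data.frame(concentration = concentrations, fraction_bound = frac,
                    replicate = as.integer(replicate))
  class(out) <- c("binding_curve_data", class(out))
  out
}

#' Fit the Hill equation to a saturation curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, multistart) of
#' `f(C) = f_max * C^h / (Kd^h + C^h)` to fraction-bound data. `f_max` is
#' fitted by default because measured fraction-bound commonly saturates
#' below 1; it can be pinned to 1.
#'
#' @param data A data frame with columns `concentration` and
#'   `fraction_bound` (replicates as repeated concentrations), e.g. a
#'   `binding_curve_data`.
#' @param fix_fmax Logical; fix the plateau at 1 instead of fitting it.
#' @return An object of class `hill_fit`: list with `Kd` (uM), `h`,
#'   `f_max`, `residual_norm`, standard errors `se` and the underlying
#'   `nls` fit object.
#' @export
fit_hill <- function(data, fix_fmax = FALSE) {
  stopifnot(all(c("concentration", "fraction_bound") %in% names(data)))
  C <- data$concentration
  f <- data$fraction_bound
  if (length(unique(C)) < 4)
    stop("need at least 4 distinct concentrations")
  if (any(C <= 0)) stop("concentrations must be positive")
  kd_starts <- unique(stats::quantile(C, c(0.25, 0.5, 0.75)))
  h_starts <- c(0.7, 1, 2, 4)
  best <- NULL
  for (kd0 in kd_starts) for (h0 in h_starts) {
    fit <- if (fix_fmax) {
      try(minpack.lm::nlsLM(
        f ~ C^h / (Kd^h + C^h),
        start = list(Kd = kd0, h = h0),
        lower = c(Kd = 1e-9, h = 1e-3),
        upper = c(Kd = Inf, h = 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(
        f ~ fmax * C^h / (Kd^h + C^h),
        start = list(Kd = kd0, h = h0, fmax = max(f)),
        lower = c(Kd = 1e-9, h = 1e-3, fmax = 1e-6),
        upper = c(Kd = Inf, h = 100, fmax = 1.5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("Hill fit failed to converge from any start")
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(Kd = unname(cf["Kd"]), h = unname(cf["h"]),
                 f_max = if (fix_fmax) 1 else unname(cf["fmax"]),
                 residual_norm = sqrt(best$rss), se = se,
                 fit = best$fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> Kd = %.4g uM, h = %.3g, f_max = %.3g (|r| = %.3g)\n",
              x$Kd, x$h, x$f_max, x$residual_norm))
  invisible(x)
}

#' Hill-equation fraction bound
#'
#' @param C Concentration(s), uM.
#' @param Kd Half-saturation constant, uM.
#' @param h Hill coefficient.
#' @param f_max Plateau fraction.
#' @return Fraction bound.
#' @export
hill_curve <- function(C, Kd, h, f_max = 1) {
  f_max * C^h / (Kd^h + C^h)
}

#' Patch statistics of a lattice state or trajectory
#'
#' Run-length encoding of occupied stretches, and, for a trajectory,
#' per-end elongation counts audited from the event log: each association
#' event is classified as a nucleation (no bound neighbour), a left- or
#' right-end patch elongation (one bound neighbour), or a gap fill / merge
#' (two bound neighbours). Patch identities are tracked through
#' elongations, merges and splits to report the fraction of patches that
#' grew at both ends — the signature of bidirectional patch elongation.
#'
#' @param x A binary occupancy vector or a `binding_trajectory`.
#' @return For a state vector: list with `patch_sizes`. For a trajectory:
#'   additionally `growth_counts` (named: nucleation, left, right, fill)
#'   and `both_end_fraction`.
#' @export
patch_statistics <- function(x) {
  state_sizes <- function(state) {
    r <- rle(state)
    r$lengths[r$values == 1L]
  }
  if (!inherits(x, "binding_trajectory")) {
    state <- as.integer(x)
    if (length(state) == 0) stop("empty state")
    return(list(patch_sizes = state_sizes(state)))
  }
  n <- x$lattice$n_sites
  state <- x$lattice$state
  pid <- integer(n)
  next_id <- 0L
  grew_left <- logical(0)
  grew_right <- logical(0)
  counts <- c(nucleation = 0L, left = 0L, right = 0L, fill = 0L)
  ev <- x$events
  for (k in seq_len(nrow(ev))) {
    i <- ev$site[k]
    if (ev$type[k] == 1L) {
      L <- i > 1 && state[i - 1] == 1L
      R <- i < n && state[i + 1] == 1L
      if (!L && !R) {
        next_id <- next_id + 1L
        pid[i] <- next_id
        grew_left[next_id] <- FALSE
        grew_right[next_id] <- FALSE
        counts["nucleation"] <- counts["nucleation"] + 1L
      } else if (L && !R) {
        pid[i] <- pid[i - 1]
        grew_right[pid[i]] <- TRUE
        counts["right"] <- counts["right"] + 1L
      } else if (!L && R) {
        pid[i] <- pid[i + 1]
        grew_left[pid[i]] <- TRUE
        counts["left"] <- counts["left"] + 1L
      } else {
        keep <- pid[i - 1]; other <- pid[i + 1]
        pid[i] <- keep
        pid[pid == other] <- keep
        grew_left[keep] <- grew_left[keep] || grew_left[other]
        grew_right[keep] <- grew_right[keep] || grew_right[other]
        counts["fill"] <- counts["fill"] + 1L
      }
      state[i] <- 1L
    } else {
      L <- i > 1 && state[i - 1] == 1L
      R <- i < n && state[i + 1] == 1L
      if (L && R) {
        # interior removal splits the patch; the right fragment keeps the
        # parent's growth history
        next_id <- next_id + 1L
        old <- pid[i]
        j <- i + 1L
        while (j <= n && state[j] == 1L && pid[j] == old) {
          pid[j] <- next_id
          j <- j + 1L
        }
        grew_left[next_id] <- grew_left[old]
        grew_right[next_id] <- grew_right[old]
      }
      pid[i] <- 0L
      state[i] <- 0L
    }
  }
  live <- unique(pid[pid > 0L])
  both <- if (length(live) == 0) NA_real_ else
    mean(grew_left[live] & grew_right[live])
  list(patch_sizes = state_sizes(state), growth_counts = counts,
       both_end_fraction = both)
}
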