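test_that("exact coverage: brute force, transfer matrix and limits agree", {
  # brute force over all 256 states equals the transfer matrix
  for (om in c(0.5, 1, 5)) {
    expect_equal(equilibrium_coverage_exact(8, 1, 1, om, mode = "brute"),
                 equilibrium_coverage_exact(8, 1, 1, om),
                 tolerance = 1e-12)
  }
  # omega = 1: independent sites, exact Langmuir at any concentration
  for (C in c(0.2, 1, 3)) {
    expect_equal(equilibrium_coverage_exact(8, C, 1, 1), C / (C + 1),
                 tolerance = 1e-12)
    expect_equal(equilibrium_coverage_exact(200, C, 1, 1), C / (C + 1),
                 tolerance = 1e-12)
  }
  # single site: half saturation at C = Kd regardless of omega
  expect_equal(equilibrium_coverage_exact(1, 0.94, 0.94, 7), 0.5)
  # ring closure agrees between brute force and transfer matrix
  expect_equal(equilibrium_coverage_exact(8, 1, 1, 3, mode = "brute",
                                          ring = TRUE),
               equilibrium_coverage_exact(8, 1, 1, 3, ring = TRUE),
               tolerance = 1e-12)
})

test_that("exact coverage is monotone nondecreasing in concentration", {
  Cs <- exp(seq(log(0.01), log(50), length.out = 25))
  for (om in c(1, 2, 5, 15)) {
    cov <- vapply(Cs, function(C) equilibrium_coverage_exact(60, C, 2, om),
                  numeric(1))
    expect_true(all(diff(cov) > -1e-12))
  }
})

test_that("Gillespie equilibrium matches the exact oracle", {
  # single site at C = Kd: Langmuir half saturation
  lat <- binding_lattice(1, 1, 1, 1, 1)
  tr <- simulate_lattice_binding(lat, 4000, seed = 3)
  cv <- trajectory_coverage(tr)
  expect_lt(abs(cv$coverage - 0.5), 3 * cv$se)

  # cooperative lattice against the transfer matrix
  for (om in c(2, 5)) {
    C <- 2 / om^2
    ex <- equilibrium_coverage_exact(60, C, 1, om)
    set.seed(20 + om)
    st <- as.integer(runif(60) < ex)
    lat <- binding_lattice(60, 1, 1, om, C, state = st)
    tr <- simulate_lattice_binding(lat, 300, seed = 40 + om)
    cv <- trajectory_coverage(tr, n_batches = 10)
    expect_lt(abs(cv$coverage - ex), 3 * cv$se)
  }
})

test_that("cooperativity produces longer contiguous patches", {
  set.seed(9)
  matched <- function(om) {
    # concentration chosen so both runs sit near 40% coverage
    f <- function(C) equilibrium_coverage_exact(120, C, 1, om) - 0.4
    C <- uniroot(f, c(1e-6, 100))$root
    st <- as.integer(runif(120) < 0.4)
    tr <- simulate_lattice_binding(
      binding_lattice(120, 1, 1, om, C, state = st), 150, seed = 17)
    mean(patch_statistics(tr$state)$patch_sizes)
  }
  expect_gt(matched(10), matched(1))
})

test_that("binding curves follow the requested mode", {
  C <- exp(seq(log(0.1), log(4), length.out = 6))
  bc <- binding_curve(C, n_sites = 80, omega = 1, mode = "exact")
  expect_equal(bc$fraction_bound, C / (C + 1), tolerance = 1e-12)

  bc5 <- binding_curve(C, n_sites = 60, k_off = 2, omega = 2,
                       mode = "simulate", t_end = 150, seed = 8)
  ex5 <- binding_curve(C, n_sites = 60, k_off = 2, omega = 2,
                       mode = "exact")
  expect_lt(max(abs(bc5$fraction_bound - ex5$fraction_bound)), 0.05)
  expect_error(binding_curve(c(-1, 2)), "positive")
})

test_that("Hill fits recover generating parameters", {
  C <- exp(seq(log(0.1), log(4), length.out = 8))
  # noise-free curve at the reported saturation parameters
  d <- data.frame(concentration = C,
                  fraction_bound = hill_curve(C, 0.94, 2.7))
  ft <- fit_hill(d)
  expect_lt(abs(ft$Kd - 0.94), 1e-6)
  expect_lt(abs(ft$h - 2.7), 1e-6)
  expect_lt(abs(ft$f_max - 1), 1e-6)

  # non-cooperative limit
  ft1 <- fit_hill(data.frame(concentration = C,
                             fraction_bound = hill_curve(C, 1, 1)))
  expect_lt(abs(ft1$h - 1), 1e-6)

  # pinned plateau
  ftp <- fit_hill(d, fix_fmax = TRUE)
  expect_lt(abs(ftp$Kd - 0.94), 1e-6)
  expect_equal(ftp$f_max, 1)

  # multiplicative noise, three replicates, fixed seed
  set.seed(5)
  noisy <- do.call(rbind, lapply(1:3, function(r) {
    data.frame(concentration = C,
               fraction_bound = hill_curve(C, 0.94, 2.7) *
                 (1 + rnorm(8, sd = 0.05)))
  }))
  ftn <- fit_hill(noisy)
  expect_lt(abs(ftn$Kd / 0.94 - 1), 0.10)
  expect_lt(abs(ftn$h / 2.7 - 1), 0.15)

  expect_error(fit_hill(data.frame(concentration = C[1:3],
                                   fraction_bound = c(0.1, 0.5, 0.9))),
               "4 distinct")
})

test_that("fitted Hill coefficient grows with cooperativity", {
  C <- exp(seq(log(0.05), log(20), length.out = 12))
  hs <- vapply(c(1, 2, 5, 15), function(om) {
    kd_int <- om^2        # keeps the half-saturation near 1 uM
    cov <- vapply(C, function(cc)
      equilibrium_coverage_exact(150, cc, kd_int, om), numeric(1))
    fit_hill(data.frame(concentration = C, fraction_bound = cov))$h
  }, numeric(1))
  expect_lt(abs(hs[1] - 1), 0.05)
  expect_true(all(diff(hs) > 0))
})

test_that("patch statistics audit bidirectional elongation", {
  expect_equal(patch_statistics(c(0, 1, 1, 0, 1, 1, 1))$patch_sizes,
               c(2, 3))
  expect_length(patch_statistics(rep(0, 10))$patch_sizes, 0)
  expect_error(patch_statistics(integer(0)), "empty")

  set.seed(2)
  st <- integer(200); st[100] <- 1L   # one seed patch mid-lattice
  lat <- binding_lattice(200, 1, 1, 10, 0.05, state = st)
  tr <- simulate_lattice_binding(lat, 40, seed = 21)
  ps <- patch_statistics(tr)
  expect_gt(ps$growth_counts[["left"]], 0)
  expect_gt(ps$growth_counts[["right"]], 0)
  expect_gt(ps$both_end_fraction, 0)
})
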