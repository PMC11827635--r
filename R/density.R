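#' Density grid
#'
#' A 3D scalar voxel grid with (possibly anisotropic) voxel size and a
#' world-space origin, the in-memory form of an MRC2014 map. Array axes
#' follow the MRC fast-to-slow convention: `values[ix, iy, iz]`; the world
#' position of voxel `(ix, iy, iz)` (1-based) is
#' `origin + (ix - 1, iy - 1, iz - 1) * voxel_size`.
#'
#' @param values 3D numeric array of finite values.
#' @param voxel_size Voxel edge length(s), Angstrom; scalar or length-3.
#' @param origin World coordinates of the first voxel centre, Angstrom.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(values, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0),
            length(origin) == 3, all(is.finite(values)))
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<density_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g A/voxel\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

voxel_volume <- function(grid) prod(grid$voxel_size)

# World coordinates of decorated-site anchors: each bound complex sits a
# fixed distance from its anchoring subunit's centroid along the subunit's
# body-frame x axis, which the generators keep pointing radially outward
# (build_filament orients subunit frames with the screw operation and
# bend_filament transports them, so this stays radial on curved models).
site_anchor_positions <- function(model, site_offset) {
  cents <- centroids(model)
  quats <- subunit_quats(model)
  t(vapply(seq_len(nrow(cents)), function(i) {
    cents[i, ] + site_offset * quat_rotate_vec(quats[i, ], c(1, 0, 0))
  }, numeric(3)))
}

#' Render a synthetic decorated-filament density map
#'
#' Deterministic forward model standing in for reconstructed frame volumes:
#' each actin subunit contributes an isotropic Gaussian blob of amplitude 1
#' at its centroid, and each decorated site a blob of amplitude equal to
#' its occupancy at the site anchor (centroid offset radially outward by
#' `site_offset`). A blob of amplitude `A` integrates to
#' `A * (2 * pi * blob_sigma^2)^{3/2}`.
#'
#' @param filament A [filament_model()].
#' @param site_occupancies Numeric vector, one occupancy in `[0, 1]` per
#'   subunit (0 = bare site).
#' @param voxel_size Voxel edge, Angstrom.
#' @param blob_sigma Gaussian blob sigma, Angstrom.
#' @param site_offset Radial offset of the bound complex from its subunit
#'   centroid, Angstrom.
#' @param pad Padding around the model bounding box, Angstrom.
#' @return A [density_grid()].
#' @export
render_density <- function(filament, site_occupancies, voxel_size = 4,
                           blob_sigma = 5, site_offset = 25,
                           pad = 4 * blob_sigma) {
  stopifnot(inherits(filament, "filament_model"), voxel_size > 0,
            blob_sigma > 0)
  n <- n_subunits(filament)
  stopifnot(length(site_occupancies) == n)
  if (any(site_occupancies < 0 | site_occupancies > 1))
    stop("occupancies must lie in [0, 1]")
  cents <- centroids(filament)
  anchors <- site_anchor_positions(filament, site_offset)
  pts <- rbind(cents, anchors)
  amps <- c(rep(1, n), site_occupancies)
  keep <- amps > 0
  pts <- pts[keep, , drop = FALSE]
  amps <- amps[keep]
  lo <- apply(rbind(cents, anchors), 2, min) - pad
  hi <- apply(rbind(cents, anchors), 2, max) + pad
  dims <- pmax(ceiling((hi - lo) / voxel_size) + 1, 2)
  vals <- array(0, dim = dims)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 1) * voxel_size)
  cut <- 4 * blob_sigma
  for (p in seq_len(nrow(pts))) {
    rng <- lapply(1:3, function(k) {
      which(abs(ax[[k]] - pts[p, k]) <= cut)
    })
    if (any(lengths(rng) == 0)) next
    gx <- exp(-(ax[[1]][rng[[1]]] - pts[p, 1])^2 / (2 * blob_sigma^2))
    gy <- exp(-(ax[[2]][rng[[2]]] - pts[p, 2])^2 / (2 * blob_sigma^2))
    gz <- exp(-(ax[[3]][rng[[3]]] - pts[p, 3])^2 / (2 * blob_sigma^2))
    vals[rng[[1]], rng[[2]], rng[[3]]] <-
      vals[rng[[1]], rng[[2]], rng[[3]]] +
      amps[p] * (gx %o% gy %o% gz)
  }
  density_grid(vals, voxel_size, origin = lo)
}

#' Split a density map between filament and bound complexes
#'
#' Partitions foreground density among reference points — actin subunit
#' centroids and the anchors of candidate bound-complex sites — by
#' nearest-reference (Voronoi) assignment within a cutoff radius; voxels
#' farther than `radius` from every reference are background. The output
#' grids partition the foreground exactly: no voxel is counted twice.
#'
#' @param grid A [density_grid()].
#' @param filament The [filament_model()] the map was rendered from (or
#'   fitted to).
#' @param complex_anchors Protomer indices (0-based) of candidate
#'   bound-complex sites.
#' @param radius Assignment cutoff, Angstrom.
#' @param site_offset Radial anchor offset, Angstrom (must match the
#'   geometry used to place/fit the complexes).
#' @return List with `filament` (a [density_grid()] of filament-assigned
#'   density) and `sites` (named list of per-site [density_grid()]s, names
#'   = protomer indices).
#' @export
split_density <- function(grid, filament, complex_anchors, radius = 15,
                          site_offset = 25) {
  stopifnot(inherits(grid, "density_grid"),
            inherits(filament, "filament_model"), radius > 0)
  cents <- centroids(filament)
  nref <- nrow(cents)
  if (length(complex_anchors) == 0) {
    warning("no complex anchors given; returning filament density only",
            call. = FALSE)
    anchors <- matrix(numeric(0), 0, 3)
  } else {
    all_anchors <- site_anchor_positions(filament, site_offset)
    anchors <- all_anchors[match(as.integer(complex_anchors),
                                 filament$subunits$index), , drop = FALSE]
    if (anyNA(anchors)) stop("complex_anchors outside the model")
  }
  refs <- rbind(cents, anchors)
  dims <- dim(grid$values)
  ax <- lapply(1:3, function(k) {
    grid$origin[k] + (seq_len(dims[k]) - 1) * grid$voxel_size[k]
  })
  best_d2 <- array(Inf, dims)
  best_id <- array(0L, dims)
  r2 <- radius^2
  for (p in seq_len(nrow(refs))) {
    rng <- lapply(1:3, function(k) which(abs(ax[[k]] - refs[p, k]) <= radius))
    if (any(lengths(rng) == 0)) next
    dx2 <- (ax[[1]][rng[[1]]] - refs[p, 1])^2
    dy2 <- (ax[[2]][rng[[2]]] - refs[p, 2])^2
    dz2 <- (ax[[3]][rng[[3]]] - refs[p, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sub_d <- best_d2[rng[[1]], rng[[2]], rng[[3]]]
    upd <- d2 <= r2 & d2 < sub_d
    sub_d[upd] <- d2[upd]
    best_d2[rng[[1]], rng[[2]], rng[[3]]] <- sub_d
    sub_i <- best_id[rng[[1]], rng[[2]], rng[[3]]]
    sub_i[upd] <- p
    best_id[rng[[1]], rng[[2]], rng[[3]]] <- sub_i
  }
  fil_vals <- grid$values * (best_id >= 1 & best_id <= nref)
  fil_grid <- density_grid(fil_vals, grid$voxel_size, grid$origin)
  sites <- list()
  if (nrow(anchors) > 0) {
    for (j in seq_len(nrow(anchors))) {
      sv <- grid$values * (best_id == nref + j)
      sites[[as.character(complex_anchors[j])]] <-
        density_grid(sv, grid$voxel_size, grid$origin)
    }
  }
  list(filament = fil_grid, sites = sites)
}

#' Integrated per-site intensities
#'
#' Sums each segmented bound-complex subvolume, scaled by the voxel volume.
#'
#' @param site_grids Named list of per-site [density_grid()]s (names =
#'   protomer indices), as returned in `split_density()$sites`.
#' @return Data frame of class `site_occupancy`: `index`, `strand`,
#'   `integrated_intensity`.
#' @export
site_intensities <- function(site_grids) {
  if (length(site_grids) == 0) stop("empty site list")
  idx <- as.integer(names(site_grids))
  ii <- vapply(site_grids, function(g) sum(g$values) * voxel_volume(g),
               numeric(1))
  out <- data.frame(index = idx, strand = idx %% 2L,
                    integrated_intensity = unname(ii))
  class(out) <- c("site_occupancy", class(out))
  out
}

#' Normalise site intensities to the maximal site
#'
#' Divides every integrated intensity by the largest one, so the maximal
#' site reads exactly 1. Because a fully occupied bound complex has
#' approximately the same rendered intensity as an actin subunit, the
#' normalised intensity serves as a per-site occupancy proxy.
#'
#' @param sites A `site_occupancy` data frame.
#' @param reference Optional external normalisation constant (e.g. the
#'   series-wide maximum); defaults to the in-table maximum.
#' @return The input with a `normalized_intensity` column added.
#' @export
normalize_sites <- function(sites, reference = NULL) {
  stopifnot(is.data.frame(sites), "integrated_intensity" %in% names(sites))
  m <- if (is.null(reference)) max(sites$integrated_intensity) else reference
  if (m <= 0) {
    warning("all site intensities are zero; normalised values set to 0",
            call. = FALSE)
    sites$normalized_intensity <- 0
  } else {
    sites$normalized_intensity <- sites$integrated_intensity / m
  }
  sites
}

#' Per-strand mean occupancy across a frame series
#'
#' For each frame of a variability series, splits the frame's density map
#' around its filament model, integrates per-site intensities and reports
#' the mean normalised intensity per strand. Normalisation defaults to the
#' series-wide maximal site so frames are mutually comparable; per-frame
#' normalisation is available.
#'
#' @param frames List of frames, each a list with elements `model`
#'   (a [filament_model()]) and `grid` (a [density_grid()]).
#' @param radius,site_offset Passed to [split_density()].
#' @param normalize `"per-series"` (default) or `"per-frame"`.
#' @return Data frame of class `occupancy_trajectory`: `frame` (1-based
#'   order along the series), `strand`, `mean_normalized_intensity`.
#' @export
strand_occupancy_trajectory <- function(frames, radius = 15,
                                        site_offset = 25,
                                        normalize = c("per-series",
                                                      "per-frame")) {
  normalize <- match.arg(normalize)
  stopifnot(length(frames) >= 1)
  per_frame <- lapply(frames, function(fr) {
    sp <- split_density(fr$grid, fr$model,
                        complex_anchors = fr$model$subunits$index,
                        radius = radius, site_offset = site_offset)
    site_intensities(sp$sites)
  })
  global_max <- max(vapply(per_frame,
                           function(s) max(s$integrated_intensity),
                           numeric(1)))
  rows <- lapply(seq_along(per_frame), function(f) {
    s <- per_frame[[f]]
    s <- normalize_sites(s, reference = if (normalize == "per-series")
      global_max else NULL)
    do.call(rbind, lapply(0:1, function(st) {
      d <- s[s$strand == st, , drop = FALSE]
      if (nrow(d) == 0) {
        message(sprintf("frame %d: no sites on strand %d", f, st))
        return(NULL)
      }
      data.frame(frame = f, strand = st,
                 mean_normalized_intensity = mean(d$normalized_intensity))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("occupancy_trajectory", class(out))
  out
}

#' Pair local lattice geometry with site occupancy
#'
#' Joins a lattice profile (twist or rise per protomer index) with
#' normalised site intensities on the protomer index and reports the
#' association between geometry and occupancy as both a rank (Spearman)
#' and a linear (Pearson) correlation coefficient, together with the
#' plotted pair table.
#'
#' @param profile A `lattice_profile` (typically strand-level, from
#'   [strand_profile()]).
#' @param sites A `site_occupancy` data frame with a
#'   `normalized_intensity` column (see [normalize_sites()]).
#' @param geometry `"twist"` or `"rise"`.
#' @return List with `table` (data frame: `index`, `strand`, geometry
#'   value, `normalized_intensity`), `spearman`, `pearson`. Correlations
#'   are `NA` (with a message) when either variable has no variance.
#' @export
correlate_geometry_occupancy <- function(profile, sites,
                                         geometry = c("twist", "rise")) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(profile, "lattice_profile"),
            "normalized_intensity" %in% names(sites))
  col <- if (geometry == "twist") "twist_deg" else "rise_ang"
  tab <- merge(profile$entries[, c("index", "strand", col)],
               sites[, c("index", "normalized_intensity")],
               by = "index")
  if (nrow(tab) == 0) stop("no overlapping protomer indices")
  x <- tab[[col]]
  y <- tab$normalized_intensity
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("geometry or occupancy has zero variance; ",
            "correlation not applicable")
    sp <- NA_real_; pe <- NA_real_
  } else {
    sp <- stats::cor(x, y, method = "spearman")
    pe <- stats::cor(x, y, method = "pearson")
  }
  list(table = tab, spearman = sp, pearson = pe)
}
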