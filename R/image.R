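#' Two-channel image pair
#'
#' A registered two-channel fluorescence image: channel A carries the
#' filament (F-actin) signal and channel B the ligand (bound complex or
#' junction marker) signal. Images are numeric matrices indexed
#' `[row, col]`; `pixel_size` converts pixels to micrometres.
#'
#' @param channel_a,channel_b Nonnegative numeric matrices of equal shape.
#' @param pixel_size Pixel edge, um.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(channel_a, channel_b, pixel_size = 0.1) {
  stopifnot(is.matrix(channel_a), is.matrix(channel_b),
            all(dim(channel_a) == dim(channel_b)),
            all(is.finite(channel_a)), all(is.finite(channel_b)),
            all(channel_a >= 0), all(channel_b >= 0), pixel_size > 0)
  structure(list(channel_a = channel_a, channel_b = channel_b,
                 pixel_size = pixel_size),
            class = "image_pair")
}

# Non-flat (ball structuring element) grayscale erosion/dilation. `heights`
# is the ball's height profile at each (dx, dy) offset; erosion subtracts
# it, dilation adds it.
ball_morph <- function(img, offsets, heights, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(img); nc <- ncol(img)
  pad_val <- if (op == "erode") Inf else -Inf
  out <- matrix(pad_val, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    dy <- offsets[k, 1]; dx <- offsets[k, 2]
    src_r <- seq_len(nr) + dy
    src_c <- seq_len(nc) + dx
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    shifted <- matrix(pad_val, nr, nc)
    shifted[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
    cand <- if (op == "erode") shifted - heights[k] else shifted + heights[k]
    out <- if (op == "erode") pmin(out, cand) else pmax(out, cand)
  }
  out
}

ball_offsets <- function(radius, grid_step = 1) {
  r_px <- floor(radius / grid_step)
  d <- expand.grid(dy = -r_px:r_px, dx = -r_px:r_px)
  dist2 <- (d$dy * grid_step)^2 + (d$dx * grid_step)^2
  keep <- dist2 <= radius^2
  list(offsets = as.matrix(d[keep, , drop = FALSE]),
       heights = sqrt(radius^2 - dist2[keep]) - radius)
}

# Block-wise reduction used by the large-radius rolling-ball path.
block_reduce <- function(img, s, fun) {
  nr <- ceiling(nrow(img) / s); nc <- ceiling(ncol(img) / s)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rows <- ((i - 1) * s + 1):min(i * s, nrow(img))
    cols <- ((j - 1) * s + 1):min(j * s, ncol(img))
    out[i, j] <- fun(img[rows, cols])
  }
  out
}

bilinear_enlarge <- function(small, nr, nc, s) {
  # sample positions of small-grid cell centres in big-grid coordinates
  src_r <- ((seq_len(nrow(small)) - 1) * s + (s + 1) / 2)
  src_c <- ((seq_len(ncol(small)) - 1) * s + (s + 1) / 2)
  interp1 <- function(pos, src, vals_idx_len) {
    # indices and weights for linear interpolation with edge clamping
    j <- findInterval(pos, src, all.inside = TRUE)
    j <- pmin(pmax(j, 1), length(src) - 1)
    w <- (pos - src[j]) / (src[j + 1] - src[j])
    w <- pmin(pmax(w, 0), 1)
    list(j = j, w = w)
  }
  ri <- interp1(seq_len(nr), src_r)
  ci <- interp1(seq_len(nc), src_c)
  a <- small[ri$j, ci$j, drop = FALSE]
  b <- small[ri$j + 1, ci$j, drop = FALSE]
  cc <- small[ri$j, ci$j + 1, drop = FALSE]
  d <- small[ri$j + 1, ci$j + 1, drop = FALSE]
  wr <- matrix(ri$w, nr, nc)
  wc <- matrix(ci$w, nr, nc, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + cc * (1 - wr) * wc +
    d * wr * wc
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image with
#' a ball structuring element of the given radius (the ball "rolls" under
#' the intensity surface) and subtracts it, clipping at zero. Offsets and
#' flat backgrounds are removed exactly; features smaller than the ball are
#' preserved. For radii above `exact_radius` the background is computed on
#' a block-minimum shrunken image and re-enlarged by bilinear
#' interpolation, mirroring common practice for large radii.
#'
#' @param image Numeric matrix.
#' @param radius_px Ball radius, pixels (default 100).
#' @param exact_radius Largest radius processed without downsampling.
#' @return The background-subtracted image (same shape, >= 0).
#' @export
subtract_background_rolling_ball <- function(image, radius_px = 100,
                                             exact_radius = 24) {
  stopifnot(is.matrix(image), radius_px >= 1)
  if (radius_px >= max(dim(image))) {
    message("ball radius exceeds image size; subtracting the global minimum")
    return(image - min(image))
  }
  if (radius_px <= exact_radius) {
    ball <- ball_offsets(radius_px)
    bg <- ball_morph(ball_morph(image, ball$offsets, ball$heights, "erode"),
                     ball$offsets, ball$heights, "dilate")
  } else {
    s <- ceiling(radius_px / exact_radius)
    small <- block_reduce(image, s, min)
    ball <- ball_offsets(radius_px, grid_step = s)
    bg_small <- ball_morph(
      ball_morph(small, ball$offsets, ball$heights, "erode"),
      ball$offsets, ball$heights, "dilate")
    bg <- bilinear_enlarge(bg_small, nrow(image), ncol(image), s)
  }
  bg <- pmin(bg, image)
  pmax(image - bg, 0)
}

#' Yen threshold of an image
#'
#' Computes the threshold maximising Yen's maximum-correlation criterion
#' over the image histogram. With foreground/background probability masses
#' `P1(t)`, `P2(t)` and squared-probability sums `S1(t)`, `S2(t)` at
#' candidate threshold `t`, the criterion is
#' `log(P1 * P2 / (S1 * S2)) ... ` equivalently
#' `-log(S1 * S2) + 2 log(P1 * (1 - P1))`; the threshold is the histogram
#' bin centre maximising it, and the mask is `image > threshold`.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param nbins Number of histogram bins over the min-max intensity range.
#' @return List with `threshold` and logical `mask`.
#' @export
threshold_mask_yen <- function(image, nbins = 256) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image; returning an empty mask", call. = FALSE)
    return(list(threshold = rng[1],
                mask = matrix(FALSE, nrow(image), ncol(image))))
  }
  brk <- seq(rng[1], rng[2], length.out = nbins + 1)
  cnt <- tabulate(findInterval(image, brk, rightmost.closed = TRUE),
                  nbins = nbins)
  centers <- (brk[-1] + brk[-(nbins + 1)]) / 2
  p <- cnt / sum(cnt)
  P1 <- cumsum(p)
  S1 <- cumsum(p^2)
  S2 <- rev(cumsum(rev(p^2)))
  # candidate thresholds: after bin t (t = 1 .. nbins - 1)
  t <- seq_len(nbins - 1)
  crit <- -log(pmax(S1[t] * S2[t + 1], .Machine$double.xmin)) +
    2 * log(pmax(P1[t] * (1 - P1[t]), .Machine$double.xmin))
  thr <- centers[which.max(crit)]
  list(threshold = thr, mask = image > thr)
}

#' Fraction of the filament mask bound by ligand
#'
#' Area of the conjunction (AND) of the filament and ligand masks divided
#' by the filament mask area.
#'
#' @param actin_mask,ligand_mask Logical matrices of equal shape.
#' @return Fraction in `[0, 1]`.
#' @export
bound_fraction <- function(actin_mask, ligand_mask) {
  stopifnot(is.logical(actin_mask), is.logical(ligand_mask),
            all(dim(actin_mask) == dim(ligand_mask)))
  a <- sum(actin_mask)
  if (a == 0) stop("empty filament mask: bound fraction undefined")
  sum(actin_mask & ligand_mask) / a
}

# Bilinear sample of a matrix at fractional (row, col) positions; positions
# outside the image clamp to the border.
bilinear_sample <- function(img, r, c) {
  r <- pmin(pmax(r, 1), nrow(img))
  c <- pmin(pmax(c, 1), ncol(img))
  r0 <- pmin(floor(r), nrow(img) - 1); c0 <- pmin(floor(c), ncol(img) - 1)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Line profile across a two-channel image
#'
#' Samples both channels along a user line with bilinear interpolation,
#' averaging across a perpendicular width.
#'
#' @param pair An [image_pair()].
#' @param from,to Line endpoints as `(row, col)` pixel coordinates
#'   (1-based), inside the image.
#' @param width_px Averaging width perpendicular to the line, pixels.
#' @param step_px Sampling step along the line, pixels.
#' @return An object of class `line_profile`: data frame with `position`
#'   (um, strictly increasing from `from`), `intensity_a`, `intensity_b`;
#'   attributes record the endpoints and width.
#' @export
line_profile <- function(pair, from, to, width_px = 1, step_px = 0.5) {
  stopifnot(inherits(pair, "image_pair"), length(from) == 2,
            length(to) == 2)
  dims <- dim(pair$channel_a)
  if (any(from < 1) || any(to < 1) || from[1] > dims[1] || to[1] > dims[1] ||
      from[2] > dims[2] || to[2] > dims[2])
    stop("line endpoints must lie inside the image")
  d <- to - from
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length line")
  u <- d / len
  perp <- c(-u[2], u[1])
  tpos <- seq(0, len, by = step_px)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out =
                max(1, round(width_px)))
  sample_channel <- function(img) {
    vals <- vapply(offs, function(o) {
      r <- from[1] + tpos * u[1] + o * perp[1]
      c <- from[2] + tpos * u[2] + o * perp[2]
      bilinear_sample(img, r, c)
    }, numeric(length(tpos)))
    if (is.null(dim(vals))) vals else rowMeans(vals)
  }
  out <- data.frame(position = tpos * pair$pixel_size,
                    intensity_a = sample_channel(pair$channel_a),
                    intensity_b = sample_channel(pair$channel_b))
  attr(out, "from") <- from
  attr(out, "to") <- to
  attr(out, "width_px") <- width_px
  class(out) <- c("line_profile", class(out))
  out
}

#' Full width at half maximum of a profile
#'
#' Baseline is the profile minimum (optionally a lower percentile);
#' half-maximum is halfway between baseline and the global maximum; the
#' width is the distance between the two half-maximum crossings flanking
#' the peak, each located by linear interpolation between samples.
#'
#' @param position Strictly increasing positions (um).
#' @param intensity Intensities at those positions.
#' @param baseline_quantile Quantile used as baseline (0 = minimum).
#' @return Width in the units of `position`.
#' @export
fwhm <- function(position, intensity, baseline_quantile = 0) {
  stopifnot(length(position) == length(intensity),
            all(diff(position) > 0))
  base <- if (baseline_quantile <= 0) min(intensity) else
    stats::quantile(intensity, baseline_quantile, names = FALSE)
  pk <- which.max(intensity)
  if (sum(intensity == intensity[pk]) > 1)
    warning("multiple global maxima; using the first", call. = FALSE)
  half <- base + (intensity[pk] - base) / 2
  cross_left <- NA_real_
  if (pk > 1) for (i in pk:2) {
    if (intensity[i - 1] <= half && intensity[i] >= half) {
      frac <- (half - intensity[i - 1]) / (intensity[i] - intensity[i - 1])
      cross_left <- position[i - 1] + frac * (position[i] - position[i - 1])
      break
    }
  }
  cross_right <- NA_real_
  if (pk < length(intensity)) for (i in pk:(length(intensity) - 1)) {
    if (intensity[i] >= half && intensity[i + 1] <= half) {
      frac <- (intensity[i] - half) / (intensity[i] - intensity[i + 1])
      cross_right <- position[i] + frac * (position[i + 1] - position[i])
      break
    }
  }
  if (is.na(cross_left) || is.na(cross_right))
    stop("undefined FWHM: no half-maximum crossing on one side of the peak")
  cross_right - cross_left
}

#' FWHM ratio of the two channels of a line profile
#'
#' Ratio of channel A's (filament) full width at half maximum to channel
#' B's (e.g. junction marker), the line-scan statistic for junctional
#' actomyosin organisation: values near 1 indicate a filament band as
#' tight as the marker band, larger values a broadened filament signal.
#'
#' @param profile A `line_profile`.
#' @param broadened_cutoff Ratio above which the result is flagged as
#'   broadened.
#' @param baseline_quantile Passed to [fwhm()].
#' @return An object of class `fwhm_result`: list with `fwhm_a`, `fwhm_b`
#'   (um), `ratio` and logical `broadened`.
#' @export
fwhm_ratio <- function(profile, broadened_cutoff = 1.5,
                       baseline_quantile = 0) {
  stopifnot(inherits(profile, "line_profile"))
  fa <- fwhm(profile$position, profile$intensity_a, baseline_quantile)
  fb <- fwhm(profile$position, profile$intensity_b, baseline_quantile)
  structure(list(fwhm_a = fa, fwhm_b = fb, ratio = fa / fb,
                 broadened = fa / fb > broadened_cutoff),
            class = "fwhm_result")
}

#' @export
print.fwhm_result <- function(x, ...) {
  cat(sprintf("<fwhm_result> A %.4g um / B %.4g um = %.3g%s\n",
              x$fwhm_a, x$fwhm_b, x$ratio,
              if (x$broadened) " (broadened)" else ""))
  invisible(x)
}

#' Fraction-bound quantification of a TIRF image pair
#'
#' The standard pipeline: rolling-ball background subtraction (by default
#' in the ligand channel only, where uneven illumination matters most),
#' Yen thresholding of each channel, mask conjunction, and the bound
#' fraction |actin AND ligand| / |actin|.
#'
#' @param pair An [image_pair()].
#' @param rolling_radius Rolling-ball radius, pixels.
#' @param subtract Channels to background-subtract: `"ligand"` (default),
#'   `"both"`, or `"none"`.
#' @param nbins Histogram bins for the Yen threshold.
#' @return List with `fraction`, `actin_mask`, `ligand_mask`,
#'   `bound_mask`, and the two thresholds.
#' @export
quantify_tirf_pair <- function(pair, rolling_radius = 100,
                               subtract = c("ligand", "both", "none"),
                               nbins = 256) {
  subtract <- match.arg(subtract)
  stopifnot(inherits(pair, "image_pair"))
  a <- pair$channel_a
  b <- pair$channel_b
  if (subtract %in% c("both"))
    a <- subtract_background_rolling_ball(a, rolling_radius)
  if (subtract %in% c("ligand", "both"))
    b <- subtract_background_rolling_ball(b, rolling_radius)
  ya <- threshold_mask_yen(a, nbins)
  yb <- threshold_mask_yen(b, nbins)
  list(fraction = bound_fraction(ya$mask, yb$mask),
       actin_mask = ya$mask, ligand_mask = yb$mask,
       bound_mask = ya$mask & yb$mask,
       threshold_a = ya$threshold, threshold_b = yb$threshold)
}
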