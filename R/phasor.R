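#' Spectral phasor transform
#'
#' Maps every pixel's emission spectrum to its first-harmonic Fourier
#' coordinates
#' \deqn{G = \frac{\sum_k I_k \cos(2\pi n (\lambda_k - \lambda_{min}) /
#'   (\lambda_{max} - \lambda_{min}))}{\sum_k I_k}, \qquad
#'   S = \frac{\sum_k I_k \sin(\cdot)}{\sum_k I_k}}
#' where the sum runs over the spectral channels (equal-bandwidth Riemann
#' discretisation at the channel centers). The angular position of a phasor
#' encodes the spectral center of mass and its radius the spectral width;
#' non-negative spectra always satisfy \eqn{G^2 + S^2 \le 1}. Mixtures of two
#' emitting species fall on the straight segment joining the pure-species
#' phasors, which is what makes the two-cursor fraction analysis linear.
#'
#' Background pixels are excluded by a total-intensity threshold: either a
#' fixed count or Otsu's method on the total-intensity image (the default).
#'
#' @param stack A [spectrum_stack()].
#' @param harmonic Positive integer harmonic `n`; the default 1 places one
#'   full trigonometric period across the acquisition range.
#' @param threshold Either `"otsu"` (default) or a single non-negative count;
#'   pixels whose summed intensity is at or below it are masked out.
#'
#' @return A tibble of class `phasor_field` with one row per pixel: `row`,
#'   `col`, `total_intensity`, `included`, and `G`, `S` (NA for excluded
#'   pixels).
#' @examples
#' st <- simulate_hsi_vesicle(f = 0.5, seed = 1)$stack
#' ph <- phasor_transform(st)
#' dplyr::count(ph, included)
#' @export
phasor_transform <- function(stack, harmonic = 1L, threshold = "otsu") {
  stopifnot(inherits(stack, "spectrum_stack"))
  if (!is_number(harmonic) || harmonic < 1 || harmonic != round(harmonic)) {
    abort("`harmonic` must be a positive integer.")
  }
  d <- dim(stack$intensities)
  n_px <- d[1] * d[2]
  # pixels x channels matrix; column-major order keeps (row, col) traceable
  I <- matrix(stack$intensities, nrow = n_px, ncol = d[3])
  total <- rowSums(I)

  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(total)
  } else {
    check_number(threshold, "threshold")
    if (threshold < 0) abort("`threshold` must be >= 0.")
    threshold
  }
  included <- total > thr
  if (!any(included)) abort("No pixels above the intensity threshold.")

  phase <- 2 * pi * harmonic * (stack$wavelengths - stack$lambda_min) /
    (stack$lambda_max - stack$lambda_min)
  G <- as.vector(I %*% cos(phase)) / total
  S <- as.vector(I %*% sin(phase)) / total
  G[!included] <- NA_real_
  S[!included] <- NA_real_

  out <- tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    G = G,
    S = S,
    total_intensity = total,
    included = included
  )
  class(out) <- c("phasor_field", class(out))
  attr(out, "harmonic") <- as.integer(harmonic)
  attr(out, "threshold") <- thr
  attr(out, "image_dim") <- d[1:2]
  out
}

# Otsu's between-class-variance threshold on a 256-bin histogram of the
# total-intensity image; returns a value on the intensity scale.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Circular phasor cursor
#'
#' A labeled circle in (G, S) space used to select pixels on the phasor plot
#' (the reciprocity principle: selected phasor-space pixels light up in the
#' image).
#'
#' @param center_g,center_s Cursor center, inside the unit circle.
#' @param radius Inclusion radius in phasor units, > 0.
#' @param label Display label.
#' @return A `phasor_cursor` object.
#' @export
phasor_cursor <- function(center_g, center_s, radius, label) {
  check_number(center_g, "center_g")
  check_number(center_s, "center_s")
  check_number(radius, "radius", positive = TRUE)
  if (center_g^2 + center_s^2 > 1) {
    abort("Cursor center must lie within the unit circle.")
  }
  structure(
    list(center_g = center_g, center_s = center_s, radius = radius,
         label = as.character(label)),
    class = "phasor_cursor"
  )
}

#' Classify phasor pixels with cursors
#'
#' Labels each included pixel with the first cursor (in input order) whose
#' circle contains its (G, S); pixels matched by no cursor get `"none"`.
#' First-cursor-wins is the deterministic tie-break for overlapping cursors.
#'
#' @param field A `phasor_field` tibble from [phasor_transform()].
#' @param cursors A list of [phasor_cursor()] objects (at least one).
#' @return `field` with a `cursor_label` character column added (`NA` for
#'   excluded pixels).
#' @export
classify_cursors <- function(field, cursors) {
  stopifnot(inherits(field, "phasor_field"))
  if (inherits(cursors, "phasor_cursor")) cursors <- list(cursors)
  if (length(cursors) < 1L) abort("Provide at least one cursor.")
  ok <- vapply(cursors, inherits, logical(1), "phasor_cursor")
  if (!all(ok)) abort("`cursors` must be a list of phasor_cursor objects.")

  lab <- rep(NA_character_, nrow(field))
  lab[field$included] <- "none"
  # reverse order so the first cursor overwrites later ones
  for (cur in rev(cursors)) {
    inside <- field$included &
      (field$G - cur$center_g)^2 + (field$S - cur$center_s)^2 <= cur$radius^2
    lab[which(inside)] <- cur$label
  }
  dplyr::mutate(field, cursor_label = lab)
}

#' Two-cursor trajectory axis
#'
#' The straight segment in phasor space along which mixture pixels fall.
#' By convention `endpoint_1` is the high-fluidity end: projected fractions
#' increase toward it and fraction 1 means most fluid.
#'
#' @param g0,s0 Phasor coordinates of the low-fluidity endpoint (fraction 0).
#' @param g1,s1 Phasor coordinates of the high-fluidity endpoint (fraction 1).
#' @return A `trajectory_axis` object.
#' @export
trajectory_axis <- function(g0, s0, g1, s1) {
  for (v in c("g0", "s0", "g1", "s1")) check_number(get(v), v)
  if (g0 == g1 && s0 == s1) abort("Trajectory endpoints must be distinct.")
  structure(
    list(g0 = unname(g0), s0 = unname(s0), g1 = unname(g1), s1 = unname(s1)),
    class = "trajectory_axis"
  )
}

#' Project phasors onto a two-cursor trajectory
#'
#' Computes, for every included pixel, the scalar projection of its (G, S)
#' onto the segment from the axis' fraction-0 endpoint to its fraction-1
#' endpoint, divided by the segment length. Components orthogonal to the axis
#' are discarded and values projecting outside the segment are clamped to
#' `[0, 1]` (the fraction is defined only on the segment).
#'
#' @param field A `phasor_field` tibble.
#' @param axis A [trajectory_axis()].
#' @return `field` with a `fraction` column added (`NA` for excluded pixels).
#' @export
project_fraction <- function(field, axis) {
  stopifnot(inherits(field, "phasor_field"), inherits(axis, "trajectory_axis"))
  ux <- axis$g1 - axis$g0
  uy <- axis$s1 - axis$s0
  len2 <- ux^2 + uy^2
  f <- ((field$G - axis$g0) * ux + (field$S - axis$s0) * uy) / len2
  dplyr::mutate(field, fraction = clamp(f, 0, 1))
}

#' Fraction histogram along the trajectory
#'
#' Normalised pixel distribution over equal-width bins on `[0, 1]`; the
#' published per-condition curves are means of such histograms across images.
#'
#' @param fractions Either a `phasor_field` tibble carrying a `fraction`
#'   column (from [project_fraction()]) or a bare numeric vector of fractions
#'   in `[0, 1]`; `NA`s (excluded pixels) are dropped.
#' @param n_bins Number of bins (default 100; the histogram center of mass is
#'   stable in the bin count, see [center_of_mass()]).
#' @return A tibble of class `fraction_histogram` with columns
#'   `bin_position` (bin centers) and `frequency` (sums to 1).
#' @export
fraction_histogram <- function(fractions, n_bins = 100L) {
  if (is.data.frame(fractions)) {
    if (is.null(fractions$fraction)) {
      abort("`fractions` has no `fraction` column; run project_fraction() first.")
    }
    fractions <- fractions$fraction
  }
  fractions <- fractions[!is.na(fractions)]
  if (length(fractions) == 0L) abort("No included pixels to histogram.")
  if (any(fractions < 0 | fractions > 1)) {
    abort("Fractions must lie in [0, 1].")
  }
  if (!is_number(n_bins) || n_bins < 1) abort("`n_bins` must be >= 1.")
  n_bins <- as.integer(n_bins)
  idx <- pmin(floor(fractions * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble(
    bin_position = (seq_len(n_bins) - 0.5) / n_bins,
    frequency = counts / sum(counts)
  )
  class(out) <- c("fraction_histogram", class(out))
  out
}

#' Center of mass of a fraction histogram
#'
#' The intensity-weighted mean position \eqn{CM = \sum_i F_i i / \sum_i F_i}
#' with `i` the bin-center fraction: a single descriptive statistic locating
#' the pixel population along the fluidity trajectory (0 = least fluid,
#' 1 = most fluid end).
#'
#' @param hist A [fraction_histogram()] tibble, or any data frame with
#'   `bin_position` and `frequency` columns.
#' @return A single number in `[0, 1]`.
#' @export
center_of_mass <- function(hist) {
  if (!is.data.frame(hist) || is.null(hist$bin_position) || is.null(hist$frequency)) {
    abort("`hist` must have `bin_position` and `frequency` columns.")
  }
  ftot <- sum(hist$frequency)
  if (ftot <= 0) abort("Histogram frequencies are all zero.")
  sum(hist$frequency * hist$bin_position) / ftot
}

#' Per-image fluidity summary
#'
#' Convenience wrapper running the full phasor chain on one stack:
#' transform, project onto the trajectory, histogram, center of mass.
#'
#' @inheritParams phasor_transform
#' @inheritParams project_fraction
#' @inheritParams fraction_histogram
#' @return A list with `field` (tibble), `histogram` (tibble) and `cm`
#'   (number).
#' @export
fluidity_summary <- function(stack, axis, harmonic = 1L, threshold = "otsu",
                             n_bins = 100L) {
  field <- phasor_transform(stack, harmonic = harmonic, threshold = threshold)
  field <- project_fraction(field, axis)
  h <- fraction_histogram(field, n_bins = n_bins)
  list(field = field, histogram = h, cm = center_of_mass(h))
}
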