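# Seeded generators emulating the statistical structure of each input type.
# Every generator is deterministic given (arguments, seed) and records its
# ground truth so the matching estimator can be checked by parameter
# recovery.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Gaussian spectral component
#'
#' Idealised pure-membrane emission spectrum used by the synthetic
#' hyperspectral generator: a Gaussian profile with the given center and
#' width. The package defaults place a gel-like component at 440 nm
#' (sigma 15 nm, gel-phase emission is narrow) and a fluid-like component at
#' 490 nm (sigma 35 nm), chosen so the centers of mass of the two sampled
#' spectra differ by ~50 nm on the default acquisition grid — the emission
#' shift between highly packed and fluid phosphatidylcholine membranes.
#'
#' @param center Center wavelength (nm).
#' @param sigma Gaussian width (nm), > 0.
#' @param amplitude Relative amplitude (> 0; spectra are later unit-normalised
#'   so this only matters for asymmetric mixing experiments).
#' @return A `spectral_component` object.
#' @export
spectral_component <- function(center, sigma, amplitude = 1) {
  check_number(center, "center")
  check_number(sigma, "sigma", positive = TRUE)
  check_number(amplitude, "amplitude", positive = TRUE)
  structure(list(center = center, sigma = sigma, amplitude = amplitude),
            class = "spectral_component")
}

default_gel_component <- function() spectral_component(440, 15)
default_fluid_component <- function() spectral_component(490, 35)

#' Reference spectra for two membrane states
#'
#' Samples the Gaussian profiles of two spectral components at the channel
#' centers and unit-normalises each (the two spectra then mix linearly in
#' intensity, which is what places mixture phasors on the straight segment
#' between the pure phasors).
#'
#' @param component_a,component_b [spectral_component()] objects; defaults
#'   are the gel-like (440 nm) and fluid-like (490 nm) components.
#' @param wavelengths Channel-center wavelengths (nm); default the 32-channel
#'   416-728 nm grid.
#' @return A tibble with columns `wavelength`, `spectrum_a`, `spectrum_b`
#'   (each summing to 1).
#' @export
make_reference_spectra <- function(component_a = default_gel_component(),
                                   component_b = default_fluid_component(),
                                   wavelengths = default_wavelengths()) {
  stopifnot(inherits(component_a, "spectral_component"),
            inherits(component_b, "spectral_component"))
  profile <- function(cmp) {
    y <- cmp$amplitude * exp(-((wavelengths - cmp$center)^2) / (2 * cmp$sigma^2))
    y / sum(y)
  }
  tibble(
    wavelength = wavelengths,
    spectrum_a = profile(component_a),
    spectrum_b = profile(component_b)
  )
}

#' @rdname make_reference_spectra
#' @param lambda_min,lambda_max,n_channels Acquisition grid parameters.
#' @export
default_wavelengths <- function(lambda_min = 416, lambda_max = 728,
                                n_channels = 32L) {
  bw <- (lambda_max - lambda_min) / n_channels
  lambda_min + bw * (seq_len(n_channels) - 0.5)
}

#' Phasor coordinates of a single spectrum
#'
#' Evaluates the spectral phasor transform for one discrete spectrum
#' (the same discrete sum used per pixel by [phasor_transform()]).
#'
#' @param intensities Non-negative channel intensities.
#' @param wavelengths Channel-center wavelengths (nm).
#' @param lambda_min,lambda_max Acquisition range (nm).
#' @param harmonic Harmonic `n` (default 1).
#' @return Named numeric vector `c(G = , S = )`.
#' @export
spectrum_phasor <- function(intensities, wavelengths = default_wavelengths(),
                            lambda_min = 416, lambda_max = 728,
                            harmonic = 1L) {
  if (any(intensities < 0)) abort("`intensities` must be non-negative.")
  tot <- sum(intensities)
  if (tot <= 0) abort("Spectrum has zero total intensity.")
  phase <- 2 * pi * harmonic * (wavelengths - lambda_min) /
    (lambda_max - lambda_min)
  c(G = sum(intensities * cos(phase)) / tot,
    S = sum(intensities * sin(phase)) / tot)
}

#' Fluidity trajectory axis from two reference components
#'
#' Builds the two-cursor trajectory whose endpoints are the phasors of the
#' pure gel-like and fluid-like reference spectra; by convention the fluid
#' endpoint is fraction 1.
#'
#' @inheritParams make_reference_spectra
#' @inheritParams spectrum_phasor
#' @return A [trajectory_axis()].
#' @export
reference_axis <- function(component_a = default_gel_component(),
                           component_b = default_fluid_component(),
                           lambda_min = 416, lambda_max = 728,
                           n_channels = 32L, harmonic = 1L) {
  wl <- default_wavelengths(lambda_min, lambda_max, n_channels)
  ref <- make_reference_spectra(component_a, component_b, wl)
  p0 <- spectrum_phasor(ref$spectrum_a, wl, lambda_min, lambda_max, harmonic)
  p1 <- spectrum_phasor(ref$spectrum_b, wl, lambda_min, lambda_max, harmonic)
  trajectory_axis(p0["G"], p0["S"], p1["G"], p1["S"])
}

#' Simulate a hyperspectral vesicle cross-section
#'
#' Renders the ring-shaped equatorial cross-section of a labeled vesicle:
#' every ring pixel carries the mixed spectrum
#' `f * fluid + (1 - f) * gel` (unit-normalised references) scaled to the
#' photon budget, with Poisson counting noise; the background is dark.
#' Detector read noise is not modeled (photon noise dominates at confocal
#' budgets).
#'
#' @param f Ground-truth fluid fraction in `[0, 1]`.
#' @param photons_per_pixel Expected photon count per ring pixel (> 0).
#' @param image_size Image side length in pixels (square image).
#' @param ring_radius Ring radius in pixels (default 0.35 * image_size).
#' @param ring_width Radial thickness of the ring in pixels.
#' @param component_gel,component_fluid Reference [spectral_component()]s.
#' @param lambda_min,lambda_max,n_channels Acquisition grid.
#' @param poisson Apply Poisson noise (TRUE) or return noiseless expected
#'   counts.
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @return A list with `stack` (a [spectrum_stack()]) and `truth`
#'   (`f`, `seed`, `n_ring_pixels`, `photons_per_pixel`).
#' @export
simulate_hsi_vesicle <- function(f,
                                 photons_per_pixel = 1e4,
                                 image_size = 64L,
                                 ring_radius = NULL,
                                 ring_width = 3,
                                 component_gel = default_gel_component(),
                                 component_fluid = default_fluid_component(),
                                 lambda_min = 416, lambda_max = 728,
                                 n_channels = 32L,
                                 poisson = TRUE,
                                 seed = NULL) {
  check_number(f, "f")
  if (f < 0 || f > 1) abort("`f` must lie in [0, 1].")
  check_number(photons_per_pixel, "photons_per_pixel", positive = TRUE)
  if (is.null(ring_radius)) ring_radius <- 0.35 * image_size

  wl <- default_wavelengths(lambda_min, lambda_max, n_channels)
  ref <- make_reference_spectra(component_gel, component_fluid, wl)
  mix <- f * ref$spectrum_b + (1 - f) * ref$spectrum_a
  expected <- photons_per_pixel * mix

  cx <- (image_size + 1) / 2
  rr <- sqrt(outer((seq_len(image_size) - cx)^2,
                   (seq_len(image_size) - cx)^2, `+`))
  ring <- abs(rr - ring_radius) <= ring_width / 2
  n_ring <- sum(ring)

  arr <- array(0, dim = c(image_size, image_size, n_channels))
  with_seed(seed, {
    for (k in seq_len(n_channels)) {
      plane <- matrix(0, image_size, image_size)
      plane[ring] <- if (poisson) {
        rpois(n_ring, expected[k])
      } else {
        expected[k]
      }
      arr[, , k] <- plane
    }
  })

  list(
    stack = spectrum_stack(arr, wl, lambda_min, lambda_max),
    truth = list(f = f, seed = seed, n_ring_pixels = n_ring,
                 photons_per_pixel = photons_per_pixel)
  )
}

#' Simulate a vesicle-condensate wetting geometry
#'
#' Constructs the labeled contour points of a vesicle-condensate
#' cross-section with a prescribed affinity contrast. The membrane segment
#' tensions are `sigma_mean -/+ W/2`, the tension triangle gives the interior
#' angles by the law of cosines, each apparent contact angle is 180 degrees
#' minus the interior angle opposite its tension, and the three circular
#' arcs are built to meet at two contact points with exactly those tangent
#' sectors. Points are sampled along each arc and jittered with isotropic
#' Gaussian positional noise of `noise_sigma` pixels.
#'
#' @param sigma_ce Condensate interfacial tension (uN/m), > 0.
#' @param W Affinity contrast (uN/m), `|W| < sigma_ce` for a realisable
#'   triangle.
#' @param sigma_mean Mean membrane segment tension (uN/m); with `W` it fixes
#'   `sigma_ie = sigma_mean - W/2` and `sigma_ic = sigma_mean + W/2`.
#' @param vesicle_radius Vesicle radius (um).
#' @param pixel_size Physical pixel size (um/pixel); contour coordinates are
#'   returned in pixels.
#' @param noise_sigma Gaussian positional noise, in pixels.
#' @param n_points Points sampled per arc.
#' @param contact_fraction Baseline contact half-chord as a fraction of the
#'   vesicle radius; shrunk automatically when `theta_e` is small so the
#'   construction stays realisable.
#' @param seed Integer seed; global RNG state restored afterwards.
#' @return A list with `contours` (tibble `x`, `y`, `arc`, `image_id`, pixel
#'   units) and `truth` (angles in degrees, `phi`, `theta_e_in`, tensions,
#'   geometry internals).
#' @export
simulate_wetting_geometry <- function(sigma_ce, W, sigma_mean = NULL,
                                      vesicle_radius = 10,
                                      pixel_size = 0.1,
                                      noise_sigma = 0,
                                      n_points = 120L,
                                      contact_fraction = 0.6,
                                      seed = NULL) {
  check_number(sigma_ce, "sigma_ce", positive = TRUE)
  check_number(W, "W")
  if (abs(W) >= sigma_ce) {
    abort("`|W|` must be < `sigma_ce` for a closed tension triangle.")
  }
  if (is.null(sigma_mean)) sigma_mean <- sigma_ce
  check_number(sigma_mean, "sigma_mean", positive = TRUE)
  sigma_ie <- sigma_mean - W / 2
  sigma_ic <- sigma_mean + W / 2
  if (sigma_ie <= 0) abort("`sigma_mean - W/2` must be > 0.")
  ang <- tensions_to_angles(sigma_ce, sigma_ie, sigma_ic)  # errors if open

  th_i <- deg2rad(ang$theta_i)
  th_e <- deg2rad(ang$theta_e)
  th_c <- deg2rad(ang$theta_c)

  # right contact point at (a, 0), interior above the chord
  phi_ie <- min(asin(contact_fraction), 0.5 * th_e)
  a <- vesicle_radius * sin(phi_ie)
  k_v <- vesicle_radius * cos(phi_ie)
  phi_ic <- phi_ie + th_i
  phi_ce <- phi_ic + th_c
  if (sin(phi_ce) >= 0) {
    abort("Internal construction failure: condensate ray does not point below the chord.")
  }

  circ_from_ray <- function(phi) {
    # circle through (a,0) and (-a,0) with tangent direction phi at (a,0);
    # NULL marks the flat (line) limit
    if (abs(sin(phi)) < 1e-9) return(NULL)
    k <- a * cos(phi) / sin(phi)
    list(center = c(0, k), radius = sqrt(a^2 + k^2))
  }
  ic <- circ_from_ray(phi_ic)
  ce <- circ_from_ray(phi_ce)

  sample_arc <- function(center, radius, side, n) {
    # the arc of the circle lying on side `side` of the chord y = 0,
    # between the two contact points, swept through its apex
    a_from <- atan2(0 - center[2], a - center[1])
    a_to <- atan2(0 - center[2], -a - center[1])
    apex <- side * pi / 2
    span_ccw <- wrap_2pi(a_to - a_from)
    ccw <- wrap_2pi(apex - a_from) < span_ccw
    tt <- if (ccw) {
      seq(a_from, a_from + span_ccw, length.out = n)
    } else {
      seq(a_from, a_from - wrap_2pi(a_from - a_to), length.out = n)
    }
    cbind(center[1] + radius * cos(tt), center[2] + radius * sin(tt))
  }

  pts_ie <- sample_arc(c(0, k_v), vesicle_radius, +1, n_points)
  pts_ce <- sample_arc(ce$center, ce$radius, -1, n_points)
  pts_ic <- if (is.null(ic)) {
    cbind(seq(a, -a, length.out = n_points), rep(0, n_points))
  } else {
    sample_arc(ic$center, ic$radius, sign(sin(phi_ic)), n_points)
  }

  pts <- rbind(pts_ie, pts_ic, pts_ce) / pixel_size
  contours <- with_seed(seed, {
    tibble(
      x = pts[, 1] + rnorm(nrow(pts), 0, noise_sigma),
      y = pts[, 2] + rnorm(nrow(pts), 0, noise_sigma),
      arc = rep(c("ie", "ic", "ce"), each = n_points),
      image_id = "sim_1"
    )
  })

  phi_val <- W / sigma_ce
  list(
    contours = contours,
    truth = list(
      theta_i = ang$theta_i, theta_e = ang$theta_e, theta_c = ang$theta_c,
      phi = phi_val, theta_e_in = intrinsic_angle(phi_val),
      W = W, sigma_ce = sigma_ce, sigma_ie = sigma_ie, sigma_ic = sigma_ic,
      contact_half_chord_um = a, vesicle_radius_um = vesicle_radius,
      ic_is_flat = is.null(ic), seed = seed
    )
  )
}

#' Simulate a condensate drift trajectory under a DC field
#'
#' Generates a 2-D trajectory combining deterministic electrophoretic drift
#' along the field axis with Brownian motion: the drift velocity is the one
#' implied by the requested zeta potential through the modified Smoluchowski
#' relation (the algebraic inverse of [zeta_potential()]), and positions
#' accumulate independent Gaussian increments of variance `2 D dt` per axis.
#'
#' @param zeta_mv Ground-truth zeta potential (mV, signed).
#' @param params A [medium_params()] object.
#' @param E Field magnitude (V/m), > 0.
#' @param D Diffusivity (um^2/s), >= 0.
#' @param duration Recording length (s); fields are typically applied for
#'   1000 s.
#' @param dt Sampling interval (s), > 0.
#' @param field_axis Field direction (unit 2-vector).
#' @param seed Integer seed; global RNG state restored afterwards.
#' @return A list with `track` (tibble `t`, `x`, `y` in s and um) and
#'   `truth` (`zeta_mv`, `nu` in m/s, `D`, `E`, `seed`).
#' @export
simulate_drift_track <- function(zeta_mv, params, E,
                                 D = 0.05, duration = 1000, dt = 1,
                                 field_axis = c(1, 0), seed = NULL) {
  if (!inherits(params, "medium_params")) {
    abort("`params` must be a medium_params object.")
  }
  check_number(E, "E", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  if (duration < dt) abort("`duration` must be at least `dt`.")
  if (D < 0) abort("`D` must be >= 0.")
  axis <- field_axis / sqrt(sum(field_axis^2))

  nu <- nu_from_zeta(zeta_mv, params, E)       # m/s
  nu_um <- nu * 1e6
  t <- seq(0, duration, by = dt)
  n <- length(t)
  track <- with_seed(seed, {
    step_sd <- sqrt(2 * D * dt)
    bx <- c(0, cumsum(rnorm(n - 1, 0, step_sd)))
    by <- c(0, cumsum(rnorm(n - 1, 0, step_sd)))
    tibble(
      t = t,
      x = nu_um * t * axis[1] + bx,
      y = nu_um * t * axis[2] + by
    )
  })
  list(
    track = track,
    truth = list(zeta_mv = zeta_mv, nu = nu, D = D, E = E, seed = seed)
  )
}
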