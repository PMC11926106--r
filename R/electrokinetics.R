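#' Medium and condensate parameters for the zeta-potential conversion
#'
#' Bundles the physical constants entering the drift-to-zeta conversion.
#' All quantities are SI: viscosities in Pa s, the inverse Debye length in
#' 1/m, the condensate radius in m, permittivity of vacuum in F/m.
#'
#' @param eta_c Condensate viscosity (Pa s).
#' @param eta_e External solution viscosity (Pa s); default water at room
#'   temperature.
#' @param kappa Inverse Debye length (1/m); default corresponds to a Debye
#'   length of ~1 nm, typical of a 100 mM ionic-strength buffer.
#' @param radius Condensate radius (m).
#' @param eps_r Relative permittivity of the external solution (default
#'   water, 78.5).
#' @param eps0 Vacuum permittivity (F/m).
#' @return A `medium_params` object.
#' @export
medium_params <- function(eta_c,
                          eta_e = 0.95e-3,
                          kappa = 1e9,
                          radius,
                          eps_r = 78.5,
                          eps0 = 8.8541878128e-12) {
  for (nm in c("eta_c", "eta_e", "kappa", "radius", "eps_r", "eps0")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  structure(
    list(eta_c = eta_c, eta_e = eta_e, kappa = kappa, radius = radius,
         eps_r = eps_r, eps0 = eps0),
    class = "medium_params"
  )
}

#' Drift velocity from a condensate trajectory
#'
#' Projects the recorded positions onto the applied-field axis and estimates
#' the drift velocity as the least-squares slope of projected position
#' versus time. The slope is robust to superimposed Brownian motion and is
#' deterministic, unlike an endpoint-displacement estimate.
#'
#' @param track A data frame with columns `t` (s) and `x`, `y` (um),
#'   strictly increasing `t`, at least two samples.
#' @param field_axis Unit 2-vector giving the field direction (normalised
#'   internally).
#' @return An object of class `drift_fit`: `nu` (signed drift velocity,
#'   m/s), `se` (standard error, m/s), `r_squared`, `n`.
#' @export
drift_velocity <- function(track, field_axis = c(1, 0)) {
  if (!is.data.frame(track) || is.null(track$t) || is.null(track$x) ||
        is.null(track$y)) {
    abort("`track` must be a data frame with t, x, y columns.")
  }
  if (nrow(track) < 2L) abort("Need at least two time points.")
  if (any(diff(track$t) <= 0)) {
    abort("Timestamps must be strictly increasing (no duplicates).")
  }
  if (length(field_axis) != 2L || all(field_axis == 0)) {
    abort("`field_axis` must be a nonzero 2-vector.")
  }
  axis <- field_axis / sqrt(sum(field_axis^2))
  proj_um <- track$x * axis[1] + track$y * axis[2]
  fit <- lm(proj_um ~ track$t)
  sm <- suppressWarnings(summary(fit))  # exact noiseless tracks are legitimate
  structure(
    list(
      nu = unname(coef(fit)[2]) * 1e-6,   # um/s -> m/s
      se = unname(sm$coefficients[2, 2]) * 1e-6,
      r_squared = sm$r.squared,
      n = nrow(track)
    ),
    class = "drift_fit"
  )
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("<drift_fit> nu = %.4g m/s (se %.2g, R^2 %.3f, n = %d)\n",
              x$nu, x$se, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.drift_fit <- function(x, ...) {
  tibble(nu = x$nu, se = x$se, r_squared = x$r_squared, n = x$n)
}

#' Zeta potential of a liquid condensate from its drift velocity
#'
#' Modified Smoluchowski relation accounting for the liquid (droplet)
#' character of the condensate:
#' \deqn{\zeta = \frac{3 \eta_c \nu}{\epsilon_0 \epsilon_r E} \cdot
#'   \frac{1}{3 \eta_e + \kappa R}.}
#' The sign of zeta follows the sign of `nu`. The denominator term
#' `3 eta_e + kappa R` is used exactly as published; note it adds a
#' viscosity (Pa s) to the dimensionless product `kappa R`, so a fixed unit
#' convention is required for reproducible values. This implementation
#' evaluates every input in SI units (see [medium_params()]); round trips
#' against [simulate_drift_track()] are exact under that convention.
#'
#' @param nu Signed drift velocity along the field (m/s); a `drift_fit`
#'   object is also accepted.
#' @param params A [medium_params()] object.
#' @param E Electric-field magnitude (V/m), > 0.
#' @param millivolts Report zeta in mV (default) rather than V.
#' @return Zeta potential (mV by default).
#' @export
zeta_potential <- function(nu, params, E, millivolts = TRUE) {
  if (inherits(nu, "drift_fit")) nu <- nu$nu
  if (!inherits(params, "medium_params")) {
    abort("`params` must be a medium_params object.")
  }
  check_number(E, "E", positive = TRUE)
  if (!is.numeric(nu)) abort("`nu` must be numeric.")
  zeta_v <- (3 * params$eta_c * nu / (params$eps0 * params$eps_r * E)) *
    (1 / (3 * params$eta_e + params$kappa * params$radius))
  if (millivolts) zeta_v * 1e3 else zeta_v
}

# drift velocity implied by a zeta potential: algebraic inverse of
# zeta_potential() under the same SI convention (used by the simulator)
nu_from_zeta <- function(zeta_mv, params, E) {
  zeta_v <- zeta_mv * 1e-3
  zeta_v * (params$eps0 * params$eps_r * E) *
    (3 * params$eta_e + params$kappa * params$radius) / (3 * params$eta_c)
}

#' Zeta-potential analysis of one or many tracks
#'
#' Data-frame-first wrapper: estimates the drift velocity per track and
#' converts it to a zeta potential.
#'
#' @param tracks A data frame with columns `t`, `x`, `y` and optionally
#'   `track_id`.
#' @param params A [medium_params()] object.
#' @param E Field magnitude (V/m).
#' @param field_axis Field direction (unit 2-vector).
#' @return A tibble with one row per track: `nu` (m/s), `zeta_mv`,
#'   `se_nu`, `r_squared`, `n`.
#' @export
zeta_analysis <- function(tracks, params, E, field_axis = c(1, 0)) {
  if (is.null(tracks$track_id)) tracks$track_id <- "track_1"
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      fit <- drift_velocity(df, field_axis = field_axis)
      tibble(
        nu = fit$nu,
        zeta_mv = zeta_potential(fit, params, E),
        se_nu = fit$se, r_squared = fit$r_squared, n = fit$n
      )
    }) |>
    dplyr::ungroup()
}
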