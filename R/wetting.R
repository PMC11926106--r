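#' Apparent contact angles from three fitted interfaces
#'
#' A vesicle-condensate cross-section shows three circular-arc interfaces
#' meeting at two contact points: membrane vs external buffer (`ie`),
#' membrane vs condensate (`ic`) and condensate vs external buffer (`ce`).
#' At the contact line the three surface tensions balance, so the tangent
#' directions of the three arcs partition the full angle at each contact
#' point into the three apparent contact angles: `theta_i` opening into the
#' vesicle interior (between the `ie` and `ic` tangents), `theta_e` into the
#' external solution (`ie`/`ce`) and `theta_c` into the condensate
#' (`ic`/`ce`). They always sum to 360 degrees.
#'
#' The contact points are located as the intersections of the `ie` and `ce`
#' circles and checked against the `ic` interface within `contact_tol`.
#' Region assignment uses the fitted geometry: the interior side of the
#' contact chord is the side holding the `ie` circle center (the vesicle body
#' subtends more than half its circle in an equatorial cross-section), the
#' condensate side is the opposite side, and the `ic` arc is taken as the
#' chord-proximal (minor) arc of its circle. Angles measured at the two
#' contact points are averaged; left/right asymmetry beyond
#' `asymmetry_warn` degrees is flagged with a warning.
#'
#' @param circle_ie,circle_ic,circle_ce [fit_circle()] results for the three
#'   arcs; `circle_ic` may be a line model (flat interface).
#' @param contact_tol Maximum distance of the `ic` interface from the
#'   ie/ce intersection points, same units as the fits; default 5% of the
#'   `ce` radius.
#' @param asymmetry_warn Left/right angle discrepancy (degrees) above which a
#'   warning is raised (default 5).
#' @return A `contact_angles` object: `theta_i`, `theta_e`, `theta_c` in
#'   degrees (left/right averages), per-side values, `asymmetry` (max
#'   per-angle discrepancy, degrees) and the contact-point coordinates.
#' @export
apparent_angles <- function(circle_ie, circle_ic, circle_ce,
                            contact_tol = NULL, asymmetry_warn = 5) {
  for (nm in c("circle_ie", "circle_ic", "circle_ce")) {
    if (!inherits(get(nm), "circle_fit")) {
      abort(sprintf("`%s` must be a circle_fit object.", nm))
    }
  }
  if (circle_ie$is_line || circle_ce$is_line) {
    abort("The ie and ce interfaces must be circles (only ic may be flat).")
  }
  if (is.null(contact_tol)) contact_tol <- 0.05 * circle_ce$radius

  cps <- circle_intersections(circle_ie, circle_ce)
  # distance of each candidate contact point from the ic interface
  dev_ic <- vapply(
    seq_len(2), function(k) point_interface_distance(cps[k, ], circle_ic),
    numeric(1)
  )
  if (any(dev_ic > contact_tol)) {
    abort(sprintf(
      paste0("The three interfaces do not share contact points: the ic ",
             "interface misses the ie/ce intersections by %.3g and %.3g ",
             "(tolerance %.3g)."),
      dev_ic[1], dev_ic[2], contact_tol
    ))
  }

  mid <- colMeans(cps)
  chord <- cps[2, ] - cps[1, ]
  m_hat <- c(-chord[2], chord[1])
  m_hat <- m_hat / sqrt(sum(m_hat^2))
  s_int <- sign(sum(m_hat * (circle_ie$center - mid)))
  if (s_int == 0) abort("Degenerate geometry: ie center lies on the contact chord.")
  # starting guess for the ic arc: the chord-proximal (minor) arc of its
  # circle; disambiguated below by requiring theta_i, theta_c in (0, 180)
  s_ic <- if (circle_ic$is_line) {
    0
  } else {
    sic <- -sign(sum(m_hat * (circle_ic$center - mid)))
    if (sic == 0) -s_int else sic
  }

  per_side <- lapply(seq_len(2), function(k) {
    p <- cps[k, ]
    u_out <- p - cps[3 - k, ]
    u_out <- u_out / sqrt(sum(u_out^2))
    ray_ie <- arc_departure_ray(circle_ie, p, m_hat, s_int)
    ray_ce <- arc_departure_ray(circle_ce, p, m_hat, -s_int)
    o <- sign(u_out[1] * (s_int * m_hat[2]) - u_out[2] * (s_int * m_hat[1]))
    phi_ie <- atan2(ray_ie[2], ray_ie[1])
    phi_ce <- atan2(ray_ce[2], ray_ce[1])
    angles_for <- function(ray_ic) {
      phi_ic <- atan2(ray_ic[2], ray_ic[1])
      th_i <- wrap_2pi(o * (phi_ic - phi_ie))
      th_c <- wrap_2pi(o * (phi_ce - phi_ic))
      c(theta_i = th_i, theta_e = 2 * pi - th_i - th_c, theta_c = th_c)
    }
    th <- if (circle_ic$is_line) {
      angles_for(-u_out)
    } else {
      ray_ic <- arc_departure_ray(circle_ic, p, m_hat, s_ic)
      cand <- angles_for(ray_ic)
      # the physical tangent choice puts both theta_i and theta_c below 180
      # degrees; the flipped tangent shifts each by 180 the wrong way
      if (cand["theta_i"] > pi || cand["theta_c"] > pi) {
        angles_for(-ray_ic)
      } else {
        cand
      }
    }
    rad2deg(th)
  })

  left <- per_side[[1]]
  right <- per_side[[2]]
  asym <- max(abs(left - right))
  if (asym > asymmetry_warn) {
    warn(sprintf(
      "Left/right contact angles differ by up to %.2f degrees (threshold %g).",
      asym, asymmetry_warn
    ))
  }
  avg <- (left + right) / 2
  structure(
    list(
      theta_i = unname(avg["theta_i"]),
      theta_e = unname(avg["theta_e"]),
      theta_c = unname(avg["theta_c"]),
      per_side = tibble(
        side = c("left", "right"),
        theta_i = c(left["theta_i"], right["theta_i"]),
        theta_e = c(left["theta_e"], right["theta_e"]),
        theta_c = c(left["theta_c"], right["theta_c"])
      ),
      asymmetry = asym,
      contact_points = cps
    ),
    class = "contact_angles"
  )
}

# both intersection points of two circle_fit circles; errors when disjoint
circle_intersections <- function(c1, c2) {
  d_vec <- c2$center - c1$center
  d <- sqrt(sum(d_vec^2))
  if (d == 0) abort("Concentric circles: no contact line.")
  if (d > c1$radius + c2$radius || d < abs(c1$radius - c2$radius)) {
    abort("The ie and ce circles do not intersect: no contact line.")
  }
  a <- (d^2 + c1$radius^2 - c2$radius^2) / (2 * d)
  h2 <- c1$radius^2 - a^2
  h <- sqrt(max(h2, 0))
  e <- d_vec / d
  base <- c1$center + a * e
  perp <- c(-e[2], e[1])
  rbind(base + h * perp, base - h * perp)
}

point_interface_distance <- function(p, fit) {
  if (fit$is_line) {
    nrm <- c(-fit$line_dir[2], fit$line_dir[1])
    abs(sum((p - fit$line_point) * nrm))
  } else {
    abs(sqrt(sum((p - fit$center)^2)) - fit$radius)
  }
}

# tangent ray with which the arc lying on side `s` of the contact chord
# (normal m_hat) leaves the contact point p
arc_departure_ray <- function(fit, p, m_hat, s) {
  r_vec <- p - fit$center
  t <- c(-r_vec[2], r_vec[1])
  t <- t / sqrt(sum(t^2))
  if (sign(sum(t * m_hat)) != s) t <- -t
  t
}

#' @export
print.contact_angles <- function(x, ...) {
  cat(sprintf(
    "<contact_angles> theta_i = %.2f, theta_e = %.2f, theta_c = %.2f deg (sum %.2f, asymmetry %.2f)\n",
    x$theta_i, x$theta_e, x$theta_c, x$theta_i + x$theta_e + x$theta_c,
    x$asymmetry
  ))
  invisible(x)
}

#' @export
tidy.contact_angles <- function(x, ...) {
  tibble(theta_i = x$theta_i, theta_e = x$theta_e, theta_c = x$theta_c,
         asymmetry = x$asymmetry)
}

grab_angles <- function(theta_i, theta_e, theta_c) {
  if (inherits(theta_i, "contact_angles")) {
    return(list(i = theta_i$theta_i, e = theta_i$theta_e, c = theta_i$theta_c))
  }
  if (is.data.frame(theta_i)) {
    return(list(i = theta_i$theta_i, e = theta_i$theta_e, c = theta_i$theta_c))
  }
  list(i = theta_i, e = theta_e, c = theta_c)
}

#' Geometric factor from the apparent contact angles
#'
#' The geometric factor
#' \deqn{\Phi = (\sin\theta_e - \sin\theta_c) / \sin\theta_i}
#' is the rescaled affinity contrast `W / Sigma_ce`: a size- and
#' shape-invariant material parameter in `[-1, 1]`. `Phi = -1` is complete
#' wetting of the membrane by the condensate, `Phi = +1` is dewetting, and
#' negative values mean the membrane prefers the condensate over the
#' external buffer.
#'
#' @param theta_i,theta_e,theta_c Apparent contact angles in degrees
#'   (vectorised). Alternatively pass a `contact_angles` object or a data
#'   frame with `theta_i`, `theta_e`, `theta_c` columns as the first
#'   argument.
#' @return The geometric factor (dimensionless).
#' @examples
#' geometric_factor(150, 90, 120)
#' @export
geometric_factor <- function(theta_i, theta_e = NULL, theta_c = NULL) {
  a <- grab_angles(theta_i, theta_e, theta_c)
  si <- sind(a$i)
  if (any(abs(si) < 1e-12)) {
    abort("`theta_i` of 0 or 180 degrees leaves the geometric factor undefined.")
  }
  (sind(a$e) - sind(a$c)) / si
}

#' Intrinsic contact angle from the geometric factor
#'
#' The nanoscopic contact angle opening toward the external solution,
#' `theta_e^in = arccos(Phi)`, in degrees. Unlike the apparent angles it does
#' not depend on the sizes of the vesicle-condensate couple. Values of `Phi`
#' within `tol` outside `[-1, 1]` (floating-point spill) are clamped; larger
#' excursions indicate an inconsistent geometry and raise an error.
#'
#' @param phi Geometric factor (vectorised).
#' @param tol Clamp window outside the unit interval (default 1e-9).
#' @return Intrinsic contact angle in degrees, in `[0, 180]`.
#' @examples
#' intrinsic_angle(0)      # 90
#' intrinsic_angle(-1)     # 180: complete wetting
#' @export
intrinsic_angle <- function(phi, tol = 1e-9) {
  if (any(abs(phi) > 1 + tol)) {
    abort("`phi` outside [-1, 1]: inconsistent wetting geometry.")
  }
  rad2deg(acos(clamp(phi, -1, 1)))
}

#' Geometric factor from the intrinsic contact angle
#'
#' Inverse of [intrinsic_angle()]: `Phi = cos(theta_e^in)`. The dewetting
#' extreme `theta_e^in = 0` gives `Phi = +1`; complete wetting
#' `theta_e^in = 180` gives `Phi = -1`.
#'
#' @param theta_e_in Intrinsic contact angle in degrees (vectorised), in
#'   `[0, 180]`.
#' @return The geometric factor.
#' @export
phi_from_intrinsic_angle <- function(theta_e_in) {
  if (any(theta_e_in < 0 | theta_e_in > 180)) {
    abort("`theta_e_in` must lie in [0, 180] degrees.")
  }
  cosd(theta_e_in)
}

#' Affinity contrast
#'
#' `W = Phi * Sigma_ce`: the difference in adhesion free energy per unit area
#' between the condensate-wetted and buffer-wetted membrane segments, bounded
#' by `-Sigma_ce <= W <= +Sigma_ce`. For glycinin condensates the interfacial
#' tension is `Sigma_ce = 15.7` uN/m (see [condensate_systems]).
#'
#' @param phi Geometric factor (vectorised).
#' @param sigma_ce Condensate-buffer interfacial tension, uN/m, > 0.
#' @return Affinity contrast in the units of `sigma_ce`.
#' @export
affinity_contrast <- function(phi, sigma_ce) {
  check_number(sigma_ce, "sigma_ce", positive = TRUE)
  phi * sigma_ce
}

#' Membrane segment tensions from the tension triangle
#'
#' By the law of sines on the closed tension triangle at the contact line,
#' \deqn{\Sigma_{ie}^m = \Sigma_{ce} \sin\theta_c / \sin\theta_i, \qquad
#'       \Sigma_{ic}^m = \Sigma_{ce} \sin\theta_e / \sin\theta_i.}
#' Only the difference `W = Sigma_ic^m - Sigma_ie^m` of the underlying
#' adhesion decomposition is identifiable from angles plus `Sigma_ce`; the
#' common membrane tension is not reported separately.
#'
#' @inheritParams geometric_factor
#' @param sigma_ce Condensate interfacial tension (uN/m), > 0.
#' @return A tibble with `sigma_ie` and `sigma_ic` (same units as
#'   `sigma_ce`).
#' @export
segment_tensions <- function(theta_i, theta_e = NULL, theta_c = NULL,
                             sigma_ce) {
  a <- grab_angles(theta_i, theta_e, theta_c)
  check_number(sigma_ce, "sigma_ce", positive = TRUE)
  si <- sind(a$i)
  if (any(abs(si) < 1e-12)) abort("Degenerate `theta_i`: tensions undefined.")
  tibble(
    sigma_ie = sigma_ce * sind(a$c) / si,
    sigma_ic = sigma_ce * sind(a$e) / si
  )
}

#' Apparent contact angles from a tension triple
#'
#' Forward map of the tension triangle: for tensions
#' `(sigma_ce, sigma_ie, sigma_ic)` satisfying the strict triangle
#' inequality, the triangle's interior angles follow from the law of cosines
#' and each apparent contact angle is 180 degrees minus the interior angle
#' opposite its tension (`theta_i` opposite `sigma_ce`, `theta_c` opposite
#' `sigma_ie`, `theta_e` opposite `sigma_ic`), so the three always sum to
#' 360 degrees. This is the inverse of [segment_tensions()] and the basis of
#' the synthetic wetting-geometry generator.
#'
#' @param sigma_ce,sigma_ie,sigma_ic Positive tensions (any common unit).
#' @return A tibble with `theta_i`, `theta_e`, `theta_c` in degrees.
#' @export
tensions_to_angles <- function(sigma_ce, sigma_ie, sigma_ic) {
  s <- cbind(sigma_ce, sigma_ie, sigma_ic)
  if (any(s <= 0)) abort("All tensions must be > 0.")
  if (any(s[, 1] >= s[, 2] + s[, 3] | s[, 2] >= s[, 1] + s[, 3] |
            s[, 3] >= s[, 1] + s[, 2])) {
    abort("Tension triple violates the strict triangle inequality: the tension triangle does not close.")
  }
  opp <- function(a, b, cc) rad2deg(acos(clamp((b^2 + cc^2 - a^2) / (2 * b * cc), -1, 1)))
  tibble(
    theta_i = as.numeric(180 - opp(s[, 1], s[, 2], s[, 3])),
    theta_e = as.numeric(180 - opp(s[, 3], s[, 1], s[, 2])),
    theta_c = as.numeric(180 - opp(s[, 2], s[, 1], s[, 3]))
  )
}

#' Consistency report for a set of contact angles
#'
#' Checks that the apparent angles describe a closed tension triangle:
#' the angle sum equals 360 degrees, the geometric factor lies in `[-1, 1]`,
#' and the vector sum of the three tensions pulling along the interface
#' tangents vanishes at the contact line. Violations are reported, not
#' fatal, so noisy experimental measurements can be inspected.
#'
#' @inheritParams geometric_factor
#' @param angle_sum_tol Tolerated deviation of the angle sum from 360
#'   degrees (default 1, suitable for experimental input; synthetic
#'   noiseless geometries satisfy 1e-6).
#' @return A one-row tibble: `angle_sum`, `angle_sum_deviation`, `phi`,
#'   `phi_in_range`, `closure_residual` (force-balance residual relative to
#'   `sigma_ce` = 1), and logical `ok`.
#' @export
validate_geometry <- function(theta_i, theta_e = NULL, theta_c = NULL,
                              angle_sum_tol = 1) {
  a <- grab_angles(theta_i, theta_e, theta_c)
  angle_sum <- a$i + a$e + a$c
  dev <- abs(angle_sum - 360)
  phi <- (sind(a$e) - sind(a$c)) / sind(a$i)
  phi_ok <- abs(phi) <= 1 + 1e-9
  # force balance with unit sigma_ce: rays at 0, theta_i, theta_i + theta_c
  st <- segment_tensions(a$i, a$e, a$c, sigma_ce = 1)
  ang_ic <- deg2rad(a$i)
  ang_ce <- deg2rad(a$i + a$c)
  fx <- st$sigma_ie + st$sigma_ic * cos(ang_ic) + 1 * cos(ang_ce)
  fy <- st$sigma_ic * sin(ang_ic) + 1 * sin(ang_ce)
  closure <- sqrt(fx^2 + fy^2)
  tibble(
    angle_sum = angle_sum,
    angle_sum_deviation = dev,
    phi = phi,
    phi_in_range = phi_ok,
    closure_residual = closure,
    ok = dev <= angle_sum_tol & phi_ok
  )
}

#' Full wetting analysis of labeled contour points
#'
#' Data-frame-first pipeline over one or many vesicle-condensate
#' cross-sections: per image, fits the three interface circles, recovers the
#' apparent contact angles, and derives the fluid-elastic parameters.
#'
#' @param contours A data frame with columns `x`, `y` (pixel coordinates),
#'   `arc` (one of `"ie"`, `"ic"`, `"ce"`) and optionally `image_id`.
#' @param sigma_ce Condensate interfacial tension in uN/m (e.g. 15.7 for
#'   glycinin; see [condensate_systems]).
#' @param pixel_size Physical size of one pixel (um/pixel); coordinates are
#'   scaled by it before fitting (angles and Phi are scale-invariant, the
#'   residual columns are in um).
#' @param angle_sum_tol Passed to [validate_geometry()].
#' @return A tibble with one row per image: the three apparent angles,
#'   `asymmetry`, `phi`, `theta_e_in`, `W`, `sigma_ie`, `sigma_ic`, the
#'   per-arc fit residuals and the validation columns.
#' @export
wetting_analysis <- function(contours, sigma_ce, pixel_size = 1,
                             angle_sum_tol = 1) {
  if (!is.data.frame(contours) || is.null(contours$arc)) {
    abort("`contours` must be a data frame with x, y and arc columns.")
  }
  check_number(pixel_size, "pixel_size", positive = TRUE)
  if (is.null(contours$image_id)) contours$image_id <- "image_1"

  contours |>
    dplyr::group_by(.data$image_id) |>
    dplyr::group_modify(function(df, key) {
      arcs <- split(df, df$arc)
      missing <- setdiff(c("ie", "ic", "ce"), names(arcs))
      if (length(missing) > 0) {
        abort(sprintf("Image is missing arc(s): %s.",
                      paste(missing, collapse = ", ")))
      }
      fits <- lapply(arcs[c("ie", "ic", "ce")], function(a) {
        fit_circle(data.frame(x = a$x * pixel_size, y = a$y * pixel_size))
      })
      ang <- apparent_angles(fits$ie, fits$ic, fits$ce)
      phi <- geometric_factor(ang)
      st <- segment_tensions(ang, sigma_ce = sigma_ce)
      val <- validate_geometry(ang, angle_sum_tol = angle_sum_tol)
      tibble(
        theta_i = ang$theta_i, theta_e = ang$theta_e, theta_c = ang$theta_c,
        asymmetry = ang$asymmetry,
        phi = phi,
        theta_e_in = intrinsic_angle(clamp(phi, -1, 1)),
        W = affinity_contrast(phi, sigma_ce),
        sigma_ie = st$sigma_ie, sigma_ic = st$sigma_ic,
        rms_ie = fits$ie$rms_residual, rms_ic = fits$ic$rms_residual,
        rms_ce = fits$ce$rms_residual,
        angle_sum_deviation = val$angle_sum_deviation,
        geometry_ok = val$ok
      )
    }) |>
    dplyr::ungroup()
}

#' Condensate systems and their interfacial tensions
#'
#' Reference interfacial tensions `Sigma_ce` (uN/m) for condensate systems
#' used with [affinity_contrast()] and [wetting_analysis()]. The glycinin
#' value, 15.7 uN/m, was determined from rheology and coalescence
#' measurements of glycinin condensates.
#'
#' @format A tibble with columns `system` and `sigma_ce_uN_m`.
#' @export
condensate_systems <- tibble::tibble(
  system = "glycinin",
  sigma_ce_uN_m = 15.7
)
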