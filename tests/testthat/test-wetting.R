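# forward-construct a geometry from prescribed apparent angles via the
# tension triangle, then invert with the analysis chain
angles_to_tensions <- function(theta_i, theta_e, theta_c, sigma_ce = 1) {
  list(
    sigma_ce = sigma_ce,
    sigma_ie = sigma_ce * sin(theta_c * pi / 180) / sin(theta_i * pi / 180),
    sigma_ic = sigma_ce * sin(theta_e * pi / 180) / sin(theta_i * pi / 180)
  )
}

recover_angles <- function(theta_i, theta_e, theta_c, noise_sigma = 0,
                           seed = NULL, pixel_size = 0.1) {
  tn <- angles_to_tensions(theta_i, theta_e, theta_c)
  sim <- simulate_wetting_geometry(
    sigma_ce = tn$sigma_ce, W = tn$sigma_ic - tn$sigma_ie,
    sigma_mean = (tn$sigma_ic + tn$sigma_ie) / 2,
    noise_sigma = noise_sigma, pixel_size = pixel_size, seed = seed
  )
  wetting_analysis(sim$contours, sigma_ce = tn$sigma_ce,
                   pixel_size = pixel_size)
}

test_that("apparent angles invert the forward construction", {
  sym <- recover_angles(120, 120, 120)
  expect_equal(sym$theta_i, 120, tolerance = 0.1 / 120)
  expect_equal(sym$theta_e, 120, tolerance = 0.1 / 120)
  expect_equal(sym$theta_c, 120, tolerance = 0.1 / 120)

  asym <- recover_angles(150, 90, 120)
  expect_equal(asym$theta_i, 150, tolerance = 0.1 / 150)
  expect_equal(asym$theta_e, 90, tolerance = 0.1 / 90)
  expect_equal(asym$theta_c, 120, tolerance = 0.1 / 120)
  expect_equal(asym$phi, (sin(pi / 2) - sin(2 * pi / 3)) / sin(5 * pi / 6),
               tolerance = 1e-4)
})

test_that("the flat membrane-condensate interface is handled via the line model", {
  # choose angles so the ic tangent leaves along the contact chord:
  # theta_i = 180 - asin(0.6) (in degrees) makes the ic interface flat
  phi_ie <- asin(0.6) * 180 / pi
  th_e <- 2 * phi_ie
  th_i <- 180 - phi_ie
  th_c <- 360 - th_i - th_e
  tn <- angles_to_tensions(th_i, th_e, th_c)
  sim <- simulate_wetting_geometry(
    sigma_ce = 1, W = tn$sigma_ic - tn$sigma_ie,
    sigma_mean = (tn$sigma_ic + tn$sigma_ie) / 2, pixel_size = 0.1
  )
  ic_pts <- sim$contours[sim$contours$arc == "ic", ]
  expect_lt(diff(range(ic_pts$y)), 1e-3 * diff(range(ic_pts$x)))
  expect_true(fit_circle(data.frame(x = ic_pts$x, y = ic_pts$y))$is_line)

  res <- wetting_analysis(sim$contours, sigma_ce = 1, pixel_size = 0.1)
  expect_equal(res$theta_i, th_i, tolerance = 0.1 / th_i)
  expect_equal(res$theta_e, th_e, tolerance = 0.1 / th_e)
  expect_equal(res$theta_c, th_c, tolerance = 0.1 / th_c)
})

test_that("geometric factor, intrinsic angle and affinity contrast follow the tension triangle", {
  # symmetry: equal external and condensate angles
  expect_equal(geometric_factor(137, 111.5, 111.5), 0)
  # direct trigonometric value
  expect_equal(geometric_factor(150, 90, 120),
               (1 - sin(2 * pi / 3)) / 0.5, tolerance = 1e-12)
  expect_error(geometric_factor(180, 90, 90), "undefined")

  expect_equal(intrinsic_angle(0), 90)
  expect_equal(intrinsic_angle(-1), 180)
  expect_equal(intrinsic_angle(1), 0)
  expect_equal(intrinsic_angle(0.26795), acos(0.26795) * 180 / pi)
  expect_equal(intrinsic_angle(1 + 1e-10), 0)  # clamp window
  expect_error(intrinsic_angle(1.01), "outside")

  # inverse map consistency: Phi = cos(theta_e_in) to machine precision
  phis <- seq(-1, 1, by = 0.01)
  expect_equal(phi_from_intrinsic_angle(intrinsic_angle(phis)), phis,
               tolerance = 1e-12)

  expect_equal(affinity_contrast(0, 15.7), 0)
  expect_equal(affinity_contrast(1, 15.7), 15.7)
  expect_equal(affinity_contrast(-0.5, 10), -5)
  expect_error(affinity_contrast(0.5, -1), "sigma_ce")
})

test_that("segment tensions obey the law of sines and scale with sigma_ce", {
  eq <- segment_tensions(120, 120, 120, sigma_ce = 1)
  expect_equal(eq$sigma_ie, 1, tolerance = 1e-12)
  expect_equal(eq$sigma_ic, 1, tolerance = 1e-12)

  st <- segment_tensions(150, 90, 120, sigma_ce = 15.7)
  expect_equal(st$sigma_ie, 15.7 * sin(2 * pi / 3) / 0.5, tolerance = 1e-12)
  expect_equal(st$sigma_ic, 15.7 * 2, tolerance = 1e-12)
  expect_equal(round(st$sigma_ie, 2), 27.19)
  expect_equal(round(st$sigma_ic, 2), 31.40)

  st2 <- segment_tensions(150, 90, 120, sigma_ce = 2 * 15.7)
  expect_equal(st2$sigma_ie, 2 * st$sigma_ie)
  expect_equal(st2$sigma_ic, 2 * st$sigma_ic)
})

test_that("tension round trip: tensions -> angles -> Phi recovers W/sigma_ce", {
  triples <- random_tension_triples(200, seed = 3)
  for (tr in triples) {
    ang <- tensions_to_angles(tr$sigma_ce, tr$sigma_mean - tr$W / 2,
                              tr$sigma_mean + tr$W / 2)
    expect_equal(ang$theta_i + ang$theta_e + ang$theta_c, 360,
                 tolerance = 1e-9)
    phi <- geometric_factor(ang$theta_i, ang$theta_e, ang$theta_c)
    expect_equal(phi, tr$W / tr$sigma_ce, tolerance = 1e-9)
    w <- affinity_contrast(phi, tr$sigma_ce)
    expect_equal(w, tr$W, tolerance = 1e-9)
    # law-of-sines closure of the reconstructed tension triangle
    st <- segment_tensions(ang$theta_i, ang$theta_e, ang$theta_c,
                           sigma_ce = tr$sigma_ce)
    expect_equal(st$sigma_ie, tr$sigma_mean - tr$W / 2, tolerance = 1e-9)
    expect_equal(st$sigma_ic, tr$sigma_mean + tr$W / 2, tolerance = 1e-9)
  }
  expect_error(tensions_to_angles(10, 1, 1), "triangle inequality")
})

test_that("Phi is monotone along constant-theta_i geometries", {
  # with theta_i fixed, theta_e + theta_c is fixed too, and Eq.-level algebra
  # gives Phi = sin((theta_c - theta_e)/2) / sin(theta_i/2): strictly
  # decreasing in theta_e (the droplet wets more as theta_e grows)
  th_i <- 140
  th_e <- seq(60, 170, by = 5)
  th_c <- 360 - th_i - th_e
  phi <- geometric_factor(rep(th_i, length(th_e)), th_e, th_c)
  expect_true(all(diff(phi) < 0))
  expect_equal(phi, sin((th_c - th_e) / 2 * pi / 180) / sin(th_i / 2 * pi / 180),
               tolerance = 1e-12)
})

test_that("validate_geometry reports closure and flags violations", {
  ok <- validate_geometry(150, 90, 120)
  expect_true(ok$ok)
  expect_lt(ok$closure_residual, 1e-9)

  bad <- validate_geometry(100, 100, 100)
  expect_false(bad$ok)
  expect_equal(bad$angle_sum_deviation, 60)

  # 1-degree measurement noise: bounded, reported, not fatal
  set.seed(53)
  devs <- replicate(50, {
    v <- validate_geometry(150 + rnorm(1), 90 + rnorm(1), 120 + rnorm(1),
                           angle_sum_tol = 5)
    v$angle_sum_deviation
  })
  expect_true(all(is.finite(devs)))
  expect_lt(max(devs), 10)
})

test_that("noisy contour pipeline recovers Phi within 0.05", {
  triples <- random_tension_triples(30, seed = 19)
  for (idx in seq_along(triples)) {
    tr <- triples[[idx]]
    sim <- simulate_wetting_geometry(
      sigma_ce = tr$sigma_ce, W = tr$W, sigma_mean = tr$sigma_mean,
      noise_sigma = 0.5, pixel_size = 0.1, seed = 1000 + idx
    )
    res <- wetting_analysis(sim$contours, sigma_ce = tr$sigma_ce,
                            pixel_size = 0.1)
    expect_lt(abs(res$phi - sim$truth$phi), 0.05)
  }
})

test_that("inconsistent interface sets are rejected", {
  c_ie <- fit_circle(circle_points(0, 8, 10))
  c_ce <- fit_circle(circle_points(0, -4, 5))
  c_far <- fit_circle(circle_points(40, 40, 2))
  expect_error(apparent_angles(c_ie, c_far, c_ce), "contact points")
  expect_error(apparent_angles(c_ie, c_ce, c_far), "do not intersect")
})
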