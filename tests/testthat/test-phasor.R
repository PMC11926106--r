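make_stack <- function(spectra, wavelengths = default_wavelengths(),
                       lambda_min = 416, lambda_max = 728) {
  # spectra: matrix pixels x channels laid out on a 1 x n image row
  arr <- array(0, dim = c(1, nrow(spectra), ncol(spectra)))
  for (p in seq_len(nrow(spectra))) arr[1, p, ] <- spectra[p, ]
  spectrum_stack(arr, wavelengths, lambda_min, lambda_max)
}

test_that("phasor identities: concentrated and uniform spectra", {
  # all intensity in a channel centered exactly at lambda_min -> phase zero
  wl <- seq(416, 728, length.out = 32)
  sp <- matrix(0, 1, 32); sp[1, 1] <- 123
  ph <- phasor_transform(make_stack(sp, wl), threshold = 0)
  expect_equal(ph$G[1], 1, tolerance = 1e-14)
  expect_equal(ph$S[1], 0, tolerance = 1e-14)

  # uniform spectrum over evenly spaced phases spanning one period cancels
  sp2 <- matrix(1, 1, 32)
  ph2 <- phasor_transform(make_stack(sp2), threshold = 0)
  expect_equal(ph2$G[1], 0, tolerance = 1e-12)
  expect_equal(ph2$S[1], 0, tolerance = 1e-12)
})

test_that("phasor matches the direct-sum oracle on a Gaussian spectrum", {
  wl <- default_wavelengths()
  sp <- matrix(exp(-((wl - 480)^2) / (2 * 30^2)), nrow = 1)
  st <- make_stack(sp)
  ph <- phasor_transform(st, threshold = 0)
  orc <- naive_phasor(st)
  expect_equal(ph$G[1], orc$G[1, 1], tolerance = 1e-12)
  expect_equal(ph$S[1], orc$S[1, 1], tolerance = 1e-12)
})

test_that("phasor equals the naive per-pixel loop oracle on random stacks", {
  set.seed(11)
  for (rep in 1:20) {
    arr <- array(runif(4 * 5 * 32, 0, 50), dim = c(4, 5, 32))
    st <- spectrum_stack(arr)
    ph <- phasor_transform(st, threshold = 0)
    orc <- naive_phasor(st)
    for (r in 1:4) for (cc in 1:5) {
      row <- ph[ph$row == r & ph$col == cc, ]
      expect_equal(row$G, orc$G[r, cc], tolerance = 1e-12)
      expect_equal(row$S, orc$S[r, cc], tolerance = 1e-12)
    }
  }
})

test_that("phasor modulus is bounded by 1 for nonnegative spectra", {
  set.seed(21)
  sp <- t(replicate(200, random_spectrum()))
  ph <- phasor_transform(make_stack(sp), threshold = 0)
  expect_true(all(ph$G^2 + ph$S^2 <= 1 + 1e-12))
})

test_that("phasor of a spectral mixture lies on the segment between components", {
  set.seed(31)
  wl <- default_wavelengths()
  for (rep in 1:50) {
    I1 <- random_spectrum(wl)
    I2 <- random_spectrum(wl)
    a <- runif(1, 0.1, 3); b <- runif(1, 0.1, 3)
    p1 <- spectrum_phasor(I1, wl)
    p2 <- spectrum_phasor(I2, wl)
    pm <- spectrum_phasor(a * I1 + b * I2, wl)
    lam <- a * sum(I1) / (a * sum(I1) + b * sum(I2))
    expect_equal(unname(pm["G"]), unname(lam * p1["G"] + (1 - lam) * p2["G"]),
                 tolerance = 1e-9)
    expect_equal(unname(pm["S"]), unname(lam * p1["S"] + (1 - lam) * p2["S"]),
                 tolerance = 1e-9)
  }
})

test_that("invalid stacks are rejected", {
  expect_error(
    phasor_transform(spectrum_stack(array(0, dim = c(2, 2, 4))), threshold = 0),
    "threshold"
  )
  expect_error(
    spectrum_stack(array(1, dim = c(2, 2, 4)), wavelengths = c(500, 450, 550, 600)),
    "increasing"
  )
  expect_error(spectrum_stack(array(-1, dim = c(2, 2, 4))), "non-negative")
})

test_that("Otsu masking separates ring from dark background and matches EBImage", {
  sim <- simulate_hsi_vesicle(0.5, photons_per_pixel = 1e3, seed = 5)
  ph <- phasor_transform(sim$stack)
  expect_equal(sum(ph$included), sim$truth$n_ring_pixels)

  skip_if_not_installed("EBImage")
  tot <- matrix(ph$total_intensity, 64, 64)
  ref <- EBImage::otsu(EBImage::Image(tot / max(tot)), range = c(0, 1)) * max(tot)
  mine <- attr(ph, "threshold")
  # same side of the bimodal gap: identical pixel partition
  expect_identical(tot > mine, tot > ref)
})

test_that("cursor classification follows first-match-wins", {
  sim <- simulate_hsi_vesicle(0, photons_per_pixel = 1e4, seed = 2,
                              poisson = FALSE)
  ph <- phasor_transform(sim$stack)
  g <- ph$G[ph$included][1]; s <- ph$S[ph$included][1]
  cur1 <- phasor_cursor(g, s, 0.05, "gel")
  cur2 <- phasor_cursor(g + 0.01, s, 0.1, "overlap")
  far <- phasor_cursor(-g, -s, 0.01, "far")

  lab <- classify_cursors(ph, list(cur1, cur2))
  expect_true(all(lab$cursor_label[lab$included] == "gel"))
  lab2 <- classify_cursors(ph, list(cur2, cur1))
  expect_true(all(lab2$cursor_label[lab2$included] == "overlap"))
  lab3 <- classify_cursors(ph, list(far))
  expect_true(all(lab3$cursor_label[lab3$included] == "none"))
  expect_true(all(is.na(lab$cursor_label[!lab$included])))
})

test_that("fraction projection is the clamped scalar projection", {
  ax <- trajectory_axis(0.2, 0.1, 0.8, 0.5)
  fake_field <- function(g, s) {
    f <- tibble::tibble(row = 1L, col = seq_along(g), G = g, S = s,
                        total_intensity = 1, included = TRUE)
    class(f) <- c("phasor_field", class(f))
    f
  }
  u <- c(0.6, 0.4) / sqrt(0.52)
  p03 <- c(0.2, 0.1) + 0.3 * c(0.6, 0.4)
  perp <- p03 + 0.07 * c(-u[2], u[1])
  fr <- project_fraction(
    fake_field(c(0.8, 0.5, perp[1], 0.2 - 0.6, 0.8 + 0.6),
               c(0.5, 0.3, perp[2], 0.1 - 0.4, 0.5 + 0.4)),
    ax
  )$fraction
  expect_equal(fr[1], 1)            # endpoint_1
  expect_equal(fr[2], 0.5)          # midpoint
  expect_equal(fr[3], 0.3, tolerance = 1e-12)  # orthogonal offset discarded
  expect_equal(fr[4], 0)            # clamped below
  expect_equal(fr[5], 1)            # clamped above
  expect_error(trajectory_axis(0.1, 0.2, 0.1, 0.2), "distinct")
})

test_that("fraction histogram and its center of mass behave as moments", {
  h <- fraction_histogram(rep(0.3, 50), n_bins = 100)
  expect_equal(sum(h$frequency), 1)
  expect_equal(sum(h$frequency > 0), 1L)
  expect_lt(abs(center_of_mass(h) - 0.3), 0.0051)  # within half a bin width

  h2 <- fraction_histogram(c(rep(0.2, 40), rep(0.6, 40)), n_bins = 10)
  expect_equal(sort(h2$frequency[h2$frequency > 0]), c(0.5, 0.5))

  # exact CM identities on explicit histograms: single bin, symmetric pair
  expect_equal(center_of_mass(tibble::tibble(bin_position = 0.3, frequency = 1)),
               0.3)
  expect_equal(
    center_of_mass(tibble::tibble(bin_position = c(0.2, 0.6),
                                  frequency = c(0.5, 0.5))),
    0.4
  )

  set.seed(41)
  h3 <- fraction_histogram(runif(2e5), n_bins = 100)
  expect_equal(center_of_mass(h3), 0.5, tolerance = 0.005)
  chi2 <- sum((h3$frequency - 0.01)^2 / 0.01) * 2e5
  expect_lt(chi2, 99 + 4 * sqrt(2 * 99))  # crude large-N uniformity check

  expect_error(fraction_histogram(numeric(0)), "No included pixels")
  expect_error(center_of_mass(tibble::tibble(bin_position = 0.5, frequency = 0)),
               "zero")
})

test_that("center of mass is stable in bin count and under intensity rescaling", {
  sim <- simulate_hsi_vesicle(0.4, photons_per_pixel = 1e4, seed = 9)
  ax <- reference_axis()
  cms <- vapply(c(50, 100, 200, 400), function(nb) {
    fluidity_summary(sim$stack, ax, n_bins = nb)$cm
  }, numeric(1))
  expect_lt(max(cms) - min(cms), 0.01)

  scaled <- spectrum_stack(sim$stack$intensities * 7.3,
                           sim$stack$wavelengths,
                           sim$stack$lambda_min, sim$stack$lambda_max)
  cm1 <- fluidity_summary(sim$stack, ax, threshold = 0)$cm
  cm2 <- fluidity_summary(scaled, ax, threshold = 0)$cm
  expect_equal(cm1, cm2, tolerance = 1e-12)
})
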