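# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# direct per-pixel, per-channel evaluation of the phasor sums
naive_phasor <- function(stack, harmonic = 1) {
  d <- dim(stack$intensities)
  G <- S <- tot <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      num_g <- num_s <- den <- 0
      for (k in seq_len(d[3])) {
        I <- stack$intensities[i, j, k]
        ph <- 2 * pi * harmonic * (stack$wavelengths[k] - stack$lambda_min) /
          (stack$lambda_max - stack$lambda_min)
        num_g <- num_g + I * cos(ph)
        num_s <- num_s + I * sin(ph)
        den <- den + I
      }
      tot[i, j] <- den
      if (den > 0) {
        G[i, j] <- num_g / den
        S[i, j] <- num_s / den
      }
    }
  }
  list(G = G, S = S, total = tot)
}

# nonlinear geometric circle fit: minimises the true orthogonal residuals
geometric_circle_fit <- function(points, start) {
  res_fun <- function(p) {
    sqrt((points$x - p[1])^2 + (points$y - p[2])^2) - p[3]
  }
  fit <- minpack.lm::nls.lm(par = start, fn = res_fun)
  stats::setNames(fit$par, c("cx", "cy", "r"))
}

# random tension triples with a closed (non-degenerate) tension triangle
random_tension_triples <- function(n, sigma_ce = 1, seed = 1,
                                   margin = 0.02) {
  set.seed(seed)
  out <- vector("list", n)
  got <- 0
  while (got < n) {
    W <- runif(1, -sigma_ce * (1 - margin), sigma_ce * (1 - margin))
    sigma_mean <- runif(1, 0.6 * sigma_ce, 3 * sigma_ce)
    s_ie <- sigma_mean - W / 2
    s_ic <- sigma_mean + W / 2
    if (s_ie <= 0) next
    sides <- c(sigma_ce, s_ie, s_ic)
    if (max(sides) >= (sum(sides) - max(sides)) * (1 - margin)) next
    got <- got + 1
    out[[got]] <- list(sigma_ce = sigma_ce, W = W, sigma_mean = sigma_mean)
  }
  out
}

# spectra on the default 32-channel grid with positive random structure
random_spectrum <- function(wl = memwet::default_wavelengths()) {
  center <- runif(1, min(wl), max(wl))
  width <- runif(1, 10, 80)
  base <- exp(-((wl - center)^2) / (2 * width^2))
  base * runif(1, 0.5, 5) + runif(length(wl), 0, 0.05)
}

circle_points <- function(cx, cy, r, n = 100, span = c(0, 2 * pi)) {
  th <- seq(span[1], span[2], length.out = n)
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}
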