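# angles are degrees at every user-facing boundary, radians internally
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

sind <- function(x) sin(deg2rad(x))
cosd <- function(x) cos(deg2rad(x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# wrap an angle (radians) into [0, 2*pi)
wrap_2pi <- function(x) x %% (2 * pi)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, positive = FALSE) {
  if (!is_number(x)) abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}
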