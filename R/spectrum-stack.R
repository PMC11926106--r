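#' Hyperspectral image stack
#'
#' Container for a per-pixel emission-spectrum image: a `rows x cols x
#' channels` array of non-negative intensities (photon-count scale) together
#' with the channel-center wavelengths and the acquisition range
#' `[lambda_min, lambda_max]`. The default metadata mirror a common confocal
#' hyperspectral acquisition: 32 channels spanning 416-728 nm, i.e. a channel
#' bandwidth of 9.75 nm.
#'
#' @param intensities Numeric array `rows x cols x channels`, all values >= 0.
#' @param wavelengths Numeric vector of channel-center wavelengths (nm),
#'   strictly increasing, one per channel. Defaults to the centers of
#'   `n_channels` equal-bandwidth channels on `[lambda_min, lambda_max]`.
#' @param lambda_min,lambda_max Acquisition range bounds (nm).
#'
#' @return A `spectrum_stack` object.
#' @examples
#' st <- spectrum_stack(array(1, dim = c(4, 4, 32)))
#' channel_bandwidth(st)
#' @export
spectrum_stack <- function(intensities,
                           wavelengths = NULL,
                           lambda_min = 416,
                           lambda_max = 728) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3-D array (rows x cols x channels).")
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    abort("`intensities` must be non-negative and free of NA.")
  }
  n_ch <- dim(intensities)[3]
  if (n_ch < 2L) abort("A spectrum stack needs at least 2 channels.")
  check_number(lambda_min, "lambda_min")
  check_number(lambda_max, "lambda_max")
  if (lambda_max <= lambda_min) abort("`lambda_max` must exceed `lambda_min`.")
  if (is.null(wavelengths)) {
    bw <- (lambda_max - lambda_min) / n_ch
    wavelengths <- lambda_min + bw * (seq_len(n_ch) - 0.5)
  }
  if (length(wavelengths) != n_ch) {
    abort("`wavelengths` must have one entry per channel.")
  }
  if (any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be strictly increasing.")
  }
  if (any(wavelengths < lambda_min) || any(wavelengths > lambda_max)) {
    abort("All channel-center wavelengths must lie in [lambda_min, lambda_max].")
  }
  structure(
    list(
      intensities = intensities,
      wavelengths = as.numeric(wavelengths),
      lambda_min = lambda_min,
      lambda_max = lambda_max
    ),
    class = "spectrum_stack"
  )
}

#' @export
print.spectrum_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<spectrum_stack> %d x %d pixels, %d channels, %g-%g nm (bandwidth %.4g nm)\n",
    d[1], d[2], d[3], x$lambda_min, x$lambda_max, channel_bandwidth(x)
  ))
  invisible(x)
}

#' @export
dim.spectrum_stack <- function(x) dim(x$intensities)

#' Spectral channel bandwidth
#'
#' Width of one spectral channel, `(lambda_max - lambda_min) / n_channels`,
#' in nm.
#'
#' @param stack A [spectrum_stack()].
#' @return A single number (nm).
#' @export
channel_bandwidth <- function(stack) {
  stopifnot(inherits(stack, "spectrum_stack"))
  (stack$lambda_max - stack$lambda_min) / dim(stack$intensities)[3]
}

#' @export
as_tibble.spectrum_stack <- function(x, ...) {
  d <- dim(x$intensities)
  tidyr::expand_grid(
    row = seq_len(d[1]), col = seq_len(d[2]), channel = seq_len(d[3])
  ) |>
    dplyr::arrange(.data$channel, .data$col, .data$row) |>
    dplyr::mutate(
      wavelength = x$wavelengths[.data$channel],
      intensity = as.vector(x$intensities)
    ) |>
    dplyr::arrange(.data$row, .data$col, .data$channel)
}

#' Read a hyperspectral stack from a multi-channel TIFF
#'
#' Reads a TIFF in which each directory (page) holds one spectral channel,
#' plus a sidecar metadata file (YAML or JSON) giving `lambda_min`,
#' `lambda_max` and optionally `n_channels` and `scale` (counts per intensity
#' unit, applied to recover a photon-count scale from normalised TIFF data).
#'
#' @param tiff_path Path to the multi-channel TIFF.
#' @param meta_path Path to the YAML/JSON sidecar. If `NULL`, the default
#'   416-728 nm range is assumed.
#' @return A [spectrum_stack()].
#' @export
read_spectrum_stack <- function(tiff_path, meta_path = NULL) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(
    unlist(lapply(pages, as.numeric)),
    dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages))
  )
  meta <- list(lambda_min = 416, lambda_max = 728, scale = 1)
  if (!is.null(meta_path)) {
    parsed <- if (grepl("\\.json$", meta_path, ignore.case = TRUE)) {
      jsonlite::read_json(meta_path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(meta_path)
    }
    meta <- modifyList(meta, parsed)
  }
  if (!is.null(meta$n_channels) && meta$n_channels != dim(arr)[3]) {
    abort(sprintf(
      "Metadata declares %d channels but the TIFF holds %d.",
      meta$n_channels, dim(arr)[3]
    ))
  }
  spectrum_stack(
    arr * meta$scale,
    lambda_min = meta$lambda_min, lambda_max = meta$lambda_max
  )
}

#' Write a hyperspectral stack to TIFF + metadata sidecar
#'
#' Inverse of [read_spectrum_stack()]: one TIFF page per channel (intensities
#' rescaled to `[0, 1]`; the scale is recorded in the sidecar so reading is
#' lossless up to float precision) and a YAML sidecar with the wavelength
#' metadata.
#'
#' @param stack A [spectrum_stack()].
#' @param tiff_path,meta_path Output paths.
#' @return Invisibly, `tiff_path`.
#' @export
write_spectrum_stack <- function(stack, tiff_path, meta_path) {
  stopifnot(inherits(stack, "spectrum_stack"))
  top <- max(stack$intensities, 1)
  pages <- lapply(
    seq_len(dim(stack$intensities)[3]),
    function(k) stack$intensities[, , k] / top
  )
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(
    list(
      lambda_min = stack$lambda_min,
      lambda_max = stack$lambda_max,
      n_channels = dim(stack$intensities)[3],
      scale = top
    ),
    meta_path
  )
  invisible(tiff_path)
}
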