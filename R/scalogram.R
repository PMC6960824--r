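#' Continuous wavelet transform scalogram
#'
#' Computes the magnitude of the continuous wavelet transform of a motion
#' signal with an analytic Morlet (Gabor) wavelet on a logarithmic scale grid
#' with a fixed number of voices per octave. The transform is evaluated in
#' the frequency domain: the signal is zero-padded to the next power of two,
#' Fourier transformed once, multiplied by the dilated wavelet's spectrum
#' `pi^(-1/4) * exp(-(s*w - w0)^2 / 2)` (supported on positive frequencies
#' only, which is what makes the wavelet analytic) and inverse transformed
#' per scale. Scales map to pseudo-frequencies through the wavelet's peak
#' response, `f = w0 / (2 pi s)`.
#'
#' @param signal A `motion_signal`, or a numeric vector (then supply
#'   `sampling_rate`).
#' @param voices_per_octave Number of logarithmically spaced scales per
#'   frequency doubling (default 12).
#' @param freq_limits Length-2 `(fmin, fmax)` in Hz, within `(0, Nyquist]`.
#'   Default `c(1, 125)`: the analog band's lower edge up to Nyquist at
#'   250 samples/s.
#' @param omega0 Morlet centre frequency in rad (default 6, the standard
#'   admissibility-friendly choice).
#' @param sampling_rate Required for bare numeric input.
#' @return Object of class `scalogram`: `magnitudes` (matrix `n_scales x
#'   n_times`, rows ordered from the highest pseudo-frequency down), `scales`
#'   (seconds), `pseudo_frequencies` (Hz, strictly decreasing), `times` (s),
#'   `wavelet`, `voices_per_octave`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1 / 250))
#' sc <- compute_scalogram(x, sampling_rate = 250)
#' dim(sc$magnitudes)
#' @export
compute_scalogram <- function(signal,
                              voices_per_octave = 12,
                              freq_limits = c(1, 125),
                              omega0 = 6,
                              sampling_rate = NULL) {
  if (inherits(signal, "motion_signal")) {
    x <- signal$samples
    fs <- signal$sampling_rate
    rid <- signal$record_id
  } else {
    x <- as.numeric(signal)
    fs <- sampling_rate
    rid <- NULL
    if (is.null(fs)) stop("sampling_rate required for bare numeric input")
  }
  n <- length(x)
  if (n == 0) stop("empty signal")
  nyq <- fs / 2
  if (!(freq_limits[1] > 0 && freq_limits[1] < freq_limits[2] &&
    freq_limits[2] <= nyq)) {
    stop(
      "freq_limits (", freq_limits[1], ", ", freq_limits[2],
      ") must satisfy 0 < fmin < fmax <= Nyquist (", nyq, " Hz)"
    )
  }
  stopifnot(voices_per_octave >= 1)

  # Scale grid: voices_per_octave log-spaced frequencies per octave, from
  # fmax downward; n_scales = ceiling(vpo * log2(fmax / fmin)).
  n_scales <- ceiling(voices_per_octave * log2(freq_limits[2] / freq_limits[1]))
  freqs <- freq_limits[2] * 2^(-(seq_len(n_scales) - 1) / voices_per_octave)
  scales <- omega0 / (2 * pi * freqs)

  npad <- 2^ceiling(log2(n))
  xhat <- stats::fft(c(x, numeric(npad - n)))
  # Angular frequencies of the padded FFT grid (rad/s), positive half only.
  w <- 2 * pi * fs * (seq_len(npad) - 1) / npad
  pos <- w < pi * fs # strictly positive-frequency half (excl. Nyquist fold)
  wpos <- w[pos]

  mags <- matrix(0, nrow = n_scales, ncol = n)
  norm0 <- pi^(-1 / 4)
  for (k in seq_len(n_scales)) {
    s <- scales[k]
    daughter <- numeric(npad)
    daughter[pos] <- norm0 * exp(-((s * wpos - omega0)^2) / 2) *
      sqrt(2 * pi * s * fs)
    wk <- stats::fft(xhat * daughter, inverse = TRUE) / npad
    mags[k, ] <- Mod(wk[seq_len(n)])
  }
  structure(
    list(
      magnitudes = mags,
      scales = scales,
      pseudo_frequencies = freqs,
      times = (seq_len(n) - 1) / fs,
      wavelet = "analytic Morlet",
      voices_per_octave = voices_per_octave,
      omega0 = omega0,
      sampling_rate = fs,
      record_id = rid
    ),
    class = "scalogram"
  )
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf(
    "<scalogram> %s, %d scales x %d times, %.2f-%.2f Hz, %d voices/octave\n",
    x$wavelet, nrow(x$magnitudes), ncol(x$magnitudes),
    min(x$pseudo_frequencies), max(x$pseudo_frequencies),
    x$voices_per_octave
  ))
  invisible(x)
}

# MATLAB-style jet colormap evaluated at v in [0, 1]; returns n x 3 matrix.
jet_rgb <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  cbind(
    r = clamp01(1.5 - abs(4 * v - 3)),
    g = clamp01(1.5 - abs(4 * v - 2)),
    b = clamp01(1.5 - abs(4 * v - 1))
  )
}

#' Render a scalogram as an RGB image
#'
#' Converts scalogram magnitudes to the fixed-size RGB array consumed by the
#' classifier: per-image min-max normalization (optionally on a dB scale),
#' colormap lookup, then bilinear resize to the target size. Rows of the
#' output run from the highest pseudo-frequency at the top to the lowest at
#' the bottom; time increases left to right. A constant scalogram maps
#' uniformly to the colormap's lowest entry. The rendering is deterministic.
#'
#' @param scalogram A [compute_scalogram()] result.
#' @param size Length-2 output size (rows, cols); default `c(227, 227)`, the
#'   input size of the classifier.
#' @param colormap `"jet"` (MATLAB-style, default) or `"gray"`.
#' @param db Normalize on a decibel scale instead of linear magnitude.
#' @return Object of class `scalogram_image`: numeric array
#'   `size[1] x size[2] x 3` with finite values in `[0, 1]`; the source
#'   `record_id` is kept as an attribute.
#' @export
render_scalogram <- function(scalogram, size = c(227, 227),
                             colormap = c("jet", "gray"), db = FALSE) {
  stopifnot(inherits(scalogram, "scalogram"), length(size) == 2)
  colormap <- match.arg(colormap)
  m <- scalogram$magnitudes
  if (length(m) == 0) stop("empty scalogram")
  if (db) m <- 20 * log10(m + .Machine$double.eps)
  rng <- range(m)
  v <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  rgb <- if (colormap == "jet") jet_rgb(as.vector(v)) else cbind(v, v, v)
  out <- array(0, dim = c(size[1], size[2], 3))
  for (ch in 1:3) {
    plane <- matrix(rgb[, ch], nrow = nrow(m))
    out[, , ch] <- resize_bilinear(plane, size[1], size[2])
  }
  out <- pmin(pmax(out, 0), 1)
  structure(out,
    class = "scalogram_image",
    record_id = scalogram$record_id
  )
}

# Bilinear resize of a matrix to nr x nc (EBImage does the interpolation;
# EBImage images are indexed (x, y) so the matrix goes in transposed).
resize_bilinear <- function(m, nr, nc) {
  img <- EBImage::Image(t(m))
  res <- EBImage::resize(img, w = nc, h = nr, filter = "bilinear")
  t(EBImage::imageData(res))
}

#' @export
print.scalogram_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<scalogram_image> %d x %d x %d, values in [%.3f, %.3f]%s\n",
    d[1], d[2], d[3], min(x), max(x),
    if (!is.null(attr(x, "record_id"))) {
      paste0(" (", attr(x, "record_id"), ")")
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Write a scalogram image as an 8-bit PNG
#'
#' @param image A `scalogram_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scalogram_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG files")
  }
  arr <- unclass(image)
  png::writePNG(arr, target = path)
  invisible(path)
}
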