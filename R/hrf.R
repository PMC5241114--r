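#' Gamma hemodynamic response function
#'
#' Single-gamma impulse response linking neural activity to the BOLD signal,
#' peak-normalised so that the maximum of the kernel is 1. The default
#' (shape 6, scale 0.9 s) peaks at (shape - 1) * scale = 4.5 s after onset.
#'
#' @param t numeric vector of times in seconds (t < 0 gives 0).
#' @param shape gamma shape parameter (> 0).
#' @param scale gamma scale parameter in seconds (> 0).
#' @return numeric vector of the HRF evaluated at `t`.
#' @export
gamma_hrf <- function(t, shape = 6, scale = 0.9) {
  if (shape <= 0 || scale <= 0) {
    stop("HRF shape and scale must be positive", call. = FALSE)
  }
  h <- ifelse(t < 0, 0, stats::dgamma(t, shape = shape, scale = scale))
  peak <- stats::dgamma((shape - 1) * scale, shape = shape, scale = scale)
  h / peak
}

#' @rdname gamma_hrf
#' @export
hrf_params <- function(shape = 6, scale = 0.9) {
  if (shape <= 0 || scale <= 0) {
    stop("HRF shape and scale must be positive", call. = FALSE)
  }
  list(shape = shape, scale = scale)
}

# HRF kernel sampled on the fine dt grid, truncated at `span_s` seconds.
hrf_kernel <- function(hrf = hrf_params(), dt = 0.1, span_s = 30) {
  gamma_hrf(seq(0, span_s, by = dt), shape = hrf$shape, scale = hrf$scale)
}

# Linear convolution of a neural time course with the HRF kernel,
# truncated to the original length. Used for block designs, where the
# run genuinely starts from rest. FFT-based, padded to a composite length.
convolve_linear <- function(x, kernel) {
  n <- length(x); m <- length(kernel)
  len <- stats::nextn(n + m - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(len - n))) *
                       stats::fft(c(kernel, numeric(len - m))),
                     inverse = TRUE)) / len
  y[seq_len(n)]
}

# Circular convolution over the run. Phase-encoding runs cycle with no
# rest, so the steady-state (periodic) response is the appropriate model
# and makes lag shifts exact up to rotation.
convolve_circular <- function(x, kernel) {
  n <- length(x)
  k <- numeric(n)
  idx <- seq_len(min(length(kernel), n))
  k[idx] <- k[idx] + kernel[idx]
  if (length(kernel) > n) {
    # wrap the kernel tail (negligible for 30 s kernels on >30 s runs)
    extra <- kernel[-idx]
    pos <- ((seq_along(extra) + n - 1L) %% n) + 1L
    for (i in seq_along(extra)) k[pos[i]] <- k[pos[i]] + extra[i]
  }
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / n
}
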