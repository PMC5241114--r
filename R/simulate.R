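#' Noise model for simulated BOLD runs
#'
#' White Gaussian noise per vertex and timepoint plus a per-vertex linear
#' drift with slope drawn uniformly from `[-drift_range, drift_range]`
#' (expressed as percent signal change accrued over the whole run), with an
#' optional AR(1) coefficient on the noise.
#'
#' @param sd white-noise SD in percent signal change units.
#' @param drift_range maximal drift magnitude over the run, percent.
#' @param ar1 AR(1) coefficient in `[0, 1)` (0 = white noise).
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(sd = 1, drift_range = 0.5, ar1 = 0) {
  if (sd < 0) stop("noise sd must be non-negative", call. = FALSE)
  if (drift_range < 0) stop("drift_range must be non-negative", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)", call. = FALSE)
  structure(list(sd = sd, drift_range = drift_range, ar1 = ar1),
            class = "noise_spec")
}

new_voxel_time_series <- function(data, design, subject_id = NA, session = NA) {
  stopifnot(ncol(data) == design$n_timepoints, !anyNA(data))
  structure(list(data = data, tr_s = design$tr_s, design = design,
                 subject_id = subject_id, session = session),
            class = "voxel_time_series")
}

#' @export
print.voxel_time_series <- function(x, ...) {
  cat(sprintf("<voxel_time_series> %d vertices x %d timepoints (%s, TR %.2f s)\n",
              nrow(x$data), ncol(x$data), x$design$kind, x$tr_s))
  invisible(x)
}

simulate_bold_run <- function(sheet, design, noise, seed) {
  amps <- tuning_amplitudes(sheet)                      # V x 4
  regs <- digit_regressors(design)                      # 4 x T
  signal <- amps %*% regs                               # V x T, percent units
  v <- nrow(signal); tt <- ncol(signal)
  set.seed(seed)
  eps <- matrix(stats::rnorm(v * tt, 0, noise$sd), v, tt)
  if (noise$ar1 > 0) {
    for (k in 2:tt) eps[, k] <- noise$ar1 * eps[, k - 1] +
        sqrt(1 - noise$ar1^2) * eps[, k]
  }
  slope <- stats::runif(v, -noise$drift_range, noise$drift_range)
  drift <- outer(slope, seq(0, 1, length.out = tt))
  new_voxel_time_series(100 + signal + eps + drift, design,
                        subject_id = sheet$subject_id, session = sheet$session)
}

#' Simulate a phase-encoding (travelling-wave) BOLD run
#'
#' Each vertex's noiseless signal is the sum over digits of its Gaussian
#' tuning amplitude times the HRF-convolved boxcar of that digit's blocks,
#' built at 0.1 s resolution (periodic steady state) and sampled at the TR.
#' White noise and a linear drift are added on top of a baseline of 100.
#'
#' @param sheet a `ground_truth_sheet`.
#' @param design a [task_design()] with phase kind.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @return a `voxel_time_series`.
#' @export
simulate_phase_run <- function(sheet, design = task_design("phase_forward"),
                               noise = noise_spec(), seed = 1L) {
  if (!is_phase_design(design)) {
    stop("design must be phase_forward or phase_backward", call. = FALSE)
  }
  simulate_bold_run(sheet, design, noise, seed)
}

#' Simulate a block-design BOLD run
#'
#' As [simulate_phase_run()] but with 12 s movement blocks alternating with
#' 12 s rest (4 blocks per digit, 256 timepoints at TR 1.5 s) and linear
#' (non-periodic) HRF convolution.
#'
#' @inheritParams simulate_phase_run
#' @export
simulate_block_run <- function(sheet, design = task_design("block"),
                               noise = noise_spec(), seed = 1L) {
  if (design$kind != "block") stop("design must be a block design", call. = FALSE)
  simulate_bold_run(sheet, design, noise, seed)
}
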