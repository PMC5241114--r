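`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lag-shifted reference model for travelling-wave analysis
#'
#' The reference is a boxcar with one 8 s 'on' period per 32 s digit cycle
#' ('off' for the remaining 24 s), repeated for all 8 cycles, circularly
#' shifted by `lag_s`, convolved with the gamma HRF and sampled at the TR
#' grid. The sampled model is standardised to zero mean and unit variance.
#'
#' @param design a phase-encoding [task_design()].
#' @param hrf [hrf_params()].
#' @param lag_s shift in seconds, `0 <= lag_s < 32`.
#' @param dt fine grid resolution in seconds.
#' @return object of class `reference_model` with `$values` (length
#'   `design$n_timepoints`), `$lag_s`, `$on_s`, `$off_s`, `$n_cycles`.
#' @export
build_reference_model <- function(design = task_design("phase_forward"),
                                  hrf = hrf_params(), lag_s = 0, dt = 0.1) {
  if (!is_phase_design(design)) {
    stop("reference models apply to phase-encoding designs", call. = FALSE)
  }
  cycle <- design$cycle_s
  lag_s <- lag_s %% cycle
  n_dt <- as.integer(round(design$duration_s / dt))
  t_fine <- (seq_len(n_dt) - 1) * dt
  # 'on' during [lag, lag + 8) of each cycle, wrapping at the cycle edge
  phase <- (t_fine - lag_s) %% cycle
  box <- as.numeric(phase < design$block_s)
  resp <- convolve_circular(box, hrf_kernel(hrf, dt))
  idx <- as.integer(round(((seq_len(design$n_timepoints) - 1) * design$tr_s) / dt)) + 1L
  vals <- resp[idx]
  vals <- (vals - mean(vals)) / stats::sd(vals)
  structure(list(values = vals, lag_s = lag_s, on_s = design$block_s,
                 off_s = cycle - design$block_s, n_cycles = design$n_cycles,
                 tr_s = design$tr_s, hrf = hrf),
            class = "reference_model")
}

#' Voxelwise lag cross-correlation stack
#'
#' Builds reference models at every lag on a grid covering the full 32 s
#' digit cycle and computes the Pearson correlation between each vertex's
#' (linearly detrended) BOLD series and each lagged model. Zero-variance
#' vertices are flagged and their correlations set to 0.
#'
#' @param ts a `voxel_time_series` from a phase-encoding run.
#' @param hrf [hrf_params()].
#' @param lag_step_s lag grid step in seconds; must divide the 32 s cycle.
#' @param detrend remove per-vertex intercept and linear trend first.
#' @return object of class `lag_correlation_stack`: `$r` (vertices x lags),
#'   `$lags_s`, `$valid` (logical per vertex), `$n_timepoints`, `$design`.
#' @export
compute_lag_correlation_stack <- function(ts, hrf = hrf_params(),
                                          lag_step_s = 1, detrend = TRUE) {
  stopifnot(inherits(ts, "voxel_time_series"))
  if (!is_phase_design(ts$design)) {
    stop("time series does not come from a phase-encoding design", call. = FALSE)
  }
  if (!all(is.finite(ts$data))) stop("non-finite BOLD data", call. = FALSE)
  cycle <- ts$design$cycle_s
  if (abs(cycle / lag_step_s - round(cycle / lag_step_s)) > 1e-9) {
    stop("lag_step_s must divide the 32 s digit cycle", call. = FALSE)
  }
  lags <- seq(0, cycle - lag_step_s, by = lag_step_s)
  key <- paste("refs", ts$design$kind, ts$design$tr_s, hrf$shape, hrf$scale,
               lag_step_s, sep = "|")
  refs <- .regressor_cache[[key]]
  if (is.null(refs)) {
    refs <- vapply(lags, function(l) {
      build_reference_model(ts$design, hrf, lag_s = l)$values
    }, numeric(ts$design$n_timepoints))            # T x L
    .regressor_cache[[key]] <- refs
  }
  x <- t(ts$data)                                  # T x V
  if (detrend) {
    tt <- seq_len(nrow(x))
    x <- stats::lm.fit(cbind(1, tt), x)$residuals
  }
  sds <- apply(x, 2, stats::sd)
  valid <- sds > 1e-12
  r <- matrix(0, ncol(x), length(lags))
  if (any(valid)) {
    r[valid, ] <- stats::cor(x[, valid, drop = FALSE], refs)
  }
  structure(list(r = r, lags_s = lags, valid = valid,
                 n_timepoints = ts$design$n_timepoints, design = ts$design),
            class = "lag_correlation_stack")
}

# Digit (2..5) owning each lag: the shifted 'on' window covers
# [lag, lag + on_s) of the cycle; its centre is assigned to the digit whose
# block contains it, boundary centres tie-broken toward the earlier digit.
lag_digit_assignment <- function(lags_s, design) {
  centre <- (lags_s + design$block_s / 2 - 1e-9) %% design$cycle_s
  block_idx <- floor(centre / design$block_s) + 1L
  design$digit_order[block_idx]
}

#' Per-digit r-maps from a lag correlation stack
#'
#' Averages the r-values over the lags assigned to each digit (by the
#' centre of the shifted 'on' window within the design's digit cycle),
#' yielding one r-map per digit. Every lag belongs to exactly one digit.
#'
#' @param stack a [compute_lag_correlation_stack()] result.
#' @param design the phase design (defaults to the stack's own design).
#' @return a vertices x 4 matrix with columns D2..D5.
#' @export
digit_rmaps_from_stack <- function(stack, design = stack$design) {
  digit <- lag_digit_assignment(stack$lags_s, design)
  out <- vapply(2:5, function(d) {
    rowMeans(stack$r[, digit == d, drop = FALSE])
  }, numeric(nrow(stack$r)))
  colnames(out) <- DIGITS
  out
}

#' Combine forward and backward r-maps
#'
#' Elementwise mean of the forward- and backward-run digit r-maps, the
#' direction-combined digit representation.
#'
#' @param fwd_rmaps,bwd_rmaps vertices x 4 matrices with columns D2..D5.
#' @return vertices x 4 matrix.
#' @export
combine_directions <- function(fwd_rmaps, bwd_rmaps) {
  if (!identical(dim(fwd_rmaps), dim(bwd_rmaps))) {
    stop("forward and backward maps have different shapes", call. = FALSE)
  }
  (fwd_rmaps + bwd_rmaps) / 2
}

#' Fisher z-statistic maps from r-maps
#'
#' z = atanh(r) * sqrt(n - 3), monotone in r for fixed n. Correlations at
#' |r| = 1 are capped just below 1 (yielding a large finite z) and flagged.
#'
#' @param rmaps vertices x digits matrix of correlations.
#' @param n_timepoints number of samples behind each correlation (> 3).
#' @return matrix of z-statistics with attribute `capped` (logical matrix).
#' @export
rmap_to_zmap <- function(rmaps, n_timepoints) {
  if (n_timepoints <= 3) stop("need more than 3 timepoints", call. = FALSE)
  capped <- abs(rmaps) >= 1 - 1e-12
  r <- pmin(pmax(rmaps, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r) * sqrt(n_timepoints - 3)
  attr(z, "capped") <- capped
  z
}

#' FDR-threshold and binarise digit z-maps
#'
#' Within the ROI, converts each digit's z-map to two-sided normal p-values,
#' applies Benjamini-Hochberg FDR at level `alpha` separately per digit, and
#' binarises. Only positively responding vertices (z > 0) enter a digit's
#' binary map; a vertex may survive in several digit maps (overlap is the
#' quantity of interest).
#'
#' @param zmaps vertices x digits z matrix.
#' @param roi_mask logical per vertex (matrix or vector).
#' @param alpha FDR level.
#' @return logical vertices x digits matrix (FALSE outside the ROI).
#' @export
threshold_digit_maps <- function(zmaps, roi_mask, alpha = 0.01) {
  roi <- as.vector(roi_mask)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  out <- matrix(FALSE, nrow(zmaps), ncol(zmaps),
                dimnames = dimnames(zmaps))
  for (d in seq_len(ncol(zmaps))) {
    z <- zmaps[roi, d]
    p_adj <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = "BH")
    out[roi, d] <- p_adj <= alpha & z > 0
  }
  out
}

#' Travelling-wave digit maps for one subject and session
#'
#' Convenience wrapper running the full phase-encoding analysis: lag
#' correlation stacks for the forward and backward runs, per-digit r-map
#' averaging, direction combination, Fisher z conversion (n = total
#' timepoints across both runs) and FDR binarisation within the ROI.
#'
#' @param ts_fwd,ts_bwd forward/backward `voxel_time_series`.
#' @param roi_mask logical ROI per vertex.
#' @param hrf [hrf_params()].
#' @param lag_step_s lag grid step, seconds.
#' @param alpha FDR level.
#' @return a `digit_map_stack`: `$r_maps`, `$z_maps`, `$binary_maps`,
#'   `$threshold_alpha`, `$n_samples`.
#' @export
map_digits <- function(ts_fwd, ts_bwd, roi_mask, hrf = hrf_params(),
                       lag_step_s = 1, alpha = 0.01) {
  stack_f <- compute_lag_correlation_stack(ts_fwd, hrf, lag_step_s)
  stack_b <- compute_lag_correlation_stack(ts_bwd, hrf, lag_step_s)
  rmaps <- combine_directions(digit_rmaps_from_stack(stack_f),
                              digit_rmaps_from_stack(stack_b))
  n <- stack_f$n_timepoints + stack_b$n_timepoints
  zmaps <- rmap_to_zmap(rmaps, n)
  structure(list(r_maps = rmaps, z_maps = zmaps,
                 binary_maps = threshold_digit_maps(zmaps, roi_mask, alpha),
                 threshold_alpha = alpha, n_samples = n),
            class = "digit_map_stack")
}
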