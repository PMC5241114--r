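DIGITS <- c("D2", "D3", "D4", "D5")
SESSIONS <- c("control1", "control2", "glued")
DIGIT_PAIRS <- c("D2-D3", "D3-D4", "D4-D5")

#' Task design for a simulated fMRI run
#'
#' Three designs are supported. Phase-encoding (travelling-wave) designs
#' cycle continuously through 8 s blocks of movement of each digit with no
#' rest, for 8 cycles: forward order D2,D3,D4,D5, backward order D5,D4,D3,D2
#' (32 s cycle, 256 s run). The block design alternates 12 s movement
#' blocks with 12 s rest blocks, 4 blocks per digit (16 movement + 16 rest
#' blocks, 384 s run).
#'
#' @param kind one of `"phase_forward"`, `"phase_backward"`, `"block"`.
#' @param tr_s repetition time in seconds.
#' @param block_order for `kind = "block"`, an integer vector of length 16
#'   giving the digit (2..5) moved in each movement block; each digit must
#'   appear exactly 4 times. Default is a balanced latin-square-style order.
#' @return an object of class `task_design`.
#' @export
task_design <- function(kind = c("phase_forward", "phase_backward", "block"),
                        tr_s = 1.5, block_order = NULL) {
  kind <- match.arg(kind)
  if (tr_s <= 0) stop("tr_s must be positive", call. = FALSE)
  if (kind == "block") {
    if (is.null(block_order)) {
      block_order <- c(2, 3, 4, 5, 3, 5, 2, 4, 4, 2, 5, 3, 5, 4, 3, 2)
    }
    if (length(block_order) != 16 ||
        !all(sort(tabulate(block_order, 5)[2:5]) == 4)) {
      stop("block_order must contain each digit 2..5 exactly 4 times",
           call. = FALSE)
    }
    d <- list(kind = kind, block_s = 12, rest_s = 12, blocks_per_digit = 4,
              tr_s = tr_s, digit_order = block_order,
              duration_s = 16 * 12 + 16 * 12)
  } else {
    order <- if (kind == "phase_forward") c(2, 3, 4, 5) else c(5, 4, 3, 2)
    d <- list(kind = kind, block_s = 8, n_cycles = 8, tr_s = tr_s,
              digit_order = order, cycle_s = 4 * 8,
              duration_s = 4 * 8 * 8)
  }
  d$n_timepoints <- as.integer(floor(d$duration_s / tr_s + 1e-9))
  class(d) <- "task_design"
  d
}

is_phase_design <- function(design) {
  design$kind %in% c("phase_forward", "phase_backward")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> %s: %d s, TR %.2f s, %d timepoints\n",
              x$kind, x$duration_s, x$tr_s, x$n_timepoints))
  invisible(x)
}

# Neural indicator time courses at fine resolution: a digits x n_dt matrix
# of 0/1 boxcars (rows named D2..D5). dt is the fine grid step in seconds.
neural_boxcars <- function(design, dt = 0.1) {
  n_dt <- as.integer(round(design$duration_s / dt))
  t_fine <- (seq_len(n_dt) - 1) * dt
  out <- matrix(0, nrow = 4, ncol = n_dt, dimnames = list(DIGITS, NULL))
  if (is_phase_design(design)) {
    within <- t_fine %% design$cycle_s
    block_idx <- pmin(floor(within / design$block_s) + 1, 4)
    digit <- design$digit_order[block_idx]
    for (d in 2:5) out[d - 1L, digit == d] <- 1
  } else {
    # movement block b occupies [ (b-1)*24, (b-1)*24 + 12 ), rest follows
    for (b in seq_along(design$digit_order)) {
      on <- t_fine >= (b - 1) * (design$block_s + design$rest_s) &
        t_fine < (b - 1) * (design$block_s + design$rest_s) + design$block_s
      out[design$digit_order[b] - 1L, on] <- 1
    }
  }
  out
}

.regressor_cache <- new.env(parent = emptyenv())

# HRF-convolved digit regressors sampled at the TR grid: digits x T matrix.
# Memoised: designs recur thousands of times across a simulated cohort.
digit_regressors <- function(design, hrf = hrf_params(), dt = 0.1) {
  key <- paste(design$kind, design$tr_s, paste(design$digit_order,
                                               collapse = ""),
               hrf$shape, hrf$scale, dt, sep = "|")
  hit <- .regressor_cache[[key]]
  if (!is.null(hit)) return(hit)
  boxes <- neural_boxcars(design, dt)
  kernel <- hrf_kernel(hrf, dt)
  conv <- if (is_phase_design(design)) {
    t(apply(boxes, 1, convolve_circular, kernel = kernel))
  } else {
    t(apply(boxes, 1, convolve_linear, kernel = kernel))
  }
  idx <- as.integer(round(((seq_len(design$n_timepoints) - 1) * design$tr_s) / dt)) + 1L
  out <- conv[, idx, drop = FALSE]
  .regressor_cache[[key]] <- out
  out
}
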