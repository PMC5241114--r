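#' Fit a logistic psychometric function to TOJ data
#'
#' Binomial maximum-likelihood fit of
#' `P(right first) = 1 / (1 + exp(-(ISI - pse) / s))` to the per-ISI
#' proportions of "right first" responses (a logistic regression of the
#' response on the signed ISI). The just-noticeable difference is
#' `jnd = s * log(3)`, i.e. half the ISI spread between the 25% and 75%
#' points of the fitted curve. Goodness of fit is reported as the squared
#' Pearson correlation between observed and fitted per-ISI proportions.
#' Fits are flagged non-converged on perfect separation (all responses
#' identical, or identical within sign), glm non-convergence, or a
#' non-positive fitted slope.
#'
#' @param run data frame with columns `isi_ms` and `right_first` (0/1), or
#'   aggregated columns `isi_ms`, `n_trials`, `n_right_first`.
#' @return a `psychometric_fit`: `pse_ms`, `slope_ms`, `jnd_ms`,
#'   `r_squared`, `converged`, `n_trials`, plus the per-ISI table.
#' @export
fit_psychometric <- function(run) {
  if (all(c("n_trials", "n_right_first") %in% names(run))) {
    tab <- run[, c("isi_ms", "n_trials", "n_right_first")]
  } else {
    stopifnot(all(c("isi_ms", "right_first") %in% names(run)))
    agg <- stats::aggregate(right_first ~ isi_ms, run,
                            function(x) c(n = length(x), k = sum(x)))
    tab <- data.frame(isi_ms = agg$isi_ms,
                      n_trials = agg$right_first[, "n"],
                      n_right_first = agg$right_first[, "k"])
  }
  tab <- tab[order(tab$isi_ms), ]
  if (nrow(tab) < 4) stop("need at least 4 distinct ISIs", call. = FALSE)
  prop <- tab$n_right_first / tab$n_trials
  out <- list(pse_ms = NA_real_, slope_ms = NA_real_, jnd_ms = NA_real_,
              r_squared = NA_real_, converged = FALSE,
              n_trials = sum(tab$n_trials), isi_table = tab)
  class(out) <- "psychometric_fit"
  if (all(tab$n_right_first == 0) || all(tab$n_right_first == tab$n_trials)) {
    return(out)   # perfect separation: no finite ML estimate
  }
  fit <- suppressWarnings(
    stats::glm(cbind(n_right_first, n_trials - n_right_first) ~ isi_ms,
               family = stats::binomial(), data = tab))
  b <- stats::coef(fit)
  fitted_p <- stats::fitted(fit)
  ok <- fit$converged && is.finite(b[2]) && b[2] > 0 &&
    stats::sd(fitted_p) > 1e-12
  out$r_squared <- if (stats::sd(fitted_p) > 1e-12 && stats::sd(prop) > 1e-12) {
    stats::cor(prop, fitted_p)^2
  } else 0
  if (!ok) return(out)
  out$slope_ms <- 1 / b[[2]]
  out$pse_ms <- -b[[1]] / b[[2]]
  out$jnd_ms <- out$slope_ms * log(3)
  out$converged <- TRUE
  out
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<psychometric_fit> pse %.1f ms, jnd %.1f ms, R^2 %.3f\n",
                x$pse_ms, x$jnd_ms, x$r_squared))
  } else {
    cat("<psychometric_fit> non-converged\n")
  }
  invisible(x)
}

#' Just-noticeable difference from a psychometric fit
#'
#' `jnd = s * log(3)`: half of the ISI difference between the 75% and 25%
#' points of the fitted logistic.
#'
#' @param fit a converged [fit_psychometric()] result.
#' @return JND in ms.
#' @export
jnd_from_fit <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged) stop("fit did not converge: no JND", call. = FALSE)
  fit$slope_ms * log(3)
}

#' Exclude subjects with poor psychometric fits
#'
#' A subject is removed entirely (complete-case repeated-measures design)
#' if any of their session-by-pair fits is non-converged or has
#' `R^2 < r2_min`.
#'
#' @param fits data frame with columns `subject`, `session`, `digit_pair`,
#'   `jnd_ms`, `r_squared`, `converged`.
#' @param r2_min goodness-of-fit threshold.
#' @return list `kept` (filtered data frame), `excluded_subjects`,
#'   `exclusion_log` (offending rows).
#' @export
exclude_poor_fits <- function(fits, r2_min = 0.4) {
  bad_row <- !fits$converged | is.na(fits$r_squared) | fits$r_squared < r2_min
  excluded <- sort(unique(fits$subject[bad_row]))
  if (length(excluded) > 0) {
    message("excluding subject(s) ", paste(excluded, collapse = ", "),
            " for poor psychometric fits (R^2 < ", r2_min, " or non-converged)")
  }
  list(kept = fits[!fits$subject %in% excluded, , drop = FALSE],
       excluded_subjects = excluded,
       exclusion_log = fits[bad_row, , drop = FALSE])
}

#' Score a motor-confusion run
#'
#' Tallies responses falling within the response window into a 4x4 target
#' by response count matrix, counts mis-presses for each adjacent digit
#' pair (presses of d+1 when d was cued plus presses of d when d+1 was
#' cued), and accounts for omissions (no in-window press) and late presses.
#'
#' @param trials data frame `block`, `target`, `response`, `rt_ms`
#'   (`response` may be `NA` for absent presses).
#' @param window_ms response window, ms.
#' @return a `confusion_summary`: `$matrix` (4x4 in-window counts),
#'   `$mispress` (data frame per adjacent pair: total count and per-block
#'   mean), `$n_omission`, `$n_late`, `$n_cues`, `$n_blocks`.
#' @export
score_confusion <- function(trials, window_ms = 700) {
  resp_ok <- !is.na(trials$response)
  if (any(!trials$response[resp_ok] %in% 2:5)) {
    stop("response digits must lie in 2..5", call. = FALSE)
  }
  in_win <- resp_ok & !is.na(trials$rt_ms) & trials$rt_ms <= window_ms
  late <- resp_ok & !is.na(trials$rt_ms) & trials$rt_ms > window_ms
  m <- matrix(0L, 4, 4, dimnames = list(DIGITS, DIGITS))
  tab <- table(factor(trials$target[in_win], levels = 2:5),
               factor(trials$response[in_win], levels = 2:5))
  m[] <- as.integer(tab)
  n_blocks <- length(unique(trials$block))
  mis <- data.frame(
    digit_pair = DIGIT_PAIRS,
    count = vapply(1:3, function(i) m[i, i + 1] + m[i + 1, i], numeric(1)))
  mis$per_block <- mis$count / n_blocks
  structure(list(matrix = m, mispress = mis,
                 n_omission = sum(!in_win & !late),
                 n_late = sum(late), n_cues = nrow(trials),
                 n_blocks = n_blocks),
            class = "confusion_summary")
}
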