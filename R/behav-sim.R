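#' Default inter-stimulus intervals for the temporal order judgment task
#'
#' Six symmetric ISI magnitudes presented in both orders (positive = the
#' right-most digit of the pair stimulated first), each repeated 16 times
#' per run (192 trials).
#' @export
TOJ_ISIS_MS <- c(-400, -250, -180, -120, -70, -30, 30, 70, 120, 180, 250, 400)

#' Logistic observer specification for the TOJ task
#'
#' The observer answers "right first" with probability
#' `lapse + (1 - 2 * lapse) * plogis((isi - pse) / s)` where
#' `s = jnd / log(3)`, so that the fitted just-noticeable difference (half
#' the 25-75% ISI spread) equals `true_jnd_ms`.
#'
#' @param pse_ms point of subjective equality, ms.
#' @param true_jnd_ms generative JND, ms (> 0); `Inf` gives a flat observer
#'   answering at chance for every ISI.
#' @param lapse_rate lapse probability in `[0, 0.05]`.
#' @return a `toj_observer` list.
#' @export
toj_observer <- function(pse_ms = 0, true_jnd_ms = 60, lapse_rate = 0.01) {
  if (!is.infinite(true_jnd_ms) && true_jnd_ms <= 0) {
    stop("true_jnd_ms must be positive", call. = FALSE)
  }
  if (lapse_rate < 0 || lapse_rate > 0.05) {
    stop("lapse_rate must lie in [0, 0.05]", call. = FALSE)
  }
  structure(list(pse_ms = pse_ms, true_jnd_ms = true_jnd_ms,
                 lapse_rate = lapse_rate), class = "toj_observer")
}

#' Simulate one TOJ run
#'
#' Draws Bernoulli "right first" responses from the logistic observer at
#' every scheduled ISI, with the trial order randomised by the seed.
#'
#' @param observer a [toj_observer()].
#' @param isi_schedule vector of signed ISIs in ms, one entry per trial;
#'   default is the 12 standard ISIs x 16 repetitions.
#' @param seed integer seed.
#' @return data frame with columns `trial`, `isi_ms`, `right_first`.
#' @export
simulate_toj_run <- function(observer, isi_schedule = rep(TOJ_ISIS_MS, 16),
                             seed = 1L) {
  if (length(isi_schedule) == 0) stop("empty ISI schedule", call. = FALSE)
  set.seed(seed)
  isi <- sample(isi_schedule)
  p <- if (is.infinite(observer$true_jnd_ms)) {
    rep(0.5, length(isi))
  } else {
    s <- observer$true_jnd_ms / log(3)
    observer$lapse_rate +
      (1 - 2 * observer$lapse_rate) * stats::plogis((isi - observer$pse_ms) / s)
  }
  data.frame(trial = seq_along(isi), isi_ms = isi,
             right_first = as.integer(stats::rbinom(length(isi), 1, p)))
}

#' Digit-confusion specification for the motor confusion task
#'
#' A 4x4 row-stochastic matrix of response probabilities
#' P(response digit | target digit), rows and columns ordered D2..D5, with
#' a diagonal-dominant structure, plus the probability that a press lands
#' outside the 700 ms response window.
#'
#' @param matrix 4x4 row-stochastic, diagonal-dominant matrix.
#' @param omission_rate probability a press misses the response window.
#' @return a `confusion_spec`.
#' @export
confusion_spec <- function(matrix = default_confusion_matrix(),
                           omission_rate = 0.05) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4, 4)) || any(matrix < 0) ||
      any(abs(rowSums(matrix) - 1) > 1e-8)) {
    stop("confusion matrix must be 4x4 row-stochastic", call. = FALSE)
  }
  if (any(diag(matrix) < apply(matrix - diag(diag(matrix)), 1, max))) {
    stop("confusion matrix must be diagonal dominant", call. = FALSE)
  }
  if (omission_rate < 0 || omission_rate >= 1) {
    stop("omission_rate must lie in [0, 1)", call. = FALSE)
  }
  dimnames(matrix) <- list(DIGITS, DIGITS)
  structure(list(matrix = matrix, omission_rate = omission_rate),
            class = "confusion_spec")
}

#' @rdname confusion_spec
#' @param adjacent probability of pressing an adjacent digit instead of the
#'   cued one (per neighbour).
#' @param far probability of pressing a non-adjacent digit (per digit).
#' @param d4d5_boost extra probability added symmetrically to the D4<->D5
#'   confusions (the planted glued-session effect), taken from the diagonal.
#' @export
default_confusion_matrix <- function(adjacent = 0.03, far = 0.005,
                                     d4d5_boost = 0) {
  m <- matrix(far, 4, 4, dimnames = list(DIGITS, DIGITS))
  for (i in 1:3) m[i, i + 1] <- m[i + 1, i] <- adjacent
  m["D4", "D5"] <- m["D4", "D5"] + d4d5_boost
  m["D5", "D4"] <- m["D5", "D4"] + d4d5_boost
  diag(m) <- 0
  diag(m) <- 1 - rowSums(m)
  m
}

# Cue sequence with no immediate repeats and near-balanced ordered
# adjacent pairings: an Eulerian circuit over the complete digraph on
# {2,3,4,5} with every ordered pair repeated floor((n-1)/12) times
# (Hierholzer), topped up with no-repeat random cues.
confusion_cue_sequence <- function(n_cues, seed = 1L) {
  set.seed(seed)
  digits <- 2:5
  m <- max((n_cues - 1) %/% 12, 0)
  seq_out <- integer(0)
  if (m > 0) {
    pairs <- expand.grid(from = digits, to = digits)
    pairs <- pairs[pairs$from != pairs$to, ]
    edges <- pairs[rep(seq_len(nrow(pairs)), m), ]
    # Hierholzer on the balanced multigraph (in-degree = out-degree)
    adj <- lapply(digits, function(d) sample(edges$to[edges$from == d]))
    names(adj) <- as.character(digits)
    stack <- c(sample(digits, 1))
    circuit <- integer(0)
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      key <- as.character(v)
      if (length(adj[[key]]) > 0) {
        u <- adj[[key]][1]
        adj[[key]] <- adj[[key]][-1]
        stack <- c(stack, u)
      } else {
        circuit <- c(circuit, v)
        stack <- stack[-length(stack)]
      }
    }
    seq_out <- rev(circuit)
  }
  while (length(seq_out) < n_cues) {
    prev <- if (length(seq_out) > 0) seq_out[length(seq_out)] else 0L
    seq_out <- c(seq_out, sample(setdiff(digits, prev), 1))
  }
  seq_out[seq_len(n_cues)]
}

#' Simulate a motor-confusion run
#'
#' Cues are issued every 700 ms in blocks of 210 presses (4 blocks by
#' default). The cue sequence has no immediate repeats and balanced ordered
#' adjacent pairings. Each cue draws a response digit from the confusion
#' matrix row of the target; with probability `omission_rate` the press
#' falls beyond the 700 ms window (drawn in (700, 1200] ms), otherwise the
#' response time is uniform in [250, 650] ms.
#'
#' @param spec a [confusion_spec()].
#' @param n_blocks number of blocks of 210 cues.
#' @param cues_per_block cues per block.
#' @param seed integer seed.
#' @return data frame `block`, `trial`, `target`, `response`, `rt_ms`.
#' @export
simulate_confusion_run <- function(spec, n_blocks = 4, cues_per_block = 210,
                                   seed = 1L) {
  stopifnot(inherits(spec, "confusion_spec"))
  out <- lapply(seq_len(n_blocks), function(b) {
    targets <- confusion_cue_sequence(cues_per_block,
                                      seed = (seed + 7919 * b) %% 2147483647)
    set.seed((seed + 104729 * b) %% 2147483647)
    resp <- vapply(targets, function(d) {
      sample(2:5, 1, prob = spec$matrix[d - 1L, ])
    }, integer(1))
    late <- stats::runif(length(targets)) < spec$omission_rate
    rt <- ifelse(late, stats::runif(length(targets), 700.001, 1200),
                 stats::runif(length(targets), 250, 650))
    data.frame(block = b, trial = seq_along(targets), target = targets,
               response = resp, rt_ms = rt)
  })
  do.call(rbind, out)
}
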