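#' Cohort specification for the synthetic study
#'
#' Defines the full generative model of the study: 9 subjects, three
#' sessions (control1, control2, glued) in counterbalanced order (order A:
#' controls first, n = floor(n/2); order B: glued first, the rest), per
#' subject and session two phase-encoding runs (forward and backward), one
#' block-design run, one TOJ run per adjacent digit pair, and one motor
#' confusion run. Glued sessions carry the planted remapping: the D4
#' tuning centre displaced toward D5 at constant tuning width, the D4-D5
#' JND inflated and the D3-D4 JND reduced, and the D4<->D5 confusion
#' probability boosted.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed master seed; every run's sub-seed derives from it.
#' @param sheet a [sheet_spec()] shared by the cohort.
#' @param noise a [noise_spec()] for the BOLD runs.
#' @param d4_shift_mm planted glued-session D4 displacement toward D5, mm.
#' @param centre_jitter_sd_mm between-session jitter of all centres, mm.
#' @param subject_centre_sd_mm between-subject jitter of all centres, mm.
#' @param toj_base_jnd_ms baseline generative JND, ms.
#' @param toj_glued_multipliers length-3 multiplier on the glued-session
#'   JND for pairs D2-D3, D3-D4, D4-D5.
#' @param toj_subject_cv,toj_session_cv lognormal coefficients of variation
#'   of the JND across subjects and sessions.
#' @param toj_pse_sd_ms SD of the point of subjective equality, ms.
#' @param toj_lapse lapse rate of the simulated observers.
#' @param flat_toj_subject optional subject index answering at chance for
#'   all pairs in one session (control2), the planted poor-fit case.
#' @param confusion_adjacent,confusion_far baseline mis-press probabilities.
#' @param confusion_d4d5_boost extra glued-session D4<->D5 confusion.
#' @param confusion_omission probability a press misses the 700 ms window.
#' @param confusion_blocks,confusion_cues_per_block run size.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 9, seed = 1L,
                        sheet = sheet_spec(), noise = noise_spec(),
                        d4_shift_mm = 3, centre_jitter_sd_mm = 0.5,
                        subject_centre_sd_mm = 1,
                        toj_base_jnd_ms = 60,
                        toj_glued_multipliers = c(1, 0.7, 1.4),
                        toj_subject_cv = 0.15, toj_session_cv = 0.08,
                        toj_pse_sd_ms = 10, toj_lapse = 0.01,
                        flat_toj_subject = NULL,
                        confusion_adjacent = 0.03, confusion_far = 0.005,
                        confusion_d4d5_boost = 0.05,
                        confusion_omission = 0.05,
                        confusion_blocks = 4, confusion_cues_per_block = 210) {
  if (n_subjects < 2) stop("n_subjects must be at least 2", call. = FALSE)
  spec <- as.list(environment())
  spec$order <- rep(c("A", "B"),
                    c(floor(n_subjects / 2), ceiling(n_subjects / 2)))
  class(spec) <- "cohort_spec"
  spec
}

# Deterministic sub-seed derivation: one master seed, mixed with fixed
# per-subject / per-session / per-run indices through an avalanching
# integer hash (xor-shift + odd-multiplier rounds, all exact in doubles,
# kept below 2^31) so that nearby master seeds yield unrelated sub-seeds.
derive_seed <- function(master, ...) {
  mix <- function(x) {
    x <- bitwXor(as.integer(x), bitwShiftR(as.integer(x), 15))
    x <- (as.double(x) * 2097143) %% 2147483647
    x <- bitwXor(as.integer(x), bitwShiftR(as.integer(x), 13))
    (as.double(x) * 1597 + 871) %% 2147483647
  }
  x <- mix(as.double(master) %% 2147483647)
  for (idx in c(...)) {
    x <- mix((x + as.double(idx) * 51749) %% 2147483647)
  }
  as.integer(x)
}

session_index <- function(session) match(session, SESSIONS)

# Subject-level generative parameters (fixed across sessions).
subject_params <- function(spec, subject) {
  set.seed(derive_seed(spec$seed, subject, 900))
  centres <- spec$sheet$digit_centres +
    stats::rnorm(4, 0, spec$subject_centre_sd_mm)
  # keep jittered centres inside the sheet's margin band
  extent <- (spec$sheet$grid_shape[2] - 1) * spec$sheet$vertex_spacing
  centres <- pmin(pmax(centres, 2 * spec$sheet$tuning_width),
                  extent - 2 * spec$sheet$tuning_width)
  jnd_mult <- exp(stats::rnorm(1, 0, spec$toj_subject_cv))
  list(centres = centres, jnd_mult = jnd_mult)
}

block_order_for <- function(subject, session) {
  orders <- list(c(2, 3, 4, 5, 3, 5, 2, 4, 4, 2, 5, 3, 5, 4, 3, 2),
                 c(3, 5, 2, 4, 5, 4, 3, 2, 2, 3, 4, 5, 4, 2, 5, 3),
                 c(4, 2, 5, 3, 2, 3, 4, 5, 5, 4, 3, 2, 3, 5, 2, 4))
  orders[[((subject + session_index(session)) %% 3) + 1]]
}

# Generative observer for one subject, session and digit pair.
toj_observer_for <- function(spec, subject, session, pair) {
  pi <- match(pair, DIGIT_PAIRS)
  if (!is.null(spec$flat_toj_subject) && subject %in% spec$flat_toj_subject &&
      session == "control2") {
    return(toj_observer(0, Inf, spec$toj_lapse))
  }
  sp <- subject_params(spec, subject)
  set.seed(derive_seed(spec$seed, subject, session_index(session), 800 + pi))
  jnd <- spec$toj_base_jnd_ms * sp$jnd_mult *
    exp(stats::rnorm(1, 0, spec$toj_session_cv))
  if (session == "glued") jnd <- jnd * spec$toj_glued_multipliers[pi]
  pse <- stats::rnorm(1, 0, spec$toj_pse_sd_ms)
  toj_observer(pse, jnd, spec$toj_lapse)
}

confusion_spec_for <- function(spec, session) {
  boost <- if (session == "glued") spec$confusion_d4d5_boost else 0
  confusion_spec(default_confusion_matrix(spec$confusion_adjacent,
                                          spec$confusion_far, boost),
                 spec$confusion_omission)
}

#' Generate all data for one subject and session
#'
#' The unit of generation behind [generate_cohort()]: the session's
#' ground-truth sheet (subject centres + session effect), the forward and
#' backward phase-encoding runs, the block-design run, one TOJ run per
#' adjacent digit pair, and the motor-confusion run. Fully determined by
#' the cohort spec's master seed.
#'
#' @param spec a [cohort_spec()].
#' @param subject subject index.
#' @param session session label.
#' @return list with `sheet`, `phase_fwd`, `phase_bwd`, `block`, `toj`
#'   (named list of trial tables per digit pair), `confusion`.
#' @export
cohort_session_data <- function(spec, subject, session) {
  session <- match.arg(session, SESSIONS)
  si <- session_index(session)
  sp <- subject_params(spec, subject)
  base_spec <- spec$sheet
  base_spec$digit_centres <- sp$centres
  base <- make_ground_truth_sheet(base_spec,
                                  seed = derive_seed(spec$seed, subject, 0))
  base$subject_id <- subject
  shift <- if (session == "glued") spec$d4_shift_mm else 0
  sheet <- apply_session_effect(
    base, session_effect(session, shift, spec$centre_jitter_sd_mm),
    seed = derive_seed(spec$seed, subject, si, 1))
  toj <- lapply(stats::setNames(DIGIT_PAIRS, DIGIT_PAIRS), function(pair) {
    simulate_toj_run(toj_observer_for(spec, subject, session, pair),
                     seed = derive_seed(spec$seed, subject, si,
                                        40 + match(pair, DIGIT_PAIRS)))
  })
  list(
    sheet = sheet,
    phase_fwd = simulate_phase_run(sheet, task_design("phase_forward"),
                                   spec$noise,
                                   derive_seed(spec$seed, subject, si, 10)),
    phase_bwd = simulate_phase_run(sheet, task_design("phase_backward"),
                                   spec$noise,
                                   derive_seed(spec$seed, subject, si, 20)),
    block = simulate_block_run(sheet,
                               task_design("block",
                                           block_order = block_order_for(subject, session)),
                               spec$noise,
                               derive_seed(spec$seed, subject, si, 30)),
    toj = toj,
    confusion = simulate_confusion_run(confusion_spec_for(spec, session),
                                       spec$confusion_blocks,
                                       spec$confusion_cues_per_block,
                                       derive_seed(spec$seed, subject, si, 50)))
}

#' Generate the full synthetic cohort
#'
#' Materialises every run for every subject and session. Reproducible: the
#' same spec and master seed yield an identical dataset. For large sheets
#' the result is memory-heavy; [run_full_study()] generates and analyses
#' subject-sessions one at a time instead, with identical sub-seeds.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort_dataset`: `$spec`, `$order` (per-subject A/B labels),
#'   `$subjects[[s]]$sessions[[session]]` as in [cohort_session_data()].
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    sessions <- lapply(stats::setNames(SESSIONS, SESSIONS), function(sess) {
      cohort_session_data(spec, s, sess)
    })
    list(subject = s, order = spec$order[s], sessions = sessions)
  })
  structure(list(spec = spec, order = spec$order, subjects = subjects),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects x %d sessions (order %s)\n",
              x$spec$n_subjects, length(SESSIONS),
              paste(x$order, collapse = "")))
  invisible(x)
}
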