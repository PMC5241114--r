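#' Configuration of a full synthetic study
#'
#' Bundles the cohort generative spec with every analysis parameter:
#' travelling-wave mapping (lag step, HRF, FDR level), RSA (ROI FDR level),
#' psychophysics (goodness-of-fit threshold, confusion response window) and
#' the inferential policy (Greenhouse-Geisser policy, alpha).
#'
#' @param cohort a [cohort_spec()].
#' @param lag_step_s travelling-wave lag grid step, seconds.
#' @param hrf [hrf_params()] used by mapping, GLM and simulation.
#' @param fdr_alpha FDR level for digit-map binarisation.
#' @param rsa_fdr_alpha FDR level defining the RSA ROI.
#' @param r2_min psychometric goodness-of-fit exclusion threshold.
#' @param window_ms confusion-task response window, ms.
#' @param gg_policy Greenhouse-Geisser policy for all ANOVAs.
#' @param alpha significance level for interactions / pairwise tests.
#' @param out_dir optional directory for measurement CSVs and figures.
#' @return a `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(), lag_step_s = 1,
                         hrf = hrf_params(), fdr_alpha = 0.01,
                         rsa_fdr_alpha = 0.01, r2_min = 0.4,
                         window_ms = 700, gg_policy = "mauchly",
                         alpha = 0.05, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"), lag_step_s > 0,
            fdr_alpha > 0, fdr_alpha < 1, rsa_fdr_alpha > 0,
            rsa_fdr_alpha < 1, r2_min >= 0, r2_min <= 1, window_ms > 0)
  gg_policy <- match.arg(gg_policy, c("mauchly", "always", "never"))
  structure(as.list(environment()), class = "study_config")
}

# Full inferential suite on one long table: two-way RM-ANOVA, simple main
# effects + Sidak pairwise per digit pair when the interaction is
# significant, Shapiro-Wilk screen per cell, control-averaging check.
analyze_long_table <- function(table, value = "value", gg_policy = "mauchly",
                               alpha = 0.05) {
  anova <- two_way_rm_anova(table, value, gg_policy)
  int_p <- anova$p_reported[anova$effect == "session:digit_pair"]
  sme <- pairwise <- NULL
  if (is.finite(int_p) && int_p < alpha) {
    sme <- simple_main_effects(table, value)
    pairwise <- do.call(rbind, lapply(unique(table$digit_pair), function(dp) {
      sub <- table[table$digit_pair == dp, ]
      cbind(data.frame(digit_pair = dp), sidak_pairwise(sub, value, alpha))
    }))
  }
  shapiro <- do.call(rbind, lapply(split(
    table, list(table$session, table$digit_pair), drop = TRUE),
    function(cell) {
      sw <- tryCatch(shapiro_wilk_check(cell[[value]]),
                     error = function(e) list(W = NA, p = NA, pass = NA))
      data.frame(session = cell$session[1], digit_pair = cell$digit_pair[1],
                 W = sw$W, p = sw$p, pass = sw$pass)
    }))
  rownames(shapiro) <- NULL
  ctrl <- control_average_sensitivity(table, value, gg_policy, alpha)
  list(anova = anova, interaction_p = int_p, simple_effects = sme,
       pairwise = pairwise, shapiro = shapiro,
       control_collapsed = ctrl[c("anova", "simple_effects",
                                  "pattern_matches")])
}

# fMRI measurements (dice / area / peak distance / RSA distances) for one
# subject across the three sessions.
subject_fmri_measures <- function(spec, subject, config) {
  per_sess <- lapply(stats::setNames(SESSIONS, SESSIONS), function(sess) {
    dat <- cohort_session_data(spec, subject, sess)
    maps <- map_digits(dat$phase_fwd, dat$phase_bwd, dat$sheet$roi_mask,
                       config$hrf, config$lag_step_s, config$fdr_alpha)
    glm <- fit_block_glm(dat$block, hrf = config$hrf)
    list(sheet = dat$sheet, maps = maps,
         overlap = measure_overlap(maps, dat$sheet, dat$sheet$roi_mask),
         betas = suppressMessages(noise_normalize_betas(glm)),
         toj = dat$toj, confusion = dat$confusion)
  })
  roi <- rsa_roi_from_zmaps(lapply(per_sess, function(x) x$maps$z_maps),
                            per_sess[[1]]$sheet$roi_mask,
                            config$rsa_fdr_alpha)
  rows <- function(sess, df, measure) {
    cbind(data.frame(subject = subject, session = sess, measure = measure),
          df)
  }
  out <- list(dice = NULL, area = NULL, peak_distance = NULL, rsa = NULL,
              jnd = NULL, mispress = NULL, rdms = list(), mds = list())
  for (sess in SESSIONS) {
    ps <- per_sess[[sess]]
    out$dice <- rbind(out$dice,
                      rows(sess, ps$overlap$dice[, c("digit_pair", "value")],
                           "dice"))
    out$area <- rbind(out$area,
                      rows(sess, ps$overlap$area, "area"))
    out$peak_distance <- rbind(out$peak_distance,
                               rows(sess, ps$overlap$peak_distance,
                                    "peak_distance"))
    rdm <- compute_rdm(ps$betas, roi)
    out$rdms[[sess]] <- rdm
    out$mds[[sess]] <- mds_embed(rdm)
    out$rsa <- rbind(out$rsa, rows(sess, adjacent_pair_distances(rdm), "rsa"))
    fits <- do.call(rbind, lapply(DIGIT_PAIRS, function(pair) {
      fit <- fit_psychometric(ps$toj[[pair]])
      data.frame(subject = subject, session = sess, digit_pair = pair,
                 jnd_ms = fit$jnd_ms, pse_ms = fit$pse_ms,
                 r_squared = fit$r_squared, converged = fit$converged)
    }))
    out$jnd <- rbind(out$jnd, fits)
    cs <- score_confusion(ps$confusion, config$window_ms)
    out$mispress <- rbind(out$mispress,
                          rows(sess, cs$mispress[, c("digit_pair",
                                                     "per_block")],
                               "mispress"))
  }
  out
}

#' Measurement tables for a whole cohort
#'
#' Runs the generation + mapping + measurement stages (no group statistics)
#' for every subject: travelling-wave digit maps, Dice/area/peak-distance
#' tables, per-session RDMs with adjacent distances and MDS embeddings,
#' psychometric fits and confusion scores. Subject-sessions are generated
#' and analysed one at a time.
#'
#' @param config a [study_config()].
#' @return list of long tables `dice`, `area`, `peak_distance`, `rsa`,
#'   `jnd_fits`, `mispress`, plus `mds` (per subject, per session).
#' @export
cohort_measurements <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  spec <- config$cohort
  per_subj <- lapply(seq_len(spec$n_subjects), function(s) {
    subject_fmri_measures(spec, s, config)
  })
  gather <- function(field) {
    tab <- do.call(rbind, lapply(per_subj, `[[`, field))
    rownames(tab) <- NULL
    tab
  }
  mispress <- gather("mispress")
  names(mispress)[names(mispress) == "per_block"] <- "value"
  list(dice = gather("dice"), area = gather("area"),
       peak_distance = gather("peak_distance"), rsa = gather("rsa"),
       jnd_fits = gather("jnd"), mispress = mispress,
       mds = lapply(per_subj, `[[`, "mds"))
}

#' Run the full synthetic study end-to-end
#'
#' Generates each subject-session (streamed, never holding the whole BOLD
#' cohort in memory), runs the travelling-wave mapping, overlap, RSA and
#' psychophysics measurements, and applies the repeated-measures
#' inferential suite to the four headline long tables (Dice, RSA adjacent
#' distances, JND after goodness-of-fit exclusion, confusion mis-presses).
#' Deterministic given the cohort spec's master seed. If `out_dir` is set,
#' the measurement tables are written as CSV and summary figures
#' (normalised to control 1 for display only; all statistics run on raw
#' values) as PDFs.
#'
#' @param config a [study_config()].
#' @return a `study_report`.
#' @export
run_full_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  spec <- config$cohort
  meas <- cohort_measurements(config)
  dice <- meas$dice
  area <- meas$area
  peak_distance <- meas$peak_distance
  rsa <- meas$rsa
  jnd_all <- meas$jnd_fits
  mispress <- meas$mispress
  # goodness-of-fit exclusion (complete-case)
  excl <- exclude_poor_fits(jnd_all, config$r2_min)
  jnd <- excl$kept
  names(jnd)[names(jnd) == "jnd_ms"] <- "value"
  bad_dice_subj <- unique(dice$subject[is.na(dice$value)])
  dice_an <- dice[!dice$subject %in% bad_dice_subj, ]
  if (length(bad_dice_subj) > 0) {
    warning("undefined Dice for subject(s) ",
            paste(bad_dice_subj, collapse = ", "),
            ": dropped from the Dice ANOVA table (complete-case)")
  }
  measurements <- list(dice = dice, area = area,
                       peak_distance = peak_distance, rsa = rsa,
                       jnd = jnd, jnd_all_fits = jnd_all,
                       mispress = mispress)
  analyses <- list(
    dice = analyze_long_table(dice_an, "value", config$gg_policy,
                              config$alpha),
    rsa = analyze_long_table(rsa, "value", config$gg_policy, config$alpha),
    jnd = analyze_long_table(jnd, "value", config$gg_policy, config$alpha),
    mispress = analyze_long_table(mispress, "value", config$gg_policy,
                                  config$alpha))
  report <- structure(
    list(config = config, seed = spec$seed, order = spec$order,
         measurements = measurements, analyses = analyses,
         excluded_subjects = excl$excluded_subjects,
         exclusion_log = excl$exclusion_log,
         group_mds = lapply(stats::setNames(SESSIONS, SESSIONS),
                            function(sess) {
                              procrustes_group_align(
                                lapply(meas$mds, `[[`, sess))
                            })),
    class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects, seed %d\n",
              x$config$cohort$n_subjects, x$seed))
  for (m in names(x$analyses)) {
    a <- x$analyses[[m]]$anova
    row <- a[a$effect == "session:digit_pair", ]
    cat(sprintf("  %-9s session x pair: F(%.1f,%.1f) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
                m,
                if (row$corrected) row$df_effect_gg else row$df_effect,
                if (row$corrected) row$df_error_gg else row$df_error,
                row$F, row$p_reported, row$partial_eta_sq))
  }
  if (length(x$excluded_subjects) > 0) {
    cat("  JND exclusions: subject(s)",
        paste(x$excluded_subjects, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Statistics-only analysis of supplied measurement tables
#'
#' Runs the repeated-measures suite on externally supplied long-format
#' tables (e.g. the published per-study source-data tables) without any
#' simulation. Each CSV must carry columns `subject`, `session`
#' (control1/control2/glued), `digit_pair` (D2-D3/D3-D4/D4-D5) and `value`,
#' with a complete subject x session x pair crossing.
#'
#' @param path_map named list/vector of CSV paths (names label the
#'   measures, e.g. `dice`, `rsa`, `jnd`, `mispress`); entries may also be
#'   data frames already in long format.
#' @param gg_policy,alpha inferential policy.
#' @return a `study_report` with `measurements` and `analyses` only.
#' @export
analyze_source_tables <- function(path_map, gg_policy = "mauchly",
                                  alpha = 0.05) {
  if (length(path_map) == 0 || is.null(names(path_map))) {
    stop("path_map must be a named list of CSVs or data frames",
         call. = FALSE)
  }
  measurements <- lapply(path_map, function(p) {
    tab <- if (is.data.frame(p)) p else read_long_table(p)
    long_to_array(tab)  # validates completeness, names the missing cell
    tab
  })
  analyses <- lapply(measurements, analyze_long_table,
                     gg_policy = gg_policy, alpha = alpha)
  structure(list(config = NULL, seed = NA, measurements = measurements,
                 analyses = analyses, excluded_subjects = integer(0)),
            class = "study_report")
}
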