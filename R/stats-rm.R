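orthonormal_helmert <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

# Long table -> subjects x A x B array, with completeness checks.
long_to_array <- function(table, value = "value") {
  need <- c("subject", "session", "digit_pair", value)
  if (!all(need %in% names(table))) {
    stop("long table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  subj <- sort(unique(table$subject))
  a_lev <- if (is.factor(table$session)) levels(table$session) else
    unique(table$session)
  b_lev <- if (is.factor(table$digit_pair)) levels(table$digit_pair) else
    unique(table$digit_pair)
  y <- array(NA_real_, c(length(subj), length(a_lev), length(b_lev)),
             dimnames = list(subj, a_lev, b_lev))
  idx <- cbind(match(table$subject, subj), match(table$session, a_lev),
               match(table$digit_pair, b_lev))
  if (anyDuplicated(idx)) stop("duplicate subject x session x pair cells",
                               call. = FALSE)
  y[idx] <- table[[value]]
  if (anyNA(y)) {
    miss <- which(is.na(y), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete crossing: missing cell subject %s, %s, %s",
                 subj[miss[1]], a_lev[miss[2]], b_lev[miss[3]]),
         call. = FALSE)
  }
  y
}

# Greenhouse-Geisser epsilon and Mauchly test from subject x condition
# scores and an orthonormal contrast matrix.
sphericity_from_scores <- function(scores_mat, contrast) {
  u <- scores_mat %*% contrast
  p <- ncol(u)
  if (p < 2) {
    return(list(epsilon = 1, mauchly_w = NA_real_, mauchly_p = NA_real_))
  }
  s <- stats::cov(u)
  lam <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / (p * sum(lam^2))
  n <- nrow(u)
  w <- p_m <- NA_real_
  if (n - 1 >= p && min(lam) > 1e-12 * max(lam)) {
    w <- prod(lam) / (mean(lam)^p)
    chi <- -(n - 1 - (2 * p^2 + p + 2) / (6 * p)) * log(w)
    df <- p * (p + 1) / 2 - 1
    p_m <- stats::pchisq(chi, df, lower.tail = FALSE)
  }
  list(epsilon = eps, mauchly_w = w, mauchly_p = p_m)
}

effect_row <- function(name, ss_eff, df_eff, ss_err, df_err, sph, gg_policy) {
  ms_eff <- ss_eff / df_eff
  ms_err <- ss_err / df_err
  degenerate <- ms_err < 1e-300
  f <- if (degenerate) {
    if (ms_eff < 1e-300) 0 else Inf
  } else ms_eff / ms_err
  p <- stats::pf(f, df_eff, df_err, lower.tail = FALSE)
  eps <- sph$epsilon
  p_gg <- stats::pf(f, eps * df_eff, eps * df_err, lower.tail = FALSE)
  corrected <- switch(gg_policy,
                      always = TRUE,
                      never = FALSE,
                      mauchly = !is.na(sph$mauchly_p) && sph$mauchly_p < 0.05)
  data.frame(effect = name, F = f, df_effect = df_eff, df_error = df_err,
             p = p,
             partial_eta_sq = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0,
             mauchly_w = sph$mauchly_w, mauchly_p = sph$mauchly_p,
             gg_epsilon = eps, df_effect_gg = eps * df_eff,
             df_error_gg = eps * df_err, p_gg = p_gg,
             corrected = corrected,
             p_reported = if (corrected) p_gg else p,
             degenerate = degenerate)
}

#' Two-way repeated-measures ANOVA (session x digit pair)
#'
#' Within-subject sums-of-squares decomposition for a complete balanced
#' subject x session x digit-pair table: each effect (two main effects and
#' the interaction) is tested against its own effect-by-subject interaction
#' mean square. Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#' Sphericity is assessed per effect with Mauchly's test on orthonormal
#' contrasts and the Greenhouse-Geisser epsilon; both uncorrected and
#' GG-corrected p-values (with fractional dfs) are always reported, and
#' `p_reported` follows `gg_policy` ("mauchly": correct when Mauchly
#' p < 0.05; "always"; "never").
#'
#' @param table long data frame `subject`, `session`, `digit_pair`, value.
#' @param value name of the measurement column.
#' @param gg_policy Greenhouse-Geisser policy.
#' @return an `anova_rm` data frame (one row per effect).
#' @export
two_way_rm_anova <- function(table, value = "value",
                             gg_policy = c("mauchly", "always", "never")) {
  gg_policy <- match.arg(gg_policy)
  y <- long_to_array(table, value)
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  grand <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_sab <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb
  m_a_c <- orthonormal_helmert(a)
  m_b_c <- orthonormal_helmert(b)
  cells <- matrix(aperm(y, c(1, 3, 2)), nrow = n)   # subj x (A-major cells)
  # columns ordered cell (i-1)*b + j to match kronecker(M_A, M_B)
  rows <- rbind(
    effect_row("session", ss_a, a - 1, ss_sa, (a - 1) * (n - 1),
               sphericity_from_scores(m_sa, m_a_c), gg_policy),
    effect_row("digit_pair", ss_b, b - 1, ss_sb, (b - 1) * (n - 1),
               sphericity_from_scores(m_sb, m_b_c), gg_policy),
    effect_row("session:digit_pair", ss_ab, (a - 1) * (b - 1), ss_sab,
               (a - 1) * (b - 1) * (n - 1),
               sphericity_from_scores(cells, kronecker(m_a_c, m_b_c)),
               gg_policy))
  attr(rows, "ss") <- c(subject = ss_s, session = ss_a, digit_pair = ss_b,
                        interaction = ss_ab, err_session = ss_sa,
                        err_digit_pair = ss_sb, err_interaction = ss_sab,
                        total = ss_tot)
  class(rows) <- c("anova_rm", "data.frame")
  rows
}

#' Greenhouse-Geisser epsilon from a subject x condition matrix
#'
#' Computed from the eigenvalues of the orthonormally contrasted condition
#' covariance matrix; bounded in `[1/(k-1), 1]`, and exactly 1 under
#' compound symmetry or with k = 2 conditions.
#'
#' @param cell_matrix subjects x conditions matrix.
#' @return epsilon.
#' @export
greenhouse_geisser_epsilon <- function(cell_matrix) {
  cell_matrix <- as.matrix(cell_matrix)
  k <- ncol(cell_matrix)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  if (k == 2) return(1)
  sphericity_from_scores(cell_matrix, orthonormal_helmert(k))$epsilon
}

one_way_rm <- function(y) {   # subjects x conditions
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  m_c <- colMeans(y); m_s <- rowMeans(y)
  ss_c <- n * sum((m_c - grand)^2)
  ss_err <- sum((y - outer(m_s, rep(1, k)) -
                   outer(rep(1, n), m_c) + grand)^2)
  sph <- sphericity_from_scores(y, orthonormal_helmert(k))
  effect_row("condition", ss_c, k - 1, ss_err, (k - 1) * (n - 1), sph,
             "mauchly")
}

#' Simple main effects of session within each digit pair
#'
#' After a significant session x pair interaction, runs a one-way
#' repeated-measures ANOVA of session separately for each digit pair, each
#' with its own per-level error term: F((k-1), (k-1)(n-1)), i.e. F(2,16)
#' for 9 subjects and 3 sessions.
#'
#' @inheritParams two_way_rm_anova
#' @return data frame with one row per digit pair.
#' @export
simple_main_effects <- function(table, value = "value") {
  y <- long_to_array(table, value)
  if (dim(y)[2] < 2) stop("need at least 2 sessions", call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(dim(y)[3]), function(j) {
    row <- one_way_rm(y[, , j])
    row$effect <- NULL
    cbind(data.frame(digit_pair = dimnames(y)[[3]][j]), row)
  }))
  out
}

#' Sidak-corrected pairwise session comparisons
#'
#' Paired t-tests between every pair of sessions for one digit pair, with
#' the Sidak family-wise adjustment `p_adj = 1 - (1 - p)^m` over the
#' m = k(k-1)/2 comparisons.
#'
#' @param table long data frame `subject`, `session`, value (one digit
#'   pair), or a subjects x sessions matrix.
#' @param value measurement column name.
#' @param alpha significance level applied to the adjusted p.
#' @return data frame per comparison: `mean_diff`, `t`, `df`, `p`,
#'   `p_sidak`, `significant`.
#' @export
sidak_pairwise <- function(table, value = "value", alpha = 0.05) {
  if (is.matrix(table)) {
    y <- table
  } else {
    subj <- sort(unique(table$subject))
    sess <- if (is.factor(table$session)) levels(table$session) else
      unique(table$session)
    y <- matrix(NA_real_, length(subj), length(sess),
                dimnames = list(subj, sess))
    y[cbind(match(table$subject, subj), match(table$session, sess))] <-
      table[[value]]
    if (anyNA(y)) stop("incomplete subject x session crossing", call. = FALSE)
  }
  k <- ncol(y)
  combos <- utils::combn(k, 2)
  m <- ncol(combos)
  out <- do.call(rbind, lapply(seq_len(m), function(i) {
    d <- y[, combos[1, i]] - y[, combos[2, i]]
    if (stats::sd(d) < 1e-300) {
      stop("zero-variance paired differences for ",
           colnames(y)[combos[1, i]], " vs ", colnames(y)[combos[2, i]],
           call. = FALSE)
    }
    tt <- stats::t.test(d)
    data.frame(comparison = paste(colnames(y)[combos[1, i]], "vs",
                                  colnames(y)[combos[2, i]]),
               mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  out$p_sidak <- 1 - (1 - out$p)^m
  out$significant <- out$p_sidak < alpha
  out
}

#' Shapiro-Wilk normality screen
#'
#' Logged screen of a sample's normality; never used as an automatic
#' analysis branch.
#'
#' @param values numeric sample (3 to 50 observations, non-constant).
#' @param alpha screening level.
#' @return list `W`, `p`, `pass`.
#' @export
shapiro_wilk_check <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 50) {
    stop("Shapiro-Wilk screen needs 3..50 observations", call. = FALSE)
  }
  if (stats::sd(values) < 1e-300) stop("constant input", call. = FALSE)
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, pass = sw$p.value >= alpha)
}

#' Control-averaging sensitivity check
#'
#' Re-runs the repeated-measures suite with the two control sessions
#' collapsed to their per-subject mean (a 2 x 3 design) and reports whether
#' the pattern of significance (interaction, and simple main effects per
#' digit pair) matches the 3-session analysis.
#'
#' @inheritParams two_way_rm_anova
#' @param alpha significance level used for the pattern comparison.
#' @return list `anova`, `simple_effects`, `full_anova`,
#'   `full_simple_effects`, `pattern_matches`.
#' @export
control_average_sensitivity <- function(table, value = "value",
                                        gg_policy = "mauchly", alpha = 0.05) {
  sessions <- unique(table$session)
  if (!all(SESSIONS %in% sessions)) {
    stop("need the three standard sessions to collapse controls",
         call. = FALSE)
  }
  full <- two_way_rm_anova(table, value, gg_policy)
  full_sme <- simple_main_effects(table, value)
  tab <- table
  tab$session <- ifelse(tab$session == "glued", "glued", "control")
  agg <- stats::aggregate(tab[[value]],
                          by = list(subject = tab$subject,
                                    session = tab$session,
                                    digit_pair = tab$digit_pair), FUN = mean)
  names(agg)[4] <- value
  collapsed <- two_way_rm_anova(agg, value, gg_policy)
  collapsed_sme <- simple_main_effects(agg, value)
  int_match <- (full$p_reported[full$effect == "session:digit_pair"] < alpha) ==
    (collapsed$p_reported[collapsed$effect == "session:digit_pair"] < alpha)
  sme_match <- all((full_sme$p_reported < alpha) ==
                     (collapsed_sme$p_reported < alpha))
  list(anova = collapsed, simple_effects = collapsed_sme,
       full_anova = full, full_simple_effects = full_sme,
       pattern_matches = int_match && sme_match)
}
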