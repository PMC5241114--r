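test_that("two-way RM-ANOVA matches the aov error-strata oracle", {
  for (seed in 1:10) {
    tab <- random_long_table(n_subjects = 5, seed = seed)
    mine <- two_way_rm_anova(tab)
    oracle <- aov_rm_oracle(tab)
    for (i in 1:3) {
      expect_equal(mine$F[i], oracle$F[i], tolerance = 1e-8)
      expect_equal(mine$df_effect[i], oracle$df_effect[i])
      expect_equal(mine$df_error[i], oracle$df_error[i])
      expect_equal(mine$p[i], oracle$p[i], tolerance = 1e-8)
      expect_equal(mine$partial_eta_sq[i], oracle$partial_eta_sq[i],
                   tolerance = 1e-8)
    }
  }
})

test_that("sums of squares partition the total", {
  tab <- random_long_table(n_subjects = 7, seed = 99)
  ss <- attr(two_way_rm_anova(tab), "ss")
  expect_equal(sum(ss[c("subject", "session", "digit_pair", "interaction",
                        "err_session", "err_digit_pair", "err_interaction")]),
               unname(ss["total"]), tolerance = 1e-8)
})

test_that("degenerate tables are flagged rather than mis-tested", {
  tab <- random_long_table(seed = 1)
  tab$value <- 1                       # identical everywhere
  res <- two_way_rm_anova(tab)
  expect_true(all(res$degenerate))
  expect_true(all(res$F == 0))
  # values depending only on subject: effects are exactly zero
  tab2 <- random_long_table(seed = 2)
  tab2$value <- as.numeric(tab2$subject)
  res2 <- two_way_rm_anova(tab2)
  expect_true(all(res2$F == 0))
  expect_error(two_way_rm_anova(random_long_table()[-1, ]), "incomplete")
})

test_that("F, p and eta^2 are invariant to positive rescaling", {
  tab <- random_long_table(seed = 5)
  a <- two_way_rm_anova(tab)
  tab$value <- tab$value * 37.5
  b <- two_way_rm_anova(tab)
  expect_equal(a$F, b$F, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  expect_equal(a$partial_eta_sq, b$partial_eta_sq, tolerance = 1e-10)
})

test_that("Greenhouse-Geisser epsilon: closed form, bounds and special cases", {
  set.seed(13)
  for (i in 1:10) {
    y <- matrix(rnorm(9 * 3), 9, 3)
    expect_equal(greenhouse_geisser_epsilon(y), gg_epsilon_oracle(y),
                 tolerance = 1e-10)
    e <- greenhouse_geisser_epsilon(y)
    expect_gte(e, 1 / 2)
    expect_lte(e, 1 + 1e-12)
  }
  # compound symmetry -> epsilon = 1 (orthonormalised covariance spherical)
  sigma <- matrix(0.4, 4, 4); diag(sigma) <- 1
  ch <- chol(sigma)
  y_cs <- matrix(rnorm(400 * 4), 400, 4) %*% ch
  s <- somatomap:::orthonormal_helmert(4)
  cov_c <- t(s) %*% sigma %*% s      # exact population check
  lam <- eigen(cov_c, only.values = TRUE)$values
  expect_equal(sum(lam)^2 / (3 * sum(lam^2)), 1, tolerance = 1e-12)
  # two conditions: always 1
  expect_equal(greenhouse_geisser_epsilon(matrix(rnorm(20), 10, 2)), 1)
  expect_error(greenhouse_geisser_epsilon(matrix(1, 5, 1)), "2 conditions")
})

test_that("GG-corrected dfs are fractional and reported alongside", {
  set.seed(21)
  tab <- random_long_table(n_subjects = 9, seed = 77)
  res <- two_way_rm_anova(tab, gg_policy = "always")
  expect_true(all(res$corrected))
  expect_true(all(res$df_effect_gg <= res$df_effect + 1e-12))
  expect_equal(res$df_effect_gg / res$df_effect,
               res$df_error_gg / res$df_error, tolerance = 1e-12)
  expect_true(all(res$p_gg > 0 & res$p_gg <= 1))
})

test_that("simple main effects run per digit pair with per-level error", {
  tab <- random_long_table(n_subjects = 9, seed = 3)
  sme <- simple_main_effects(tab)
  expect_equal(nrow(sme), 3)
  expect_equal(sme$df_effect, rep(2, 3))
  expect_equal(sme$df_error, rep(16, 3))   # 2 * (9 - 1)
  tab8 <- random_long_table(n_subjects = 8, seed = 3)
  expect_equal(simple_main_effects(tab8)$df_error, rep(14, 3))
  # oracle: one-way RM-ANOVA via aov on one pair
  sub <- tab[tab$digit_pair == "D3-D4", ]
  sub$digit_pair <- NULL
  fit <- stats::aov(value ~ session + Error(factor(subject) / session),
                    data = transform(sub, session = factor(session)))
  block <- summary(fit)[["Error: factor(subject):session"]][[1]]
  expect_equal(sme$F[sme$digit_pair == "D3-D4"], block[1, "F value"],
               tolerance = 1e-8)
  expect_equal(sme$p[sme$digit_pair == "D3-D4"], block[1, "Pr(>F)"],
               tolerance = 1e-8)
  # identical session means per subject -> F = 0
  flat <- tab
  flat$value <- as.numeric(flat$subject)
  expect_true(all(simple_main_effects(flat)$F == 0))
})

test_that("Sidak correction closed form and dominance", {
  y <- matrix(rnorm(27), 9, 3, dimnames = list(NULL, somatomap:::SESSIONS))
  out <- sidak_pairwise(y)
  expect_equal(nrow(out), 3)
  expect_equal(out$p_sidak, 1 - (1 - out$p)^3, tolerance = 1e-12)
  expect_true(all(out$p_sidak >= out$p))
  # the printed closed form: raw p = 0.05 with m = 3
  expect_equal(1 - (1 - 0.05)^3, 0.142625, tolerance = 1e-12)
  const <- matrix(rep(1:9, 3), 9, 3)
  expect_error(sidak_pairwise(const), "zero-variance")
})

test_that("Shapiro-Wilk screen calibrates and flags bad input", {
  set.seed(31)
  rej_norm <- mean(vapply(1:500, function(i) {
    shapiro_wilk_check(rnorm(20))$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej_norm - 0.05), 3 * sqrt(0.05 * 0.95 / 500) + 0.01)
  rej_exp <- mean(vapply(1:200, function(i) {
    shapiro_wilk_check(rexp(50))$p < 0.05
  }, logical(1)))
  expect_gt(rej_exp, 0.5)
  expect_error(shapiro_wilk_check(rep(2, 10)), "constant")
  expect_error(shapiro_wilk_check(rnorm(2)), "3..50")
})

test_that("control averaging preserves the inference pattern", {
  # identical controls: collapsing is a no-op on the inference
  tab <- random_long_table(n_subjects = 6, seed = 8)
  c1 <- tab$session == "control1"
  key <- paste(tab$subject, tab$digit_pair)
  tab$value[tab$session == "control2"] <-
    tab$value[c1][match(key[tab$session == "control2"], key[c1])]
  res <- control_average_sensitivity(tab)
  expect_true(res$pattern_matches)
  collapsed_int <- res$anova[res$anova$effect == "session:digit_pair", ]
  full_sme <- res$full_simple_effects
  expect_equal(nrow(res$anova), 3)
  # null data: trivially consistent (both null)
  null_tab <- random_long_table(n_subjects = 9, seed = 123)
  expect_true(control_average_sensitivity(null_tab)$pattern_matches)
})
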