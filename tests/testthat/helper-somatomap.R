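# Shared fixtures: everything is generated in code at test time.

# A thin sheet (few rows) keeps BOLD matrices small; tuning depends only on
# the column axis so the science is unchanged.
small_sheet_spec <- function(rows = 4) sheet_spec(grid_shape = c(rows, 100))

noiseless <- function() noise_spec(sd = 0, drift_range = 0)

# Random complete subject x session x pair long table.
random_long_table <- function(n_subjects = 5, seed = 1) {
  set.seed(seed)
  tab <- expand.grid(subject = seq_len(n_subjects),
                     session = c("control1", "control2", "glued"),
                     digit_pair = c("D2-D3", "D3-D4", "D4-D5"),
                     stringsAsFactors = FALSE)
  tab$value <- stats::rnorm(nrow(tab))
  tab
}

# Independent repeated-measures oracle built on stats::aov error strata.
aov_rm_oracle <- function(tab) {
  tab$subject <- factor(tab$subject)
  tab$session <- factor(tab$session)
  tab$digit_pair <- factor(tab$digit_pair)
  fit <- stats::aov(value ~ session * digit_pair +
                      Error(subject / (session * digit_pair)), data = tab)
  s <- summary(fit)
  grab <- function(stratum, effect) {
    block <- s[[paste0("Error: subject:", stratum)]][[1]]
    i <- grep(effect, trimws(rownames(block)), fixed = TRUE)[1]
    j <- grep("Residuals", rownames(block))
    data.frame(effect = effect, F = block[i, "F value"],
               df_effect = block[i, "Df"], df_error = block[j, "Df"],
               p = block[i, "Pr(>F)"],
               partial_eta_sq = block[i, "Sum Sq"] /
                 (block[i, "Sum Sq"] + block[j, "Sum Sq"]))
  }
  rbind(grab("session", "session"),
        grab("digit_pair", "digit_pair"),
        grab("session:digit_pair", "session:digit_pair"))
}

# Independent Greenhouse-Geisser oracle: the classic closed form written
# directly on the condition covariance matrix.
gg_epsilon_oracle <- function(y) {
  S <- stats::cov(y)
  k <- ncol(S)
  sbar <- mean(S)
  dbar <- mean(diag(S))
  si <- rowMeans(S)
  (k * (dbar - sbar))^2 /
    ((k - 1) * (sum(S^2) - 2 * k * sum(si^2) + k^2 * sbar^2))
}

# Mean glued-minus-control difference for one digit pair of a long table.
glued_minus_control <- function(tab, pair) {
  sub <- tab[tab$digit_pair == pair, ]
  mean(sub$value[sub$session == "glued"]) -
    mean(sub$value[sub$session != "glued"])
}
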