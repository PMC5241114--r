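test_that("block GLM recovers tuning exactly on noiseless runs", {
  sh <- make_ground_truth_sheet(small_sheet_spec(rows = 1), seed = 4)
  ts <- simulate_block_run(sh, noise = noiseless(), seed = 1)
  glm <- fit_block_glm(ts)
  amps <- somatomap:::tuning_amplitudes(sh)
  expect_equal(unname(glm$betas), unname(amps), tolerance = 1e-8)
  expect_lt(max(glm$residual_var), 1e-16)
  # pure-noise run: betas centred on zero across seeds
  sh0 <- sh; sh0$amplitude <- 0
  mean_beta <- rowMeans(vapply(1:20, function(s) {
    colMeans(fit_block_glm(simulate_block_run(sh0, noise = noise_spec(sd = 1),
                                              seed = s))$betas)
  }, numeric(4)))
  expect_lt(max(abs(mean_beta)), 0.05)
  # a design without one digit is rank deficient
  bad <- ts
  bad$design$digit_order <- rep(c(2, 3, 4, 4), 4)
  expect_error(fit_block_glm(bad, design = bad$design), "digit")
})

test_that("noise normalisation divides by residual SD and is scale invariant", {
  glm <- structure(list(betas = matrix(4, 2, 4), residual_var = c(4, 1),
                        df_residual = 100),
                   class = "glm_result")
  nb <- noise_normalize_betas(glm)
  expect_equal(unname(nb[1, ]), rep(2, 4))
  expect_equal(unname(nb[2, ]), rep(4, 4))   # unit variance: identity
  # scaling a vertex's time series rescales betas and residual SD alike
  sh <- make_ground_truth_sheet(small_sheet_spec(rows = 1), seed = 4)
  ts <- simulate_block_run(sh, noise = noise_spec(sd = 0.5), seed = 2)
  ts2 <- ts; ts2$data <- ts2$data * 7
  n1 <- noise_normalize_betas(fit_block_glm(ts))
  n2 <- noise_normalize_betas(fit_block_glm(ts2))
  expect_equal(n1, n2, tolerance = 1e-8)
  glm0 <- structure(list(betas = matrix(1, 2, 4), residual_var = c(0, 0)),
                    class = "glm_result")
  expect_error(noise_normalize_betas(glm0), "zero residual variance")
})

test_that("RDM axioms and brute-force equivalence", {
  set.seed(6)
  betas <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, somatomap:::DIGITS))
  roi <- rep(TRUE, 20)
  rdm <- compute_rdm(betas, roi)
  expect_equal(rdm, t(rdm))
  expect_equal(unname(diag(rdm)), rep(0, 4))
  expect_true(all(rdm >= 0))
  brute <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    brute[i, j] <- sqrt(sum((betas[, i] - betas[, j])^2))
  }
  expect_equal(unname(rdm), brute, tolerance = 1e-12)
  # identical patterns -> 0; orthogonal unit vectors -> sqrt(2)
  same <- cbind(betas[, 1], betas[, 1], betas[, 1], betas[, 1])
  expect_equal(max(compute_rdm(same, roi)), 0)
  eye <- diag(4)
  expect_equal(unname(compute_rdm(rbind(eye, matrix(0, 2, 4)), rep(TRUE, 6))),
               sqrt(2) * (1 - diag(4)), tolerance = 1e-12)
  # invariant to vertex ordering
  perm <- sample(20)
  expect_equal(compute_rdm(betas[perm, ], roi), rdm)
  expect_error(compute_rdm(betas[, 1:3], roi), "pattern")
})

test_that("adjacent pair extraction reads the super-diagonal", {
  rdm <- matrix(0, 4, 4, dimnames = list(somatomap:::DIGITS,
                                         somatomap:::DIGITS))
  rdm[cbind(1:3, 2:4)] <- c(1, 2, 3)
  rdm <- rdm + t(rdm)
  out <- adjacent_pair_distances(rdm)
  expect_equal(out$value, c(1, 2, 3))
  expect_equal(out$digit_pair, c("D2-D3", "D3-D4", "D4-D5"))
  expect_equal(adjacent_pair_distances(t(rdm))$value, out$value)
})

test_that("classical MDS round-trips Euclidean-realisable RDMs", {
  set.seed(8)
  pts <- matrix(rnorm(8), 4, 2)
  rdm <- as.matrix(stats::dist(pts))
  emb <- mds_embed(rdm, k = 2)
  expect_equal(as.matrix(stats::dist(emb)), rdm, tolerance = 1e-8,
               ignore_attr = TRUE)
  # collinear points: 1-D structure recovered in the embedding distances
  line <- cbind(c(0, 1, 3, 6), 0)
  emb_l <- mds_embed(as.matrix(stats::dist(line)), k = 2)
  expect_equal(as.matrix(stats::dist(emb_l)), as.matrix(stats::dist(line)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(attr(emb_l, "deficient"))   # only one positive eigenvalue
  z <- mds_embed(matrix(0, 4, 4), k = 2)
  expect_equal(max(abs(z)), 0)
})

test_that("group Procrustes alignment removes rigid differences", {
  set.seed(9)
  base <- matrix(rnorm(8), 4, 2)
  rot <- matrix(c(0, -1, 1, 0), 2, 2)        # 90 degrees
  out <- procrustes_group_align(list(base, base %*% rot))
  expect_lt(out$disparity, 1e-12)
  mirror <- base %*% diag(c(-1, 1))
  out_m <- procrustes_group_align(list(base, mirror))
  expect_lt(out_m$disparity, 1e-12)          # reflection allowed
  expect_equal(out$se_correction, sqrt(8 / 4))
  # alignment never increases summed squared deviation from the mean
  for (s in 1:5) {
    set.seed(s)
    confs <- lapply(1:6, function(i) matrix(rnorm(8), 4, 2))
    centred <- lapply(confs, function(e) sweep(e, 2, colMeans(e)))
    m0 <- Reduce(`+`, centred) / 6
    before <- sum(vapply(centred, function(e) sum((e - m0)^2), numeric(1)))
    expect_lte(procrustes_group_align(confs)$disparity, before + 1e-9)
  }
  expect_error(procrustes_group_align(list(base)), "at least two")
  flat <- matrix(1, 4, 2)
  expect_error(procrustes_group_align(list(flat, flat)), "degenerate")
})

test_that("glued sessions move the D4 pattern away from D3 and toward D5", {
  signs <- vapply(1:8, function(seed) {
    spec <- cohort_spec(n_subjects = 2, seed = seed,
                        sheet = small_sheet_spec(rows = 2))
    rdms <- lapply(somatomap:::SESSIONS, function(sess) {
      dat <- cohort_session_data(spec, 1, sess)
      glm <- fit_block_glm(dat$block)
      compute_rdm(suppressMessages(noise_normalize_betas(glm)),
                  dat$sheet$roi_mask)
    })
    d34 <- vapply(rdms, function(r) r["D3", "D4"], numeric(1))
    d45 <- vapply(rdms, function(r) r["D4", "D5"], numeric(1))
    c(d34 = d34[3] - mean(d34[1:2]), d45 = d45[3] - mean(d45[1:2]))
  }, numeric(2))
  expect_gt(mean(signs["d34", ] > 0), 0.7)   # D3-D4 distance up when glued
  expect_gt(mean(signs["d45", ] < 0), 0.7)   # D4-D5 distance down
})
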