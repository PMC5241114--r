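#' Fit the block-design GLM
#'
#' Ordinary least squares fit of four gamma-HRF-convolved digit regressors
#' plus intercept and linear drift to every vertex's time series. Returns
#' per-vertex digit parameter estimates and residual variance.
#'
#' @param ts a `voxel_time_series` from a block run.
#' @param design the block [task_design()] (defaults to the run's own).
#' @param hrf [hrf_params()].
#' @return a `glm_result`: `$betas` (vertices x 4, columns D2..D5),
#'   `$residual_var`, `$df_residual`, `$design`.
#' @export
fit_block_glm <- function(ts, design = ts$design, hrf = hrf_params()) {
  stopifnot(inherits(ts, "voxel_time_series"))
  if (design$kind != "block") stop("need a block design", call. = FALSE)
  if (length(unique(design$digit_order)) < 4) {
    stop("rank-deficient design: every digit must be cued", call. = FALSE)
  }
  regs <- t(digit_regressors(design, hrf))          # T x 4
  tt <- seq_len(design$n_timepoints)
  x <- cbind(intercept = 1, drift = (tt - mean(tt)) / length(tt), regs)
  if (qr(x)$rank < ncol(x)) stop("rank-deficient design matrix", call. = FALSE)
  fit <- stats::lm.fit(x, t(ts$data))
  betas <- t(fit$coefficients[DIGITS, , drop = FALSE])
  df <- design$n_timepoints - ncol(x)
  rss <- colSums(fit$residuals^2)
  structure(list(betas = betas, residual_var = rss / df, df_residual = df,
                 design = design),
            class = "glm_result")
}

#' Univariate noise normalisation of GLM betas
#'
#' Divides each vertex's digit parameter estimates by the vertex's residual
#' standard deviation. Vertices with (near) zero residual variance cannot
#' be normalised; they are excluded (set to `NA`) and counted.
#'
#' @param glm a [fit_block_glm()] result.
#' @param tol variance floor below which a vertex is excluded.
#' @return matrix of normalised betas with attribute `n_excluded`.
#' @export
noise_normalize_betas <- function(glm, tol = 1e-10) {
  stopifnot(inherits(glm, "glm_result"))
  bad <- glm$residual_var <= tol
  if (all(bad)) stop("all vertices have zero residual variance", call. = FALSE)
  out <- glm$betas / sqrt(pmax(glm$residual_var, tol))
  out[bad, ] <- NA_real_
  if (any(bad)) {
    message(sum(bad), " zero-variance vertices excluded from noise normalisation")
  }
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Representational dissimilarity matrix
#'
#' Pairwise Euclidean distances between the four digits' noise-normalised
#' activity patterns over the ROI vertices.
#'
#' @param betas vertices x 4 matrix of (normalised) parameter estimates.
#' @param roi_mask logical per vertex.
#' @return symmetric 4x4 matrix with zero diagonal, dimnames D2..D5.
#' @export
compute_rdm <- function(betas, roi_mask) {
  roi <- as.vector(roi_mask)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  if (ncol(betas) != 4) stop("need one pattern per digit", call. = FALSE)
  pat <- betas[roi, , drop = FALSE]
  pat <- pat[stats::complete.cases(pat), , drop = FALSE]
  if (nrow(pat) == 0) stop("no usable ROI vertices", call. = FALSE)
  rdm <- as.matrix(stats::dist(t(pat)))
  dimnames(rdm) <- list(DIGITS, DIGITS)
  rdm
}

#' Adjacent digit-pair distances from an RDM
#'
#' Extracts the three super-diagonal entries (D2-D3, D3-D4, D4-D5) as a
#' long-format table.
#'
#' @param rdm a 4x4 RDM.
#' @return data frame `digit_pair`, `value`.
#' @export
adjacent_pair_distances <- function(rdm) {
  stopifnot(all(dim(rdm) == c(4, 4)))
  data.frame(digit_pair = DIGIT_PAIRS,
             value = rdm[cbind(1:3, 2:4)])
}

#' Classical (Torgerson) MDS embedding of an RDM
#'
#' Double-centres the squared distances and embeds on the top `k`
#' eigenvectors scaled by the square root of their eigenvalues (arbitrary
#' units). If fewer than `k` positive eigenvalues exist the missing axes
#' are zero-padded and flagged.
#'
#' @param rdm a symmetric dissimilarity matrix.
#' @param k embedding dimension.
#' @return points matrix (rows = digits) with attribute `deficient`.
#' @export
mds_embed <- function(rdm, k = 2) {
  n <- nrow(rdm)
  fit <- suppressWarnings(   # cmdscale warns when the spectrum is deficient;
    stats::cmdscale(stats::as.dist(rdm), k = min(k, n - 1), eig = TRUE))
  pts <- fit$points
  n_pos <- sum(fit$eig > max(fit$eig, 0) * 1e-8)
  deficient <- n_pos < k
  if (ncol(pts) < k) {
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  } else if (deficient && ncol(pts) == k) {
    pts[, seq(n_pos + 1, k)] <- 0   # axes beyond the positive spectrum
  }
  rownames(pts) <- rownames(rdm)
  attr(pts, "deficient") <- deficient
  pts
}

# Full Procrustes alignment of Y onto X (translation, rotation/reflection,
# scaling); both are n x k point sets.
procrustes_fit <- function(x, y) {
  fit <- vegan::procrustes(x, y, scale = TRUE, symmetric = FALSE)
  fit$Yrot
}

#' Group Procrustes alignment of per-participant MDS embeddings
#'
#' Iteratively aligns every participant's configuration (translation,
#' rotation/reflection and scaling) to the evolving group mean until the
#' summed squared deviation changes by less than `tol` (relative), keeping
#' the mean configuration at constant scale. Per-point standard errors of
#' the aligned configurations are inflated by a correction factor for the
#' degrees of freedom absorbed by the alignment
#' (sqrt(n*k / (n*k - d_align)), d_align = 4 in 2-D: rotation + scale +
#' 2 translations).
#'
#' @param embeddings list of n x k point matrices (>= 2, equal sizes).
#' @param tol relative convergence tolerance on the disparity.
#' @param max_iter iteration cap.
#' @param d_align alignment degrees of freedom removed per configuration.
#' @return an `aligned_embedding`: `$aligned` (list), `$mean` (n x k),
#'   `$se` (n x k corrected SEs), `$se_correction`, `$disparity`,
#'   `$iterations`.
#' @export
procrustes_group_align <- function(embeddings, tol = 1e-8, max_iter = 100,
                                   d_align = 4) {
  if (length(embeddings) < 2) stop("need at least two embeddings", call. = FALSE)
  dims <- lapply(embeddings, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("embeddings must share one shape", call. = FALSE)
  }
  if (any(vapply(embeddings, function(e) stats::sd(as.vector(e)) < 1e-12,
                 logical(1)))) {
    stop("degenerate (all-coincident) configuration", call. = FALSE)
  }
  n <- nrow(embeddings[[1]]); k <- ncol(embeddings[[1]])
  centred <- lapply(embeddings, function(e) sweep(e, 2, colMeans(e)))
  target_ss <- mean(vapply(centred, function(e) sum(e^2), numeric(1)))
  ref <- centred[[1]] * sqrt(target_ss / sum(centred[[1]]^2))
  aligned <- centred
  disparity <- Inf
  for (it in seq_len(max_iter)) {
    aligned <- lapply(aligned, function(e) procrustes_fit(ref, e))
    m <- Reduce(`+`, aligned) / length(aligned)
    m <- sweep(m, 2, colMeans(m))
    if (sum(m^2) < 1e-15) stop("mean configuration collapsed", call. = FALSE)
    ref <- m * sqrt(target_ss / sum(m^2))
    new_disp <- sum(vapply(aligned, function(e) sum((e - ref)^2), numeric(1)))
    if (is.finite(disparity) &&
        abs(disparity - new_disp) <= tol * max(disparity, 1e-300)) {
      disparity <- new_disp
      break
    }
    disparity <- new_disp
  }
  arr <- simplify2array(aligned)                       # n x k x P
  se_corr <- sqrt(n * k / (n * k - d_align))
  se <- apply(arr, c(1, 2), stats::sd) / sqrt(length(aligned)) * se_corr
  structure(list(aligned = aligned, mean = ref, se = se,
                 se_correction = se_corr, disparity = disparity,
                 iterations = it),
            class = "aligned_embedding")
}

#' RSA region of interest from phase-encoding maps
#'
#' The RSA ROI is defined from the phase-encoding data averaged across
#' sessions: per digit, the session-mean z-map is FDR-thresholded (alpha)
#' within the anatomical ROI, and the union over digits of the surviving
#' vertices is returned.
#'
#' @param zmaps_by_session list (one element per session) of vertices x 4
#'   z matrices.
#' @param roi_mask logical anatomical ROI per vertex.
#' @param alpha FDR level.
#' @return logical vertex vector.
#' @export
rsa_roi_from_zmaps <- function(zmaps_by_session, roi_mask, alpha = 0.01) {
  mean_z <- Reduce(`+`, zmaps_by_session) / length(zmaps_by_session)
  bin <- threshold_digit_maps(mean_z, roi_mask, alpha)
  rowSums(bin) > 0
}
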