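#' Parameters of the synthetic cortical sheet
#'
#' The synthetic stand-in for the registered cortical surface is a flat 2-D
#' vertex grid. Digit tuning is Gaussian along the column (somatotopic)
#' axis: each digit d in D2..D5 has a peak-tuning column coordinate
#' (`digit_centres`, mm), a common tuning width (Gaussian SD, mm) and a
#' peak amplitude in percent BOLD signal change. The region of interest
#' (the SI ROI analogue) is the band of columns spanning all four centres
#' plus three tuning widths on each side, clipped to the grid.
#'
#' @param grid_shape integer (rows, cols) vertex counts.
#' @param vertex_spacing mm between neighbouring vertices.
#' @param digit_centres named numeric, column coordinate (mm) of peak tuning
#'   for D2..D5; must be strictly increasing.
#' @param tuning_width Gaussian SD of tuning, mm (> 0).
#' @param amplitude peak percent signal change.
#' @return a `sheet_spec` list.
#' @export
sheet_spec <- function(grid_shape = c(40, 100), vertex_spacing = 1,
                       digit_centres = c(D2 = 25, D3 = 45, D4 = 65, D5 = 85),
                       tuning_width = 6, amplitude = 1) {
  spec <- list(grid_shape = as.integer(grid_shape),
               vertex_spacing = vertex_spacing,
               digit_centres = stats::setNames(as.numeric(digit_centres), DIGITS),
               tuning_width = tuning_width, amplitude = amplitude)
  class(spec) <- "sheet_spec"
  spec
}

validate_centres <- function(centres, width) {
  if (any(diff(centres) <= 0)) {
    stop("digit centres must be strictly ordered D2 < D3 < D4 < D5",
         call. = FALSE)
  }
  if (width <= 0) stop("tuning_width must be positive", call. = FALSE)
  invisible(centres)
}

#' Build a ground-truth cortical sheet
#'
#' Constructs the vertex grid, checks the tuning invariants (ordered
#' centres, positive width, grid wide enough to hold all centres with at
#' least two tuning widths of margin) and attaches the ROI mask.
#' Deterministic: the seed is recorded for downstream run simulation.
#'
#' @param spec a [sheet_spec()].
#' @param seed integer seed recorded with the sheet.
#' @return an object of class `ground_truth_sheet`.
#' @export
make_ground_truth_sheet <- function(spec = sheet_spec(), seed = 1L) {
  validate_centres(spec$digit_centres, spec$tuning_width)
  extent <- (spec$grid_shape[2] - 1) * spec$vertex_spacing
  if (min(spec$digit_centres) < 2 * spec$tuning_width ||
      max(spec$digit_centres) > extent - 2 * spec$tuning_width) {
    stop("grid too small: centres need at least 2 tuning widths of margin",
         call. = FALSE)
  }
  col_mm <- (seq_len(spec$grid_shape[2]) - 1) * spec$vertex_spacing
  roi_cols <- col_mm >= min(spec$digit_centres) - 3 * spec$tuning_width &
    col_mm <= max(spec$digit_centres) + 3 * spec$tuning_width
  roi_mask <- matrix(rep(roi_cols, each = spec$grid_shape[1]),
                     nrow = spec$grid_shape[1])
  sheet <- list(grid_shape = spec$grid_shape,
                vertex_spacing = spec$vertex_spacing,
                digit_centres = spec$digit_centres,
                tuning_width = spec$tuning_width,
                amplitude = spec$amplitude,
                roi_mask = roi_mask, seed = as.integer(seed))
  class(sheet) <- "ground_truth_sheet"
  sheet
}

#' @export
print.ground_truth_sheet <- function(x, ...) {
  cat(sprintf("<ground_truth_sheet> %d x %d vertices (%.1f mm spacing)\n",
              x$grid_shape[1], x$grid_shape[2], x$vertex_spacing))
  cat("  centres (mm):",
      paste(names(x$digit_centres), sprintf("%.1f", x$digit_centres),
            collapse = ", "), "\n")
  cat(sprintf("  tuning width %.1f mm, amplitude %.2f%%, ROI %d vertices\n",
              x$tuning_width, x$amplitude, sum(x$roi_mask)))
  invisible(x)
}

n_vertices <- function(sheet) prod(sheet$grid_shape)

# Column coordinate (mm) of every vertex, in column-major vertex order.
vertex_col_mm <- function(sheet) {
  rep((seq_len(sheet$grid_shape[2]) - 1) * sheet$vertex_spacing,
      each = sheet$grid_shape[1])
}

# Row/col (1-based) of a vertex index in column-major order.
vertex_rowcol <- function(sheet, idx) {
  r <- ((idx - 1L) %% sheet$grid_shape[1]) + 1L
  c <- ((idx - 1L) %/% sheet$grid_shape[1]) + 1L
  cbind(row = r, col = c)
}

# Per-vertex tuning amplitude for each digit: vertices x 4 matrix (percent
# signal change), Gaussian in the somatotopic (column) axis.
tuning_amplitudes <- function(sheet) {
  x <- vertex_col_mm(sheet)
  out <- vapply(sheet$digit_centres, function(mu) {
    sheet$amplitude * exp(-(x - mu)^2 / (2 * sheet$tuning_width^2))
  }, numeric(length(x)))
  colnames(out) <- DIGITS
  out
}

#' Session effect on the digit map
#'
#' Encodes the planted remapping: in the glued session the D4 tuning centre
#' is displaced by `d4_shift_mm` (positive = toward D5), with tuning width
#' and amplitude unchanged (area-preserving). Control sessions must carry a
#' zero shift. `centre_jitter_sd_mm` adds independent between-session
#' Gaussian jitter to all four centres.
#'
#' @param session one of `"control1"`, `"control2"`, `"glued"`.
#' @param d4_shift_mm signed displacement of the D4 centre, mm.
#' @param centre_jitter_sd_mm SD of per-centre session jitter, mm.
#' @return a `session_effect` list.
#' @export
session_effect <- function(session, d4_shift_mm = 0, centre_jitter_sd_mm = 0) {
  session <- match.arg(session, SESSIONS)
  if (session != "glued" && d4_shift_mm != 0) {
    stop("d4_shift_mm must be 0 for control sessions", call. = FALSE)
  }
  if (centre_jitter_sd_mm < 0) {
    stop("centre_jitter_sd_mm must be non-negative", call. = FALSE)
  }
  structure(list(session = session, d4_shift_mm = d4_shift_mm,
                 centre_jitter_sd_mm = centre_jitter_sd_mm),
            class = "session_effect")
}

#' Apply a session effect to a ground-truth sheet
#'
#' Displaces the D4 centre by the session's shift and jitters all centres;
#' errors if the resulting centres are no longer strictly ordered.
#'
#' @param sheet a [make_ground_truth_sheet()] result.
#' @param effect a [session_effect()].
#' @param seed integer seed for the jitter draw.
#' @return a new `ground_truth_sheet` with updated centres.
#' @export
apply_session_effect <- function(sheet, effect, seed = sheet$seed) {
  stopifnot(inherits(sheet, "ground_truth_sheet"),
            inherits(effect, "session_effect"))
  centres <- sheet$digit_centres
  centres["D4"] <- centres["D4"] + effect$d4_shift_mm
  if (effect$centre_jitter_sd_mm > 0) {
    set.seed(seed)
    centres <- centres + stats::rnorm(4, 0, effect$centre_jitter_sd_mm)
  }
  if (any(diff(centres) <= 0)) {
    stop("session effect destroys the D2 < D3 < D4 < D5 centre ordering",
         call. = FALSE)
  }
  out <- sheet
  out$digit_centres <- centres
  out$session <- effect$session
  out
}
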