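#' Dice overlap between two binarised digit maps
#'
#' Dice = 2|A n B| / (|A| + |B|), computed within the ROI only; ranges from
#' 0 (no overlap) to 1 (identical non-empty maps). When both maps are empty
#' within the ROI the coefficient is undefined and returned as `NA` with
#' `undefined = TRUE`.
#'
#' @param mapA,mapB logical vertex maps (vectors or matrices of equal size).
#' @param roi_mask logical per vertex.
#' @return a list with `dice`, `n_A`, `n_B`, `n_intersect`, `undefined`.
#' @export
dice_coefficient <- function(mapA, mapB, roi_mask) {
  a <- as.vector(mapA); b <- as.vector(mapB); roi <- as.vector(roi_mask)
  if (length(a) != length(b) || length(a) != length(roi)) {
    stop("maps and ROI must share one vertex grid", call. = FALSE)
  }
  a <- a & roi; b <- b & roi
  n_a <- sum(a); n_b <- sum(b); n_ab <- sum(a & b)
  if (n_a + n_b == 0) {
    return(list(dice = NA_real_, n_A = 0L, n_B = 0L, n_intersect = 0L,
                undefined = TRUE))
  }
  list(dice = 2 * n_ab / (n_a + n_b), n_A = n_a, n_B = n_b,
       n_intersect = n_ab, undefined = FALSE)
}

#' Surface area of a binarised digit representation
#'
#' Survivor count times the per-vertex area.
#'
#' @param map logical vertex map.
#' @param vertex_area area of one vertex, mm^2.
#' @return area in mm^2.
#' @export
digit_surface_area <- function(map, vertex_area = 1) {
  sum(as.vector(map)) * vertex_area
}

#' Peak vertex of a z-map within the ROI
#'
#' Returns the ROI vertex with the maximal z-statistic; ties are broken
#' deterministically toward the lowest vertex index and flagged.
#'
#' @param zmap numeric z per vertex.
#' @param roi_mask logical per vertex.
#' @return list with `vertex` (index into the full grid), `z`, `tie`.
#' @export
peak_vertex <- function(zmap, roi_mask) {
  z <- as.vector(zmap); roi <- as.vector(roi_mask)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  zr <- z[roi]
  zmax <- max(zr)
  hits <- which(roi)[zr >= zmax - 1e-12]
  list(vertex = hits[1], z = zmax, tie = length(hits) > 1)
}

#' Geodesic distance between two vertices on the sheet
#'
#' Shortest-path distance on the 8-connected vertex grid graph (edge
#' weights: spacing for rook moves, spacing * sqrt(2) for diagonal moves),
#' the synthetic analogue of surface geodesic distance. On the full uniform
#' grid this equals the closed form
#' `min(|dr|,|dc|) * sqrt(2) * h + (max(|dr|,|dc|) - min(|dr|,|dc|)) * h`.
#'
#' @param vertexA,vertexB vertex indices (column-major).
#' @param sheet the `ground_truth_sheet` supplying grid shape and spacing.
#' @return distance in mm.
#' @export
peak_to_peak_distance <- function(vertexA, vertexB, sheet) {
  v <- n_vertices(sheet)
  if (vertexA < 1 || vertexA > v || vertexB < 1 || vertexB > v) {
    stop("vertex index outside the sheet", call. = FALSE)
  }
  rc <- vertex_rowcol(sheet, c(vertexA, vertexB))
  dr <- abs(rc[1, "row"] - rc[2, "row"])
  dc <- abs(rc[1, "col"] - rc[2, "col"])
  h <- sheet$vertex_spacing
  (min(dr, dc) * sqrt(2) + (max(dr, dc) - min(dr, dc))) * h
}

#' Overlap measurements for one subject-session digit map stack
#'
#' Computes adjacent-pair Dice coefficients, per-digit surface areas, peak
#' vertices and adjacent peak-to-peak geodesic distances from a
#' [map_digits()] stack.
#'
#' @param maps a `digit_map_stack`.
#' @param sheet the `ground_truth_sheet` (geometry only).
#' @param roi_mask logical ROI per vertex.
#' @return list of data frames `dice`, `area`, `peak_distance` in long
#'   format (one row per digit pair or digit).
#' @export
measure_overlap <- function(maps, sheet, roi_mask) {
  vertex_area <- sheet$vertex_spacing^2
  dice <- do.call(rbind, lapply(1:3, function(i) {
    d <- dice_coefficient(maps$binary_maps[, i], maps$binary_maps[, i + 1],
                          roi_mask)
    data.frame(digit_pair = DIGIT_PAIRS[i], value = d$dice,
               n_A = d$n_A, n_B = d$n_B, n_intersect = d$n_intersect)
  }))
  area <- data.frame(
    digit = DIGITS,
    value = vapply(seq_len(4), function(i) {
      digit_surface_area(maps$binary_maps[, i] & as.vector(roi_mask),
                         vertex_area)
    }, numeric(1)))
  peaks <- lapply(seq_len(4), function(i) peak_vertex(maps$z_maps[, i], roi_mask))
  pkdist <- data.frame(
    digit_pair = DIGIT_PAIRS,
    value = vapply(1:3, function(i) {
      peak_to_peak_distance(peaks[[i]]$vertex, peaks[[i + 1]]$vertex, sheet)
    }, numeric(1)))
  list(dice = dice, area = area, peak_distance = pkdist, peaks = peaks)
}
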