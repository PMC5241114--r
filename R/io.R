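#' Read a long-format measurement table
#'
#' CSV with columns `subject`, `session`, `digit_pair`, `value` (extra
#' columns are kept). Session and digit-pair labels are validated against
#' the study vocabulary.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_long_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "session", "digit_pair", "value")
  if (!all(need %in% names(tab))) {
    stop("malformed table ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(tab$session %in% SESSIONS)) {
    stop("unknown session labels in ", path, call. = FALSE)
  }
  if (!all(tab$digit_pair %in% c(DIGIT_PAIRS, DIGITS))) {
    stop("unknown digit/pair labels in ", path, call. = FALSE)
  }
  tab
}

#' Write a long-format measurement table
#'
#' @param table data frame with at least `subject`, `session`,
#'   `digit_pair`, `value`.
#' @param path CSV destination.
#' @export
write_long_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write the study report's tables and figures
#'
#' Writes every measurement table as CSV, the per-measure ANOVA tables, and
#' summary figures in the style of the study's headline panels (group mean
#' with standard error per digit pair and session, displayed normalised to
#' control 1; statistics are always computed on the raw values).
#'
#' @param report a `study_report`.
#' @param out_dir destination directory (created if absent).
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(report$measurements)) {
    write_long_table(report$measurements[[m]],
                     file.path(out_dir, paste0(m, ".csv")))
  }
  for (m in names(report$analyses)) {
    utils::write.csv(report$analyses[[m]]$anova,
                     file.path(out_dir, paste0("anova_", m, ".csv")),
                     row.names = FALSE)
  }
  for (m in c("dice", "rsa", "jnd", "mispress")) {
    tab <- report$measurements[[m]]
    if (is.null(tab) || !all(c("digit_pair", "value") %in% names(tab)) ||
        !all(tab$digit_pair %in% DIGIT_PAIRS)) next
    fig <- plot_session_by_pair(tab, m)
    ggplot2::ggsave(file.path(out_dir, paste0(m, ".pdf")), fig,
                    width = 5, height = 4)
  }
  invisible(out_dir)
}

#' Session-by-pair summary figure
#'
#' Group mean and standard error of a measure per digit pair and session,
#' normalised per subject and pair to the control 1 value (display
#' convention only).
#'
#' @param table long table `subject`, `session`, `digit_pair`, `value`.
#' @param label y-axis label.
#' @param normalise divide by each subject/pair's control-1 value.
#' @return a ggplot object.
#' @export
plot_session_by_pair <- function(table, label = "value", normalise = TRUE) {
  tab <- table
  if (normalise) {
    base <- tab[tab$session == "control1", c("subject", "digit_pair", "value")]
    names(base)[3] <- "base"
    tab <- merge(tab, base, by = c("subject", "digit_pair"))
    tab$value <- tab$value / tab$base
  }
  agg <- stats::aggregate(value ~ session + digit_pair, tab, function(x) {
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  })
  agg <- cbind(agg[1:2], as.data.frame(agg$value))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$digit_pair, y = .data$mean,
                                    fill = .data$session)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = "digit pair",
                  y = if (normalise) paste(label, "(norm. to control 1)") else label) +
    ggplot2::theme_minimal()
}

#' Write a BOLD run to disk
#'
#' Plain-text matrix form (vertices x timepoints CSV, with a JSON-style
#' header comment carrying TR and design kind), or NIfTI (the vertex grid
#' unrolled to a rows x cols x 1 x time image) when the RNifti package is
#' available and `format = "nifti"`.
#'
#' @param ts a `voxel_time_series`.
#' @param path destination file.
#' @param sheet the sheet (needed to fold vertices for NIfTI export).
#' @param format `"csv"` or `"nifti"`.
#' @export
write_run <- function(ts, path, sheet = NULL, format = c("csv", "nifti")) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, "w")
    writeLines(sprintf("# tr_s=%g kind=%s", ts$tr_s, ts$design$kind), con)
    utils::write.table(ts$data, con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    close(con)
  } else {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("NIfTI export needs the RNifti package", call. = FALSE)
    }
    if (is.null(sheet)) stop("NIfTI export needs the sheet geometry",
                             call. = FALSE)
    arr <- array(ts$data, c(sheet$grid_shape[1], sheet$grid_shape[2], 1,
                            ncol(ts$data)))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(sheet$vertex_spacing, sheet$vertex_spacing, 1,
                             ts$tr_s)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}
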