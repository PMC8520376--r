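#' Read cardiac CSV inputs
#'
#' Plain comma-separated files with a header row, UTF-8, `.` decimal.
#'
#' * Volume-time curves: columns `time_s,volume_ml`.
#' * ECG annotations: columns `lead,qt_ms`; optionally a separate one-row
#'   file `v1_ptf_amplitude_mm,v1_ptf_duration_s` for the P-wave terminal
#'   force inputs.
#' * Biplane discs: columns `index,d4ch_cm,d2ch_cm`, preceded by a comment
#'   line `# long_axis_cm: <L>` carrying the long-axis length.
#'
#' @param path CSV file path.
#' @return A tibble; `read_biplane_discs()` attaches the long-axis length as
#'   the `long_axis_cm` attribute.
#' @export
read_vtc <- function(path) {
  df <- read_checked_csv(path, c("time_s", "volume_ml"))
  validate_vtc(df)
}

#' @rdname read_vtc
#' @param ptf_path Optional path to the one-row PTFV1 CSV; when given, the
#'   returned tibble carries a `ptf` attribute with `amplitude_mm` and
#'   `duration_s`.
#' @export
read_ecg_annotations <- function(path, ptf_path = NULL) {
  df <- read_checked_csv(path, c("lead", "qt_ms"))
  if (!is.null(ptf_path)) {
    ptf <- read_checked_csv(ptf_path,
                            c("v1_ptf_amplitude_mm", "v1_ptf_duration_s"))
    attr(df, "ptf") <- list(amplitude_mm = ptf$v1_ptf_amplitude_mm[1L],
                            duration_s = ptf$v1_ptf_duration_s[1L])
  }
  df
}

#' @rdname read_vtc
#' @export
read_biplane_discs <- function(path) {
  header <- readLines(path, n = 5L)
  meta <- grep("^#", header, value = TRUE)
  L <- NA_real_
  hit <- regmatches(meta, regexpr("long_axis_cm:\\s*[0-9.]+", meta))
  hit <- unlist(hit)
  if (length(hit)) L <- as.numeric(sub(".*:\\s*", "", hit[1L]))
  if (is.na(L)) {
    stop("discs CSV must carry a `# long_axis_cm: <L>` comment line",
         call. = FALSE)
  }
  df <- read_checked_csv(path, c("index", "d4ch_cm", "d2ch_cm"),
                         comment = "#")
  attr(df, "long_axis_cm") <- L
  df
}

read_checked_csv <- function(path, required, comment = "") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, comment = comment,
                        progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("malformed CSV %s: missing column(s) %s", path,
                 paste0("`", missing, "`", collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Plot a volume-time curve with its diastolic segments
#'
#' @param curve Data frame with `time_s` and `volume_ml`.
#' @return A ggplot object with the detected filling segments shaded.
#' @export
plot_vtc <- function(curve) {
  curve <- validate_vtc(curve)
  seg <- detect_diastolic_segments(curve$volume_ml)
  bands <- tibble::tibble(from = curve$time_s[seg$es],
                          to = curve$time_s[seg$ed])
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$time_s,
                                           y = .data$volume_ml))
  if (nrow(bands)) {
    p <- p + ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$from, xmax = .data$to,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "LV volume (mL)",
                  title = "Volume-time curve",
                  subtitle = "shaded: diastolic filling segments") +
    ggplot2::theme_minimal()
}
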