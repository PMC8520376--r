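#' Left ventricular ejection fraction
#'
#' \eqn{\mathrm{LVEF} = 100 (\mathrm{LVEDV} - \mathrm{LVESV}) /
#' \mathrm{LVEDV}}, the fraction of the end-diastolic volume ejected per
#' beat.
#'
#' @param lvedv End-diastolic volume (mL), `> lvesv`.
#' @param lvesv End-systolic volume (mL), `> 0`.
#' @return Ejection fraction in percent, in `(0, 100)`. Vectorized.
#' @examples
#' lvef(120, 40)  # 66.67
#' @export
lvef <- function(lvedv, lvesv) {
  if (any(lvesv <= 0)) stop("`lvesv` must be > 0", call. = FALSE)
  if (any(lvesv >= lvedv)) {
    stop("`lvedv` must exceed `lvesv` (end-diastole is the larger volume)",
         call. = FALSE)
  }
  100 * (lvedv - lvesv) / lvedv
}

#' Biplane Simpson method-of-discs volume
#'
#' The chamber is modelled as a stack of `n` elliptical discs whose paired
#' diameters come from orthogonal apical four- and two-chamber views:
#' \deqn{V = \frac{\pi}{4} \frac{L}{n} \sum_{i=1}^{n} a_i b_i,}
#' with \eqn{a_i, b_i} the disc diameters (cm), \eqn{L} the long-axis length
#' (cm), and the result in mL. Diameters are conventionally measured at
#' mid-disc stations \eqn{(i - 1/2) L / n}.
#'
#' @param discs Data frame with numeric columns `d4ch_cm` and `d2ch_cm`
#'   (paired disc diameters, equal length `n >= 4`, all positive).
#' @param long_axis_cm Positive long-axis length L (cm). If `discs` carries a
#'   `long_axis_cm` attribute (as set by [read_biplane_discs()]), it is used
#'   when the argument is missing.
#' @return Volume in mL (scalar).
#' @examples
#' # discs sampled from an ellipsoid, closed form (pi/6) D1 D2 L
#' n <- 20; L <- 8
#' z <- (seq_len(n) - 0.5) * L / n
#' shrink <- sqrt(pmax(0, 1 - ((z - L / 2) / (L / 2))^2))
#' simpson_biplane_volume(
#'   data.frame(d4ch_cm = 4 * shrink, d2ch_cm = 3 * shrink), long_axis_cm = L)
#' @export
simpson_biplane_volume <- function(discs, long_axis_cm = NULL) {
  stopifnot(is.data.frame(discs))
  if (is.null(long_axis_cm)) long_axis_cm <- attr(discs, "long_axis_cm")
  if (is.null(long_axis_cm) || !is.numeric(long_axis_cm) ||
      long_axis_cm <= 0) {
    stop("`long_axis_cm` must be a positive length in cm", call. = FALSE)
  }
  if (!all(c("d4ch_cm", "d2ch_cm") %in% names(discs))) {
    stop("`discs` needs columns `d4ch_cm` and `d2ch_cm`", call. = FALSE)
  }
  a <- discs$d4ch_cm; b <- discs$d2ch_cm
  if (anyNA(a) || anyNA(b)) {
    stop("disc diameter lists have unequal lengths or missing values",
         call. = FALSE)
  }
  n <- length(a)
  if (n < 4L) stop("need at least 4 discs", call. = FALSE)
  if (any(a <= 0) || any(b <= 0)) {
    stop("all disc diameters must be positive", call. = FALSE)
  }
  (pi / 4) * (long_axis_cm / n) * sum(a * b)
}

#' Mean diastolic filling rate from a volume-time curve
#'
#' The mean filling rate (MFR) is the average slope of the left-ventricular
#' volume-time curve over the diastolic filling segment(s) — from an
#' end-systolic minimum to the next end-diastolic maximum. Per-point slopes
#' use central finite differences in the segment interior and one-sided
#' differences at the segment ends; the MFR is the arithmetic mean of those
#' slopes (with several cycles, the mean of per-cycle MFRs).
#'
#' @param curve Data frame with strictly increasing `time_s` and positive
#'   `volume_ml` columns, at least 4 samples.
#' @param es_index,ed_index Optional integer vectors annotating end-systole
#'   and the following end-diastole per cycle (equal lengths, `ed > es`,
#'   segment length `>= 2`). When omitted, segments are detected as each
#'   local volume minimum followed by the next local maximum.
#' @return MFR in mL/s (scalar), with the per-cycle breakdown in the
#'   `"cycles"` attribute (a tibble with `es_index`, `ed_index`, `mfr`).
#' @examples
#' t <- seq(0, 1, length.out = 64)
#' vtc <- data.frame(time_s = t, volume_ml = 70 - 30 * cos(2 * pi * t))
#' mean_filling_rate(vtc)  # analytic mean slope 120 mL/s
#' @export
mean_filling_rate <- function(curve, es_index = NULL, ed_index = NULL) {
  curve <- validate_vtc(curve)
  t <- curve$time_s; v <- curve$volume_ml
  if (is.null(es_index) || is.null(ed_index)) {
    seg <- detect_diastolic_segments(v)
    es_index <- seg$es; ed_index <- seg$ed
  }
  es_index <- as.integer(es_index); ed_index <- as.integer(ed_index)
  if (length(es_index) == 0L || length(es_index) != length(ed_index)) {
    stop("no diastolic filling segment could be annotated", call. = FALSE)
  }
  if (any(ed_index - es_index < 1L)) {
    stop("each diastolic segment needs at least 2 samples", call. = FALSE)
  }
  cycles <- purrr::map2_dbl(es_index, ed_index, function(i0, i1) {
    mean(pointwise_slopes(t[i0:i1], v[i0:i1]))
  })
  out <- mean(cycles)
  attr(out, "cycles") <- tibble::tibble(es_index = es_index,
                                        ed_index = ed_index, mfr = cycles)
  out
}

validate_vtc <- function(curve) {
  stopifnot(is.data.frame(curve))
  if (!all(c("time_s", "volume_ml") %in% names(curve))) {
    stop("volume-time curve needs columns `time_s` and `volume_ml`",
         call. = FALSE)
  }
  if (nrow(curve) < 4L) stop("need at least 4 samples", call. = FALSE)
  if (any(diff(curve$time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  if (any(curve$volume_ml <= 0)) {
    stop("`volume_ml` must be positive", call. = FALSE)
  }
  curve
}

# Central differences interior, one-sided at the ends; handles nonuniform
# sampling via the standard three-point formula.
pointwise_slopes <- function(t, v) {
  n <- length(t)
  if (n == 2L) return(rep(diff(v) / diff(t), 2L))
  s <- numeric(n)
  s[1L] <- (v[2L] - v[1L]) / (t[2L] - t[1L])
  s[n] <- (v[n] - v[n - 1L]) / (t[n] - t[n - 1L])
  i <- 2:(n - 1L)
  s[i] <- (v[i + 1L] - v[i - 1L]) / (t[i + 1L] - t[i - 1L])
  s
}

# Each strict local minimum paired with the next strict local maximum.
# Endpoints count as extrema so a single half-cycle (min at 1, max at n)
# is detected.
detect_diastolic_segments <- function(v) {
  n <- length(v)
  is_min <- c(v[1L] < v[2L],
              v[2:(n - 1L)] < v[1:(n - 2L)] & v[2:(n - 1L)] <= v[3:n],
              v[n] < v[n - 1L])
  is_max <- c(v[1L] > v[2L],
              v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n],
              v[n] > v[n - 1L])
  mins <- which(is_min); maxs <- which(is_max)
  es <- integer(0); ed <- integer(0)
  for (m in mins) {
    nxt <- maxs[maxs > m]
    if (length(nxt)) {
      es <- c(es, m)
      ed <- c(ed, nxt[1L])
    }
  }
  list(es = es, ed = ed)
}

#' Diastolic function velocity ratios
#'
#' E/A (early over late diastolic mitral inflow velocity) and E/E' (early
#' inflow over early diastolic mitral annulus velocity), the standard
#' Doppler indices of diastolic function.
#'
#' @param measurements Data frame (or one-row tibble) with positive columns
#'   `e_peak`, `a_peak`, `e_prime` in cm/s.
#' @return Tibble with columns `e_over_a` and `e_over_eprime` (one row per
#'   input row).
#' @examples
#' ratio_metrics(data.frame(e_peak = 80, a_peak = 60, e_prime = 10))
#' @export
ratio_metrics <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  need <- c("e_peak", "a_peak", "e_prime")
  if (!all(need %in% names(measurements))) {
    stop("`measurements` needs columns e_peak, a_peak, e_prime",
         call. = FALSE)
  }
  if (any(measurements$a_peak <= 0) || any(measurements$e_prime <= 0) ||
      any(measurements$e_peak <= 0)) {
    stop("velocities must be positive", call. = FALSE)
  }
  tibble::tibble(
    e_over_a = measurements$e_peak / measurements$a_peak,
    e_over_eprime = measurements$e_peak / measurements$e_prime
  )
}

#' QT dispersion across ECG leads
#'
#' QTd = max(QT) - min(QT) over the leads of a synchronized 12-lead ECG
#' (ms); an index of repolarization heterogeneity. Values outside the
#' 200-700 ms plausibility window trigger a warning (not an error).
#'
#' @param annotations Data frame with columns `lead` and `qt_ms`; 2 to 12
#'   leads.
#' @return QT dispersion in ms (scalar, `>= 0`).
#' @examples
#' qt_dispersion(data.frame(lead = c("I", "II", "V1", "V5", "V6"),
#'                          qt_ms = c(380, 395, 402, 410, 441)))  # 61
#' @export
qt_dispersion <- function(annotations) {
  stopifnot(is.data.frame(annotations))
  if (!all(c("lead", "qt_ms") %in% names(annotations))) {
    stop("`annotations` needs columns `lead` and `qt_ms`", call. = FALSE)
  }
  qt <- annotations$qt_ms
  if (length(qt) < 2L) {
    stop("QT dispersion needs at least 2 leads", call. = FALSE)
  }
  if (length(qt) > 12L) {
    stop("more than 12 leads supplied", call. = FALSE)
  }
  if (any(qt <= 200 | qt >= 700)) {
    warning("QT interval outside the 200-700 ms plausibility window",
            call. = FALSE)
  }
  max(qt) - min(qt)
}

#' P-wave terminal force in lead V1
#'
#' PTFV1 = (negative-phase amplitude, mm at 10 mm/mV) x (negative-phase
#' duration, s), in mm·s. Reported as a negative number; values more
#' negative than about -0.04 mm·s are the classic left-atrial-overload
#' abnormality.
#'
#' @param amplitude_mm Nonpositive amplitude of the terminal (negative)
#'   P-wave phase in V1, mm.
#' @param duration_s Nonnegative duration of that phase, s.
#' @return PTFV1 in mm·s (`<= 0`). Vectorized.
#' @examples
#' ptfv1(-1.0, 0.04)  # -0.04
#' @export
ptfv1 <- function(amplitude_mm, duration_s) {
  if (any(amplitude_mm > 0)) {
    stop("`amplitude_mm` must be <= 0 (terminal P-wave phase is negative)",
         call. = FALSE)
  }
  if (any(duration_s < 0)) {
    stop("`duration_s` must be >= 0", call. = FALSE)
  }
  amplitude_mm * duration_s
}
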