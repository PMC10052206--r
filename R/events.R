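# Event detection on trends and raw channels: presyncopal complexity surges,
# reference MBP/HR drops, and lead times between them.

event_annotation <- function(kind, time, detail = "") {
  structure(list(kind = kind, time = time, detail = detail),
            class = "qct_event")
}

#' @export
print.qct_event <- function(x, ...) {
  cat(sprintf("[%s] t = %.1f s %s\n", x$kind, x$time,
              if (nzchar(x$detail)) paste0("(", x$detail, ")") else ""))
  invisible(x)
}

resolve_baseline <- function(times, baseline) {
  .check(!is.null(baseline), "a baseline interval is required")
  if (length(baseline) == 1) baseline <- c(min(times), min(times) + baseline)
  .check(length(baseline) == 2 && baseline[2] > baseline[1],
         "baseline must be a span in seconds or an interval c(start, end)")
  baseline
}

#' Detect a sustained complexity surge
#'
#' Deterministic stand-in for reading a rise off the trend by eye: the alert
#' fires at the first time the complexity exceeds
#' `median(baseline) + k * MAD(baseline)` for at least `s` consecutive trend
#' points after the baseline interval. MAD is the raw median absolute
#' deviation (no consistency constant); when the baseline is so quiet that
#' its MAD vanishes, a floor of 5% of the baseline median is used so the
#' threshold stays meaningful.
#'
#' @param fit A `qct_trend` (or a data frame with `window_end_time` and `C`).
#' @param baseline Baseline interval `c(start, end)` in seconds, or a single
#'   span in seconds taken from the start of the trend. Defaults to
#'   `config$surge_baseline` of the fit.
#' @param k Threshold multiplier (default 6).
#' @param s Required consecutive exceeding points (default 5).
#' @return An event annotation of kind `"presyncope_alert"` (time = first
#'   point of the sustained run), or `NULL` when no surge occurs.
#' @export
detect_surge <- function(fit, baseline = NULL, k = 6, s = 5) {
  tr <- if (inherits(fit, "qct_trend")) fit$trend else fit
  .check(all(c("window_end_time", "C") %in% names(tr)),
         "fit must carry window_end_time and C")
  if (is.null(baseline) && inherits(fit, "qct_trend"))
    baseline <- fit$config$surge_baseline
  baseline <- resolve_baseline(tr$window_end_time, baseline)
  in_base <- tr$window_end_time >= baseline[1] & tr$window_end_time <= baseline[2]
  .check(sum(in_base) >= 10,
         "insufficient baseline: need >= 10 trend points in the interval")
  base_c <- tr$C[in_base]
  med <- median(base_c)
  spread <- mad(base_c, constant = 1)
  thr <- med + k * max(spread, 0.05 * med)

  after <- which(tr$window_end_time > baseline[2])
  if (length(after) < s) return(NULL)
  exceed <- tr$C[after] > thr
  run <- rle(exceed)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= s)
  if (length(hit) == 0) return(NULL)
  first <- ends[hit[1]] - run$lengths[hit[1]] + 1
  event_annotation("presyncope_alert", tr$window_end_time[after[first]],
                   sprintf("C %.2f > threshold %.2f sustained %d points",
                           tr$C[after[first]], thr, s))
}

sustained_below <- function(times, x, threshold, s) {
  ok <- !is.na(x)
  below <- x < threshold & ok
  run <- rle(as.vector(below))
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= s)
  if (length(hit) == 0) return(NULL)
  times[ends[hit[1]] - run$lengths[hit[1]] + 1]
}

#' Reference hemodynamic events (MBP and HR drops)
#'
#' The classic markers a complexity surge is compared against: `mbp_drop`
#' fires at the first time MBP stays below its baseline median minus `d_mbp`
#' for at least `sustain` beats; `hr_drop` analogously with `d_hr`. Both are
#' deterministic.
#'
#' @param records Beat-record data frame with `t`, `mbp`, `hr`.
#' @param baseline Baseline interval `c(start, end)` in seconds (or a span
#'   from the start of the record).
#' @param d_mbp,d_hr Drop sizes (mmHg, bpm); defaults 20 and 15.
#' @param sustain Required consecutive beats below threshold (default 5).
#' @return Named list with elements `mbp_drop` and `hr_drop` (event
#'   annotations or `NULL` when the channel never drops).
#' @export
reference_events <- function(records, baseline, d_mbp = 20, d_hr = 15,
                             sustain = 5) {
  .check(all(c("t", "mbp", "hr") %in% names(records)),
         "records must carry t, mbp and hr")
  baseline <- resolve_baseline(records$t, baseline)
  in_base <- records$t >= baseline[1] & records$t <= baseline[2]
  .check(sum(in_base & !is.na(records$mbp)) >= 10 &&
         sum(in_base & !is.na(records$hr)) >= 10,
         "insufficient baseline: need >= 10 valid beats in the interval")
  after <- records$t > baseline[2]
  mbp_med <- median(records$mbp[in_base], na.rm = TRUE)
  hr_med <- median(records$hr[in_base], na.rm = TRUE)
  t_mbp <- sustained_below(records$t[after], records$mbp[after],
                           mbp_med - d_mbp, sustain)
  t_hr <- sustained_below(records$t[after], records$hr[after],
                          hr_med - d_hr, sustain)
  list(
    mbp_drop = if (is.null(t_mbp)) NULL else
      event_annotation("mbp_drop", t_mbp,
                       sprintf("MBP below %.1f mmHg sustained", mbp_med - d_mbp)),
    hr_drop = if (is.null(t_hr)) NULL else
      event_annotation("hr_drop", t_hr,
                       sprintf("HR below %.1f bpm sustained", hr_med - d_hr)))
}

#' Lead time between an alert and a reference event
#'
#' `reference$time - alert$time` in seconds: positive when the complexity
#' alert led the reference change, negative when it lagged.
#'
#' @param alert,reference Event annotations (lists with a `time` field).
#' @return Lead time in seconds, or `NA_real_` when either event is missing.
#' @export
lead_time <- function(alert, reference) {
  if (is.null(alert) || is.null(reference) ||
      is.null(alert$time) || is.null(reference$time)) {
    message("lead time undefined: missing annotation")
    return(NA_real_)
  }
  reference$time - alert$time
}
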