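# Sliding-window complexity trends. Windows are beat-counted and causal
# (right-aligned): the state reported at time t is computed from the `window`
# beats ending at t, which is the online-monitoring convention.

#' Beat-indexed complexity trend
#'
#' The package's main entry point. Takes a beat-record table (or an already
#' assembled state matrix), slides a causal window of `window` beats in steps
#' of `step` beats, and for every window position builds the dependency
#' matrices, the complexity `C`, its bounds `C_min`/`C_critical` and the
#' per-variable complexity profile. Gap handling is pairwise: each variable
#' pair uses its pairwise-complete rows, and pairs falling below the
#' `min_valid_fraction` gap policy are forced unstructured for that window.
#'
#' All stochastic steps (the permutation surrogates) are driven by `seed`;
#' each window/pair has a stream derived from `(seed, window index, pair
#' index)`, so the trend is reproducible bit for bit and unaffected by the
#' caller's RNG state.
#'
#' @param records A beat-record data frame (see [read_beats()]) or a
#'   `qct_state_matrix` from [assemble_state_matrix()].
#' @param subject A [qct_subject()] (required when derived variables must be
#'   computed from ICG primitives).
#' @param window,step Window length and step, in beats (override the config).
#' @param config A [qct_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param store_matrices Keep each window's `qct_matrix_pair` in the result
#'   (needed by [profile_at()] and [complexity_map()] at a time point).
#' @return An object of class `qct_trend`: list with `trend` (data frame:
#'   `window_index`, `window_end_time`, `C`, `C_min`, `C_critical`,
#'   `n_beats_used`), `profiles` (windows x variables percentage matrix),
#'   `states` (list of matrix pairs, if stored), `variables`, `window`,
#'   `step`, `config`, `seed`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_hutt(scenario_presets()$baseline_supine)
#' fit <- qct(sim$records, subject = qct_subject(80, 180, "male"),
#'            window = 100, step = 25)
#' print(fit)
#' }
qct <- function(records, subject = NULL, window = config$window,
                step = config$step, config = qct_config(),
                seed = config$seed, store_matrices = TRUE) {
  sm <- if (inherits(records, "qct_state_matrix")) records
        else assemble_state_matrix(records, subject, config)
  M <- nrow(sm$data)
  .check(M >= window, sprintf(
    "insufficient data: %d beats for a window of %d", M, window))
  .check(step >= 1, "step must be >= 1")

  ends <- seq(from = window, to = M, by = step)
  n_win <- length(ends)
  vars <- sm$variables
  trend <- data.frame(window_index = seq_len(n_win),
                      window_end_time = sm$times[ends],
                      C = NA_real_, C_min = NA_real_, C_critical = NA_real_,
                      n_beats_used = NA_integer_)
  profiles <- matrix(NA_real_, n_win, length(vars),
                     dimnames = list(NULL, vars))
  states <- if (store_matrices) vector("list", n_win) else NULL

  for (w in seq_len(n_win)) {
    rows <- (ends[w] - window + 1):ends[w]
    mp <- build_matrices(sm$data[rows, , drop = FALSE],
                         mask = sm$mask[rows, , drop = FALSE],
                         alpha = config$alpha,
                         n_surrogates = config$n_surrogates,
                         min_valid_fraction = config$min_valid_fraction,
                         seed = seed, window_index = w)
    bounds <- complexity_bounds(mp)
    trend$C[w] <- complexity(mp)
    trend$C_min[w] <- bounds[["c_min"]]
    trend$C_critical[w] <- bounds[["c_critical"]]
    trend$n_beats_used[w] <- min(diag(mp$n_valid))
    profiles[w, ] <- complexity_profile(mp, method = config$profile_method)
    if (store_matrices) states[[w]] <- mp
  }
  structure(list(trend = trend, profiles = profiles, states = states,
                 variables = vars, window = as.integer(window),
                 step = as.integer(step), config = config,
                 seed = as.integer(seed)),
            class = "qct_trend")
}

#' @export
as.data.frame.qct_trend <- function(x, ...) {
  prof <- as.data.frame(x$profiles)
  names(prof) <- paste0("profile_", names(prof))
  cbind(x$trend, prof)
}

#' @export
print.qct_trend <- function(x, ...) {
  cat(sprintf("Complexity trend: %d windows of %d beats (step %d), %d variables\n",
              nrow(x$trend), x$window, x$step, length(x$variables)))
  cat(sprintf("  time span: %.1f - %.1f s\n",
              min(x$trend$window_end_time), max(x$trend$window_end_time)))
  cat(sprintf("  C: median %.2f bits (range %.2f - %.2f); bounds %.2f - %.2f bits\n",
              median(x$trend$C), min(x$trend$C), max(x$trend$C),
              median(x$trend$C_min), median(x$trend$C_critical)))
  invisible(x)
}

#' @export
summary.qct_trend <- function(object, ...) {
  tr <- object$trend
  edge_freq <- NULL
  if (!is.null(object$states)) {
    N <- length(object$variables)
    acc <- matrix(0, N, N, dimnames = list(object$variables, object$variables))
    for (mp in object$states) acc <- acc + mp$S
    acc <- acc / length(object$states)
    diag(acc) <- NA
    edge_freq <- acc
  }
  out <- list(n_windows = nrow(tr), window = object$window, step = object$step,
              variables = object$variables,
              c_summary = summary(tr$C),
              margin = summary((tr$C_critical - tr$C) /
                               pmax(tr$C_critical - tr$C_min, .Machine$double.eps)),
              mean_profile = colMeans(object$profiles),
              edge_frequency = edge_freq)
  class(out) <- "summary.qct_trend"
  out
}

#' @export
print.summary.qct_trend <- function(x, ...) {
  cat(sprintf("Complexity trend summary: %d windows of %d beats (step %d)\n",
              x$n_windows, x$window, x$step))
  cat("C (bits):\n"); print(x$c_summary)
  cat("Relative headroom (C_critical - C) / (C_critical - C_min):\n")
  print(x$margin)
  cat("Mean complexity profile (%):\n")
  print(round(sort(x$mean_profile, decreasing = TRUE), 1))
  if (!is.null(x$edge_frequency)) {
    freq <- x$edge_frequency
    ut <- which(upper.tri(freq) & freq >= 0.5, arr.ind = TRUE)
    if (nrow(ut)) {
      cat("Pairs structured in >= 50% of windows:\n")
      lab <- apply(ut, 1, function(ij)
        sprintf("  %s-%s: %.0f%%", rownames(freq)[ij[1]],
                colnames(freq)[ij[2]], 100 * freq[ij[1], ij[2]]))
      cat(paste(lab, collapse = "\n"), "\n")
    }
  }
  invisible(x)
}

#' Plot a complexity trend
#'
#' Complexity versus time with the `C_min`/`C_critical` bounds; optionally a
#' second panel with the MBP and HR channels of the underlying recording and
#' vertical markers at annotated events.
#'
#' @param x A `qct_trend`.
#' @param records Optional beat-record data frame for the MBP/HR overlay.
#' @param events Optional list of event annotations to mark.
#' @param ... Passed to `plot()`.
#' @export
plot.qct_trend <- function(x, records = NULL, events = NULL, ...) {
  tr <- x$trend
  overlay <- !is.null(records)
  if (overlay) {
    old <- par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
    on.exit(par(old))
  }
  plot(tr$window_end_time, tr$C, type = "l", lwd = 1.5,
       xlab = "time (s)", ylab = "complexity (bits)",
       ylim = range(tr$C_min, tr$C_critical), ...)
  lines(tr$window_end_time, tr$C_min, lty = 3, col = "grey40")
  lines(tr$window_end_time, tr$C_critical, lty = 3, col = "grey40")
  if (!is.null(events)) {
    for (e in events) if (!is.null(e)) abline(v = e$time, col = "red3", lty = 2)
  }
  if (overlay) {
    plot(records$t, records$mbp, type = "l", col = "blue3",
         xlab = "time (s)", ylab = "MBP (mmHg) / HR (bpm)",
         ylim = range(c(records$mbp, records$hr), na.rm = TRUE))
    lines(records$t, records$hr, col = "darkorange3")
    legend("topright", legend = c("MBP", "HR"), bty = "n",
           col = c("blue3", "darkorange3"), lty = 1)
    if (!is.null(events)) {
      for (e in events) if (!is.null(e)) abline(v = e$time, col = "red3", lty = 2)
    }
  }
  invisible(x)
}

#' Complexity profile at a time point
#'
#' Extracts the per-variable complexity profile of the window ending at (or
#' just before) `at_time`, sorted in decreasing order of contribution - the
#' presentation used for profiling the moment of syncope.
#'
#' @param fit A `qct_trend` (fitted with `store_matrices = TRUE` if the
#'   matrices are also wanted).
#' @param at_time Time in seconds.
#' @return List with `time` (the window end actually used), `window_index`,
#'   `profile` (sorted percentages) and, when available, the window's
#'   `qct_matrix_pair` as `state`.
#' @export
profile_at <- function(fit, at_time) {
  .check(inherits(fit, "qct_trend"), "fit must be a qct_trend")
  idx <- which(fit$trend$window_end_time <= at_time)
  .check(length(idx) > 0,
         "at_time is earlier than the first complete window")
  w <- max(idx)
  prof <- sort(fit$profiles[w, ], decreasing = TRUE)
  list(time = fit$trend$window_end_time[w], window_index = w,
       profile = prof,
       state = if (!is.null(fit$states)) fit$states[[w]] else NULL)
}
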