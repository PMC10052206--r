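# Run configuration: every tunable of the pipeline in one validated,
# serializable object.

#' Pipeline configuration
#'
#' Collects all tunable parameters of the analysis pipeline. Defaults follow
#' the monitoring setup the package documents: window of 100 beats stepped
#' beat by beat, surrogate test at `alpha = 0.05` with 200 permutations, and
#' the 11-component hemodynamic state vector.
#'
#' @param window Sliding-window length in beats (>= 4; 50/100/125 are the
#'   documented choices).
#' @param step Window step in beats (>= 1).
#' @param alpha Significance level of the dependency test.
#' @param n_surrogates Number of permutation surrogates per pair.
#' @param min_valid_fraction Gap policy: minimum fraction of window rows a
#'   pair needs before it is forced unstructured.
#' @param variables State-vector variable names, in order.
#' @param include_pp If `TRUE`, pulse pressure replaces SBP/DBP in the state
#'   vector (avoids an algebraically redundant triple).
#' @param seed Default integer seed for all stochastic steps.
#' @param cvp_assumed Assumed central venous pressure (mmHg) for SVR.
#' @param heather_index_form `"product"` (`dZmax * TRC`) or `"quotient"`
#'   (`dZmax / TRC`).
#' @param profile_method Profile attribution method, see
#'   [complexity_profile()].
#' @param surge_k Surge threshold multiplier on the baseline MAD.
#' @param surge_s Number of consecutive exceeding points required.
#' @param surge_baseline Optional default baseline interval `c(start, end)`
#'   in seconds for [detect_surge()].
#' @param d_mbp,d_hr Sustained drops (mmHg, bpm) defining the MBP/HR
#'   reference events.
#' @return An object of class `qct_config` (a validated named list).
#' @export
qct_config <- function(window = 100, step = 1, alpha = 0.05, n_surrogates = 200,
                       min_valid_fraction = 0.5, variables = NULL,
                       include_pp = FALSE, seed = 1, cvp_assumed = 6,
                       heather_index_form = c("product", "quotient"),
                       profile_method = c("leave_one_out", "eigenvector"),
                       surge_k = 6, surge_s = 5, surge_baseline = NULL,
                       d_mbp = 20, d_hr = 15) {
  heather_index_form <- match.arg(heather_index_form)
  profile_method <- match.arg(profile_method)
  if (is.null(variables)) {
    variables <- if (include_pp)
      c("HR", "PP", "MBP", "LVET", "PEP", "SV", "CO", "HI", "TAC", "SVR")
    else QCT_VARIABLES
  }
  .check(window >= 4, "window must be >= 4 beats")
  .check(step >= 1, "step must be >= 1")
  .check(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  .check(n_surrogates >= 1, "n_surrogates must be >= 1")
  .check(min_valid_fraction >= 0 && min_valid_fraction <= 1,
         "min_valid_fraction must be in [0, 1]")
  .check(length(variables) >= 2 && !anyDuplicated(variables),
         "variables must be >= 2 unique names")
  .check(surge_k > 0 && surge_s >= 1, "surge parameters must be positive")
  .check(d_mbp > 0 && d_hr > 0, "event thresholds must be positive")
  .check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
         "seed must be a single integer")
  structure(list(window = as.integer(window), step = as.integer(step),
                 alpha = alpha, n_surrogates = as.integer(n_surrogates),
                 min_valid_fraction = min_valid_fraction,
                 variables = variables, include_pp = include_pp,
                 seed = as.integer(seed), cvp_assumed = cvp_assumed,
                 heather_index_form = heather_index_form,
                 profile_method = profile_method,
                 surge_k = surge_k, surge_s = as.integer(surge_s),
                 surge_baseline = surge_baseline,
                 d_mbp = d_mbp, d_hr = d_hr),
            class = "qct_config")
}

#' @export
print.qct_config <- function(x, ...) {
  cat(sprintf(paste0("qct_config: window %d, step %d, alpha %.3f, ",
                     "%d surrogates, %d variables, seed %d\n"),
              x$window, x$step, x$alpha, x$n_surrogates,
              length(x$variables), x$seed))
  invisible(x)
}

#' Save / load a configuration as YAML
#'
#' The YAML round-trip is exact: `load_config(save_config(cfg, f))` restores
#' an identical configuration.
#'
#' @param config A [qct_config()].
#' @param path YAML file path.
#' @return `save_config()` returns `path` invisibly; `load_config()` a
#'   `qct_config`.
#' @export
save_config <- function(config, path) {
  .check(inherits(config, "qct_config"), "config must be a qct_config")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$surge_baseline <- if (is.null(raw$surge_baseline)) NULL
                        else as.numeric(unlist(raw$surge_baseline))
  do.call(qct_config, raw)
}

# short provenance stamp used in output headers
config_hash <- function(config) {
  fnv1a_hash(yaml::as.yaml(unclass(config)))
}
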