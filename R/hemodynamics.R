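# Impedance-cardiography parameter derivation: from the per-beat ICG
# primitives (Z0, dZmax, TRC, LVET) and blood pressures to the derived
# hemodynamic variables (SV, CO, HI, TAC, SVR) that make up the state vector.

#' Subject anthropometry and analysis constants
#'
#' Bundles the subject-level information needed to derive stroke volume and
#' vascular resistance from impedance-cardiography primitives: weight, height,
#' sex, the assumed central venous pressure (CVP is not measured by ICG) and
#' an optional multiplicative correction on the electrically participating
#' tissue volume.
#'
#' @param weight Body weight in kg (> 0).
#' @param height Body height in cm (> 0).
#' @param sex `"male"` or `"female"`.
#' @param cvp Assumed central venous pressure in mmHg used in the SVR
#'   derivation. Default 6.
#' @param vept_correction Multiplicative correction factor on VEPT (default 1),
#'   the hook for weight/sex adjustments of the basic height-cubed convention.
#' @return An object of class `qct_subject`.
#' @seealso [compute_vept()]
#' @export
#' @examples
#' qct_subject(weight = 80, height = 180, sex = "male")
qct_subject <- function(weight, height, sex = c("male", "female"),
                        cvp = 6, vept_correction = 1) {
  sex <- match.arg(sex)
  .check(is.numeric(weight) && length(weight) == 1 && is.finite(weight) && weight > 0,
         "weight must be a single positive number (kg)")
  .check(is.numeric(height) && length(height) == 1 && is.finite(height) && height > 0,
         "height must be a single positive number (cm)")
  .check(is.numeric(cvp) && length(cvp) == 1 && is.finite(cvp) && cvp >= 0,
         "cvp must be a single non-negative number (mmHg)")
  .check(is.numeric(vept_correction) && vept_correction > 0,
         "vept_correction must be positive")
  structure(list(weight = weight, height = height, sex = sex,
                 cvp = cvp, vept_correction = vept_correction),
            class = "qct_subject")
}

#' @export
print.qct_subject <- function(x, ...) {
  cat(sprintf("Subject: %s, %.0f kg, %.0f cm (CVP %.1f mmHg, VEPT %.0f mL)\n",
              x$sex, x$weight, x$height, x$cvp, compute_vept(x)))
  invisible(x)
}

#' Volume of electrically participating tissue (VEPT)
#'
#' Computes the thoracic tissue volume used in the impedance-cardiography
#' stroke-volume derivation, following the Sramek convention
#' `VEPT = (0.17 * height)^3 / 4.25` (height in cm, volume in mL), with an
#' optional multiplicative correction factor standing in for the
#' weight/sex-based adjustment used by some devices.
#'
#' @param subject A [qct_subject()], or a numeric weight in kg when `height`
#'   is supplied directly.
#' @param height Body height in cm (only when `subject` is a bare weight).
#' @param sex `"male"` or `"female"` (only for the bare-argument form).
#' @param correction Multiplicative correction factor (default taken from the
#'   subject, or 1).
#' @return Volume in mL.
#' @export
#' @examples
#' compute_vept(qct_subject(80, 180, "male"))  # (0.17*180)^3 / 4.25
compute_vept <- function(subject, height = NULL, sex = "male", correction = NULL) {
  if (inherits(subject, "qct_subject")) {
    h <- subject$height
    corr <- if (is.null(correction)) subject$vept_correction else correction
    w <- subject$weight
  } else {
    w <- subject
    h <- height
    corr <- if (is.null(correction)) 1 else correction
  }
  .check(is.numeric(w) && all(is.finite(w)) && all(w > 0), "weight must be positive")
  .check(is.numeric(h) && all(is.finite(h)) && all(h > 0), "height must be positive")
  (0.17 * h)^3 / 4.25 * corr
}

# guard a vectorized precondition, ignoring NA (gaps)
.bad <- function(x, test) any(test(x[!is.na(x)]))

#' Derived hemodynamic parameters
#'
#' One-line derivations of the beat-level hemodynamic parameters from the
#' impedance-cardiography primitives and blood pressures:
#'
#' * `derive_sv(vept, dzmax, lvet, z0)` — stroke volume,
#'   `SV = VEPT * dZmax * LVET / Z0` (mL).
#' * `derive_co(sv, hr)` — cardiac output, `CO = SV * HR / 1000` (L/min).
#' * `derive_hi(dzmax, trc, form)` — Heather index; `form = "product"` gives
#'   `dZmax * TRC` and `form = "quotient"` the conventional `dZmax / TRC`.
#' * `derive_tac(sv, sbp, dbp)` — total arterial compliance,
#'   `TAC = SV / (SBP - DBP)` (mL/mmHg).
#' * `derive_svr(mbp, cvp, co)` — systemic vascular resistance,
#'   `SVR = 80 * (MBP - CVP) / CO` (dyn s cm^-5).
#'
#' All functions are vectorized and propagate `NA` (recording gaps) through
#' to the result; preconditions are checked on the non-missing entries only.
#'
#' @param vept Electrically participating tissue volume, mL.
#' @param dzmax Maximum impedance change rate, ohm/s.
#' @param lvet Left ventricular ejection time, s (> 0).
#' @param z0 Baseline thoracic impedance, ohm (> 0).
#' @param sv Stroke volume, mL.
#' @param hr Heart rate, beats/min (>= 0).
#' @param trc R-peak to impedance C-point interval, s (> 0).
#' @param form Heather index form, `"product"` (as used here) or `"quotient"`.
#' @param sbp,dbp Systolic and diastolic pressure, mmHg (SBP > DBP).
#' @param mbp Mean blood pressure, mmHg.
#' @param cvp Assumed central venous pressure, mmHg.
#' @param co Cardiac output, L/min (> 0).
#' @name hemodynamic-derivations
NULL

#' @rdname hemodynamic-derivations
#' @export
derive_sv <- function(vept, dzmax, lvet, z0) {
  .check(!.bad(z0, function(v) v <= 0), "z0 must be positive")
  .check(!.bad(lvet, function(v) v <= 0), "lvet must be positive")
  vept * dzmax * lvet / z0
}

#' @rdname hemodynamic-derivations
#' @export
derive_co <- function(sv, hr) {
  .check(!.bad(hr, function(v) v < 0), "hr must be non-negative")
  .check(!.bad(sv, function(v) v < 0), "sv must be non-negative")
  sv * hr / 1000
}

#' @rdname hemodynamic-derivations
#' @export
derive_hi <- function(dzmax, trc, form = c("product", "quotient")) {
  form <- match.arg(form)
  .check(!.bad(trc, function(v) v <= 0), "trc must be positive")
  if (form == "product") dzmax * trc else dzmax / trc
}

#' @rdname hemodynamic-derivations
#' @export
derive_tac <- function(sv, sbp, dbp) {
  pp <- sbp - dbp
  .check(!.bad(pp, function(v) v <= 0),
         "degenerate pressures: sbp must exceed dbp")
  sv / pp
}

#' @rdname hemodynamic-derivations
#' @export
derive_svr <- function(mbp, cvp, co) {
  .check(!.bad(co, function(v) v <= 0), "co must be positive")
  80 * (mbp - cvp) / co
}

# canonical state-vector variable set (N = 11)
QCT_VARIABLES <- c("HR", "SBP", "DBP", "MBP", "LVET", "PEP",
                   "SV", "CO", "HI", "TAC", "SVR")

#' Assemble the beat-by-beat state matrix
#'
#' Takes a per-beat record table (one row per heartbeat, columns `t, hr, sbp,
#' dbp, mbp, lvet, pep, z0, dzmax, trc`; empty cells are gaps), derives the
#' dependent hemodynamic parameters from the primitives, and returns the
#' `M x N` state matrix plus a missingness mask consumed by the complexity
#' engine. A derived value is missing exactly when at least one of its inputs
#' is missing; rows whose pressures are degenerate (`SBP <= DBP`) have the
#' pulse-pressure-derived cells masked with a warning rather than aborting.
#'
#' @param records Data frame of beat records (see [read_beats()]).
#' @param subject A [qct_subject()]; required when any derived variable is
#'   requested.
#' @param config A [qct_config()]; `config$variables` selects and orders the
#'   state-vector components (default the 11 canonical variables), and
#'   `config$heather_index_form` / `config$include_pp` control the HI form and
#'   whether pulse pressure replaces SBP/DBP.
#' @return An object of class `qct_state_matrix`: a list with `data`
#'   (numeric matrix, `M x N`), `mask` (logical matrix, `TRUE` = missing),
#'   `variables` and `times`.
#' @export
assemble_state_matrix <- function(records, subject = NULL, config = qct_config()) {
  need <- c("t", "hr", "sbp", "dbp", "mbp", "lvet", "pep", "z0", "dzmax", "trc")
  names(records) <- tolower(names(records))
  missing_cols <- setdiff(need, names(records))
  .check(length(missing_cols) == 0,
         paste("missing beat-record columns:", paste(missing_cols, collapse = ", ")))
  vars <- config$variables
  .check(length(vars) >= 2 || nrow(records) == 0, "state vector needs at least 2 variables")
  .check(!anyDuplicated(vars), "state-vector variable names must be unique")

  M <- nrow(records)
  if (M == 0) {
    return(structure(list(data = matrix(numeric(0), 0, length(vars),
                                        dimnames = list(NULL, vars)),
                          mask = matrix(logical(0), 0, length(vars)),
                          variables = vars, times = numeric(0)),
                     class = "qct_state_matrix"))
  }
  tt <- records$t
  .check(all(diff(tt[!is.na(tt)]) > 0), "beat times must be strictly increasing")

  derived_needed <- any(vars %in% c("SV", "CO", "HI", "TAC", "SVR"))
  if (derived_needed)
    .check(inherits(subject, "qct_subject"),
           "a qct_subject is required to derive SV/CO/HI/TAC/SVR")

  # guard degenerate pressures before derivation (derive_tac would abort)
  pp <- records$sbp - records$dbp
  degen <- !is.na(pp) & pp <= 0
  if (any(degen)) {
    warning(sprintf("%d beat(s) with SBP <= DBP: pulse-pressure cells masked", sum(degen)))
    records$sbp[degen] <- NA_real_
    records$dbp[degen] <- NA_real_
  }

  cols <- list(HR = records$hr, SBP = records$sbp, DBP = records$dbp,
               MBP = records$mbp, LVET = records$lvet, PEP = records$pep,
               PP = records$sbp - records$dbp)
  if (derived_needed) {
    vept <- compute_vept(subject)
    sv <- derive_sv(vept, records$dzmax, records$lvet, records$z0)
    co <- derive_co(sv, records$hr)
    cols$SV  <- sv
    cols$CO  <- co
    cols$HI  <- derive_hi(records$dzmax, records$trc, config$heather_index_form)
    cols$TAC <- sv / (records$sbp - records$dbp)
    cols$SVR <- derive_svr(records$mbp, subject$cvp, co)
  }
  unknown <- setdiff(vars, names(cols))
  .check(length(unknown) == 0,
         paste("unknown state-vector variable(s):", paste(unknown, collapse = ", ")))

  data <- do.call(cbind, cols[vars])
  colnames(data) <- vars
  structure(list(data = data, mask = is.na(data), variables = vars, times = tt),
            class = "qct_state_matrix")
}

#' @export
print.qct_state_matrix <- function(x, ...) {
  cat(sprintf("State matrix: %d beats x %d variables (%s), %.1f%% cells missing\n",
              nrow(x$data), length(x$variables),
              paste(x$variables, collapse = ", "), 100 * mean(x$mask)))
  invisible(x)
}
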