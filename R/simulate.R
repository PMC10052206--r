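# Synthetic head-up tilt test (HUTT) generator. Three slow latent states -
# venous return, autonomic (sympathetic/vagal) tone and vascular tone -
# follow phase-dependent targets with AR(1) noise; the measured channels are
# derived from them so that the hemodynamic algebra (SV/CO/HI/TAC/SVR)
# holds for every generated beat by construction. The generator is a test
# fixture emulating the tilt-test phenomenology, not a physiological model.

PHASE_KINDS <- c("supine_rest", "tilt_transition", "passive", "ntg",
                 "collapse", "supine_restore")

#' Define a synthetic head-up tilt test scenario
#'
#' The phase schedule and physiological parameters driving
#' [simulate_hutt()]. Phases run in the given order; `supine_rest` must come
#' first, and a `collapse` phase is present exactly when
#' `syncope = "vasis_type1_mixed"`. In a mixed-type collapse the vascular
#' tone (hence MBP) declines first - optionally after a gentle prodromal
#' drift of `warning_lead` seconds - and the vagal HR depression follows
#' `hr_delay` seconds after the overt decline starts, so the MBP-first
#' ordering of VASIS type 1 holds by construction.
#'
#' @param name Scenario label.
#' @param phases Data frame with columns `kind` (one of `r
#'   paste(PHASE_KINDS, collapse = ", ")`) and `duration` (seconds, > 0).
#' @param subject A [qct_subject()].
#' @param baseline_hr,baseline_mbp,baseline_sv Supine set points (bpm, mmHg,
#'   mL).
#' @param syncope `"none"` or `"vasis_type1_mixed"`.
#' @param noise_sd Named list of relative AR(1) innovation scales for the
#'   latents `ven`, `sym`, `vag`, `vas`.
#' @param ar_coefficient AR(1) coefficient of the latent deviations.
#' @param baroreflex Fraction of beat-to-beat cardiac-output fluctuation
#'   buffered away from MBP at the regulation time scale (0 = none,
#'   1 = perfect autoregulation). Phase-level shifts always pass through.
#' @param gap_rate_mbp Fraction of MBP cells masked as recording gaps
#'   (bursty, see [inject_gaps()]); 0 disables.
#' @param gap_burst_length Mean gap burst length in beats.
#' @param warning_lead Prodromal drift duration (s) at the start of the
#'   collapse phase (0 = abrupt collapse).
#' @param hr_delay Delay (s) from overt MBP decline to vagal HR depression.
#' @param seed Integer seed making the simulation deterministic.
#' @return An object of class `hutt_scenario`.
#' @export
hutt_scenario <- function(name = "custom",
                          phases = data.frame(kind = "supine_rest", duration = 300),
                          subject = qct_subject(80, 180, "male"),
                          baseline_hr = 62, baseline_mbp = 95, baseline_sv = 85,
                          syncope = c("none", "vasis_type1_mixed"),
                          noise_sd = list(ven = 0.035, sym = 0.02,
                                          vag = 0.012, vas = 0.03),
                          ar_coefficient = 0.7, baroreflex = 1,
                          gap_rate_mbp = 0, gap_burst_length = 5,
                          warning_lead = 0, hr_delay = 60, seed = 1) {
  syncope <- match.arg(syncope)
  .check(is.data.frame(phases) && all(c("kind", "duration") %in% names(phases)),
         "phases must be a data frame with kind and duration")
  .check(all(phases$kind %in% PHASE_KINDS),
         paste("unknown phase kind; allowed:", paste(PHASE_KINDS, collapse = ", ")))
  .check(all(phases$duration > 0), "phase durations must be positive")
  .check(phases$kind[1] == "supine_rest", "the first phase must be supine_rest")
  has_collapse <- "collapse" %in% phases$kind
  .check(has_collapse == (syncope != "none"),
         "a collapse phase is present exactly when syncope is vasis_type1_mixed")
  .check(gap_rate_mbp >= 0 && gap_rate_mbp < 1, "gap_rate_mbp must be in [0, 1)")
  .check(ar_coefficient >= 0 && ar_coefficient < 1,
         "ar_coefficient must be in [0, 1)")
  .check(baroreflex >= 0 && baroreflex <= 1, "baroreflex must be in [0, 1]")
  .check(inherits(subject, "qct_subject"), "subject must be a qct_subject")
  for (nm in c("ven", "sym", "vag", "vas"))
    .check(is.numeric(noise_sd[[nm]]) && noise_sd[[nm]] >= 0,
           paste("noise_sd must provide a non-negative", nm))
  if (has_collapse) {
    dur <- phases$duration[phases$kind == "collapse"][1]
    .check(warning_lead + hr_delay < dur,
           "warning_lead + hr_delay must be shorter than the collapse phase")
  }
  structure(list(name = name, phases = phases, subject = subject,
                 baseline_hr = baseline_hr, baseline_mbp = baseline_mbp,
                 baseline_sv = baseline_sv, syncope = syncope,
                 noise_sd = noise_sd, ar_coefficient = ar_coefficient,
                 baroreflex = baroreflex,
                 gap_rate_mbp = gap_rate_mbp,
                 gap_burst_length = gap_burst_length,
                 warning_lead = warning_lead, hr_delay = hr_delay,
                 seed = as.integer(seed)),
            class = "hutt_scenario")
}

#' @export
print.hutt_scenario <- function(x, ...) {
  cat(sprintf("HUTT scenario '%s': %s, %.0f s total, seed %d\n", x$name,
              paste(x$phases$kind, collapse = " > "),
              sum(x$phases$duration), x$seed))
  invisible(x)
}

# phase-dependent latent targets c(ven, sym, vag, vas); `e` = seconds into
# the phase, `D` its duration.
latent_targets <- function(kind, e, D, scn) {
  switch(kind,
    supine_rest    = c(ven = 1, sym = 1, vag = 1, vas = 1),
    tilt_transition= c(ven = 0.72, sym = 1.25, vag = 0.90, vas = 1.10),
    passive        = c(ven = 0.72, sym = 1.25, vag = 0.90, vas = 1.10),
    ntg            = c(ven = 0.65, sym = 1.45, vag = 0.90, vas = 0.70),
    supine_restore = c(ven = 1, sym = 1, vag = 1, vas = 1),
    collapse = {
      W <- scn$warning_lead
      if (W > 0 && e <= W) {
        # prodrome: gentle accelerating vasodilatory drift, HR compensating
        c(ven = 0.72 - 0.04 * e / W,
          sym = 1.25 + 0.10 * e / W,
          vag = 0.90,
          vas = 1.10 - 0.08 * e / W)
      } else {
        u <- (e - W) / (D - W)                      # overt collapse progress
        vas_start <- if (W > 0) 1.02 else 1.10
        sym_start <- if (W > 0) 1.35 else 1.25
        ven_start <- if (W > 0) 0.68 else 0.72
        onset <- W + scn$hr_delay                   # vagal surge onset
        vag <- if (e <= onset) 0.90 else
          0.90 + 0.55 * (e - onset) / (D - onset)
        c(ven = ven_start - 0.10 * u,
          sym = sym_start - 0.40 * u,
          vag = vag,
          vas = vas_start - (vas_start - 0.55) * u^2)
      }
    })
}

# time constants (s) of the exponential approach to the phase targets, per
# latent (ven, sym, vag, vas). During posture transitions the mechanical
# volume shift is near-immediate while the autonomic and vasomotor responses
# lag behind it, which is what makes the transition windows rich in
# moderate (high joint entropy) cross-dependencies.
phase_tau <- function(kind) {
  switch(kind,
         supine_rest     = c(30, 30, 30, 30),
         tilt_transition = c(3, 8, 6, 12),
         passive         = c(30, 30, 30, 30),
         ntg             = c(60, 45, 45, 60),
         collapse        = c(8, 8, 8, 8),
         supine_restore  = c(4, 8, 6, 10))
}

# Target amplitude of the shared low-frequency (Mayer-band) vasomotor
# oscillation. Autonomic stress - the posture transition, the nitrate
# challenge, and the pre-collapse prodrome - recruits a coherent ~0.045 Hz
# oscillation across the latents; it grows during the prodrome and fades
# once a phase settles, which is what couples the channels and drives the
# transient complexity rises.
osc_target <- function(kind, e, scn) {
  switch(kind,
         tilt_transition = 0.10,
         ntg             = 0.03,
         collapse = {
           W <- scn$warning_lead
           if (W > 0) 0.10 * sqrt(min(1, e / W)) else 0.10
         },
         0)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a beat-to-beat head-up tilt test recording
#'
#' Generates one heartbeat per row: beat times advance by `60 / HR`
#' seconds, latent states follow the scenario's phase targets with AR(1)
#' noise, ICG primitives and pressures are derived from the latents, and the
#' derived hemodynamic parameters are computed with the package's own
#' derivation functions - so recomputing SV/CO/HI/TAC/SVR from the stored
#' primitives reproduces the stored values. HR is kept within 40-110 bpm and
#' MBP within 52-135 mmHg (the calibration envelopes of the monitored
#' recordings the generator emulates). Deterministic given the scenario
#' seed; the caller's RNG state is untouched.
#'
#' @param scenario A [hutt_scenario()].
#' @return A list of class `hutt_simulation`: `records` (beat data frame
#'   with primitives and derived columns), `truth` (named event times:
#'   `tilt`, `ntg`, `supine_restore`, `mbp_decline_onset`,
#'   `hr_depression_onset`, `syncope`, plus the latent trajectories), and
#'   `scenario`.
#' @export
#' @examples
#' sim <- simulate_hutt(scenario_presets()$baseline_supine)
#' head(sim$records)
simulate_hutt <- function(scenario) {
  .check(inherits(scenario, "hutt_scenario"), "scenario must be a hutt_scenario")
  scn <- scenario
  ph <- scn$phases
  ph$start <- cumsum(c(0, ph$duration[-nrow(ph)]))
  ph$end <- ph$start + ph$duration
  total <- sum(ph$duration)
  subject <- scn$subject
  vept <- compute_vept(subject)
  cvp <- subject$cvp

  hr0 <- scn$baseline_hr; mbp0 <- scn$baseline_mbp; sv0 <- scn$baseline_sv
  co0 <- sv0 * hr0 / 1000
  svr0 <- 80 * (mbp0 - cvp) / co0
  tac0 <- 1.9
  pp0 <- sv0 / tac0
  z00 <- 25; lvet0 <- 0.30; trc0 <- 0.15; pep0 <- 0.09
  phi <- scn$ar_coefficient
  sdv <- unlist(scn$noise_sd[c("ven", "sym", "vag", "vas")])

  n_cap <- ceiling(total / (60 / 110)) + 2
  rec <- matrix(NA_real_, n_cap, 15)
  colnames(rec) <- c("t", "hr", "sbp", "dbp", "mbp", "lvet", "pep",
                     "z0", "dzmax", "trc", "sv", "co", "hi", "tac", "svr")
  lat_out <- matrix(NA_real_, n_cap, 5)
  colnames(lat_out) <- c("t", "ven", "sym", "vag", "vas")

  beta <- scn$baroreflex
  with_seed(scn$seed, {
    base <- c(ven = 1, sym = 1, vag = 1, vas = 1)
    dev <- c(ven = 0, sym = 0, vag = 0, vas = 0)
    oamp <- 0                                        # vasomotor oscillation
    ow <- c(ven = 0.6, sym = 1.0, vag = -0.5, vas = 1.0)  # vagal antiphase
    t <- 0; i <- 0; dt <- 60 / hr0
    while (t < total) {
      i <- i + 1
      p <- which(t >= ph$start & t < ph$end)[1]
      kind <- ph$kind[p]
      e <- t - ph$start[p]
      tg <- latent_targets(kind, e, ph$duration[p], scn)
      base <- base + (tg - base) * (1 - exp(-dt / phase_tau(kind)))
      boost <- if (kind == "collapse") 1.5 else 1    # autonomic instability
      dev <- phi * dev + boost * sdv * sqrt(1 - phi^2) * rnorm(4)
      otgt <- osc_target(kind, e, scn)
      tau_o <- if (otgt > oamp) 5 else 45            # fast onset, slow fade
      oamp <- oamp + (otgt - oamp) * (1 - exp(-dt / tau_o))
      osc <- oamp * sin(2 * pi * t / 22)
      lat <- base * (1 + dev + ow * osc)

      hr <- clamp(hr0 * lat["sym"] / lat["vag"] + rnorm(1, 0, 1.0), 40, 110)
      sv <- max(20, sv0 * lat["ven"] + rnorm(1, 0, 1.0))
      lvet <- max(0.12, lvet0 * (60 / hr)^0.3 + rnorm(1, 0, 0.008))
      pep <- max(0.04, pep0 * (1 + 0.5 * (1 - lat["sym"])) + rnorm(1, 0, 0.004))
      z0 <- max(5, z00 * (1 + 0.08 * (1 - lat["ven"])) + rnorm(1, 0, 0.15))
      trc <- max(0.05, trc0 * (60 / hr)^0.2 + rnorm(1, 0, 0.005))
      dzmax <- sv * z0 / (vept * lvet)               # inverts the SV formula
      co <- derive_co(sv, hr)
      # the regulation point tracks the phase-level output plus a damped
      # share of the slow vasomotor wave (the reflex loop generates the
      # wave and only partially buffers it); random beat-to-beat CO
      # fluctuation is buffered by the (co / co_s)^(1 - beta) term
      bo <- base * (1 + 0.2 * ow * osc)
      hr_s <- clamp(hr0 * bo["sym"] / bo["vag"], 40, 110)
      co_s <- max(0.5, sv0 * bo["ven"] * hr_s / 1000)
      mbp <- clamp(cvp + svr0 * lat["vas"] * co_s * (co / co_s)^(1 - beta) / 80 +
                     rnorm(1, 0, 3.5),
                   52, 135)
      pp <- max(8, pp0 * (0.15 * sv / sv0 + 0.85 * lat["vas"]^0.7) +
                  rnorm(1, 0, 0.8))
      dbp <- max(20, mbp - pp / 3 + rnorm(1, 0, 1.0))
      sbp <- dbp + pp

      rec[i, ] <- c(t, hr, sbp, dbp, mbp, lvet, pep, z0, dzmax, trc,
                    sv, co, derive_hi(dzmax, trc), derive_tac(sv, sbp, dbp),
                    derive_svr(mbp, cvp, co))
      lat_out[i, ] <- c(t, lat)
      dt <- 60 / hr
      t <- t + dt
    }
    records <- as.data.frame(rec[seq_len(i), , drop = FALSE])
    latents <- as.data.frame(lat_out[seq_len(i), , drop = FALSE])

    if (scn$gap_rate_mbp > 0) {
      records <- inject_gaps(records, channel = "mbp",
                             rate = scn$gap_rate_mbp,
                             burst_length = scn$gap_burst_length,
                             seed = scn$seed + 1)
    }

    phase_start <- function(kind) {
      s <- ph$start[ph$kind == kind]
      if (length(s)) s[1] else NA_real_
    }
    collapse_start <- phase_start("collapse")
    events <- list(
      tilt = phase_start("tilt_transition"),
      ntg = phase_start("ntg"),
      supine_restore = phase_start("supine_restore"),
      mbp_decline_onset = collapse_start,
      hr_depression_onset = if (is.na(collapse_start)) NA_real_ else
        collapse_start + scn$warning_lead + scn$hr_delay,
      syncope = if (is.na(collapse_start)) NA_real_ else
        ph$end[ph$kind == "collapse"][1])

    structure(list(records = records,
                   truth = list(events = events, latents = latents,
                                phases = ph),
                   scenario = scn),
              class = "hutt_simulation")
  })
}

#' @export
print.hutt_simulation <- function(x, ...) {
  ev <- x$truth$events
  ev <- ev[!vapply(ev, function(v) is.null(v) || is.na(v), logical(1))]
  cat(sprintf("HUTT simulation '%s': %d beats over %.0f s\n", x$scenario$name,
              nrow(x$records), max(x$records$t)))
  if (length(ev))
    cat("  events:", paste(sprintf("%s@%.0fs", names(ev), unlist(ev)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Inject bursty recording gaps into one channel
#'
#' Masks cells of a single channel in bursts whose lengths are geometric
#' with mean `burst_length`, at a stationary masked fraction close to
#' `rate`. Only the named channel is ever touched. Deterministic given
#' `seed`; the caller's RNG state is untouched.
#'
#' @param records Beat-record data frame.
#' @param channel Column name to mask (e.g. `"mbp"`).
#' @param rate Target masked fraction in `[0, 1)`.
#' @param burst_length Mean burst length in beats (>= 1).
#' @param seed Integer seed.
#' @return The records with `NA` gaps in the chosen channel.
#' @export
inject_gaps <- function(records, channel, rate, burst_length = 5, seed = 1) {
  .check(is.data.frame(records), "records must be a data frame")
  .check(channel %in% names(records),
         paste("unknown channel:", channel))
  .check(rate >= 0 && rate < 1, "rate must be in [0, 1)")
  .check(burst_length >= 1, "burst_length must be >= 1")
  if (rate == 0) return(records)
  n <- nrow(records)
  with_seed(seed, {
    # alternating renewal process: masked runs ~ 1 + Geom(1/burst_length),
    # start probability chosen for a stationary masked fraction of `rate`
    p_start <- rate / ((1 - rate) * burst_length)
    mask <- logical(n)
    i <- 1
    while (i <= n) {
      if (runif(1) < p_start) {
        len <- 1 + stats::rgeom(1, prob = 1 / burst_length)
        mask[i:min(n, i + len - 1)] <- TRUE
        i <- i + len
      } else {
        i <- i + 1
      }
    }
    records[[channel]][mask] <- NA_real_
    records
  })
}

#' Bundled scenario presets
#'
#' Named scenarios covering the tilt-test phenomenology end to end:
#'
#' * `baseline_supine` - supine rest only; the stationarity/gap-robustness
#'   workbench.
#' * `negative_with_ntg` - completed test: tilt, passive standing, a
#'   nitroglycerine provocation and supine restoration, no syncope.
#' * `type1_mixed_early` - abrupt VASIS type-1 (mixed) collapse during the
#'   passive phase: progressive MBP fall, HR depression 60 s later.
#' * `type1_mixed_with_warning` - the same collapse preceded by a 150 s
#'   prodromal vasodilatory drift, producing a complexity rise well before
#'   the overt MBP/HR changes.
#'
#' @param seed Integer seed stored in every preset.
#' @return Named list of [hutt_scenario()] objects.
#' @export
scenario_presets <- function(seed = 1) {
  ph <- function(...) {
    kv <- list(...)
    data.frame(kind = names(kv), duration = as.numeric(unlist(kv)))
  }
  list(
    baseline_supine = hutt_scenario(
      name = "baseline_supine",
      phases = ph(supine_rest = 450),
      seed = seed),
    negative_with_ntg = hutt_scenario(
      name = "negative_with_ntg",
      phases = ph(supine_rest = 300, tilt_transition = 20, passive = 360,
                  ntg = 360, supine_restore = 150),
      seed = seed),
    type1_mixed_early = hutt_scenario(
      name = "type1_mixed_early",
      phases = ph(supine_rest = 300, tilt_transition = 20, passive = 360,
                  collapse = 150, supine_restore = 120),
      syncope = "vasis_type1_mixed", warning_lead = 0, hr_delay = 60,
      seed = seed),
    type1_mixed_with_warning = hutt_scenario(
      name = "type1_mixed_with_warning",
      phases = ph(supine_rest = 300, tilt_transition = 20, passive = 360,
                  collapse = 240, supine_restore = 120),
      syncope = "vasis_type1_mixed", warning_lead = 150, hr_delay = 45,
      seed = seed))
}
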