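# Synthetic HUTT generator: schedule validation, determinism, physiological
# envelopes, internal algebraic consistency, event ordering, and gaps.

test_that("invalid phase schedules are configuration errors", {
  expect_error(hutt_scenario(phases = data.frame(kind = "passive", duration = 60)),
               "supine_rest")
  expect_error(hutt_scenario(phases = data.frame(kind = c("supine_rest", "flying"),
                                                 duration = c(60, 60))),
               "unknown phase kind")
  expect_error(hutt_scenario(phases = data.frame(kind = "supine_rest", duration = 0)),
               "positive")
  expect_error(hutt_scenario(syncope = "vasis_type1_mixed"),
               "collapse phase")
  ph <- data.frame(kind = c("supine_rest", "collapse"), duration = c(60, 60))
  expect_error(hutt_scenario(phases = ph, syncope = "none"), "collapse phase")
  expect_error(hutt_scenario(phases = ph, syncope = "vasis_type1_mixed",
                             warning_lead = 40, hr_delay = 30), "shorter")
  expect_error(hutt_scenario(gap_rate_mbp = 1), "gap_rate_mbp")
  expect_error(hutt_scenario(baroreflex = 1.5), "baroreflex")
})

test_that("the same scenario and seed reproduce the recording exactly", {
  scn <- scenario_presets(seed = 4)$negative_with_ntg
  a <- simulate_hutt(scn)
  b <- simulate_hutt(scn)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$events, b$truth$events)
  c2 <- simulate_hutt(scenario_presets(seed = 5)$negative_with_ntg)
  expect_false(identical(a$records$hr, c2$records$hr))
})

test_that("the negative scenario stays inside the monitoring envelopes", {
  sim <- simulate_hutt(scenario_presets(seed = 1)$negative_with_ntg)
  r <- sim$records
  expect_true(all(r$hr >= 40 & r$hr <= 110))
  expect_true(all(r$mbp >= 52 & r$mbp <= 135, na.rm = TRUE))
  expect_true(all(r$sbp > r$dbp, na.rm = TRUE))
  expect_true(all(diff(r$t) > 0))
  expect_true(is.na(sim$truth$events$syncope))
})

test_that("stored derived values recompute exactly from the primitives", {
  sim <- simulate_hutt(scenario_presets(seed = 2)$type1_mixed_early)
  r <- sim$records
  subj <- scenario_presets(seed = 2)$type1_mixed_early$subject
  vept <- compute_vept(subj)
  expect_equal(r$sv, derive_sv(vept, r$dzmax, r$lvet, r$z0), tolerance = 1e-10)
  expect_equal(r$co, derive_co(r$sv, r$hr), tolerance = 1e-10)
  expect_equal(r$tac, derive_tac(r$sv, r$sbp, r$dbp), tolerance = 1e-10)
  expect_equal(r$svr, derive_svr(r$mbp, subj$cvp, r$co), tolerance = 1e-10)
  expect_equal(r$hi, derive_hi(r$dzmax, r$trc), tolerance = 1e-10)
})

test_that("a mixed-type collapse declines MBP before depressing HR", {
  sim <- simulate_hutt(scenario_presets(seed = 1)$type1_mixed_with_warning)
  ev <- sim$truth$events
  expect_lt(ev$mbp_decline_onset, ev$hr_depression_onset)
  expect_lt(ev$hr_depression_onset, ev$syncope)
  expect_lt(ev$tilt, ev$mbp_decline_onset)
  # the truth markers are real: MBP and HR fall from passive levels to syncope
  r <- sim$records
  passive <- r$t > ev$tilt + 60 & r$t < ev$mbp_decline_onset
  terminal <- r$t > ev$syncope - 15 & r$t <= ev$syncope
  expect_lt(median(r$mbp[terminal], na.rm = TRUE) + 20,
            median(r$mbp[passive], na.rm = TRUE))
  expect_lt(median(r$hr[terminal]) + 15, median(r$hr[passive]))
})

test_that("supine rest is stationary: windowed channel means drift below 5%", {
  sim <- simulate_hutt(scenario_presets(seed = 1)$baseline_supine)
  r <- sim$records
  chunk <- cut(r$t, breaks = seq(0, 450, by = 90))
  for (ch in c("hr", "mbp", "sv", "lvet", "sbp", "dbp")) {
    m <- tapply(r[[ch]], chunk, mean, na.rm = TRUE)
    expect_lt((max(m) - min(m)) / mean(m), 0.05)
  }
})

test_that("gap injection hits the target rate and only the named channel", {
  sim <- simulate_hutt(scenario_presets(seed = 3)$baseline_supine)
  big <- do.call(rbind, replicate(4, sim$records, simplify = FALSE))
  big$t <- seq_len(nrow(big))                 # only the mask pattern matters
  g <- inject_gaps(big, channel = "mbp", rate = 0.2, burst_length = 5, seed = 2)
  rate <- mean(is.na(g$mbp))
  expect_gte(rate, 0.16)
  expect_lte(rate, 0.24)
  for (ch in setdiff(names(g), "mbp")) expect_false(anyNA(g[[ch]]))
  # deterministic given the seed
  g2 <- inject_gaps(big, channel = "mbp", rate = 0.2, burst_length = 5, seed = 2)
  expect_identical(g$mbp, g2$mbp)
  expect_error(inject_gaps(big, channel = "nope", rate = 0.1), "unknown channel")
  expect_error(inject_gaps(big, channel = "mbp", rate = 1), "rate")
})

test_that("the bundled presets cover the documented study arms", {
  pres <- scenario_presets()
  expect_true(all(c("baseline_supine", "negative_with_ntg",
                    "type1_mixed_early", "type1_mixed_with_warning")
                  %in% names(pres)))
  for (p in pres) expect_s3_class(p, "hutt_scenario")
  expect_equal(pres$negative_with_ntg$syncope, "none")
  expect_equal(pres$type1_mixed_early$syncope, "vasis_type1_mixed")
  expect_gt(pres$type1_mixed_with_warning$warning_lead, 0)
  expect_equal(pres$type1_mixed_early$warning_lead, 0)
  # prodromal drift must fit inside the collapse phase
  scn <- pres$type1_mixed_with_warning
  dur <- scn$phases$duration[scn$phases$kind == "collapse"]
  expect_lt(scn$warning_lead + scn$hr_delay, dur)
})

test_that("beat intervals follow the instantaneous heart rate", {
  sim <- simulate_hutt(scenario_presets(seed = 1)$baseline_supine)
  r <- sim$records
  # t[i+1] - t[i] = 60 / hr[i]
  expect_equal(diff(r$t), 60 / r$hr[-nrow(r)], tolerance = 1e-10)
})
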