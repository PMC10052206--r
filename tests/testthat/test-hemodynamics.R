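# Parameter-derivation layer: closed-form checks against hand-computed
# values, NA (gap) propagation, and state-matrix assembly.

test_that("VEPT follows the height-cubed convention with optional correction", {
  expect_equal(compute_vept(qct_subject(80, 180, "male")), (0.17 * 180)^3 / 4.25)
  expect_equal(compute_vept(qct_subject(60, 165, "female")), (0.17 * 165)^3 / 4.25)
  expect_equal(
    compute_vept(qct_subject(80, 180, "male", vept_correction = 1.1)),
    (0.17 * 180)^3 / 4.25 * 1.1)
  expect_equal(compute_vept(70, height = 170), (0.17 * 170)^3 / 4.25)
  expect_error(qct_subject(-1, 180, "male"), "weight")
  expect_error(qct_subject(80, 0, "male"), "height")
})

test_that("stroke volume, cardiac output and resistance follow their formulas", {
  vept <- 6000
  expect_equal(derive_sv(vept, dzmax = 1.2, lvet = 0.3, z0 = 25),
               vept * 1.2 * 0.3 / 25)
  expect_equal(derive_co(sv = 80, hr = 60), 4.8)
  expect_equal(derive_tac(sv = 80, sbp = 120, dbp = 80), 2)
  expect_equal(derive_svr(mbp = 95, cvp = 6, co = 5), 80 * 89 / 5)
  expect_equal(derive_hi(dzmax = 1.2, trc = 0.15), 0.18)
  expect_equal(derive_hi(dzmax = 1.2, trc = 0.15, form = "quotient"), 8)
})

test_that("derivations are vectorized and propagate recording gaps", {
  sv <- derive_sv(6000, c(1.2, NA, 1.0), c(0.3, 0.3, NA), c(25, 25, 25))
  expect_true(is.na(sv[2]) && is.na(sv[3]) && !is.na(sv[1]))
  co <- derive_co(c(80, NA), c(NA, 60))
  expect_true(all(is.na(co)))
})

test_that("degenerate physical inputs are rejected", {
  expect_error(derive_sv(6000, 1.2, lvet = 0, z0 = 25), "lvet")
  expect_error(derive_sv(6000, 1.2, lvet = 0.3, z0 = -1), "z0")
  expect_error(derive_tac(80, sbp = 100, dbp = 100), "degenerate")
  expect_error(derive_svr(95, 6, co = 0), "co")
  expect_error(derive_co(80, hr = -5), "hr")
})

test_that("the state matrix derives all 11 canonical variables per beat", {
  subj <- test_subject()
  rec <- data.frame(t = c(0, 1, 2), hr = 60, sbp = 120, dbp = 80, mbp = 95,
                    lvet = 0.3, pep = 0.09, z0 = 25, dzmax = 1.2, trc = 0.15)
  sm <- assemble_state_matrix(rec, subj)
  expect_s3_class(sm, "qct_state_matrix")
  expect_identical(colnames(sm$data),
                   c("HR", "SBP", "DBP", "MBP", "LVET", "PEP",
                     "SV", "CO", "HI", "TAC", "SVR"))
  vept <- compute_vept(subj)
  sv <- vept * 1.2 * 0.3 / 25
  expect_equal(unname(sm$data[1, "SV"]), sv)
  expect_equal(unname(sm$data[1, "CO"]), sv * 60 / 1000)
  expect_equal(unname(sm$data[1, "TAC"]), sv / 40)
  expect_equal(unname(sm$data[1, "SVR"]), 80 * (95 - 6) / (sv * 60 / 1000))
  expect_false(any(sm$mask))
})

test_that("a missing primitive masks exactly the variables derived from it", {
  subj <- test_subject()
  rec <- data.frame(t = 0:2, hr = 60, sbp = 120, dbp = 80, mbp = 95,
                    lvet = 0.3, pep = 0.09, z0 = 25, dzmax = 1.2, trc = 0.15)
  rec$dzmax[2] <- NA
  sm <- assemble_state_matrix(rec, subj)
  # SVR is downstream of CO, so it is masked along with the SV chain
  expect_true(all(sm$mask[2, c("SV", "CO", "HI", "TAC", "SVR")]))
  expect_false(any(sm$mask[2, c("HR", "SBP", "DBP", "MBP", "LVET", "PEP")]))
})

test_that("beats with SBP <= DBP are masked with a warning, not an abort", {
  subj <- test_subject()
  rec <- data.frame(t = 0:2, hr = 60, sbp = c(120, 80, 120), dbp = 80,
                    mbp = 95, lvet = 0.3, pep = 0.09, z0 = 25,
                    dzmax = 1.2, trc = 0.15)
  expect_warning(sm <- assemble_state_matrix(rec, subj), "SBP <= DBP")
  expect_true(all(sm$mask[2, c("SBP", "DBP", "TAC")]))
  expect_false(sm$mask[1, "TAC"])
})

test_that("assembly validates its inputs", {
  subj <- test_subject()
  rec <- data.frame(t = 0:2, hr = 60, sbp = 120, dbp = 80, mbp = 95,
                    lvet = 0.3, pep = 0.09, z0 = 25, dzmax = 1.2, trc = 0.15)
  expect_error(assemble_state_matrix(rec[, -3], subj), "missing beat-record")
  expect_error(assemble_state_matrix(rec, subject = NULL), "qct_subject")
  bad <- rec; bad$t <- c(0, 2, 1)
  expect_error(assemble_state_matrix(bad, subj), "strictly increasing")
  cfg <- qct_config(variables = c("HR", "XX"))
  expect_error(assemble_state_matrix(rec, subj, cfg), "unknown state-vector")
  empty <- assemble_state_matrix(rec[0, ], subj)
  expect_equal(nrow(empty$data), 0)
})

test_that("pulse pressure can replace SBP/DBP in the state vector", {
  subj <- test_subject()
  rec <- data.frame(t = 0:2, hr = 60, sbp = 120, dbp = 80, mbp = 95,
                    lvet = 0.3, pep = 0.09, z0 = 25, dzmax = 1.2, trc = 0.15)
  sm <- assemble_state_matrix(rec, subj, qct_config(include_pp = TRUE))
  expect_true("PP" %in% colnames(sm$data))
  expect_false(any(c("SBP", "DBP") %in% colnames(sm$data)))
  expect_equal(unname(sm$data[1, "PP"]), 40)
})
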