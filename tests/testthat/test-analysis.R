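# Pipeline-level analyses. Short signatures and readouts keep each decode
# cheap; the full reference protocol is exercised by the acceptance tests.

test_that("a control-level signature yields fold one in every layer", {
  m <- default_model()
  tr <- ca_trace(c(0, 1500), rep(m$control_ca, 2))
  dec <- decode_signature(tr, m, gene_params(), readout_s = 1500)
  expect_rel_equal(dec$ca_fold, rep(1, length(dec$times)), 1e-9)
  expect_rel_equal(dec$m22x_fold, rep(1, length(dec$times)), 1e-4)
  expect_rel_equal(dec$mrna_fold, rep(1, length(dec$times)), 1e-4)
})

test_that("every elevated signature class is amplified super-linearly", {
  m <- default_model()
  traces <- list(
    oscillatory = synthetic_signature("oscillatory", t_end = 420),
    transient = synthetic_signature("transient", peak = 1.2),
    prolonged = synthetic_signature("prolonged", peak = 0.35,
                                    rise_s = 30, duration = 200))
  for (tr in traces) {
    amp <- amplification_analysis(tr, m)
    expect_gt(amp$summary$peak_m22x_fold, amp$summary$peak_ca_fold)
  }
})

test_that("dynamic and equilibrium amplification agree for a held step", {
  m <- default_model()
  tr <- ca_trace(c(0, 2e4), rep(2 * m$control_ca, 2))
  amp <- amplification_analysis(tr, m, out_dt = 50)
  eq <- steady_state_amplification(2, m)$m22x_fold
  expect_rel_equal(tail(amp$m22x_fold, 1), eq, 1e-3)
  expect_equal(steady_state_amplification(1, m)$m22x_fold, 1,
               tolerance = 1e-9)
})

test_that("equilibrium amplification approaches f^4 at low occupancy", {
  m <- default_model()
  out <- steady_state_amplification(2, m, control_ca = 0.01)
  expect_lt(abs(out$m22x_fold - 16) / 16, 0.25)
})

test_that("DNA-binding affinity steers the decoded expression fold", {
  m <- default_model()
  tr <- short_piecewise()
  folds <- vapply(c(1.1e-3, 1.1e-2, 1.1e-1), function(k4)
    decode_signature(tr, m, gene_params(k4 = k4),
                     readout_s = 1200)$summary$mrna_fold_at_readout,
    numeric(1))
  expect_true(all(diff(folds) < 0))   # tighter affinity, larger fold
  expect_gt(folds[1], folds[2])
  expect_lt(folds[3], 1.05)           # weak affinity barely induces
  expect_false(folds[3] >= 1.5)       # below the induction threshold
})

test_that("expression accumulates over cycles and relaxes afterwards", {
  m <- default_model()
  tr <- reference_piecewise(period = 40, duration = 400)
  h <- history_trace(tr, m, gene_params(), readout_s = 3600)
  # actual fold never exceeds the attainable potential along the history
  expect_lt(max(h$actual$mrna_fold), max(h$potential$fold) + 1e-9)
  # end-of-cycle folds are non-decreasing across the ten cycles
  eoc <- vapply(1:10, function(k) {
    idx <- which.min(abs(h$actual$time_s - (600 + k * 40)))
    h$actual$mrna_fold[idx]
  }, numeric(1))
  expect_true(all(diff(eoc) >= -1e-9))
  # after the signature (plus delay) the fold decays back toward one
  late <- h$actual[h$actual$time_s > 1100, ]
  expect_true(all(diff(late$mrna_fold) < 1e-9))
  expect_gt(min(late$mrna_fold), 1)
})

test_that("a held input converges onto its potential-curve point", {
  m <- default_model()
  lvl <- 2 * m$control_ca
  tr <- ca_trace(c(0, 4e4), c(lvl, lvl))
  gp <- gene_params(tau_s = 0)
  dec <- decode_signature(tr, m, gp, readout_s = 4e4, out_dt = 100,
                          gene_dt = 100)
  m22_eq <- steady_state(m, lvl)[["M22X"]]
  pot <- mrna_steady_state(m22_eq, gp, dec$controls$m22x_um)$fold
  expect_rel_equal(dec$summary$mrna_fold_at_readout, pot, 5e-3)
})

test_that("calibration recovers itself and responds monotonically", {
  m <- default_model()
  tr <- short_piecewise()
  gp <- gene_params()
  # fixed point: target the fold produced by the template's own total
  self <- decode_signature(tr, m, gp,
                           readout_s = 1200)$summary$mrna_fold_at_readout
  camt <- calibrate_cam_total(self, tr, m, gp, bounds = c(2, 50),
                              readout_s = 1200)
  expect_lt(abs(as.numeric(camt) - m$base$cam_total) / m$base$cam_total,
            0.01)
  expect_lt(abs(attr(camt, "achieved_fold") - self) / self, 0.01)
  # a higher target needs more CaM: recover a second known total
  m20 <- cam_model(cam_total = 20)
  self20 <- decode_signature(tr, m20, gp,
                             readout_s = 1200)$summary$mrna_fold_at_readout
  camt2 <- calibrate_cam_total(self20, tr, m, gp, bounds = c(2, 50),
                               readout_s = 1200)
  expect_lt(abs(as.numeric(camt2) - 20) / 20, 0.01)
  expect_gt(as.numeric(camt2), as.numeric(camt))
})

test_that("unreachable calibration targets produce a diagnostic", {
  m <- default_model()
  expect_error(
    calibrate_cam_total(1e6, short_piecewise(), m, gene_params(),
                        bounds = c(2, 20), readout_s = 1200),
    "achievable range")
})

test_that("scans agree with direct decoding and order as expected", {
  m <- default_model()
  spec <- list(a = 0.16, ca_max = 0.52, ca_min = 0.10, duration = 80)
  sc <- period_scan(c(20, 40, 80), spec, m, gene_params(),
                    readout_s = 1200)
  expect_equal(sc$n_spikes, c(4L, 2L, 1L))
  expect_true(all(diff(sc$mrna_fold_at_readout) > 0))
  direct <- decode_signature(do.call(piecewise_signature,
                                     c(spec, list(period = 40))),
                             m, gene_params(), readout_s = 1200)
  expect_rel_equal(sc$mrna_fold_at_readout[2],
                   direct$summary$mrna_fold_at_readout, 1e-9)

  ds <- duration_scan(c(0, 1, 2, 4), c(spec["a"], spec["ca_max"],
                                       spec["ca_min"], period = 40),
                      m, gene_params(), readout_s = 1200)
  expect_equal(ds$mrna_fold_at_readout[1], 1)
  expect_true(all(diff(ds$mrna_fold_at_readout) > 0))
})
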