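test_that("tissue and protocol constructors enforce physical invariants", {
  expect_error(tissue_properties("bad", -1, 70, 0.7),
               class = "chpwater_invalid_parameter")
  expect_error(tissue_properties("bad", 900, 0, 0.7),
               class = "chpwater_invalid_parameter")
  expect_error(tissue_properties("bad", 60, 70, 0.7),
               class = "chpwater_invalid_parameter")  # t2 > t1
  expect_error(tissue_properties("bad", 900, 70, 0),
               class = "chpwater_invalid_parameter")
  expect_error(spin_echo_protocol(tr_ms = 100, readout_duration_ms = 153),
               class = "chpwater_invalid_parameter")
  wm <- tissue_properties("wm", 900, 70, 0.7)
  expect_error(spin_echo_signal(wm, spin_echo_protocol(), gain = 0),
               class = "chpwater_invalid_parameter")
})

test_that("spin-echo signal reproduces its proton-density limit and value", {
  wm <- tissue_properties("wm", 900, 70, 0.70)
  # TR/T1 = 50, TE/T2 = 1e-6: the TE term still deviates from unity by
  # ~1e-6, so the A*C limit is approached at that order
  p_lim <- spin_echo_protocol(tr_ms = 50 * 900, te_ms = 70e-6,
                              readout_duration_ms = 70e-6)
  expect_lt(abs(spin_echo_signal(wm, p_lim) - 0.70), 1e-5)
  # deeper limit: TE/T2 = 1e-12 reaches A*C to machine precision
  p_deep <- spin_echo_protocol(tr_ms = 50 * 900, te_ms = 70e-12,
                               readout_duration_ms = 70e-12)
  expect_equal(spin_echo_signal(wm, p_deep), 0.70, tolerance = 1e-12)
  # direct evaluation at the study protocol
  expect_equal(spin_echo_signal(wm, spin_echo_protocol(tr_ms = 5000, te_ms = 9)),
               0.6131659, tolerance = 1e-6)
})

test_that("signal is monotone in TR and TE and gain cancels in ratios", {
  set.seed(7)
  for (i in 1:20) {
    tis <- random_tissue()
    # keep TR/T1 and TE/T2 in ranges where the ordering is representable
    tr <- sort(runif(2, 0.2, 8)) * tis$t1_ms
    te <- sort(runif(2, 0.05, 2)) * tis$t2_ms
    s_tr <- vapply(tr, function(x)
      spin_echo_signal(tis, spin_echo_protocol(tr_ms = x, te_ms = 5,
                                               readout_duration_ms = 5)), 1)
    expect_true(s_tr[2] > s_tr[1])
    s_te <- vapply(te, function(x)
      spin_echo_signal(tis, spin_echo_protocol(tr_ms = 9 * tis$t1_ms,
                                               te_ms = x,
                                               readout_duration_ms = te[2])), 1)
    expect_true(s_te[2] < s_te[1])
    # gain cancellation: two tissues, any gain
    tis2 <- random_tissue()
    a <- runif(1, 0.1, 10)
    p <- spin_echo_protocol()
    expect_equal(spin_echo_signal(tis, p, a) / spin_echo_signal(tis2, p, a),
                 spin_echo_signal(tis, p) / spin_echo_signal(tis2, p),
                 tolerance = 1e-12)
  }
  # TR >> T1, TE << T2: ratio collapses to the water-density ratio
  chp <- tissue_properties("chp", 900, 70, 0.895)
  wm <- tissue_properties("wm", 900, 70, 0.70)
  p <- spin_echo_protocol(tr_ms = 1e6, te_ms = 1e-4,
                          readout_duration_ms = 1e-4)
  expect_equal(spin_echo_signal(chp, p) / spin_echo_signal(wm, p),
               0.895 / 0.70, tolerance = 1e-9)
})

test_that("DRIVE closed form equals the iterated cycle recursion", {
  wm <- tissue_properties("wm", 900, 70, 0.70)
  expect_equal(drive_steady_state(wm, spin_echo_protocol()),
               0.9959306, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:50) {
    tis <- random_tissue()
    t_ro <- runif(1, 50, 400)
    tr <- t_ro + runif(1, 500, 20000)
    for (drv in c(TRUE, FALSE)) {
      p <- spin_echo_protocol(tr_ms = tr, te_ms = 9, drive_enabled = drv,
                              readout_duration_ms = t_ro)
      expect_equal(drive_steady_state(tis, p),
                   drive_recursion_oracle(tis$t1_ms, tis$t2_ms, tr, t_ro, drv),
                   tolerance = 1e-12)
    }
  }
  # full recovery limit and the DRIVE advantage for long-T1 species
  csf <- tissue_properties("csf", 4250, 1750, 1)
  expect_equal(drive_steady_state(csf, spin_echo_protocol(tr_ms = 1e7)), 1,
               tolerance = 1e-9)
  p_on <- spin_echo_protocol(drive_enabled = TRUE)
  p_off <- spin_echo_protocol(drive_enabled = FALSE)
  expect_gt(drive_steady_state(csf, p_on), drive_steady_state(csf, p_off))
})

test_that("protocol bias behaves as the long-TR validation predicts", {
  wm <- tissue_properties("wm", 900, 70, 0.70)
  csf <- tissue_properties("csf", 4250, 1750, 1)
  p <- spin_echo_protocol()
  expect_equal(protocol_bias(wm, test = p, reference = p), 0)
  b_wm <- protocol_bias(wm)
  expect_gt(b_wm, 0)
  expect_lt(b_wm, 0.05)
  expect_gt(abs(protocol_bias(csf)), abs(b_wm))
  # bias shrinks monotonically as the test TR approaches the reference TR
  # with matched DRIVE states
  trs <- c(5000, 8000, 12000, 16000, 20000)
  biases <- vapply(trs, function(tr)
    abs(protocol_bias(csf,
                      test = spin_echo_protocol(tr_ms = tr,
                                                drive_enabled = FALSE))), 1)
  expect_true(all(diff(biases) < 0))
  expect_equal(biases[length(biases)], 0)
})

test_that("ratio bias propagates per-tissue biases into density error", {
  expect_equal(ratio_bias(0.02, 0.02), 0)
  expect_equal(ratio_bias(0.0219, 0.0217), 1.9575e-4, tolerance = 1e-4)
  b <- 0.0123
  expect_equal(ratio_bias(b, 0), b)
  expect_error(ratio_bias(0.1, -1), class = "chpwater_degenerate")
})
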