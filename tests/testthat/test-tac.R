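test_that("noise-free tent curves behave as expected at the extremes", {
  s <- defaultFrameSchedule()
  increasing <- simulateTAC(kineticParams(2.5, 2, 0.05, 2), s, 1)
  expect_equal(which.max(increasing), 16L)
  flat <- simulateTAC(kineticParams(2, 10, -0.1, 2), s, 1)
  expect_equal(flat, rep(2, 16))
  washout <- simulateTAC(kineticParams(3, 7, -0.05, 1), s, 1)
  # frame containing minute 7 (420 s) is frame 12 (280-580 s)
  expect_equal(which.max(washout), 12L)
})

test_that("frame averages match dense numeric integration of the tent curve", {
  s <- defaultFrameSchedule()
  grid <- expand.grid(peak = c(1, 3.5, 7, 12, 18, 25, 33, 39),
                      slope = c(-0.12, -0.03, 0.02))
  for (r in seq_len(nrow(grid))) {
    p <- kineticParams(3, grid$peak[r], grid$slope[r], baseline = 1)
    got <- simulateTAC(p, s, 1)
    ref <- numericTentAverages(3, grid$peak[r], grid$slope[r], 1, s)
    expect_equal(got, unname(ref), tolerance = 1e-6)
  }
})

test_that("kinetic parameter validation and noise clipping hold", {
  expect_error(kineticParams(3, 7, noiseSd = -1), "noiseSd")
  expect_error(kineticParams(1, 7, baseline = 2), "amplitude")
  expect_error(kineticParams(3, 0), "peakTimeMin")
  s <- defaultFrameSchedule()
  tac <- simulateTAC(kineticParams(0.2, 5, -0.1, 0.01, noiseSd = 0.5), s, 7)
  expect_true(all(tac >= 0))
  # seeded noise is reproducible
  expect_identical(tac, simulateTAC(kineticParams(0.2, 5, -0.1, 0.01, 0.5), s, 7))
})
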