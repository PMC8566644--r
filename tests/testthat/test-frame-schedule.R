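test_that("default schedule reproduces the 16-frame 40-min protocol", {
  s <- defaultFrameSchedule()
  expect_equal(nFrames(s), 16L)
  expect_equal(frameStarts(s)[1L], 0)
  expect_equal(frameEnds(s)[1L], 10)
  expect_equal(c(frameStarts(s)[11L], frameEnds(s)[11L]), c(160, 280))
  expect_equal(c(frameStarts(s)[16L], frameEnds(s)[16L]), c(1780, 2380))
  expect_equal(totalDuration(s), 2380)
  expect_equal(frameDurations(s),
               c(rep(10, 7), rep(30, 3), 120, rep(300, 3), rep(600, 2)))
})

test_that("schedules are contiguous and validated", {
  s <- frameSchedule(c(5, 10, 20))
  expect_equal(frameStarts(s), c(0, 5, 15))
  expect_equal(frameMids(s), c(2.5, 10, 25))
  expect_error(new("FrameSchedule", start = c(0, 6), end = c(5, 10)),
               "contiguous")
  expect_error(new("FrameSchedule", start = c(1, 5), end = c(5, 10)),
               "start at 0")
  expect_error(new("FrameSchedule", start = c(0, 5), end = c(5, 5)),
               "positive duration")
})
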