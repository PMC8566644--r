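test_that("summation windows select frames by mid-time", {
  s <- defaultFrameSchedule()
  expect_equal(framesInWindow(s, c(20, 40)), c(15L, 16L))
  expect_equal(framesInWindow(s, c(5, 15)), c(12L, 13L))
  study <- uniformStudy(seq_len(16))
  # equal-duration frames 15 and 16: plain mean of the frame values
  expect_equal(unique(as.vector(summationImage(study, c(20, 40)))), 15.5)
  # duration-weighted, not plain, mean when durations differ
  study2 <- uniformStudy(c(rep(0, 10), 1, 2, 2, 2, 0, 0))
  expect_equal(unique(as.vector(summationImage(study2, c(2.5, 20)))),
               (120 * 1 + 300 * 2 * 3) / (120 + 900))
  constant <- uniformStudy(rep(3, 16))
  expect_equal(unique(as.vector(summationImage(constant, c(5, 15)))), 3)
  expect_error(summationImage(study, c(41, 42)), "\\[41, 42\\)")
})

test_that("background mean is a masked arithmetic mean", {
  img <- array(7, c(3, 3, 2))
  mask <- array(FALSE, c(3, 3, 2)); mask[1:2, 1, 1] <- TRUE
  expect_equal(backgroundMean(img, mask), 7)
  img[1, 1, 1] <- 1; img[2, 1, 1] <- 3
  expect_equal(backgroundMean(img, mask), 2)
  img[3, 3, 2] <- 1e6                     # outside the mask: no influence
  expect_equal(backgroundMean(img, mask), 2)
  expect_error(backgroundMean(img, array(FALSE, c(3, 3, 2))), "empty")
})

test_that("TBR images are exact voxel-wise normalisations", {
  sp <- c(2.03, 2.03, 2.43)
  img <- array(2, c(3, 3, 3))
  expect_equal(unique(as.vector(imageData(tbrImage(img, 2, sp)))), 1)
  img[2, 2, 2] <- 3.2
  expect_equal(imageData(tbrImage(img, 2, sp))[2, 2, 2], 1.6)
  expect_error(tbrImage(img, 0, sp), "positive")
  # self-normalisation: background mean of the TBR image is exactly 1
  mask <- array(FALSE, c(3, 3, 3)); mask[, 1, ] <- TRUE
  img2 <- array(runif(27, 1, 4), c(3, 3, 3))
  bg <- backgroundMean(img2, mask)
  expect_equal(backgroundMean(tbrImage(img2, bg, sp), mask), 1)
})

test_that("tumour segmentation keeps the largest 26-connected component", {
  sp <- rep(2.03, 3)
  arr <- array(1, c(8, 8, 4))
  expect_error(segmentTumour(parametricImage(arr, "TBR_20_40", sp)),
               class = "dynFET_fet_negative")
  arr[2:6, 2, 2] <- 2; arr[2:6, 3, 2] <- 2          # blob of 10
  arr[8, 8, 4] <- 2; arr[8, 7, 4] <- 2; arr[7, 8, 4] <- 2   # blob of 3
  mask <- segmentTumour(parametricImage(arr, "TBR_20_40", sp))
  expect_equal(sum(mask), 10L)
  expect_true(all(which(mask) %in% which(arr >= 1.6)))
  single <- array(1, c(4, 4, 4)); single[2, 2, 2] <- 1.6
  expect_equal(sum(segmentTumour(parametricImage(single, "TBR_20_40", sp))), 1L)
  expect_error(segmentTumour(parametricImage(arr, "TBR_5_15", sp)), "TBR_20_40")
})

test_that("raising the segmentation threshold never adds voxels", {
  withSeed(21, {
    arr <- array(runif(8 * 8 * 6, 0.5, 2.5), c(8, 8, 6))
    img <- parametricImage(arr, "TBR_20_40", rep(2.03, 3))
    prev <- segmentTumour(img, 1.2)
    for (thr in c(1.4, 1.6, 1.8)) {
      cur <- tryCatch(segmentTumour(img, thr), error = function(e) NULL)
      if (is.null(cur)) break
      expect_true(all(arr[cur] >= thr))
      prev <- cur
    }
  })
})

test_that("TTP classification follows the slope override and 2.7-min rule", {
  s <- defaultFrameSchedule()
  expect_equal(classifyVoxelTTP(seq(1, 4, length.out = 16), s), 6L)
  # peak inside the 2.67-4.67 min frame, negative late slope -> category 1
  tac <- simulateTAC(kineticParams(3, 220 / 60, -0.08 * 3, 1), s, 1)
  expect_equal(classifyVoxelTTP(tac, s), 1L)
  # early blood-flush spike is ignored; eligible max in 9.67-14.67 min frame
  tac2 <- c(rep(9, 7), 9, 9, 9, 1, 2, 3, 2.5, 2, 1.5)
  expect_equal(classifyVoxelTTP(tac2, s), 3L)
  expect_error(classifyVoxelTTP(rep(1, 3), frameSchedule(c(10, 10, 10))),
               "late-slope|length")
})

test_that("TTP classification is invariant to positive rescaling", {
  s <- defaultFrameSchedule()
  withSeed(4, {
    for (k in 1:20) {
      tac <- runif(16, 0.5, 3)
      expect_equal(classifyVoxelTTP(tac * 7.3, s), classifyVoxelTTP(tac, s))
    }
  })
})

test_that("TTP images encode category midpoints inside the mask", {
  s <- defaultFrameSchedule()
  dims <- c(5, 5, 3)
  early <- simulateTAC(kineticParams(3, 220 / 60, -0.2, 1), s, 1)
  rising <- simulateTAC(kineticParams(2.5, 2, 0.05, 2), s, 1)
  nvox <- prod(dims)
  vol <- array(0, c(dims, 16))
  half <- seq_len(floor(nvox / 2))
  for (f in 1:16) {
    plane <- rep(rising[f], nvox)
    plane[half] <- early[f]
    vol[, , , f] <- plane
  }
  study <- dynamicStudy(vol, s)
  mask <- array(TRUE, dims)
  img <- ttpImage(study, mask)
  expect_setequal(unique(as.vector(imageData(img))), c(2.5, 35))
  # constant TAC over the mask -> constant TTP image
  study2 <- uniformStudy(early, dims)
  expect_equal(unique(as.vector(imageData(ttpImage(study2, mask)))), 2.5)
  # outside-mask voxels are NA
  mask2 <- mask; mask2[1, 1, 1] <- FALSE
  expect_true(is.na(imageData(ttpImage(study, mask2))[1, 1, 1]))
  expect_error(ttpImage(study, array(FALSE, dims)), "empty")
})

test_that("noise-free TTP categories recover the planted kinetics", {
  spec <- cohortSpec(4, 0.25, seed = 17, noiseSd = 0)
  pat <- phantomPatient(spec, 2)
  img <- ttpImage(pat$study, pat$tumourMask)
  planted <- ttpCategories()$representative_min[pat$truth$categories]
  expect_equal(imageData(img)[pat$tumourMask], planted)
})
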