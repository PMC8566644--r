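test_that("phantom label counts are exact and seeded", {
  spec <- cohortSpec(20, 0.2, seed = 11)
  labs <- phantomLabels(spec)
  expect_equal(sum(labs == 0L), 4L)
  expect_identical(labs, phantomLabels(spec))
  expect_equal(sum(phantomLabels(cohortSpec(15, 0.3, seed = 2)) == 0L),
               round(15 * 0.3))
  expect_error(cohortSpec(4, 0.05), "at least one patient per class")
})

test_that("phantom studies are reproducible, non-negative and well-formed", {
  spec <- cohortSpec(6, 0.2, seed = 5)
  a <- phantomPatient(spec, 2)
  b <- phantomPatient(spec, 2)
  expect_identical(studyVolume(a$study), studyVolume(b$study))
  expect_true(min(studyVolume(a$study)) >= 0)
  expect_false(any(a$tumourMask & a$backgroundMask))
  expect_s4_class(a$study, "DynamicStudy")
})

test_that("background kinetics are flat and tumour TBR >= 1.6 without noise", {
  spec <- cohortSpec(4, 0.25, seed = 9, noiseSd = 0)
  pat <- phantomPatient(spec, 1)
  vol <- studyVolume(pat$study)
  nF <- dim(vol)[4L]
  bgIdx <- which(pat$backgroundMask)
  tacs <- matrix(vol, ncol = nF)[bgIdx, ]
  expect_equal(max(tacs) - min(tacs), 0)
  par <- parametricImages(pat$study, pat$backgroundMask, tumour = pat$tumourMask)
  expect_true(all(imageData(par$tbr2040)[pat$tumourMask] >= 1.6))
})

test_that("effect controls the label-dependent heterogeneity shift", {
  spec0 <- cohortSpec(8, 0.5, seed = 3, effect = 0)
  mix0 <- vapply(generatePhantom(spec0), function(p) p$truth$mixing, numeric(1))
  expect_equal(length(unique(mix0)), 1L)   # classes exchangeable at effect 0
  spec1 <- cohortSpec(8, 0.5, seed = 3, effect = 1)
  pats <- generatePhantom(spec1)
  mix1 <- vapply(pats, function(p) p$truth$mixing, numeric(1))
  labs <- vapply(pats, function(p) p$label, integer(1))
  expect_true(all(mix1[labs == 1L] > mix1[labs == 0L]))
})

test_that("a tumour that cannot fit the grid is rejected", {
  spec <- cohortSpec(2, 0.5, gridShape = c(10L, 10L, 8L), seed = 1)
  expect_error(phantomPatient(spec, 1), "fit|voxels")
})
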