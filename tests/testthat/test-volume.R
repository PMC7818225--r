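randomAverages <- function(seed = 1, nch = 65, ns = 326) {
  set.seed(seed)
  new("AverageERPSet",
      means = array(rnorm(4 * 6 * nch * ns), c(4, 6, nch, ns)),
      counts = matrix(5L, 4, 6), times = seq(-100, 550, by = 2),
      samplingRate = 500, montage = testMontage(), subject = 1L,
      metadata = list())
}

test_that("the 50-500 ms window at 500 Hz yields 226 frames", {
  g <- testGrid()
  erp <- matrix(0, 65, 326)
  times <- seq(-100, 550, by = 2)
  vol <- buildVolume(erp, times, g)
  expect_equal(dim(volumeValues(vol))[3], 226)
  expect_equal(length(sampleTimes(vol)), 226)
  vol2 <- buildVolume(erp, times, g, windowMs = c(50, 52))
  expect_equal(dim(volumeValues(vol2))[3], 2)
  expect_error(buildVolume(erp, times, g, windowMs = c(-200, 500)),
               "outside")
})

test_that("each frame equals the interpolated ERP slice at that time", {
  g <- testGrid()
  set.seed(4)
  erp <- matrix(rnorm(65 * 326), 65, 326)
  times <- seq(-100, 550, by = 2)
  vol <- buildVolume(erp, times, g)
  fi <- which(sampleTimes(vol) == 100)
  ref <- interpolateFrame(erp[1:61, which(times == 100)], g)
  expect_equal(volumeValues(vol)[, , fi], ref)
})

test_that("Gaussian smoothing preserves constants, bounds and the mask", {
  g <- testGrid()
  erp <- matrix(5, 65, 326)
  vol <- smoothVolume(buildVolume(erp, seq(-100, 550, by = 2), g))
  v <- volumeValues(vol)
  expect_lt(max(abs(v[!is.na(v)] - 5)), 1e-9)
  expect_identical(is.na(v[, , 1]), !scalpMask(g))
  set.seed(5)
  erp2 <- matrix(rnorm(65 * 326), 65, 326)
  raw <- buildVolume(erp2, seq(-100, 550, by = 2), g)
  sm <- smoothVolume(raw)
  expect_gte(min(volumeValues(sm), na.rm = TRUE),
             min(volumeValues(raw), na.rm = TRUE) - 1e-9)
  expect_lte(max(volumeValues(sm), na.rm = TRUE),
             max(volumeValues(raw), na.rm = TRUE) + 1e-9)
})

test_that("smoothing is linear in its input", {
  g <- testGrid()
  set.seed(6)
  t6 <- seq(-100, 550, by = 2)
  v1 <- buildVolume(matrix(rnorm(65 * 326), 65), t6, g)
  v2 <- buildVolume(matrix(rnorm(65 * 326), 65), t6, g)
  lin <- v1
  lin@values <- 2 * v1@values - 3 * v2@values
  s12 <- smoothVolume(lin)@values
  ref <- 2 * smoothVolume(v1)@values - 3 * smoothVolume(v2)@values
  expect_lt(max(abs(s12 - ref), na.rm = TRUE), 1e-8)
})

test_that("impulse response widths match the [16 16 16] FWHM within 5%", {
  g <- testGrid()
  nT <- 101
  vals <- array(0, c(g@n, g@n, nT))
  vals[array(!scalpMask(g), dim(vals))] <- NA_real_
  centre <- c(16, 16, 51)
  vals[centre[1], centre[2], centre[3]] <- 1
  vol <- new("ScalpTimeVolume", values = vals,
             times = seq(0, by = 2, length.out = nT), grid = g,
             provenance = list())
  sm <- volumeValues(smoothVolume(vol))
  fwhmOf <- function(prof, spacing) {
    prof <- prof / max(prof, na.rm = TRUE)
    i <- which.max(prof)
    cross <- function(side) {
      idx <- if (side > 0) seq(i, length(prof)) else seq(i, 1)
      k <- which(prof[idx] < 0.5)[1]
      a <- prof[idx[k - 1]]; b <- prof[idx[k]]
      (k - 2 + (a - 0.5) / (a - b)) * spacing
    }
    cross(1) + cross(-1)
  }
  fx <- fwhmOf(sm[, centre[2], centre[3]], g@pixelSizeMm)
  fy <- fwhmOf(sm[centre[1], , centre[3]], g@pixelSizeMm)
  ft <- fwhmOf(sm[centre[1], centre[2], ], 2)
  expect_equal(fx, 16, tolerance = 0.05)
  expect_equal(fy, 16, tolerance = 0.05)
  expect_equal(ft, 16, tolerance = 0.05)
})

test_that("volumes survive a disk round trip bit-identically", {
  g <- testGrid()
  set.seed(7)
  vol <- smoothVolume(buildVolume(matrix(rnorm(65 * 326), 65),
                                  seq(-100, 550, by = 2), g))
  prefix <- withr::local_tempfile()
  saveVolume(vol, prefix)
  back <- loadVolume(prefix, g)
  expect_identical(volumeValues(back), volumeValues(vol))
  expect_identical(sampleTimes(back), sampleTimes(vol))
})

test_that("NIfTI export writes the grid geometry into the header", {
  g <- testGrid()
  vol <- buildVolume(matrix(1, 65, 326), seq(-100, 550, by = 2), g)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolumeNifti(vol, path)
  img <- RNifti::readNifti(path)
  expect_equal(dim(img), dim(volumeValues(vol)))
  expect_equal(RNifti::pixdim(img)[1:2], rep(g@pixelSizeMm, 2))
  expect_true(all(is.na(img[, , 1][!scalpMask(g)])))
})

test_that("the batched voxel matrix equals the volume-by-volume route", {
  g <- testGrid()
  av <- randomAverages(8)
  Y1 <- volumesToMatrix(buildSubjectVolumes(av, g))
  Y2 <- subjectVoxelMatrix(av, g)
  expect_equal(Y2, Y1, tolerance = 1e-12)
  Y1r <- volumesToMatrix(buildSubjectVolumes(av, g, spec = NULL))
  Y2r <- subjectVoxelMatrix(av, g, spec = NULL)
  expect_equal(Y2r, Y1r, tolerance = 1e-12)
})
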