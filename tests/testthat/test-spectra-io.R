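# Delimited-text round trips, validation errors, QC filtering, regridding.

test_that("write/read round trip is the identity on valid datasets", {
  set.seed(11)
  cases <- list(
    make_spectra(matrix(runif(12, 0, 2), 3, 4), c("T", "NT", "T"),
                 patients = c("p1", "p2", "p1")),
    make_spectra(matrix(runif(5, 0, 2), 1, 5), "NT"),          # single spectrum
    make_spectra(matrix(stats::rnorm(40, 1, 0.3), 8, 5),
                 rep(c("T", "NT"), 4),
                 wn = c(1000.25, 1013.71239, 1200, 1456.5, 1799.9))
  )
  for (ds in cases) {
    sp <- withr::local_tempfile(fileext = ".csv")
    md <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(ds, sp, md)
    back <- readSpectra(sp, md)
    expect_equal(wavenumbers(back), wavenumbers(ds), tolerance = 1e-12)
    expect_equal(absorbance(back), absorbance(ds), tolerance = 1e-12)
    expect_identical(spectrumIds(back), spectrumIds(ds))
    expect_identical(patientIds(back), patientIds(ds))
    expect_identical(classLabels(back), classLabels(ds))
  }
})

test_that("an empty dataset (0 spectra, non-empty grid) round trips", {
  ds <- make_spectra(matrix(numeric(0), 0, 4), character(0))
  sp <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(ds, sp, md)
  back <- readSpectra(sp, md)
  expect_equal(wavenumbers(back), wavenumbers(ds))
  expect_identical(ncol(back), 0L)
})

test_that("descending wavenumber columns are sorted ascending on read", {
  sp <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("spectrum_id,1008,1004,1000",
               "s1,0.3,0.2,0.1",
               "s2,0.6,0.5,0.4"), sp)
  writeLines(c("spectrum_id,patient_id,label",
               "s1,p1,T", "s2,p2,NT"), md)
  ds <- readSpectra(sp, md)
  expect_equal(wavenumbers(ds), c(1000, 1004, 1008))
  expect_equal(unname(absorbance(ds)[, "s1"]), c(0.1, 0.2, 0.3))
  expect_equal(unname(absorbance(ds)[, "s2"]), c(0.4, 0.5, 0.6))
})

test_that("input errors name the offending spectrum or cell", {
  sp <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("spectrum_id,1000,1004", "s1,0.1,0.2", "s2,0.3,0.4"), sp)

  writeLines(c("spectrum_id,patient_id,label", "s1,p1,T", "s2,p2,X"), md)
  expect_error(readSpectra(sp, md), "s2")

  writeLines(c("spectrum_id,patient_id,label", "s1,p1,T", "s3,p2,NT"), md)
  expect_error(readSpectra(sp, md), "s3")

  writeLines(c("spectrum_id,patient_id,label", "s1,p1,T", "s1,p1,NT",
               "s2,p2,NT"), md)
  expect_error(readSpectra(sp, md), "duplicate.*s1")

  writeLines(c("spectrum_id,patient_id,label", "s1,p1,T", "s2,p2,NT"), md)
  writeLines(c("spectrum_id,1000,1004", "s1,0.1,oops", "s2,0.3,0.4"), sp)
  expect_error(readSpectra(sp, md), "s1.*1004")
})

test_that("quality filter keeps in-bounds spectra and reports rejections", {
  a <- rbind(c(0.8, 0.7, 0.1),   # Amide I max 0.8: retained
             c(0.0, 0.0, 0.0),   # all zeros: rejected, value 0
             c(2.5, 2.6, 0.2))   # saturated: rejected
  ds <- make_spectra(a, c("T", "NT", "T"),
                     wn = c(1620, 1660, 1750))
  out <- qualityFilter(ds, qcParams(0.1, 2.0, c(1600, 1700)))
  expect_identical(spectrumIds(out$dataset), "s001")
  expect_equal(out$rejected$spectrum_id, c("s002", "s003"))
  expect_equal(out$rejected$peak_absorbance, c(0, 2.6))
  expect_identical(ncol(out$dataset) + nrow(out$rejected), ncol(ds))

  # unbounded parameters: identity
  all_in <- qualityFilter(ds, qcParams(0, Inf, c(1600, 1700)))
  expect_identical(spectrumIds(all_in$dataset), spectrumIds(ds))

  expect_error(qualityFilter(ds, qcParams(0.1, 2, c(900, 950))),
               "does not overlap")
})

test_that("resampling interpolates linearly without extrapolation", {
  ds <- make_spectra(matrix(c(0, 1, 2, 0.5, 1.5, 2.5), 2, 3, byrow = TRUE),
                     c("T", "NT"), wn = c(1000, 1004, 1008))
  # identity grid: unchanged
  same <- resampleToGrid(ds, c(1000, 1004, 1008))
  expect_equal(absorbance(same), absorbance(ds))
  # midpoint of A(1000)=0, A(1004)=1 is 0.5
  mid <- resampleToGrid(ds, 1002)
  expect_equal(unname(absorbance(mid)[1, ]), c(0.5, 1.0))
  expect_identical(classLabels(mid), classLabels(ds))
  # no extrapolation
  expect_error(resampleToGrid(ds, c(999, 1004)), "extrapolation")

  # interpolated values stay within the bracketing samples
  set.seed(4)
  big <- make_spectra(matrix(runif(60), 5, 12), rep(c("T", "NT"), c(3, 2)))
  target <- sort(runif(20, min(wavenumbers(big)), max(wavenumbers(big))))
  res <- resampleToGrid(big, target)
  a <- absorbance(big)
  for (p in seq_along(target)) {
    lo <- max(which(wavenumbers(big) <= target[p]))
    hi <- min(which(wavenumbers(big) >= target[p]))
    expect_true(all(absorbance(res)[p, ] >= pmin(a[lo, ], a[hi, ]) - 1e-12))
    expect_true(all(absorbance(res)[p, ] <= pmax(a[lo, ], a[hi, ]) + 1e-12))
  }
})

test_that("SpectraSet validity rejects malformed objects", {
  expect_error(make_spectra(matrix(1, 2, 2), c("T", "X")), "label")
  expect_error(make_spectra(matrix(1, 2, 2), c("T", "NT"),
                            ids = c("a", "a")), "duplicate")
  expect_error(make_spectra(matrix(c(1, NA, 1, 1), 2, 2), c("T", "NT")),
               "finite")
  expect_error(make_spectra(matrix(1, 2, 3), c("T", "NT"),
                            wn = c(1000, 1000, 1004)))
})
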