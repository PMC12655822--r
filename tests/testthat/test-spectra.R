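test_that("read_spectrum_table parses delimited text and rejects bad axes", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("250,0", "257,1", "264,0"), path)
  sp <- read_spectrum_table(path)
  expect_equal(sp$wavenumber, c(250, 257, 264))
  expect_equal(sp$intensity, c(0, 1, 0))

  writeLines(c("wavenumber\tcell1\tcell2", "250\t1\t4", "257\t2\t5"), path)
  multi <- read_spectrum_table(path)
  expect_setequal(unique(multi$spectrum), c("cell1", "cell2"))
  expect_equal(multi$intensity[multi$spectrum == "cell2"], c(4, 5))

  writeLines(c("264,0", "257,1", "250,0"), path)
  expect_error(read_spectrum_table(path), "not strictly increasing.*row")

  writeLines(c("250,0", "257,1,9", "264,0"), path)
  expect_error(read_spectrum_table(path), "ragged")
})

test_that("write/read round trip is value-identical at full precision", {
  path <- withr::local_tempfile(fileext = ".csv")
  sp <- withr::with_seed(5, tibble::tibble(
    wavenumber = sort(runif(40, 250, 3000)),
    intensity = rnorm(40) * pi))
  write_spectrum_table(sp, path)
  back <- read_spectrum_table(path)
  expect_identical(back$wavenumber, sp$wavenumber)
  expect_identical(back$intensity, sp$intensity)
})

test_that("resample_to_axis interpolates linearly onto the target grid", {
  grid <- axis_spec(0, 10, 5)
  ramp <- tibble::tibble(wavenumber = c(0, 10), intensity = c(0, 10))
  out <- resample_to_axis(ramp, grid)
  expect_equal(out$intensity, c(0, 5, 10))

  already <- tibble::tibble(wavenumber = axis_points(grid),
                            intensity = c(3, 1, 4))
  expect_equal(resample_to_axis(already, grid)$intensity, c(3, 1, 4))

  # piecewise-linear on the coarse nodes: fine-grid round trip is exact
  # at shared nodes (oracle: direct evaluation there)
  coarse <- axis_spec(250, 950, 100)
  pl <- tibble::tibble(wavenumber = axis_points(coarse),
                       intensity = abs(axis_points(coarse) - 600) / 100)
  fine <- resample_to_axis(pl, axis_spec(250, 950, 25))
  back <- resample_to_axis(fine, coarse)
  expect_equal(back$intensity, pl$intensity, tolerance = 1e-12)

  far <- tibble::tibble(wavenumber = c(5000, 6000), intensity = c(1, 1))
  expect_error(resample_to_axis(far, grid), "overlap")

  padded <- resample_to_axis(tibble::tibble(wavenumber = c(400, 500),
                                            intensity = c(1, 1)),
                             axis_spec(250, 1000, 50))
  expect_gt(attr(padded, "n_padded"), 0)
  expect_equal(padded$intensity[padded$wavenumber < 400], rep(0, 3))
})

test_that("a constant spectrum is pure baseline for every configuration", {
  x <- axis_points(axis_spec(250, 1000, 10))
  for (const in c(0.5, 7, 120)) {
    for (cfg in list(c(1, 1), c(4, 3), c(6, 2))) {
      out <- baseline_correct(
        tibble::tibble(wavenumber = x, intensity = rep(const, length(x))),
        n_segments = cfg[[1]], degree = cfg[[2]])
      expect_equal(out$intensity, rep(0, length(x)), tolerance = 1e-8)
    }
  }
})

test_that("baseline correction recovers a peak sitting on a linear ramp", {
  x <- axis_points(axis_spec())
  fwhm <- 30
  peak <- 100 / (1 + (2 * (x - 1200) / fwhm)^2)
  ramp <- 0.02 * x + 5
  sp <- tibble::tibble(wavenumber = x, intensity = ramp + peak)
  corrected <- baseline_correct(sp, floor_zero = FALSE)
  # oracle: subtracting the known ramp leaves exactly `peak`
  away <- abs(x - 1200) > 3 * fwhm
  expect_lt(max(abs(corrected$intensity[away] - peak[away])), 1)

  twice <- baseline_correct(corrected, floor_zero = FALSE)
  expect_lt(abs(max(twice$intensity) - max(corrected$intensity)) /
              max(corrected$intensity), 0.05)
})

test_that("baseline correction rejects segments with too few points", {
  sp <- tibble::tibble(wavenumber = c(1, 2, 3, 4), intensity = rep(1, 4))
  expect_error(baseline_correct(sp, n_segments = 2, degree = 3), "degree")
})

test_that("boxcar smoothing is a centered shrinking-window mean", {
  sp <- tibble::tibble(wavenumber = 1:5, intensity = c(0, 0, 3, 0, 0))
  expect_equal(boxcar_smooth(sp, 3)$intensity, c(0, 1, 1, 1, 0))
  expect_equal(boxcar_smooth(sp, 1)$intensity, sp$intensity)

  const <- tibble::tibble(wavenumber = 1:9, intensity = rep(4, 9))
  for (w in c(1, 3, 5, 9)) {
    expect_equal(boxcar_smooth(const, w)$intensity, const$intensity)
  }

  expect_error(boxcar_smooth(sp, 2), "odd")
  expect_error(boxcar_smooth(sp, -3), "odd")
  expect_error(boxcar_smooth(sp, 7), "length")

  # interior mean is preserved up to edge effects
  noisy <- withr::with_seed(2, tibble::tibble(wavenumber = 1:101,
                                              intensity = rnorm(101)))
  sm <- boxcar_smooth(noisy, 5)
  expect_equal(mean(sm$intensity[3:99]), mean(noisy$intensity[3:99]),
               tolerance = 0.02)
})

test_that("preprocessing acts per spectrum in multi-spectrum tables", {
  x <- 1:20
  df <- dplyr::bind_rows(
    tibble::tibble(wavenumber = x, spectrum = "a", intensity = 5),
    tibble::tibble(wavenumber = x, spectrum = "b",
                   intensity = c(rep(0, 9), 10, rep(0, 10))))
  sm <- boxcar_smooth(df, 5)
  expect_equal(sm$intensity[sm$spectrum == "a"], rep(5, 20))
  expect_equal(sum(sm$intensity[sm$spectrum == "b"]), 10)
})
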