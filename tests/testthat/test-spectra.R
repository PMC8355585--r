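test_that("ASCII peak lists parse with headers, comments and mixed delimiters", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("100.0 10", "101.0 20"), f)
  sp <- read_peaklist(f)
  expect_equal(nrow(sp), 2)
  expect_equal(attr(sp, "mode"), "centroid")

  writeLines(c("mass intensity", "# a comment", "101.0,20", "100.0\t10"), f)
  sp <- read_peaklist(f)
  expect_equal(sp$mz, c(100, 101))           # sorted on load
  expect_equal(attr(sp, "skipped"), 2L)

  writeLines(c("100.0 10", "100.0 5"), f)
  expect_warning(sp <- read_peaklist(f), "duplicate")
  expect_equal(sp$intensity, 15)

  writeLines(c("no", "numbers here"), f)
  expect_error(read_peaklist(f), "no numeric")
})

test_that("noise is the scaled median or mean of nonzero intensities", {
  sp <- glyquant:::new_spectrum(1:5, c(1, 2, 3, 4, 100))
  expect_equal(estimate_noise(sp, "median", 2), 6)
  expect_equal(estimate_noise(sp, "mean", 1), 22)
  spc <- glyquant:::new_spectrum(1:4, rep(7, 4))
  expect_equal(estimate_noise(spc, "median", 1.5),
               estimate_noise(spc, "mean", 1.5))
  sp0 <- glyquant:::new_spectrum(1:3, c(0, 0, 0))
  expect_warning(n0 <- estimate_noise(sp0), "zero")
  expect_equal(n0, 0)
})

test_that("Gaussian centroiding recovers synthetic peak centres", {
  grid <- seq(999, 1001, by = 0.005)
  y <- 100 * exp(-(grid - 1000)^2 / (2 * 0.02^2))
  sp <- glyquant:::new_spectrum(grid, y, mode = "profile")
  pk <- pick_peaks(sp, noise = 1)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 1000), 0.001)
  expect_equal(pk$intensity, 100, tolerance = 1e-3)

  ## two Gaussians 3 sigma apart resolve into two centroids
  y2 <- 100 * exp(-(grid - 999.8)^2 / (2 * 0.02^2)) +
    80 * exp(-(grid - 999.86)^2 / (2 * 0.02^2))
  pk2 <- pick_peaks(glyquant:::new_spectrum(grid, y2, mode = "profile"),
                    noise = 1)
  expect_equal(nrow(pk2), 2)
  expect_lt(abs(pk2$mz[1] - 999.8), 0.005)
  expect_lt(abs(pk2$mz[2] - 999.86), 0.005)

  ## flat spectrum below the noise floor yields nothing
  pk3 <- pick_peaks(glyquant:::new_spectrum(grid, rep(5, length(grid)),
                                            mode = "profile"), noise = 10)
  expect_equal(nrow(pk3), 0)
})

test_that("median centroid error stays below a fifth of the grid step", {
  set.seed(7)
  step <- 0.005
  errs <- replicate(100, {
    centre <- runif(1, 500, 3000)
    sigma <- runif(1, 0.015, 0.05)
    height <- runif(1, 50, 500)
    grid <- seq(centre - 0.5, centre + 0.5, by = step)
    y <- height * exp(-(grid - centre)^2 / (2 * sigma^2))
    pk <- pick_peaks(glyquant:::new_spectrum(grid, y, mode = "profile"),
                     noise = 1)
    abs(pk$mz[which.max(pk$intensity)] - centre)
  })
  expect_lt(median(errs), 0.2 * step)
})

test_that("envelope detection assigns charge from isotope spacing", {
  sp1 <- tibble::tibble(mz = 1000 + c(0, 1, 2) * 1.0033548,
                        intensity = c(100, 60, 20), snr = Inf)
  env <- detect_envelopes(sp1)
  expect_equal(nrow(env), 1)
  expect_equal(env$charge, 1L)
  expect_equal(env$n_peaks, 3L)
  expect_equal(env$mono_mz, 1000)

  sp2 <- tibble::tibble(mz = 1000 + c(0, 1, 2) * 1.0033548 / 2,
                        intensity = c(100, 60, 20), snr = Inf)
  expect_equal(detect_envelopes(sp2)$charge, 2L)

  ## two peaks are not enough under the default minimum of three isotopes
  sp3 <- tibble::tibble(mz = c(1000, 1001.0034), intensity = c(10, 5),
                        snr = Inf)
  expect_equal(nrow(detect_envelopes(sp3)), 0)
  expect_equal(nrow(detect_envelopes(sp3, min_isotopes = 2)), 1)
})

test_that("raising snr_min or min_isotopes never adds envelopes", {
  set.seed(3)
  mz <- sort(c(1000 + (0:5) * 1.0033548, 1200 + (0:2) * 1.0033548,
               runif(10, 900, 1300)))
  pk <- tibble::tibble(mz = mz, intensity = runif(length(mz), 10, 100),
                       snr = runif(length(mz), 1, 50))
  n_prev <- Inf
  for (s in c(0, 5, 15, 40)) {
    n <- nrow(detect_envelopes(pk, snr_min = s))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (m in 2:5) {
    n <- nrow(detect_envelopes(pk, min_isotopes = m, snr_min = 0))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("rendered database glycans come back as exactly one envelope at the theoretical mono m/z", {
  db <- the_full_db()
  set.seed(19)
  sample_db <- db[sample(nrow(db), 60), ]
  fe <- derivatization("free end")
  for (i in seq_len(nrow(sample_db))) {
    rec <- sample_db[i, ]
    mix <- mixture_spec(tibble::tibble(composition = rec$composition,
                                       adduct = "Na+", ratio_hl = 0),
                        deriv = fe)
    env <- detect_envelopes(render_sticks(mix), snr_min = 0)
    expect_equal(nrow(env), 1)
    expect_lt(abs(env$mono_mz -
                    theoretical_mz(rec$free_mass, adduct("Na+"))), 1e-4)
  }
})

test_that("mass calibration shifts observed m/z before matching", {
  env <- tibble::tibble(envelope = 1L, charge = 1L, mono_mz = 1000.05,
                        mono_intensity = 10, mono_snr = Inf, n_peaks = 3L,
                        peak_mz = list(1000.05 + 0:2 * 1.0033548),
                        intensity = list(c(10, 5, 2)))
  out <- apply_mass_calibration(env, 0.05)
  expect_equal(out$mono_mz, 1000.00)
  expect_equal(out$peak_mz[[1]][1], 1000.00)
  expect_identical(apply_mass_calibration(env, 0), env)
})
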