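test_that("a rendered glycan is matched back at ~0 ppm and tagged L", {
  run <- duplex_run("Hex3HexNAc2", ratio_hl = 0,
                    deriv = derivatization("free end"))
  m <- run$matches
  hit <- m[m$composition == "Hex3HexNAc2" & m$adduct == "Na+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$channel, "L")
  expect_lt(abs(hit$error_ppm), 0.01)
  expect_equal(hit$rank, 1L)
})

test_that("matches outside the ppm tolerance are rejected; shrinking tolerance never adds matches", {
  fe <- derivatization("free end")
  mix <- mixture_spec(tibble::tibble(composition = "Hex3HexNAc2",
                                     adduct = "Na+", ratio_hl = 0),
                      deriv = fe)
  sp <- render_sticks(mix)
  shifted <- glyquant:::new_spectrum(sp$mz * (1 + 100e-6), sp$intensity)
  cfg <- search_config(db = small_db(), deriv = fe, noise_level = 0)
  run <- run_pipeline(shifted, cfg)
  expect_equal(nrow(run$matches), 0)

  n_prev <- 0
  for (tol in c(5, 20, 50, 200)) {
    cfg_t <- search_config(db = small_db(), deriv = fe, noise_level = 0,
                           tolerance_ppm = tol)
    n <- nrow(run_pipeline(sp, cfg_t)$matches)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("a planted constant mass offset breaks matching and calibration repairs it", {
  fe <- derivatization("free end")
  mix <- mixture_spec(tibble::tibble(composition = "Hex3HexNAc2",
                                     adduct = "Na+", ratio_hl = 0),
                      deriv = fe)
  sp <- render_sticks(mix)
  ## +20 ppm residual error plus a +0.06 Da constant shift (~65 ppm at 933)
  shifted <- glyquant:::new_spectrum(sp$mz * (1 + 20e-6) + 0.06,
                                     sp$intensity)
  cfg0 <- search_config(db = small_db(), deriv = fe, noise_level = 0)
  expect_equal(nrow(run_pipeline(shifted, cfg0)$matches), 0)
  cfg1 <- search_config(db = small_db(), deriv = fe, noise_level = 0,
                        calibration_offset = 0.06)
  m <- run_pipeline(shifted, cfg1)$matches
  expect_true("Hex3HexNAc2" %in% m$composition)
  expect_lt(abs(m$error_ppm[m$composition == "Hex3HexNAc2"] - 20), 1)
})

test_that("ambiguous envelopes report every candidate, ranked by ppm error", {
  ## Hex5HexNAc4 + Na+ and Hex4HexNAc4dHex1 + K+ are near-isobaric
  db <- glycan_db("mammalian", bounds = c(hex = 5, hexnac = 4, dhex = 1,
                                          sialic = 0))
  fe <- derivatization("free end")
  mix <- mixture_spec(tibble::tibble(composition = "Hex5HexNAc4",
                                     adduct = "Na+", ratio_hl = 0),
                      deriv = fe)
  cfg <- search_config(db = db, deriv = fe, noise_level = 0,
                       tolerance_ppm = 50)
  m <- run_pipeline(render_sticks(mix), cfg)$matches
  expect_setequal(unique(m$composition),
                  c("Hex5HexNAc4", "Hex4HexNAc4dHex1"))
  expect_equal(m$adduct[m$composition == "Hex4HexNAc4dHex1"], "K+")
  expect_equal(m$rank, order(abs(m$error_ppm)))
})

test_that("duplex pairing requires the label separation; light-only stays unpaired", {
  run <- duplex_run("Hex3HexNAc2", ratio_hl = 1)
  pr <- pair_for(run, "Hex3HexNAc2")
  expect_equal(nrow(pr), 1)
  expect_equal(pr$flag, "ok")

  run_l <- duplex_run("Hex3HexNAc2", ratio_hl = 0)
  expect_true(all(run_l$pairs$flag == "unpaired"))
  expect_true(all(is.na(run_l$pairs$ratio_LH)))

  ## two adducts of the same duplex give two pairs
  run2 <- duplex_run("Hex3HexNAc2", ratio_hl = 2,
                     adducts = c("Na+", "K+"))
  ok <- run2$pairs[run2$pairs$flag == "ok" &
                     run2$pairs$composition == "Hex3HexNAc2", ]
  expect_setequal(ok$adduct, c("Na+", "K+"))
  expect_equal(ok$ratio_HL, c(2, 2), tolerance = 1e-6)
})

test_that("overlap calibration arithmetic follows the ratio equations", {
  r <- calibrated_ratio(100, 120, c(1, 0.5, 0.2), 0, 2)
  expect_equal(r$calibr_ratio, 0.2)
  expect_equal(r$ratio_LH, 1.0)
  expect_equal(r$ratio_raw, 100 / 120)
  ## corrected heavy intensity <= 0 is flagged, not reported as a ratio
  r2 <- calibrated_ratio(100, 20, c(1, 0.5, 0.2), 0, 2)
  expect_equal(r2$flag, "overlap_dominated")
  expect_true(is.na(r2$ratio_LH))
  r3 <- calibrated_ratio(0, 10, c(1, 0.5), 0, 2)
  expect_equal(r3$flag, "zero_intensity")
  ## label deltas round half away from zero
  expect_equal(glyquant:::round_half_away(2.0126), 2)
  expect_equal(glyquant:::round_half_away(3.0105), 3)
  expect_equal(glyquant:::round_half_away(2.5), 3)
})

test_that("stick duplex ratios are recovered exactly and the raw ratio is biased", {
  db <- small_db()
  set.seed(23)
  light_records <- db[db$free_mass < 2000, ]
  recs <- light_records[sample(nrow(light_records), 6), ]
  derivs <- list(d2_duplex(), derivatization("GREDIL"))
  for (i in seq_len(nrow(recs))) {
    deriv <- derivs[[(i %% 2) + 1]]
    truth <- c(0.1, 0.5, 1, 2, 10)[(i %% 5) + 1]
    run <- duplex_run(recs$composition[i], ratio_hl = truth, deriv = deriv,
                      db = db)
    pr <- pair_for(run, recs$composition[i])
    expect_equal(nrow(pr), 1)
    expect_equal(pr$ratio_HL, truth, tolerance = 1e-6)
    ## uncalibrated ratio is at least as biased, strictly when overlap > 0
    err_cal <- abs(pr$ratio_LH - 1 / truth)
    err_raw <- abs(pr$ratio_raw - 1 / truth)
    expect_gte(err_raw, err_cal)
    if (pr$calibr_ratio > 0) expect_gt(err_raw, err_cal)
  }
})

test_that("the report records config, matches and pair columns; delta 0 leaves ratios empty", {
  out <- withr::local_tempfile(fileext = ".tsv")
  run <- duplex_run("Hex3HexNAc2", ratio_hl = 5)
  write_report(run$matches, run$pairs, run$config, out,
               source_file = "fixture")
  lines <- readLines(out)
  expect_true(any(grepl("^# tolerance_ppm = 50$", lines)))
  hdr <- strsplit(grep("^source_file\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(hdr[1:6], c("source_file", "composition", "derivatization",
                           "adduct", "charge", "channel"))
  tab <- utils::read.delim(out, comment.char = "#")
  row <- tab[tab$composition == "Hex3HexNAc2" & tab$channel == "L", ]
  expect_equal(row$ratio_HL, 5, tolerance = 1e-6)

  ## identification-only run: ratio columns stay empty
  run0 <- duplex_run("Hex3HexNAc2", ratio_hl = 0,
                     deriv = derivatization("free end"))
  write_report(run0$matches, run0$pairs, run0$config, out)
  tab0 <- utils::read.delim(out, comment.char = "#")
  expect_true(all(is.na(tab0$ratio_LH)))
  expect_true(any(grepl("^# delta_mass = 0$", readLines(out))))

  ## empty match set: header-only file
  write_report(glyquant:::empty_matches(), NULL, run0$config, out)
  tab_empty <- utils::read.delim(out, comment.char = "#")
  expect_equal(nrow(tab_empty), 0)
})
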