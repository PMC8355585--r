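test_that("residue element maps and masses follow the residue formulas", {
  expect_equal(residue_elements("Hex1"), parse_formula("C6H10O5"))
  expect_equal(residue_elements("Hex3HexNAc2"), parse_formula("C34H56N2O25"))
  ## hand-summed from the atomic mass table
  expect_equal(residue_mass("Hex3HexNAc3"), 1095.396589, tolerance = 1e-8)
  expect_equal(element_mass("H2O"), 18.010565, tolerance = 1e-6)
})

test_that("residue mass is additive over compositions", {
  set.seed(11)
  for (i in 1:25) {
    a <- list(hex = sample(0:6, 1), hexnac = sample(0:4, 1),
              dhex = sample(0:2, 1), neuac = sample(0:2, 1),
              neugc = sample(0:1, 1))
    b <- list(hex = sample(1:6, 1), hexnac = sample(0:4, 1),
              dhex = sample(0:2, 1), neuac = sample(0:2, 1),
              neugc = sample(0:1, 1))
    ab <- mapply(`+`, a, b, SIMPLIFY = FALSE)
    expect_equal(residue_mass(ab), residue_mass(a) + residue_mass(b),
                 tolerance = 1e-12)
  }
})

test_that("composition strings round-trip through parse/format", {
  comps <- c("Hex3HexNAc2", "Hex1", "HexNAc2dHex1", "Hex5HexNAc4NeuAc2",
             "Hex2NeuGc1", "Hex3HexNAc2dHex1NeuAc1NeuGc1")
  parsed <- parse_composition(comps)
  expect_equal(format_composition(parsed$hex, parsed$hexnac, parsed$dhex,
                                  parsed$neuac, parsed$neugc), comps)
  expect_error(parse_composition("Hex3Pent1"), "parse")
})

test_that("combinatorial database enumerates bounds exhaustively", {
  db <- glycan_db("mammalian", bounds = c(hex = 1, hexnac = 1, dhex = 0,
                                          sialic = 0))
  expect_setequal(db$composition, c("Hex1", "HexNAc1", "Hex1HexNAc1"))
  expect_false(any(duplicated(db$composition)))
  ## ordered by free mass then name
  expect_equal(db$free_mass, sort(db$free_mass))

  full <- the_full_db()
  expect_true(all(full$free_mass <= 4500))
  expect_true(all(full$hex <= 12 & full$hexnac <= 7 & full$dhex <= 5 &
                    full$neuac + full$neugc <= 4))
  expect_equal(full$free_mass - full$residue_mass,
               rep(18.010565, nrow(full)), tolerance = 1e-6)
})

test_that("human database is the NeuGc-free subset of the mammalian one", {
  b <- c(hex = 4, hexnac = 3, dhex = 1, sialic = 2)
  mam <- glycan_db("mammalian", bounds = b)
  hum <- glycan_db("human", bounds = b)
  expect_true(all(hum$neugc == 0))
  expect_setequal(hum$composition,
                  mam$composition[mam$neugc == 0])
})

test_that("derivatization presets carry the duplex label deltas", {
  pf <- derivatization("PFBHA")
  expect_equal(pf$delta_mass, 2.012553, tolerance = 1e-6)
  expect_equal(pf$light_mass, 213.021305, tolerance = 1e-6)
  gr <- derivatization("GREDIL")
  expect_equal(gr$delta_mass, 3.010523, tolerance = 1e-6)
  ## delta equals mass(heavy) - mass(light) by construction
  expect_equal(gr$delta_mass, element_mass(gr$heavy) - element_mass(gr$light),
               tolerance = 1e-9)
  fe <- derivatization("free end")
  expect_equal(fe$light_mass, element_mass("H2O"), tolerance = 1e-12)
  expect_true(is.na(fe$delta_mass))
  ## custom tag by element map
  cu <- derivatization("d0/d2", light = "H2O", heavy = "OD2")
  expect_equal(cu$delta_mass, 2.012553, tolerance = 1e-6)
  expect_error(derivatization("nope"), "preset")
})

test_that("neutral and ionised masses follow adduct arithmetic", {
  db <- small_db()
  fe <- neutral_mass(db, derivatization("free end"), "light")
  expect_equal(fe$neutral_mass, db$free_mass, tolerance = 1e-12)
  rec <- db[db$composition == "Hex3HexNAc2", ]
  expect_equal(rec$free_mass, 910.327781, tolerance = 1e-6)
  expect_equal(theoretical_mz(1000, adduct("H+")), 1001.007276,
               tolerance = 1e-6)
  expect_equal(theoretical_mz(1000, adduct("Na+")) - 1000, 22.989220,
               tolerance = 1e-6)
  ## negative mode loses a proton
  expect_equal(theoretical_mz(1000, adduct("-H")), 1000 - 1.007276,
               tolerance = 1e-6)
  ## double sodiation halves m/z
  expect_equal(theoretical_mz(1000, adduct("Na+"), k = 2),
               (1000 + 2 * 22.989220) / 2, tolerance = 1e-6)
})

test_that("printed reference m/z values are reproduced within 2 mDa", {
  pf <- derivatization("PFBHA")
  na <- adduct("Na+")
  printed <- c(Hex3HexNAc3 = 1331.40601, Hex3HexNAc6 = 1940.64413,
               Hex3HexNAc7 = 2143.7235, Hex5HexNAc2 = 1452.43229)
  for (comp in names(printed)) {
    mz <- theoretical_mz(residue_mass(comp) + pf$light_mass, na)
    expect_lt(abs(mz - printed[[comp]]), 2e-3)
  }
  ## pairwise differences are exact residue-mass multiples
  hexnac <- residue_mass("HexNAc1"); hex <- residue_mass("Hex1")
  expect_equal(printed[["Hex3HexNAc6"]] - printed[["Hex3HexNAc3"]],
               3 * hexnac, tolerance = 1e-4 / (3 * hexnac))
  expect_equal(printed[["Hex3HexNAc7"]] - printed[["Hex3HexNAc6"]],
               hexnac, tolerance = 1e-4 / hexnac)
  expect_equal(printed[["Hex5HexNAc2"]] - printed[["Hex3HexNAc3"]],
               2 * hex - hexnac, tolerance = 1e-4 / 100)
})

test_that("user database tables load, collapse duplicates, and reject bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# my glycans", "Hex,HexNAc", "3,2"), f)
  db <- read_glycan_db(f)
  expect_equal(nrow(db), 1)
  expect_equal(db$free_mass, 910.327781, tolerance = 1e-6)
  expect_equal(db$source_db, "custom")

  writeLines(c("Hex\tHexNAc", "3\t2", "3\t2", "1\t0"), f)
  expect_warning(db2 <- read_glycan_db(f), "duplicate")
  expect_equal(nrow(db2), 2)

  writeLines(c("Hex,HexNAc", "3,-1"), f)
  expect_error(read_glycan_db(f), "line 2")

  writeLines(c("Hex,Pentose", "1,1"), f)
  expect_error(read_glycan_db(f), "unknown column")

  writeLines("# nothing", f)
  expect_warning(db3 <- read_glycan_db(f), "empty")
  expect_equal(nrow(db3), 0)
})

test_that("element arithmetic validates counts", {
  expect_equal(el_add("C2H4", "CH2"), parse_formula("C3H6"))
  expect_equal(el_subtract("C2H4", "CH2"), parse_formula("CH2"))
  expect_error(el_subtract("CH2", "C2H4"), "negative")
  expect_error(parse_formula("C2Xx"), "unknown element")
  ## label pseudo-elements carry exact heavy-isotope masses
  expect_equal(element_mass("D") - element_mass("H"), 1.006277,
               tolerance = 1e-6)
  expect_equal(element_mass("O18") - element_mass("O"), 2.004246,
               tolerance = 1e-6)
})
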