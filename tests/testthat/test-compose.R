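test_that("enumeration matches reported assignments and handles edge cases", {
  r <- enumerate_compositions(503.1604, enum_config())
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$n_hex, r$n_pent), c(3L, 0L))

  r <- enumerate_compositions(575.1813, enum_config())
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$n_hex, r$n_pent), c(1L, 3L))

  expect_equal(nrow(enumerate_compositions(150.0, enum_config())), 0L)
  expect_error(enumerate_compositions(-1), "positive")
})

test_that("enumeration equals the exhaustive double-loop oracle", {
  set.seed(20260928)
  mzs <- runif(200, 150, 2000)
  for (tol in c(1, 5, 20)) {
    cfg <- enum_config(ms1_tol_ppm = tol)
    for (mz in mzs) {
      got <- enumerate_compositions(mz, cfg)
      want <- oracle_enumerate(mz, tol)
      key <- function(d) sort(paste(d$n_hex, d$n_pent))
      expect_identical(key(got), key(want),
                       label = sprintf("mz %.4f tol %g", mz, tol))
    }
  }
})

test_that("widening the tolerance never shrinks the result set", {
  set.seed(42)
  mzs <- runif(50, 150, 2000)
  for (mz in mzs) {
    key <- function(tol) {
      d <- enumerate_compositions(mz, enum_config(ms1_tol_ppm = tol))
      paste(d$n_hex, d$n_pent)
    }
    expect_true(all(key(1) %in% key(5)))
    expect_true(all(key(5) %in% key(20)))
  }
})

test_that("results come back sorted by absolute ppm", {
  set.seed(7)
  for (mz in runif(30, 150, 2000)) {
    d <- enumerate_compositions(mz, enum_config(ms1_tol_ppm = 500))
    expect_false(is.unsorted(abs(d$ppm_error)))
  }
})

test_that("benchmark masses enumerate uniquely to the reported compositions", {
  b <- pch_benchmark()$expected
  # documented wide setting covers all rows, including the two >5 ppm ones
  for (i in seq_len(nrow(b))) {
    r <- enumerate_compositions(b$mz[i], enum_config(ms1_tol_ppm = 10))
    expect_equal(nrow(r), 1L, label = sprintf("peak %d", b$peak_no[i]))
    expect_equal(c(r$n_hex, r$n_pent), c(b$n_hex[i], b$n_pent[i]))
  }
  # the tight default covers all but the two reported outliers (-5.33, -8.48)
  hit5 <- vapply(b$mz, function(m) nrow(enumerate_compositions(m, enum_config())), 0L)
  expect_equal(sum(hit5 == 1L), 42L)
  expect_equal(b$peak_no[hit5 == 0L], c(34L, 38L))
})

test_that("classification splits hexose-only / pentose-only / mixed", {
  expect_equal(classify_composition(3, 0), "FOS")
  expect_equal(classify_composition(0, 4), "AOS")
  expect_equal(classify_composition(1, 3), "MIXED")
  expect_equal(classify_composition(c(2, 0, 5), c(0, 2, 5)),
               c("FOS", "AOS", "MIXED"))
  expect_error(classify_composition(1, 0), "polymerization")
})

test_that("display names follow field conventions", {
  expect_equal(composition_name(5, 0), "1F-fructofuranosyl nystose")
  expect_equal(composition_name(0, 6), "arabinohexaose")
  expect_equal(composition_name(2, 1), "2Fru:1Ara")
  expect_equal(composition_name(1, 3), "3Ara:1Fru")
  expect_equal(composition_name(8, 0), "fructo-oligosaccharide DP8/GF7")
  expect_equal(composition_name(12, 0), "fructo-oligosaccharide DP12/GF11")
  # ambiguous palette: no residue identity can be assumed for mixed species
  p <- monosaccharide_palette(c("Glc", "Gal"), c("Ara", "Xyl"))
  expect_equal(composition_name(2, 1, p), "hex2pent1")
})

test_that("palettes reject overlapping member sets", {
  expect_error(monosaccharide_palette(c("Fru", "Ara"), "Ara"), "disjoint")
})

test_that("inclusion list covers the DP/scan-range lattice without duplicates", {
  incl <- build_inclusion_list(enum_config())
  expect_false(any(duplicated(incl[, c("n_hex", "n_pent")])))
  expect_false(is.unsorted(incl$mz))
  expect_true(all(incl$mz >= 150 & incl$mz <= 2000))

  hex_only <- incl[incl$n_pent == 0L, ]
  expect_equal(hex_only$dp, 2:12)  # DP12 at ~1961.64 still inside the range
  expect_equal(round_mz(incl$mz[incl$n_hex == 4 & incl$n_pent == 0], 4), 665.2146)

  # a hexose DP13 target (~2123.69) would exceed the scan range
  wide <- build_inclusion_list(enum_config(dp_max = 13))
  expect_false(any(wide$n_hex == 13 & wide$n_pent == 0))

  # every benchmark composition is a PRM target
  b <- pch_benchmark()$expected
  expect_true(all(paste(b$n_hex, b$n_pent) %in% paste(incl$n_hex, incl$n_pent)))
})
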