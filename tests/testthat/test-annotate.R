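test_that("intensity screen is strictly greater-than and order-preserving", {
  f <- data.frame(rt_min = 1:3, mz = c(500, 600, 700),
                  intensity = c(5000, 10000, 10001))
  kept <- intensity_filter(f, 10000)
  expect_equal(kept$intensity, 10001)
  expect_equal(nrow(intensity_filter(f, 0)), 3L)
  expect_equal(nrow(intensity_filter(f[0, ], 10000)), 0L)
})

test_that("a full reported DP6 spectrum matches 11 rungs with a 5-loss chain", {
  sp <- ms2_spectrum(989.3172, DP6_REPORTED_FRAGMENTS,
                     rev(seq_along(DP6_REPORTED_FRAGMENTS)))
  m <- match_spectrum(sp, predict_ladder(6, 0), ms2_tol_ppm = 10)
  expect_equal(m$matched, 11L)
  expect_equal(m$total, 12L)  # the precursor's own water loss went unobserved
  expect_equal(m$chain, 5L)
  expect_true(all(abs(m$deviations$ppm) < 10))
})

test_that("empty and sparse spectra match as expected", {
  lad <- predict_ladder(3, 0)
  m0 <- match_spectrum(ms2_spectrum(503.1618, numeric(0), numeric(0)), lad)
  expect_equal(m0$matched, 0L)
  expect_equal(m0$coverage, 0)

  m1 <- match_spectrum(ms2_spectrum(503.1618, 341.1089, 100), lad)
  expect_equal(m1$matched, 1L)
  expect_equal(m1$chain, 1L)
})

test_that("peak-to-rung pairing is one-to-one, nearest ppm first", {
  lad <- predict_ladder(3, 0)
  # two peaks near the same rung: only one may claim it, the closer one
  sp <- ms2_spectrum(503.1618, c(341.1086, 341.1090), c(10, 10))
  m <- match_spectrum(sp, lad)
  expect_equal(m$matched, 1L)
  expect_equal(m$deviations$peak_mz, 341.1090)
})

test_that("positive-polarity spectra are rejected", {
  sp <- ms2_spectrum(503.1618, 341.1089, 1, polarity = "positive")
  expect_error(match_spectrum(sp, predict_ladder(3, 0)), "negative")
})

test_that("MSI levels follow the standards/MS2 evidence hierarchy", {
  strong <- match_spectrum(
    ms2_spectrum(989.3172, DP6_REPORTED_FRAGMENTS, rep(1, 11)),
    predict_ladder(6, 0))
  weak <- match_spectrum(ms2_spectrum(503.1618, 341.1089, 1), predict_ladder(3, 0))
  expect_equal(assign_msi_level(TRUE, strong), 1L)
  expect_equal(assign_msi_level(FALSE, strong), 3L)
  expect_equal(assign_msi_level(FALSE, weak), 4L)    # one rung is not a ladder
  expect_equal(assign_msi_level(FALSE, NULL), 4L)
  expect_equal(assign_msi_level(TRUE, NULL), 1L)
  expect_error(assign_msi_level(FALSE, NULL, min_rungs = 0), "min_rungs")
})

test_that("evidence can only raise a feature's confidence", {
  std <- standards_table("nystose", 4, 0, 22.73)
  sp <- ms2_spectrum(665.2129, round_mz(dfi_set(4, 0), 4), rep(1, 8))
  base <- annotate_feature(22.73, 665.2129)
  with_ms2 <- annotate_feature(22.73, 665.2129, spectrum = sp)
  with_std <- annotate_feature(22.73, 665.2129, spectrum = sp, standards = std)
  expect_equal(base$msi_level[1], 4L)
  expect_equal(with_ms2$msi_level[1], 3L)
  expect_equal(with_std$msi_level[1], 1L)
  expect_equal(with_std$name[1], "nystose")
})

test_that("retention time separates a standard from its isomers", {
  std <- standards_table("nystose", 4, 0, 22.73)
  sp <- ms2_spectrum(665.2130, round_mz(dfi_set(4, 0), 4), rep(1, 8))
  iso <- annotate_feature(22.16, 665.2130, spectrum = sp, standards = std)
  expect_equal(iso$msi_level[1], 3L)
  expect_equal(iso$name[1], "nystose")  # suffixing happens at series assembly
})

test_that("MS1-only mixed composition lands at Level 4 with a ratio name", {
  cand <- annotate_feature(14.06, 473.1493)
  expect_equal(cand$name[1], "2Fru:1Ara")
  expect_equal(cand$class[1], "MIXED")
  expect_equal(cand$msi_level[1], 4L)
})

test_that("isomer series keep the canonical name on the Level-1 member", {
  sp4 <- lapply(c(503.1604, 503.1603, 503.1603, 503.1602), function(p)
    ms2_spectrum(p, round_mz(dfi_set(3, 0), 4), rep(1, 6)))
  names(sp4) <- paste0("s", 1:4)
  features <- data.frame(
    feature_id = paste0("f", 1:4),
    rt_min = c(18.38, 20.76, 21.16, 21.73),
    mz = c(503.1604, 503.1603, 503.1603, 503.1602),
    intensity = 1e5, ms2_id = paste0("s", 1:4)
  )
  std <- standards_table("1-kestose", 3, 0, 21.16)
  ann <- annotate_features(features, sp4, standards = std)
  expect_equal(sort(ann$name),
               sort(c("1-kestose", rep("1-kestose isomer", 3))))
  expect_equal(ann$name[ann$rt_min == 21.16], "1-kestose")
  expect_equal(ann$peak_no, 1:4)  # numbered by elution order
})

test_that("groups without a standard keep the plain series name", {
  features <- data.frame(rt_min = c(21.43, 21.95), mz = c(809.2546, 809.2551),
                         intensity = 1e5)
  ann <- annotate_features(features)
  expect_equal(ann$name, rep("arabinohexaose", 2))
})

test_that("peak numbering breaks retention ties by m/z", {
  features <- data.frame(rt_min = c(22.16, 22.16), mz = c(665.2130, 575.1813),
                         intensity = 1e5)
  ann <- annotate_features(features)
  expect_equal(ann$experimental_mz, c(575.1813, 665.2130))
  expect_equal(ann$peak_no, 1:2)
})

test_that("annotation is deterministic and reports unannotatable features", {
  features <- data.frame(rt_min = c(10, 11), mz = c(413.1289, 333.3333),
                         intensity = c(2e4, 2e4))
  a1 <- annotate_features(features)
  a2 <- annotate_features(features)
  expect_identical(a1, a2)
  expect_equal(a1$composition[a1$experimental_mz == 413.1289], "Pent3")
  expect_true(is.na(a1$composition[a1$experimental_mz == 333.3333]))
})
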