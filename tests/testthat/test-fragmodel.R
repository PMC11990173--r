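test_that("pure-hexose ladders step by one residue with water companions", {
  lad <- predict_ladder(3, 0)
  expect_equal(round_mz(lad$y_mz, 4), c(503.1618, 341.1089, 179.0561))
  expect_equal(round_mz(lad$y_minus_water_mz, 4), c(485.1512, 323.0984, 161.0455))
  k <- mass_constants()
  expect_true(all(abs(diff(lad$y_mz) + k$hexose_residue) < 1e-6))
  expect_true(all(abs(lad$y_mz - lad$y_minus_water_mz - k$water) < 1e-6))
  # reported experimental counterparts sit within 10 ppm of the model
  reported <- c(485.1516, 323.0985, 179.0553, 161.0446)
  theo <- c(485.1512, 323.0984, 179.0561, 161.0455)
  expect_true(all(abs((reported - theo) / theo * 1e6) < 10))
})

test_that("the smallest ladder (DP2 hexose) has two rungs", {
  lad <- predict_ladder(2, 0)
  expect_equal(round_mz(lad$y_mz, 4), c(341.1089, 179.0561))
  expect_equal(nrow(lad), 2L)
  expect_error(predict_ladder(1, 0), "polymerization")
})

test_that("pentose ladders lose 132.0423 per step", {
  lad <- predict_ladder(0, 4)
  expect_equal(round_mz(lad$y_mz[1], 4), 545.1723)
  expect_equal(round_mz(lad$y_mz[2], 4), 413.1301)
  expect_true(all(abs(diff(lad$y_mz) + mass_constants()$pentose_residue) < 1e-6))
})

test_that("mixed ladders branch over both residue classes", {
  lad <- predict_ladder(1, 3)
  # two pentose losses from the precursor: 575.1829 - 2 x 132.042259
  expect_true(any(abs(lad$y_mz - 311.0983) < 1e-3))
  got <- lad$y_mz[which.min(abs(lad$y_mz - 311.0983))]
  expect_lt(abs((311.0977 - got) / got * 1e6), 10)  # reported value, 10 ppm
  # rung count: every remaining multiset, (a+1)(b+1)-1
  for (a in 0:3) for (b in 0:3) {
    if (a + b < 2) next
    expect_equal(nrow(predict_ladder(a, b)), (a + 1) * (b + 1) - 1,
                 label = sprintf("(%d,%d)", a, b))
  }
})

test_that("ladders terminate at the monosaccharide and telescope exactly", {
  for (comp in list(c(6, 0), c(0, 5), c(2, 2))) {
    lad <- predict_ladder(comp[1], comp[2])
    expect_equal(min(lad$dp_remain), 1L)
    expect_true(all(lad$y_mz > 0))
    k <- mass_constants()
    # precursor minus terminal equals the residues in between
    for (i in seq_len(nrow(lad))) {
      lost <- (comp[1] - lad$n_hex_remain[i]) * k$hexose_residue +
        (comp[2] - lad$n_pent_remain[i]) * k$pentose_residue
      expect_lt(abs(lad$y_mz[1] - lad$y_mz[i] - lost), 1e-6)
    }
  }
})

test_that("the DFI set of a hexose-only DP n composition has 2n values", {
  for (n in 2:8) expect_length(dfi_set(n, 0), 2L * n)
})

test_that("neutral-loss decomposition labels the reported losses", {
  expect_equal(neutral_loss_decomposition(503.1618, 341.1089), "hexose")
  expect_equal(neutral_loss_decomposition(341.1089, 323.0984), "water")
  expect_equal(neutral_loss_decomposition(575.1829, 311.0983), "2xpentose")
  expect_equal(neutral_loss_decomposition(503.1618, 323.0984), "hexose+water")
  expect_equal(neutral_loss_decomposition(503.1618, 400.0), "none")
  expect_error(neutral_loss_decomposition(300, 400), "exceed")
})

test_that("consecutive hexose ladder rungs round-trip through loss decomposition", {
  for (n in 3:8) {
    lad <- predict_ladder(n, 0)
    labels <- mapply(neutral_loss_decomposition,
                     lad$y_mz[-nrow(lad)], lad$y_mz[-1])
    expect_true(all(labels == "hexose"), label = sprintf("DP%d", n))
  }
})
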