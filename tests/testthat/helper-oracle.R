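# Independent oracles, kept separate from the package's own code paths.

# element masses written out as literals (CODATA/AME monoisotopic values)
ORACLE_HEXOSE <- 6 * 12 + 10 * 1.007825032 + 5 * 15.994914620
ORACLE_PENTOSE <- 5 * 12 + 8 * 1.007825032 + 4 * 15.994914620
ORACLE_WATER <- 2 * 1.007825032 + 15.994914620
ORACLE_PROTON <- 1.007276466

# brute-force composition search: a plain double loop over residue counts,
# with the DP window applied explicitly
oracle_enumerate <- function(mz, tol_ppm, dp_min = 2, dp_max = 12,
                             a_max = 13, b_max = 16) {
  hits <- list()
  for (a in 0:a_max) {
    for (b in 0:b_max) {
      dp <- a + b
      if (dp < dp_min || dp > dp_max) next
      theo <- a * ORACLE_HEXOSE + b * ORACLE_PENTOSE + ORACLE_WATER - ORACLE_PROTON
      if (abs((mz - theo) / theo * 1e6) <= tol_ppm) {
        hits[[length(hits) + 1]] <- c(a, b)
      }
    }
  }
  if (!length(hits)) return(data.frame(n_hex = integer(0), n_pent = integer(0)))
  m <- do.call(rbind, hits)
  data.frame(n_hex = m[, 1], n_pent = m[, 2])
}

# neutral monoisotopic masses computed with an external mass calculator
# (pyteomics 5.0.1), frozen here
PYTEOMICS_NEUTRAL <- c(
  "H2O" = 18.0105647,
  "C18H32O16" = 504.1690349,
  "C15H26O13" = 414.1373409,
  "C17H30O15" = 474.1584703,
  "C30H52O26" = 828.2746818,
  "C24H42O21" = 666.2218584,
  "C42H72O36" = 1152.3803286,
  "C30H50O25" = 810.2641171,
  "C48H82O41" = 1314.4331520,
  "C20H34O17" = 546.1795996,
  "C21H36O18" = 576.1901643,
  "C54H92O46" = 1476.4859755,
  "C60H102O51" = 1638.5387989,
  "C66H112O56" = 1800.5916223,
  "C72H122O61" = 1962.6444457,
  "C36H62O31" = 990.3275052,
  "C6H12O6" = 180.0633881,
  "C12H22O11" = 342.1162115
)

# reported theoretical masses that are true 4-decimal roundings of the
# computed values (the remaining four reported values are truncations)
ROUND_EXACT_FORMULAS <- c(
  "C17H30O15" = 473.1512, "C15H26O13" = 413.1301, "C30H52O26" = 827.2674,
  "C18H32O16" = 503.1618, "C30H50O25" = 809.2568, "C20H34O17" = 545.1723,
  "C24H42O21" = 665.2146, "C54H92O46" = 1475.4787, "C60H102O51" = 1637.5315,
  "C66H112O56" = 1799.5843, "C36H62O31" = 989.3202
)

# the 11 fragment m/z values reported for the DP6 fructan standard:
# precursor, five sequential hexose losses, five water-loss companions
DP6_REPORTED_FRAGMENTS <- c(
  989.3172,
  827.2651, 665.2156, 503.1620, 341.1084, 179.0550,
  809.2600, 647.2039, 485.1523, 323.0978, 161.0443
)
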