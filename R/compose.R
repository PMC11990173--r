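# Composition enumeration under palette constraints, series classification,
# field-standard display names, and PRM inclusion-list generation.

#' Monosaccharide palette
#'
#' Records which hexoses and pentoses the sample can contain, typically the
#' result of a monosaccharide-composition analysis (e.g. ion chromatography
#' after acid hydrolysis). MS1/MS2 masses cannot distinguish isomeric
#' monosaccharides, so the palette is what licenses naming a hexose-only
#' composition a fructo-oligosaccharide or a pentose-only one an
#' arabino-oligosaccharide.
#'
#' `hexose_label`/`pentose_label` give the residue identity assumed when
#' naming compositions (e.g. `"Fru"` when fructans dominate the hexose pool,
#' `"Ara"` when arabinose is the only pentose detected). A `NULL` label makes
#' [composition_name()] fall back to neutral `hex<i>pent<j>` naming for mixed
#' species.
#'
#' @param hexoses,pentoses Character vectors of monosaccharide names; must be
#'   disjoint.
#' @param hexose_label,pentose_label Single residue names used in display
#'   names, or `NULL` when no single identity can be assumed.
#' @param note Free-text provenance, e.g. `"IC monosaccharide analysis"`.
#' @return An object of class `monosaccharide_palette`.
#' @examples
#' default_palette()
#' @export
monosaccharide_palette <- function(hexoses, pentoses,
                                   hexose_label = if (length(hexoses) == 1) hexoses else NULL,
                                   pentose_label = if (length(pentoses) == 1) pentoses else NULL,
                                   note = "") {
  hexoses <- as.character(hexoses)
  pentoses <- as.character(pentoses)
  if (length(intersect(hexoses, pentoses))) {
    stop("hexose and pentose palettes must be disjoint", call. = FALSE)
  }
  structure(
    list(hexoses = hexoses, pentoses = pentoses,
         hexose_label = hexose_label, pentose_label = pentose_label,
         note = note),
    class = "monosaccharide_palette"
  )
}

#' Default palette: a fructan-dominated plant oligosaccharide pool
#'
#' Hexoses fructose, glucose, galactose and mannose; arabinose as the sole
#' pentose. Hexose-only series are named as fructo-oligosaccharides on the
#' assumption (recorded in the palette labels) that the hexose chains are
#' fructans with a terminal glucose, which mass spectra alone cannot prove;
#' annotations carry this as palette-assumed evidence.
#'
#' @return A `monosaccharide_palette`.
#' @export
default_palette <- function() {
  monosaccharide_palette(
    hexoses = c("Fru", "Glc", "Gal", "Man"),
    pentoses = "Ara",
    hexose_label = "Fru",
    pentose_label = "Ara",
    note = "IC monosaccharide analysis; GlcN detected but amino sugars are outside the hexose/pentose composition model"
  )
}

#' @export
print.monosaccharide_palette <- function(x, ...) {
  cat("Monosaccharide palette\n")
  cat("  hexoses: ", paste(x$hexoses, collapse = ", "),
      if (!is.null(x$hexose_label)) sprintf(" (named as %s)", x$hexose_label),
      "\n", sep = "")
  cat("  pentoses:", paste(x$pentoses, collapse = ", "),
      if (!is.null(x$pentose_label)) sprintf(" (named as %s)", x$pentose_label),
      "\n")
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Enumeration configuration
#'
#' @param dp_min,dp_max Degree-of-polymerization bounds (defaults 2 and 12).
#' @param ms1_tol_ppm Precursor mass tolerance in ppm (default 5).
#' @param scan_mz_min,scan_mz_max Instrument scan range (default m/z
#'   150-2000, the acquisition range of the reference method).
#' @return A list of class `enum_config`.
#' @export
enum_config <- function(dp_min = 2L, dp_max = 12L, ms1_tol_ppm = 5,
                        scan_mz_min = 150, scan_mz_max = 2000) {
  dp_min <- as.integer(dp_min); dp_max <- as.integer(dp_max)
  if (dp_min < 2L) stop("dp_min must be >= 2", call. = FALSE)
  if (dp_max < dp_min) stop("dp_max must be >= dp_min", call. = FALSE)
  if (ms1_tol_ppm <= 0) stop("ms1_tol_ppm must be > 0", call. = FALSE)
  if (scan_mz_max <= scan_mz_min) stop("invalid scan range", call. = FALSE)
  structure(list(dp_min = dp_min, dp_max = dp_max, ms1_tol_ppm = ms1_tol_ppm,
                 scan_mz_min = scan_mz_min, scan_mz_max = scan_mz_max),
            class = "enum_config")
}

# all (n_hex, n_pent) grid points inside the DP bounds
composition_grid <- function(cfg) {
  g <- expand.grid(n_hex = 0:cfg$dp_max, n_pent = 0:cfg$dp_max)
  g <- g[g$n_hex + g$n_pent >= cfg$dp_min & g$n_hex + g$n_pent <= cfg$dp_max, ]
  g$dp <- g$n_hex + g$n_pent
  g
}

#' Enumerate residue compositions matching an observed precursor m/z
#'
#' Searches all hexose/pentose residue compositions with
#' `dp_min <= DP <= dp_max` whose deprotonated theoretical m/z lies within
#' `ms1_tol_ppm` of the observed value.
#'
#' @param observed_mz Observed [M - H]- m/z (single positive number).
#' @param cfg An [enum_config()].
#' @return A data.frame with columns `n_hex`, `n_pent`, `dp`, `formula`,
#'   `theoretical_mz`, `ppm_error`, sorted by |ppm| ascending, ties broken
#'   by smaller `n_pent` then smaller `dp`. Zero rows when nothing matches.
#' @examples
#' enumerate_compositions(503.1604, enum_config())  # 3 hexoses (DP3 FOS)
#' @export
enumerate_compositions <- function(observed_mz, cfg = enum_config()) {
  if (!is.numeric(observed_mz) || length(observed_mz) != 1L || observed_mz <= 0) {
    stop("observed_mz must be a single positive number", call. = FALSE)
  }
  g <- composition_grid(cfg)
  theo <- composition_mz(g$n_hex, g$n_pent)
  ppm <- (observed_mz - theo) / theo * 1e6
  keep <- abs(ppm) <= cfg$ms1_tol_ppm
  out <- data.frame(
    n_hex = g$n_hex[keep], n_pent = g$n_pent[keep], dp = g$dp[keep],
    theoretical_mz = theo[keep], ppm_error = ppm[keep]
  )
  out <- out[order(abs(out$ppm_error), out$n_pent, out$dp), , drop = FALSE]
  out$formula <- if (nrow(out)) composition_formula(out$n_hex, out$n_pent) else character(0)
  rownames(out) <- NULL
  out[, c("n_hex", "n_pent", "dp", "formula", "theoretical_mz", "ppm_error")]
}

#' Classify a residue composition into FOS / AOS / MIXED
#'
#' Hexose-only compositions are labelled `"FOS"` (fructo-oligosaccharide,
#' a palette-level assumption), pentose-only `"AOS"`
#' (arabino-oligosaccharide), and everything else `"MIXED"`. Vectorized.
#'
#' @inheritParams residue_composition
#' @param palette A [monosaccharide_palette()]; recorded for the naming
#'   assumption but not needed for the class split itself.
#' @return Character vector in `c("FOS", "AOS", "MIXED")`.
#' @export
classify_composition <- function(n_hex, n_pent, palette = default_palette()) {
  rc <- residue_composition(n_hex, n_pent)
  ifelse(rc$n_pent == 0L, "FOS", ifelse(rc$n_hex == 0L, "AOS", "MIXED"))
}

# canonical fructan names for low DP; beyond DP7 the literature uses DPn/GF(n-1)
.fos_names <- c(
  "2" = "sucrose",
  "3" = "1-kestose",
  "4" = "nystose",
  "5" = "1F-fructofuranosyl nystose",
  "6" = "1,1,1,1-kestohexaose",
  "7" = "fructoheptasaccharide"
)

.aos_greek <- c(
  "2" = "arabinobiose", "3" = "arabinotriose", "4" = "arabinotetraose",
  "5" = "arabinopentaose", "6" = "arabinohexaose", "7" = "arabinoheptaose",
  "8" = "arabinooctaose", "9" = "arabinononaose", "10" = "arabinodecaose",
  "11" = "arabinoundecaose", "12" = "arabinododecaose"
)

#' Display name for a residue composition
#'
#' Hexose-only series get the canonical fructan names up to DP7 and
#' `"fructo-oligosaccharide DP<n>/GF<n-1>"` beyond; pentose-only series get
#' arabino-oligosaccharide names (`arabinotriose`, ...); mixed series are
#' named by residue ratio using the palette labels, larger count first
#' (e.g. `"2Fru:1Ara"`, `"3Ara:1Fru"`). When a palette label is missing the
#' mixed name falls back to `"hex<i>pent<j>"`, since the residue identities
#' cannot be resolved from mass alone.
#'
#' @inheritParams classify_composition
#' @return Character vector of names.
#' @examples
#' composition_name(4, 0)  # "nystose"
#' composition_name(1, 3)  # "3Ara:1Fru"
#' @export
composition_name <- function(n_hex, n_pent, palette = default_palette()) {
  rc <- residue_composition(n_hex, n_pent)
  cls <- classify_composition(rc$n_hex, rc$n_pent, palette)
  out <- character(nrow(rc))
  for (i in seq_len(nrow(rc))) {
    dp <- rc$dp[i]
    out[i] <- switch(cls[i],
      FOS = if (dp <= 7L) .fos_names[[as.character(dp)]]
            else sprintf("fructo-oligosaccharide DP%d/GF%d", dp, dp - 1L),
      AOS = if (dp <= 12L) .aos_greek[[as.character(dp)]]
            else sprintf("arabino-oligosaccharide DP%d", dp),
      MIXED = {
        hl <- palette$hexose_label; pl <- palette$pentose_label
        if (is.null(hl) || is.null(pl)) {
          sprintf("hex%dpent%d", rc$n_hex[i], rc$n_pent[i])
        } else {
          hx <- sprintf("%d%s", rc$n_hex[i], hl)
          pt <- sprintf("%d%s", rc$n_pent[i], pl)
          # dominant residue first, hexose first on ties
          if (rc$n_pent[i] > rc$n_hex[i]) paste(pt, hx, sep = ":")
          else paste(hx, pt, sep = ":")
        }
      }
    )
  }
  out
}

#' Build a PRM inclusion list from molecular predictions
#'
#' Enumerates every hexose/pentose composition in the DP range whose
#' [M - H]- falls inside the instrument scan range and returns it as a
#' parallel-reaction-monitoring target list, sorted by m/z.
#'
#' @param cfg An [enum_config()].
#' @param palette A [monosaccharide_palette()] used for class labels and
#'   display names.
#' @return A data.frame with columns `n_hex`, `n_pent`, `dp`, `formula`,
#'   `mz`, `charge` (always `"1-"`), `class`, `name`.
#' @export
build_inclusion_list <- function(cfg = enum_config(), palette = default_palette()) {
  g <- composition_grid(cfg)
  mz <- composition_mz(g$n_hex, g$n_pent)
  keep <- mz >= cfg$scan_mz_min & mz <= cfg$scan_mz_max
  g <- g[keep, , drop = FALSE]; mz <- mz[keep]
  ord <- order(mz)
  g <- g[ord, , drop = FALSE]; mz <- mz[ord]
  data.frame(
    n_hex = g$n_hex, n_pent = g$n_pent, dp = g$dp,
    formula = composition_formula(g$n_hex, g$n_pent),
    mz = mz, charge = "1-",
    class = classify_composition(g$n_hex, g$n_pent, palette),
    name = composition_name(g$n_hex, g$n_pent, palette),
    row.names = NULL
  )
}
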