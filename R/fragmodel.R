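# Y-ion neutral-loss fragment ladders. Negative-mode CID of underivatized
# oligosaccharides proceeds almost entirely by glycosidic cleavage: the
# deprotonated precursor loses dehydrated residues (hexose 162.0528 Da,
# pentose 132.0423 Da) one at a time, and every Y ion has a water-loss
# companion 18.0106 Da below it. Cross-ring fragments are not modeled.

#' Predict the diagnostic Y-ion ladder for a residue composition
#'
#' Rung 0 is the deprotonated precursor. For single-class compositions the
#' ladder is linear; for mixed compositions a loss of either residue class is
#' allowed at every step, so one rung is generated for every distinct
#' multiset of remaining residues (`(a+1)(b+1) - 1` rungs for composition
#' `(a, b)` before m/z deduplication). The ladder terminates at the
#' deprotonated monosaccharides; rungs are never extended below one residue.
#'
#' @inheritParams residue_composition
#' @return An object of class `fragment_ladder`: a data.frame with columns
#'   `n_hex_remain`, `n_pent_remain`, `dp_remain`, `y_mz`,
#'   `y_minus_water_mz`, `is_precursor`, sorted by decreasing `y_mz`, with
#'   the parent composition in attributes `n_hex`/`n_pent`.
#' @examples
#' predict_ladder(3, 0)  # sucrose-type DP3 ladder: 503.16 / 341.11 / 179.06
#' @export
predict_ladder <- function(n_hex, n_pent) {
  rc <- residue_composition(n_hex, n_pent)
  if (nrow(rc) != 1L) stop("predict_ladder takes a single composition", call. = FALSE)
  a <- rc$n_hex; b <- rc$n_pent
  g <- expand.grid(n_hex_remain = 0:a, n_pent_remain = 0:b)
  g <- g[g$n_hex_remain + g$n_pent_remain >= 1L, , drop = FALSE]
  k <- mass_constants()
  y <- g$n_hex_remain * k$hexose_residue + g$n_pent_remain * k$pentose_residue +
    k$water - k$proton
  out <- data.frame(
    n_hex_remain = g$n_hex_remain,
    n_pent_remain = g$n_pent_remain,
    dp_remain = g$n_hex_remain + g$n_pent_remain,
    y_mz = unname(y),
    y_minus_water_mz = unname(y - k$water),
    is_precursor = g$n_hex_remain == a & g$n_pent_remain == b
  )
  # distinct multisets never collide in mass for this residue pair, but the
  # contract is dedup-by-m/z, so enforce it
  out <- out[!duplicated(round(out$y_mz, 6)), , drop = FALSE]
  out <- out[order(-out$y_mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_hex = a, n_pent = b, class = c("fragment_ladder", "data.frame"))
}

#' Diagnostic fragment-ion set of a composition
#'
#' All ladder m/z values (Y ions including the precursor, plus water-loss
#' companions), deduplicated and sorted. A hexose-only DP-n composition
#' yields exactly 2n values.
#'
#' @inheritParams residue_composition
#' @return Sorted numeric vector of m/z values.
#' @export
dfi_set <- function(n_hex, n_pent) {
  lad <- predict_ladder(n_hex, n_pent)
  v <- sort(c(lad$y_mz, lad$y_minus_water_mz))
  v[!c(FALSE, diff(v) < 1e-6)]
}

# candidate neutral losses, in Da, built from the residue/water constants
neutral_loss_table <- function() {
  k <- mass_constants()
  c(
    "water" = unname(k$water),
    "pentose" = unname(k$pentose_residue),
    "hexose" = unname(k$hexose_residue),
    "pentose+water" = unname(k$pentose_residue + k$water),
    "hexose+water" = unname(k$hexose_residue + k$water),
    "2xpentose" = unname(2 * k$pentose_residue),
    "pentose+hexose" = unname(k$pentose_residue + k$hexose_residue),
    "2xhexose" = unname(2 * k$hexose_residue)
  )
}

#' Identify the neutral loss between a parent and a child ion
#'
#' Matches `parent_mz - child_mz` against water, single-residue and
#' two-step losses (e.g. hexose+water = 180.0634 Da, the loss of an intact
#' hexose monosaccharide).
#'
#' @param parent_mz,child_mz m/z values with `parent_mz > child_mz`.
#' @param tol_ppm Tolerance in ppm, converted to an absolute window at the
#'   parent m/z (default 10).
#' @return The loss label (`"water"`, `"hexose"`, `"pentose"`,
#'   `"hexose+water"`, `"pentose+water"`, `"2xhexose"`, `"2xpentose"`,
#'   `"pentose+hexose"`) or `"none"`.
#' @examples
#' neutral_loss_decomposition(503.1618, 341.1089)  # "hexose"
#' @export
neutral_loss_decomposition <- function(parent_mz, child_mz, tol_ppm = 10) {
  if (parent_mz <= child_mz) stop("parent_mz must exceed child_mz", call. = FALSE)
  losses <- neutral_loss_table()
  delta <- parent_mz - child_mz
  tol_da <- tol_ppm * 1e-6 * parent_mz
  dev <- abs(delta - losses)
  if (min(dev) <= tol_da) names(losses)[which.min(dev)] else "none"
}
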