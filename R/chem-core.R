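# Exact-mass arithmetic for elemental formulas and oligosaccharide residue
# compositions. All masses are monoisotopic, in Da, and kept at full double
# precision internally; rounding happens only at presentation time.

.element_masses <- c(
  C = 12,
  H = 1.007825032,
  O = 15.994914620,
  N = 14.003074005
)

.proton_mass <- 1.007276466

#' Monoisotopic mass constants
#'
#' Returns the physical constants used throughout the package: monoisotopic
#' element masses, the proton mass used for deprotonation, and the dehydrated
#' residue masses of a hexose (C6H10O5) and a pentose (C5H8O4) together with
#' water. Residue masses are derived from the element table, so the set is
#' internally consistent by construction.
#'
#' @return A named list with elements `elements` (named numeric vector),
#'   `proton`, `hexose_residue`, `pentose_residue` and `water` (Da).
#' @examples
#' mass_constants()$hexose_residue  # 162.0528 Da
#' @export
mass_constants <- function() {
  el <- .element_masses
  list(
    elements = el,
    proton = .proton_mass,
    hexose_residue = unname(6 * el["C"] + 10 * el["H"] + 5 * el["O"]),
    pentose_residue = unname(5 * el["C"] + 8 * el["H"] + 4 * el["O"]),
    water = unname(2 * el["H"] + el["O"])
  )
}

#' Parse a molecular formula in Hill notation
#'
#' Accepts formulas over C, H, O and N such as `"C18H32O16"`. An omitted
#' count means one atom. Repeated element symbols are summed.
#'
#' @param text A single formula string.
#' @return A named integer vector of element counts, in Hill order
#'   (C first, then H, then remaining elements alphabetically).
#' @examples
#' parse_formula("C18H32O16")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula '", text, "': unexpected characters", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Z][a-z]?", "", tokens)
  bad <- setdiff(syms, names(.element_masses))
  if (length(bad)) {
    stop("unknown element symbol '", bad[1], "' in formula '", text, "'",
         call. = FALSE)
  }
  counts <- ifelse(nzchar(cnts), as.integer(cnts), 1L)
  out <- tapply(counts, syms, sum)
  out <- stats::setNames(as.integer(out), names(out))
  hill_order(out)
}

# Hill order: C, H, then alphabetical; zero counts dropped.
hill_order <- function(counts) {
  counts <- counts[counts > 0]
  rest <- sort(setdiff(names(counts), c("C", "H")))
  ord <- intersect(c("C", "H", rest), names(counts))
  counts[ord]
}

#' Format element counts as a canonical Hill-order formula string
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return A single string, e.g. `"C18H32O16"`; count 1 is omitted.
#' @export
format_formula <- function(counts) {
  counts <- hill_order(counts)
  if (!length(counts)) stop("empty formula", call. = FALSE)
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

as_formula_counts <- function(f) {
  if (is.character(f)) parse_formula(f) else hill_order(f)
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' @param f Formula string or named count vector.
#' @return Mass in Da (full double precision).
#' @examples
#' neutral_monoisotopic_mass("H2O")  # 18.010565
#' @export
neutral_monoisotopic_mass <- function(f) {
  counts <- as_formula_counts(f)
  if (!length(counts)) stop("cannot compute the mass of an empty formula",
                            call. = FALSE)
  sum(counts * .element_masses[names(counts)])
}

#' m/z of the deprotonated ion [M - H]-
#'
#' Negative-ESI convention: the neutral mass minus the mass of a proton
#' (1.007276466 Da), i.e. the molecule loses H+ and keeps its electrons.
#'
#' @param f Formula string or named count vector; must contain hydrogen.
#' @return m/z of the singly deprotonated species.
#' @examples
#' deprotonated_mz("C18H32O16")  # 503.1618 (1-kestose and isomers)
#' @export
deprotonated_mz <- function(f) {
  counts <- as_formula_counts(f)
  if (is.na(counts["H"]) || counts["H"] < 1L) {
    stop("formula has no hydrogen: cannot deprotonate", call. = FALSE)
  }
  neutral_monoisotopic_mass(counts) - .proton_mass
}

#' Relative mass error in parts per million
#'
#' @param observed,theoretical m/z values (theoretical must be > 0).
#' @return `(observed - theoretical) / theoretical * 1e6`, vectorized.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0", call. = FALSE)
  (observed - theoretical) / theoretical * 1e6
}

#' Residue composition of an oligosaccharide
#'
#' An oligosaccharide chain of `n_hex` hexose residues (C6H10O5) and
#' `n_pent` pentose residues (C5H8O4) plus one water for the intact
#' (non-dehydrated) molecule. The degree of polymerization
#' DP = `n_hex + n_pent` must be at least 2.
#'
#' @param n_hex,n_pent Non-negative integer residue counts (vectorized,
#'   recycled to a common length).
#' @return A data.frame with columns `n_hex`, `n_pent`, `dp`.
#' @export
residue_composition <- function(n_hex, n_pent) {
  n <- max(length(n_hex), length(n_pent))
  n_hex <- as.integer(rep_len(n_hex, n))
  n_pent <- as.integer(rep_len(n_pent, n))
  if (any(is.na(n_hex)) || any(is.na(n_pent)) ||
      any(n_hex < 0L) || any(n_pent < 0L)) {
    stop("residue counts must be non-negative integers", call. = FALSE)
  }
  dp <- n_hex + n_pent
  if (any(dp < 2L)) {
    stop("degree of polymerization must be >= 2 for an oligosaccharide",
         call. = FALSE)
  }
  data.frame(n_hex = n_hex, n_pent = n_pent, dp = dp)
}

#' Molecular formula of a residue composition
#'
#' The intact oligomer: `n_hex` dehydrated hexoses, `n_pent` dehydrated
#' pentoses, plus one water. C = 6h + 5p, H = 10h + 8p + 2, O = 5h + 4p + 1.
#'
#' @inheritParams residue_composition
#' @return Character vector of Hill-order formula strings.
#' @examples
#' composition_formula(3, 0)  # "C18H32O16"
#' composition_formula(2, 1)  # "C17H30O15"
#' @export
composition_formula <- function(n_hex, n_pent) {
  rc <- residue_composition(n_hex, n_pent)
  vapply(seq_len(nrow(rc)), function(i) {
    format_formula(c(
      C = 6L * rc$n_hex[i] + 5L * rc$n_pent[i],
      H = 10L * rc$n_hex[i] + 8L * rc$n_pent[i] + 2L,
      O = 5L * rc$n_hex[i] + 4L * rc$n_pent[i] + 1L
    ))
  }, character(1))
}

#' Neutral mass and deprotonated m/z of a residue composition
#'
#' @inheritParams residue_composition
#' @return Numeric vector of masses (Da) or m/z values.
#' @export
composition_neutral_mass <- function(n_hex, n_pent) {
  rc <- residue_composition(n_hex, n_pent)
  k <- mass_constants()
  unname(rc$n_hex * k$hexose_residue + rc$n_pent * k$pentose_residue + k$water)
}

#' @rdname composition_neutral_mass
#' @export
composition_mz <- function(n_hex, n_pent) {
  composition_neutral_mass(n_hex, n_pent) - .proton_mass
}

#' Decompose a molecular formula into hexose/pentose residue counts
#'
#' Inverts [composition_formula()]: solves the element counts for the unique
#' `(n_hex, n_pent)` pair and checks full consistency (including hydrogen and
#' the absence of other elements). Returns `NA` counts when the formula is
#' not an intact hexose/pentose oligomer.
#'
#' @param formula Formula string or named count vector (vectorized over a
#'   character vector).
#' @return A data.frame with columns `n_hex`, `n_pent`, `dp` (NA when the
#'   formula does not decompose).
#' @examples
#' formula_to_composition("C24H42O21")  # nystose: 4 hexoses
#' @export
formula_to_composition <- function(formula) {
  if (!is.character(formula)) formula <- format_formula(formula)
  one <- function(fs) {
    counts <- parse_formula(fs)
    C <- if (is.na(counts["C"])) 0L else counts["C"]
    H <- if (is.na(counts["H"])) 0L else counts["H"]
    O <- if (is.na(counts["O"])) 0L else counts["O"]
    extra <- setdiff(names(counts), c("C", "H", "O"))
    a <- 5L * (O - 1L) - 4L * C      # n_hex
    b <- 5L * C - 6L * (O - 1L)      # n_pent
    ok <- !length(extra) && a >= 0L && b >= 0L && a + b >= 2L &&
      H == 10L * a + 8L * b + 2L
    if (ok) c(a, b) else c(NA_integer_, NA_integer_)
  }
  ab <- t(vapply(formula, one, integer(2)))
  data.frame(n_hex = ab[, 1], n_pent = ab[, 2], dp = ab[, 1] + ab[, 2],
             row.names = NULL)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Presentation rounding for m/z tables (base `round` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 4).
#' @return Rounded numeric vector.
#' @export
round_mz <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
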