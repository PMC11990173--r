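# Spectrum-to-ladder matching, MSI confidence assignment, and isomer-series
# assembly: the annotation engine proper.

#' Construct an MS2 spectrum
#'
#' @param precursor_mz Precursor [M - H]- m/z.
#' @param mz,intensity Numeric vectors of centroided peaks (re-sorted by m/z
#'   on construction).
#' @param polarity `"negative"` (the only polarity the annotation engine
#'   accepts) or `"positive"`.
#' @param rt_min Optional retention time in minutes.
#' @return An object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(precursor_mz, mz, intensity = rep(1, length(mz)),
                         polarity = "negative", rt_min = NA_real_) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity lengths differ", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  polarity <- match.arg(polarity, c("negative", "positive"))
  ord <- order(mz)
  structure(
    list(precursor_mz = precursor_mz,
         peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
         polarity = polarity, rt_min = rt_min),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("MS2 spectrum: precursor m/z %.4f (%s), %d peaks\n",
              x$precursor_mz, x$polarity, nrow(x$peaks)))
  invisible(x)
}

#' Keep features above an intensity threshold
#'
#' Strictly-greater-than filter (a peak at exactly the threshold is
#' dropped); input order is preserved.
#'
#' @param features Data.frame with an `intensity` column.
#' @param threshold Minimum intensity, default 10000 (the screening cutoff
#'   used when selecting chromatographic peaks for identification).
#' @return The filtered data.frame.
#' @export
intensity_filter <- function(features, threshold = 10000) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  features[features$intensity > threshold, , drop = FALSE]
}

# per-rung absolute tolerance: ppm window with a Da floor for low m/z
.ms2_tol_da <- function(mz, tol_ppm, floor_da) {
  pmax(tol_ppm * 1e-6 * mz, floor_da)
}

#' Match an MS2 spectrum against a predicted fragment ladder
#'
#' Every ladder value (Y ions including the precursor, plus water-loss
#' companions) lying inside `[scan_mz_min, precursor]` is paired with at
#' most one observed peak; pairing is greedy by smallest |ppm| with
#' one-to-one assignment. The tolerance is `ms2_tol_ppm` with an absolute
#' floor of `mz_floor_da` (low-m/z ions carry fewer ppm per milli-Dalton).
#'
#' @param sp An [ms2_spectrum()] (must be negative polarity).
#' @param ladder A [predict_ladder()] result for the candidate composition.
#' @param ms2_tol_ppm Fragment tolerance in ppm (default 10).
#' @param mz_floor_da Absolute tolerance floor in Da (default 0.003).
#' @param scan_mz_min Lower end of the acquisition range; ladder values
#'   below it are excluded from the denominator (default 150).
#' @return A list of class `ladder_match`: `matched`, `total`, `coverage`,
#'   `chain` (longest run of consecutive single-loss Y fragments below the
#'   precursor), and `deviations`, a data.frame of per-match ppm errors.
#' @export
match_spectrum <- function(sp, ladder, ms2_tol_ppm = 10, mz_floor_da = 0.003,
                           scan_mz_min = 150) {
  stopifnot(inherits(sp, "ms2_spectrum"), inherits(ladder, "fragment_ladder"))
  if (sp$polarity != "negative") {
    stop("ladder matching is defined for negative-mode spectra", call. = FALSE)
  }
  rungs <- rbind(
    data.frame(kind = "Y", mz = ladder$y_mz, dp_remain = ladder$dp_remain,
               is_precursor = ladder$is_precursor),
    data.frame(kind = "Y-H2O", mz = ladder$y_minus_water_mz,
               dp_remain = ladder$dp_remain, is_precursor = FALSE)
  )
  hi <- sp$precursor_mz + .ms2_tol_da(sp$precursor_mz, ms2_tol_ppm, mz_floor_da)
  rungs <- rungs[rungs$mz >= scan_mz_min & rungs$mz <= hi, , drop = FALSE]
  rungs <- rungs[order(-rungs$mz), , drop = FALSE]
  total <- nrow(rungs)

  pk <- sp$peaks
  pairs <- NULL
  if (total && nrow(pk)) {
    tol <- .ms2_tol_da(rungs$mz, ms2_tol_ppm, mz_floor_da)
    idx <- lapply(seq_len(total), function(i) which(abs(pk$mz - rungs$mz[i]) <= tol[i]))
    n_each <- lengths(idx)
    if (sum(n_each)) {
      pairs <- data.frame(
        rung = rep(seq_len(total), n_each),
        peak = unlist(idx)
      )
      pairs$ppm <- (pk$mz[pairs$peak] - rungs$mz[pairs$rung]) /
        rungs$mz[pairs$rung] * 1e6
      pairs <- pairs[order(abs(pairs$ppm)), , drop = FALSE]
    }
  }

  rung_peak <- rep(NA_integer_, total)
  if (!is.null(pairs)) {
    peak_used <- rep(FALSE, nrow(pk))
    for (i in seq_len(nrow(pairs))) {
      r <- pairs$rung[i]; p <- pairs$peak[i]
      if (is.na(rung_peak[r]) && !peak_used[p]) {
        rung_peak[r] <- p
        peak_used[p] <- TRUE
      }
    }
  }

  hit <- !is.na(rung_peak)
  dev <- data.frame(
    kind = rungs$kind[hit], rung_mz = rungs$mz[hit],
    dp_remain = rungs$dp_remain[hit],
    peak_mz = pk$mz[rung_peak[hit]],
    ppm = (pk$mz[rung_peak[hit]] - rungs$mz[hit]) / rungs$mz[hit] * 1e6
  )

  # longest consecutive run of DP levels, below the precursor, at which a
  # Y fragment matched: evidence of an unbroken sequential-loss series
  frag_levels <- sort(unique(rungs$dp_remain[rungs$kind == "Y" & !rungs$is_precursor]),
                      decreasing = TRUE)
  matched_lv <- unique(rungs$dp_remain[hit & rungs$kind == "Y" & !rungs$is_precursor])
  chain <- best <- 0L
  for (lv in frag_levels) {
    if (lv %in% matched_lv) {
      chain <- chain + 1L
      best <- max(best, chain)
    } else chain <- 0L
  }

  structure(
    list(matched = sum(hit), total = total,
         coverage = if (total) sum(hit) / total else 0,
         chain = best, deviations = dev),
    class = "ladder_match"
  )
}

#' @export
print.ladder_match <- function(x, ...) {
  cat(sprintf("Ladder match: %d/%d rungs (coverage %.2f), chain %d\n",
              x$matched, x$total, x$coverage, x$chain))
  invisible(x)
}

#' Assign an MSI confidence level
#'
#' Level 1: confirmed against an authentic standard (mass and retention
#' time). Level 3: putative compound class, supported by at least
#' `min_rungs` matched ladder fragments. Level 4: formula-only assignment
#' from accurate mass. Level 2 does not occur in this scheme (no spectral
#' library is involved).
#'
#' @param has_standard_match Logical.
#' @param ms2_match A `ladder_match` or `NULL` when no spectrum exists.
#' @param min_rungs Minimum matched rungs for Level 3 (default 2; a single
#'   fragment is not accepted as evidence of a ladder).
#' @return Integer 1, 3 or 4.
#' @export
assign_msi_level <- function(has_standard_match, ms2_match = NULL, min_rungs = 2L) {
  if (min_rungs < 1L) stop("min_rungs must be >= 1", call. = FALSE)
  if (isTRUE(has_standard_match)) return(1L)
  if (!is.null(ms2_match) && ms2_match$matched >= min_rungs) return(3L)
  4L
}

#' Standards table constructor
#'
#' @param name Compound names.
#' @param n_hex,n_pent Residue compositions of the standards.
#' @param rt_min Expected retention times in minutes (`NA` when the
#'   standard was not observed under the current gradient).
#' @return A data.frame of class `standards_table`.
#' @export
standards_table <- function(name, n_hex, n_pent, rt_min) {
  rc <- residue_composition(n_hex, n_pent)
  out <- data.frame(name = as.character(name), n_hex = rc$n_hex,
                    n_pent = rc$n_pent, rt_min = as.numeric(rt_min))
  class(out) <- c("standards_table", "data.frame")
  out
}

# composition string in glycomics style, e.g. Hex3, Hex1Pent3
composition_string <- function(n_hex, n_pent) {
  paste0(ifelse(n_hex > 0, sprintf("Hex%d", n_hex), ""),
         ifelse(n_pent > 0, sprintf("Pent%d", n_pent), ""))
}

#' Annotate a single precursor feature
#'
#' Enumerates candidate compositions for the feature's m/z, scores each
#' against the MS2 spectrum (when present) via its predicted ladder, checks
#' the standards table (composition plus retention time within
#' `rt_window_min`), assigns MSI levels, and ranks candidates by
#' (MSI level, MS2 coverage, |ppm|).
#'
#' @param rt_min,mz,intensity The feature's retention time (min), observed
#'   [M - H]- m/z and intensity.
#' @param cfg An [enum_config()].
#' @param palette A [monosaccharide_palette()].
#' @param standards A [standards_table()] or `NULL`.
#' @param spectrum An [ms2_spectrum()] for this feature, or `NULL`.
#' @param ms2_tol_ppm,mz_floor_da Fragment-matching tolerance (see
#'   [match_spectrum()]).
#' @param rt_window_min Half-width of the standard retention-time window in
#'   minutes (default 0.30).
#' @param min_rungs Level-3 evidence threshold (default 2).
#' @return A data.frame of ranked candidate annotations (zero rows when no
#'   composition lies within tolerance) with columns `n_hex`, `n_pent`,
#'   `dp`, `formula`, `composition`, `theoretical_mz`, `ppm_error`, `class`,
#'   `name`, `msi_level`, `ms2_matched`, `ms2_total`, `ms2_coverage`,
#'   `ms2_chain`, `evidence`.
#' @export
annotate_feature <- function(rt_min, mz, intensity = NA_real_,
                             cfg = enum_config(), palette = default_palette(),
                             standards = NULL, spectrum = NULL,
                             ms2_tol_ppm = 10, mz_floor_da = 0.003,
                             rt_window_min = 0.30, min_rungs = 2L) {
  cand <- enumerate_compositions(mz, cfg)
  n <- nrow(cand)
  cand$composition <- composition_string(cand$n_hex, cand$n_pent)
  cand$class <- if (n) classify_composition(cand$n_hex, cand$n_pent, palette) else character(0)
  cand$name <- if (n) composition_name(cand$n_hex, cand$n_pent, palette) else character(0)
  cand$msi_level <- integer(n)
  cand$ms2_matched <- rep(NA_integer_, n); cand$ms2_total <- rep(NA_integer_, n)
  cand$ms2_coverage <- rep(NA_real_, n); cand$ms2_chain <- rep(NA_integer_, n)
  cand$evidence <- character(n)

  for (i in seq_len(n)) {
    mm <- NULL
    if (!is.null(spectrum)) {
      mm <- match_spectrum(spectrum, predict_ladder(cand$n_hex[i], cand$n_pent[i]),
                           ms2_tol_ppm = ms2_tol_ppm, mz_floor_da = mz_floor_da,
                           scan_mz_min = cfg$scan_mz_min)
      cand$ms2_matched[i] <- mm$matched
      cand$ms2_total[i] <- mm$total
      cand$ms2_coverage[i] <- mm$coverage
      cand$ms2_chain[i] <- mm$chain
    }
    std_name <- NA_character_
    if (!is.null(standards) && nrow(standards)) {
      hit <- standards$n_hex == cand$n_hex[i] & standards$n_pent == cand$n_pent[i] &
        !is.na(standards$rt_min) & abs(standards$rt_min - rt_min) <= rt_window_min
      if (any(hit)) std_name <- standards$name[which(hit)[1]]
    }
    cand$msi_level[i] <- assign_msi_level(!is.na(std_name), mm, min_rungs)
    if (!is.na(std_name)) cand$name[i] <- std_name
    ev <- c(
      if (!is.na(std_name)) sprintf("standard %s (rt window %.2f min)", std_name, rt_window_min),
      if (!is.null(mm)) sprintf("MS2 %d/%d rungs, chain %d", mm$matched, mm$total, mm$chain),
      if (cand$class[i] == "FOS") "FOS (palette-assumed)"
    )
    cand$evidence[i] <- paste(ev, collapse = "; ")
  }
  cov <- ifelse(is.na(cand$ms2_coverage), -1, cand$ms2_coverage)
  cand[order(cand$msi_level, -cov, abs(cand$ppm_error)), , drop = FALSE]
}

#' Annotate a feature table end to end
#'
#' Applies the intensity filter, annotates every remaining feature (best
#' candidate per feature), then assembles isomer series: features sharing a
#' composition are grouped, the Level-1 member (if any) keeps the canonical
#' name and the others receive an `"isomer"` suffix, and peak numbers are
#' assigned by elution order (retention time ascending, ties by m/z).
#'
#' @param features Data.frame with columns `rt_min`, `mz`, `intensity` and
#'   optionally `ms2_id` (key into `spectra`) and `feature_id`.
#' @param spectra Named list of [ms2_spectrum()] objects keyed by `ms2_id`,
#'   or `NULL`.
#' @inheritParams annotate_feature
#' @param intensity_threshold Screening threshold (default 10000).
#' @return A data.frame of class `annotation_table` with one row per
#'   retained feature: `peak_no`, `rt_min`, `experimental_mz`,
#'   `theoretical_mz`, `error_ppm`, `formula`, `composition`, `class`,
#'   `name`, `msi_level`, `evidence` (annotation columns are `NA` for
#'   features with no composition within tolerance).
#' @export
annotate_features <- function(features, spectra = NULL,
                              cfg = enum_config(), palette = default_palette(),
                              standards = NULL, intensity_threshold = 10000,
                              ms2_tol_ppm = 10, mz_floor_da = 0.003,
                              rt_window_min = 0.30, min_rungs = 2L) {
  req <- c("rt_min", "mz", "intensity")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  features <- intensity_filter(features, intensity_threshold)
  n <- nrow(features)
  out <- data.frame(
    rt_min = features$rt_min, experimental_mz = features$mz,
    intensity = features$intensity,
    theoretical_mz = NA_real_, error_ppm = NA_real_,
    formula = NA_character_, composition = NA_character_,
    n_hex = NA_integer_, n_pent = NA_integer_,
    class = NA_character_, name = NA_character_, msi_level = NA_integer_,
    evidence = NA_character_
  )
  if ("feature_id" %in% names(features)) out$feature_id <- features$feature_id
  for (i in seq_len(n)) {
    sp <- NULL
    if (!is.null(spectra) && "ms2_id" %in% names(features)) {
      id <- features$ms2_id[i]
      if (!is.na(id) && nzchar(as.character(id))) sp <- spectra[[as.character(id)]]
    }
    cand <- annotate_feature(features$rt_min[i], features$mz[i],
                             features$intensity[i], cfg, palette, standards,
                             sp, ms2_tol_ppm, mz_floor_da, rt_window_min,
                             min_rungs)
    if (nrow(cand)) {
      best <- cand[1, ]
      out$theoretical_mz[i] <- best$theoretical_mz
      out$error_ppm[i] <- best$ppm_error
      out$formula[i] <- best$formula
      out$composition[i] <- best$composition
      out$n_hex[i] <- best$n_hex
      out$n_pent[i] <- best$n_pent
      out$class[i] <- best$class
      out$name[i] <- best$name
      out$msi_level[i] <- best$msi_level
      out$evidence[i] <- best$evidence
    }
  }
  assemble_isomer_series(out)
}

#' Assemble isomer series and number peaks by elution order
#'
#' Groups annotations by composition. When a group contains a Level-1
#' (standard-confirmed) member, that member keeps the canonical name and
#' every other member is renamed `"<name> isomer"`. Groups without a
#' Level-1 member keep the plain series name for all members. Peak numbers
#' are assigned by retention time ascending, ties broken by m/z ascending.
#'
#' @param ann An annotation data.frame as built by [annotate_features()].
#' @return The same data.frame with `peak_no` assigned, rows sorted by
#'   elution order, class `annotation_table`.
#' @export
assemble_isomer_series <- function(ann) {
  ord <- order(ann$rt_min, ann$experimental_mz)
  ann <- ann[ord, , drop = FALSE]
  ann$peak_no <- seq_len(nrow(ann))
  for (comp in unique(ann$composition[!is.na(ann$composition)])) {
    g <- which(!is.na(ann$composition) & ann$composition == comp)
    lv1 <- g[ann$msi_level[g] == 1L]
    if (length(lv1)) {
      canon <- ann$name[lv1[1]]
      others <- setdiff(g, lv1)
      ann$name[others] <- paste(canon, "isomer")
    }
  }
  rownames(ann) <- NULL
  front <- c("peak_no", "rt_min", "experimental_mz", "theoretical_mz",
             "error_ppm", "formula", "composition", "class", "name",
             "msi_level")
  ann <- ann[, c(front, setdiff(names(ann), front))]
  class(ann) <- c("annotation_table", "data.frame")
  ann
}

#' Summarize an annotation table
#'
#' @param ann An `annotation_table`.
#' @return A list with `n_features`, `n_annotated`, `class_counts` and
#'   `level_counts` (named integer vectors).
#' @export
annotation_summary <- function(ann) {
  cls <- table(factor(ann$class, levels = c("FOS", "AOS", "MIXED")))
  lev <- table(factor(ann$msi_level, levels = c(1, 3, 4)))
  list(
    n_features = nrow(ann),
    n_annotated = sum(!is.na(ann$composition)),
    class_counts = stats::setNames(as.integer(cls), names(cls)),
    level_counts = stats::setNames(as.integer(lev), paste0("level", names(lev)))
  )
}
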