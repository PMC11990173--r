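# File I/O: CSV feature tables, MGF and mzML spectra, YAML palette and run
# configuration, and the fixed-format output tables.

#' Read a precursor feature table from CSV
#'
#' Expected columns: `rt_min`, `mz`, `intensity`; optional `ms2_id` and
#' `feature_id`. Row numbers are preserved in `source_row`.
#'
#' @param path CSV file path.
#' @return A data.frame of features.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("rt_min", "mz", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("feature table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in req) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(as.character(df[[col]])))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           " of ", path, call. = FALSE)
    }
    df[[col]] <- v
  }
  df$source_row <- seq_len(nrow(df))
  df
}

#' Read a standards table from CSV
#'
#' Expected columns: `name`, `n_hex`, `n_pent`, `rt_min`.
#'
#' @param path CSV file path.
#' @return A [standards_table()].
#' @export
read_standards <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "n_hex", "n_pent", "rt_min")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("standards table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  standards_table(df$name, df$n_hex, df$n_pent, df$rt_min)
}

#' Read spectra and precursor features from MGF or mzML
#'
#' Dispatches on the file extension. MGF blocks become one feature (from
#' `PEPMASS`/`RTINSECONDS`) plus its MS2 peak list; in mzML, each MS1 scan
#' contributes a feature at its base peak and MS2 scans are linked to their
#' precursor scan. Positive-polarity scans are skipped with a message.
#'
#' @param path File path ending in `.mgf` or `.mzML`.
#' @return A list with `features` (data.frame: `feature_id`, `rt_min`, `mz`,
#'   `intensity`, `ms2_id`) and `spectra` (named list of [ms2_spectrum()]).
#' @export
read_spectra <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mgf = read_mgf(path),
    mzml = read_mzml(path),
    stop("unsupported spectra format '.", ext, "' (use .mgf or .mzML)",
         call. = FALSE)
  )
}

#' Read an MGF file
#'
#' Minimal Mascot Generic Format reader: `BEGIN IONS`/`END IONS` blocks with
#' `PEPMASS` (m/z and optional intensity), `RTINSECONDS`, `CHARGE` and peak
#' lines. Charges without a trailing `-` are treated as positive polarity
#' and skipped.
#'
#' @param path MGF file path.
#' @return Same shape as [read_spectra()].
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty MGF file: ", path, call. = FALSE)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends) || !length(starts)) {
    stop("malformed MGF (unbalanced BEGIN/END IONS): ", path, call. = FALSE)
  }
  feats <- list(); spectra <- list(); skipped <- 0L
  for (b in seq_along(starts)) {
    blk <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    kv <- blk[grepl("=", blk, fixed = TRUE)]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pep <- strsplit(trimws(get("PEPMASS")), "[ \t]+")[[1]]
    if (all(is.na(pep))) stop("MGF block ", b, " lacks PEPMASS: ", path, call. = FALSE)
    prec_mz <- as.numeric(pep[1])
    prec_int <- if (length(pep) > 1) as.numeric(pep[2]) else NA_real_
    charge <- get("CHARGE")
    negative <- is.na(charge) || grepl("-", charge, fixed = TRUE)
    if (!negative) { skipped <- skipped + 1L; next }
    rt <- as.numeric(get("RTINSECONDS")) / 60
    pk <- blk[!grepl("=", blk, fixed = TRUE) & nzchar(trimws(blk))]
    id <- sprintf("mgf_%d", b)
    if (length(pk)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), as.numeric))
      spectra[[id]] <- ms2_spectrum(prec_mz, mat[, 1], mat[, 2],
                                    polarity = "negative", rt_min = rt)
    }
    feats[[b]] <- data.frame(
      feature_id = id, rt_min = rt, mz = prec_mz, intensity = prec_int,
      ms2_id = if (length(pk)) id else NA_character_
    )
  }
  if (skipped) message("skipped ", skipped, " positive-polarity MGF block(s)")
  list(features = do.call(rbind, feats), spectra = spectra)
}

#' Write spectra to MGF
#'
#' @param features Feature data.frame (as from [read_spectra()] or
#'   [generate_dataset()]).
#' @param spectra Named list of [ms2_spectrum()] keyed by `ms2_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(features, spectra, path) {
  out <- character(0)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    out <- c(out,
      "BEGIN IONS",
      sprintf("TITLE=%s", f$feature_id),
      sprintf("PEPMASS=%.6f %.1f", f$mz, f$intensity),
      sprintf("RTINSECONDS=%.3f", f$rt_min * 60),
      "CHARGE=1-")
    id <- as.character(f$ms2_id)
    if (!is.na(id) && nzchar(id) && !is.null(spectra[[id]])) {
      pk <- spectra[[id]]$peaks
      out <- c(out, sprintf("%.6f %.2f", pk$mz, pk$intensity))
    }
    out <- c(out, "END IONS", "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read centroided spectra from mzML (via mzR)
#'
#' MS1 scans yield one feature each at their most intense peak; MS2 scans
#' are attached to their precursor scan. Positive-polarity scans are skipped
#' with a message.
#'
#' @param path mzML file path.
#' @return Same shape as [read_spectra()].
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  if (!nrow(hdr)) stop("empty mzML file: ", path, call. = FALSE)
  # mzR polarity: 0 negative, 1 positive
  pos <- sum(hdr$polarity == 1, na.rm = TRUE)
  if (pos) message("skipped ", pos, " positive-polarity scan(s)")
  hdr <- hdr[is.na(hdr$polarity) | hdr$polarity != 1, , drop = FALSE]
  feats <- list(); spectra <- list()
  ms1 <- hdr[hdr$msLevel == 1L, , drop = FALSE]
  ms2 <- hdr[hdr$msLevel == 2L, , drop = FALSE]
  for (i in seq_len(nrow(ms1))) {
    pk <- mzR::peaks(fh, ms1$seqNum[i])
    if (!nrow(pk)) next
    top <- which.max(pk[, 2])
    id <- sprintf("scan_%d", ms1$acquisitionNum[i])
    child <- ms2[!is.na(ms2$precursorScanNum) &
                   ms2$precursorScanNum == ms1$acquisitionNum[i], , drop = FALSE]
    ms2_id <- NA_character_
    if (nrow(child)) {
      ms2_id <- sprintf("scan_%d", child$acquisitionNum[1])
      cpk <- mzR::peaks(fh, child$seqNum[1])
      spectra[[ms2_id]] <- ms2_spectrum(child$precursorMZ[1], cpk[, 1], cpk[, 2],
                                        polarity = "negative",
                                        rt_min = child$retentionTime[1] / 60)
    }
    feats[[length(feats) + 1L]] <- data.frame(
      feature_id = id, rt_min = ms1$retentionTime[i] / 60,
      mz = pk[top, 1], intensity = pk[top, 2], ms2_id = ms2_id
    )
  }
  list(features = do.call(rbind, feats), spectra = spectra)
}

#' Write a dataset to mzML (via mzR)
#'
#' One MS1 scan per feature (containing the precursor peak) followed by its
#' MS2 scan when present. Retention times are written in seconds, polarity
#' negative.
#'
#' @inheritParams write_mgf
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(features, spectra, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the mzR package", call. = FALSE)
  }
  pks <- list(); rows <- list(); acq <- 0L
  empty_hdr <- function() list(
    precursorScanNum = NA_integer_, precursorMZ = NA_real_,
    precursorCharge = NA_integer_, precursorIntensity = NA_real_,
    collisionEnergy = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_, isolationWindowUpperOffset = NA_real_
  )
  add_scan <- function(mat, level, rt_sec, extra) {
    acq <<- acq + 1L
    pks[[acq]] <<- mat
    h <- utils::modifyList(empty_hdr(), extra)
    rows[[acq]] <<- data.frame(
      seqNum = acq, acquisitionNum = acq, msLevel = level, polarity = 0L,
      peaksCount = nrow(mat), totIonCurrent = sum(mat[, 2]),
      retentionTime = rt_sec,
      basePeakMZ = mat[which.max(mat[, 2]), 1],
      basePeakIntensity = max(mat[, 2]),
      collisionEnergy = h$collisionEnergy, ionisationEnergy = 0,
      lowMZ = min(mat[, 1]), highMZ = max(mat[, 1]),
      precursorScanNum = h$precursorScanNum, precursorMZ = h$precursorMZ,
      precursorCharge = h$precursorCharge,
      precursorIntensity = h$precursorIntensity,
      mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
      mergedResultStartScanNum = NA_integer_,
      mergedResultEndScanNum = NA_integer_,
      injectionTime = 0, filterString = NA_character_,
      spectrumId = sprintf("scan=%d", acq), centroided = TRUE,
      ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = h$isolationWindowTargetMZ,
      isolationWindowLowerOffset = h$isolationWindowLowerOffset,
      isolationWindowUpperOffset = h$isolationWindowUpperOffset,
      scanWindowLowerLimit = 150, scanWindowUpperLimit = 2000
    )
    acq
  }
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    parent <- add_scan(cbind(mz = f$mz, intensity = f$intensity), 1L,
                       f$rt_min * 60, list())
    id <- as.character(f$ms2_id)
    if (!is.na(id) && nzchar(id) && !is.null(spectra[[id]])) {
      sp <- spectra[[id]]
      add_scan(as.matrix(sp$peaks), 2L, f$rt_min * 60 + 0.5, list(
        precursorScanNum = parent, precursorMZ = sp$precursor_mz,
        precursorCharge = -1L, precursorIntensity = f$intensity,
        collisionEnergy = 30,
        isolationWindowTargetMZ = sp$precursor_mz,
        isolationWindowLowerOffset = 1.5, isolationWindowUpperOffset = 1.5
      ))
    }
  }
  mzR::writeMSData(pks, file = path, header = do.call(rbind, rows))
  invisible(path)
}

#' Run configuration
#'
#' All pipeline tunables in one serializable object. Defaults follow the
#' reference acquisition: scan range m/z 150-2000, DP 2-12, 5 ppm precursor
#' and 10 ppm fragment tolerances, 10,000-count intensity screen, 0.30 min
#' standard retention window, two matched rungs for Level 3.
#'
#' @param dp_min,dp_max,ms1_tol_ppm,scan_mz_min,scan_mz_max See [enum_config()].
#' @param ms2_tol_ppm,mz_floor_da,intensity_threshold,rt_window_min,min_rungs
#'   See [annotate_features()].
#' @param seed Integer seed for simulation entry points.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dp_min = 2L, dp_max = 12L, ms1_tol_ppm = 5,
                       scan_mz_min = 150, scan_mz_max = 2000,
                       ms2_tol_ppm = 10, mz_floor_da = 0.003,
                       intensity_threshold = 10000, rt_window_min = 0.30,
                       min_rungs = 2L, seed = 1L) {
  cfg <- enum_config(dp_min, dp_max, ms1_tol_ppm, scan_mz_min, scan_mz_max)
  stopifnot(ms2_tol_ppm > 0, mz_floor_da >= 0, intensity_threshold >= 0,
            rt_window_min >= 0, min_rungs >= 1)
  structure(c(unclass(cfg),
              list(ms2_tol_ppm = ms2_tol_ppm, mz_floor_da = mz_floor_da,
                   intensity_threshold = intensity_threshold,
                   rt_window_min = rt_window_min,
                   min_rungs = as.integer(min_rungs),
                   seed = as.integer(seed))),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The round trip is stable: `read_run_config(write_run_config(x, p))`
#' reproduces `x`.
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

# enum_config view of a run_config
as_enum_config <- function(cfg) {
  enum_config(cfg$dp_min, cfg$dp_max, cfg$ms1_tol_ppm,
              cfg$scan_mz_min, cfg$scan_mz_max)
}

#' Read / write a monosaccharide palette as YAML
#'
#' @param palette A [monosaccharide_palette()].
#' @param path YAML file path.
#' @export
write_palette <- function(palette, path) {
  yaml::write_yaml(unclass(palette), path)
  invisible(path)
}

#' @rdname write_palette
#' @export
read_palette <- function(path) {
  x <- yaml::read_yaml(path)
  monosaccharide_palette(x$hexoses, x$pentoses,
                         hexose_label = x$hexose_label,
                         pentose_label = x$pentose_label,
                         note = if (is.null(x$note)) "" else x$note)
}

#' Write an annotation table as CSV with fixed presentation formatting
#'
#' m/z columns are printed at 4 decimals and ppm at 2 decimals (half away
#' from zero), so identical inputs give byte-identical files.
#'
#' @param ann An `annotation_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(ann, path) {
  out <- ann[, c("peak_no", "rt_min", "experimental_mz", "theoretical_mz",
                 "error_ppm", "formula", "composition", "class", "name",
                 "msi_level")]
  fmt <- function(x, d) ifelse(is.na(x), "", sprintf(paste0("%.", d, "f"), round_mz(x, d)))
  out$rt_min <- fmt(out$rt_min, 2)
  out$experimental_mz <- fmt(out$experimental_mz, 4)
  out$theoretical_mz <- fmt(out$theoretical_mz, 4)
  out$error_ppm <- fmt(out$error_ppm, 2)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write a PRM inclusion list as CSV
#'
#' @param inclusion Output of [build_inclusion_list()].
#' @param path Output CSV path.
#' @param rt_window Optional retention-time window string or vector recorded
#'   per target (empty by default).
#' @return `path`, invisibly.
#' @export
write_inclusion_csv <- function(inclusion, path, rt_window = "") {
  out <- data.frame(
    mz = sprintf("%.4f", round_mz(inclusion$mz, 4)),
    charge = inclusion$charge,
    rt_window = rt_window,
    formula = inclusion$formula,
    composition = composition_string(inclusion$n_hex, inclusion$n_pent),
    class = inclusion$class,
    name = inclusion$name
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
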