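# Synthetic LC-MS/MS dataset generation with known ground truth, so every
# pipeline stage can be exercised without instrument data.

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation plan
#'
#' Describes a set of planted oligosaccharide compounds and the noise model
#' used to turn them into synthetic spectra. Mass errors are Gaussian in ppm
#' (`mass_jitter_ppm` standard deviation around `mass_bias_ppm`); fragment
#' ladder intensities decay geometrically rung by rung; each MS2 spectrum
#' additionally receives uniform-m/z noise peaks.
#'
#' Setting `mass_bias_ppm` to about -2.5 reproduces the small systematic
#' negative offset typical of externally calibrated Orbitrap runs; the
#' default plan is unbiased.
#'
#' @param compounds Data.frame with columns `n_hex`, `n_pent`, `rt_min`,
#'   `intensity`, `has_ms2`, `is_standard`.
#' @param mass_jitter_ppm Gaussian mass error SD in ppm (default 1.5).
#' @param mass_bias_ppm Systematic mass offset in ppm (default 0).
#' @param decay Intensity decay factor per ladder rung (default 0.6).
#' @param n_noise_peaks Noise peaks per MS2 spectrum (default 20).
#' @param noise_mz_range m/z range of noise peaks (default 150-2000, the
#'   acquisition range).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_plan`.
#' @export
sim_plan <- function(compounds, mass_jitter_ppm = 1.5, mass_bias_ppm = 0,
                     decay = 0.6, n_noise_peaks = 20,
                     noise_mz_range = c(150, 2000), seed = 1L) {
  req <- c("n_hex", "n_pent", "rt_min", "intensity", "has_ms2", "is_standard")
  miss <- setdiff(req, names(compounds))
  if (length(miss)) stop("compounds lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(compounds$rt_min <= 0)) stop("retention times must be positive", call. = FALSE)
  if (mass_jitter_ppm < 0) stop("mass_jitter_ppm must be >= 0", call. = FALSE)
  residue_composition(compounds$n_hex, compounds$n_pent)  # validates
  structure(
    list(compounds = compounds, mass_jitter_ppm = mass_jitter_ppm,
         mass_bias_ppm = mass_bias_ppm, decay = decay,
         n_noise_peaks = as.integer(n_noise_peaks),
         noise_mz_range = noise_mz_range, seed = as.integer(seed)),
    class = "sim_plan"
  )
}

#' Default simulation plan: DP 2-8 oligosaccharides with isomer groups
#'
#' Plants every hexose-only and pentose-only composition with DP 2-8 plus
#' six mixed compositions, each as `n_isomers` co-eluting isomers at
#' distinct retention times, all with MS2 ladders. One isomer of each
#' hexose-only DP 2-7 composition is flagged as a standard.
#'
#' @param n_isomers Isomers per composition (default 3).
#' @param seed Seed passed to [sim_plan()].
#' @return A `sim_plan`.
#' @export
default_sim_plan <- function(n_isomers = 3L, seed = 1L) {
  base <- rbind(
    data.frame(n_hex = 2:8, n_pent = 0L),
    data.frame(n_hex = 0L, n_pent = 2:8),
    data.frame(n_hex = c(1L, 2L, 1L, 3L, 2L, 1L),
               n_pent = c(1L, 1L, 2L, 1L, 2L, 3L))
  )
  comp <- base[rep(seq_len(nrow(base)), each = n_isomers), ]
  n <- nrow(comp)
  # evenly spread elution with per-isomer offsets; intensities span the
  # range typically retained by the 10,000-count screen
  comp$rt_min <- seq(10, 30, length.out = n)
  comp$intensity <- round(10^seq(4.5, 6, length.out = n))
  comp$has_ms2 <- TRUE
  comp$is_standard <- FALSE
  first <- !duplicated(base[rep(seq_len(nrow(base)), each = n_isomers), c("n_hex", "n_pent")])
  comp$is_standard <- first & comp$n_pent == 0L & comp$n_hex <= 7L
  rownames(comp) <- NULL
  sim_plan(comp, seed = seed)
}

#' Generate a synthetic dataset from a simulation plan
#'
#' Each planted compound yields an MS1 precursor feature at its theoretical
#' deprotonated m/z perturbed by Gaussian ppm error and, when `has_ms2`, an
#' MS2 spectrum containing its full fragment ladder (Y ions and water-loss
#' companions, intensities decaying per rung, the same ppm jitter) plus
#' uniform noise peaks.
#'
#' @param plan A [sim_plan()].
#' @return A list with `features` (data.frame: `feature_id`, `rt_min`, `mz`,
#'   `intensity`, `ms2_id`), `spectra` (named list of [ms2_spectrum()]),
#'   `truth` (data.frame with the planted composition, class, expected name
#'   and realized ppm error per feature) and `standards`
#'   (a [standards_table()] built from the `is_standard` rows).
#' @export
generate_dataset <- function(plan) {
  stopifnot(inherits(plan, "sim_plan"))
  comp <- plan$compounds
  if (anyDuplicated(comp[, c("rt_min", "n_hex", "n_pent")])) {
    stop("duplicate (rt, composition) entries make the ground truth ambiguous",
         call. = FALSE)
  }
  with_seed(plan$seed, {
    n <- nrow(comp)
    theo <- composition_mz(comp$n_hex, comp$n_pent)
    eps <- stats::rnorm(n, plan$mass_bias_ppm, plan$mass_jitter_ppm)
    obs <- theo * (1 + eps * 1e-6)
    feats <- data.frame(
      feature_id = sprintf("sim_%03d", seq_len(n)),
      rt_min = comp$rt_min, mz = obs, intensity = comp$intensity,
      ms2_id = ifelse(comp$has_ms2, sprintf("sim_%03d", seq_len(n)), NA_character_)
    )
    spectra <- list()
    for (i in seq_len(n)) {
      if (!comp$has_ms2[i]) next
      lad <- predict_ladder(comp$n_hex[i], comp$n_pent[i])
      frag_mz <- c(lad$y_mz, lad$y_minus_water_mz)
      rung_idx <- rep(seq_len(nrow(lad)) - 1L, 2)
      frag_int <- comp$intensity[i] * plan$decay^rung_idx *
        rep(c(1, 0.5), each = nrow(lad))
      fe <- stats::rnorm(length(frag_mz), plan$mass_bias_ppm, plan$mass_jitter_ppm)
      frag_mz <- frag_mz * (1 + fe * 1e-6)
      if (plan$n_noise_peaks > 0) {
        nz_mz <- stats::runif(plan$n_noise_peaks, plan$noise_mz_range[1],
                              plan$noise_mz_range[2])
        nz_int <- stats::runif(plan$n_noise_peaks, 0.001, 0.02) * comp$intensity[i]
        frag_mz <- c(frag_mz, nz_mz)
        frag_int <- c(frag_int, nz_int)
      }
      spectra[[feats$feature_id[i]]] <- ms2_spectrum(
        obs[i], frag_mz, frag_int, polarity = "negative", rt_min = comp$rt_min[i]
      )
    }
    truth <- data.frame(
      feature_id = feats$feature_id, rt_min = comp$rt_min,
      n_hex = comp$n_hex, n_pent = comp$n_pent,
      composition = composition_string(comp$n_hex, comp$n_pent),
      class = classify_composition(comp$n_hex, comp$n_pent),
      name = composition_name(comp$n_hex, comp$n_pent),
      theoretical_mz = theo, observed_mz = obs, ppm_realized = eps
    )
    std <- comp[comp$is_standard, , drop = FALSE]
    standards <- if (nrow(std)) {
      standards_table(composition_name(std$n_hex, std$n_pent),
                      std$n_hex, std$n_pent, std$rt_min)
    } else standards_table(character(0), integer(0), integer(0), numeric(0))
    list(features = feats, spectra = spectra, truth = truth,
         standards = standards)
  })
}

#' Write a generated dataset's ground truth to CSV
#'
#' @param dataset Output of [generate_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(dataset, path) {
  utils::write.csv(dataset$truth, path, row.names = FALSE)
  invisible(path)
}

#' Score composition recovery against ground truth
#'
#' Joins an annotation table back to the generator's truth table by feature
#' id and reports the fraction of planted compounds whose top-ranked
#' annotation has the correct residue composition.
#'
#' @param ann An `annotation_table` carrying `feature_id`.
#' @param truth The `truth` component of [generate_dataset()].
#' @return A list with `n`, `n_correct`, `recovery` and the merged
#'   data.frame `detail`.
#' @export
score_recovery <- function(ann, truth) {
  m <- merge(truth, ann[, c("feature_id", "composition", "error_ppm")],
             by = "feature_id", suffixes = c("_true", "_called"))
  ok <- !is.na(m$composition_called) & m$composition_called == m$composition_true
  list(n = nrow(m), n_correct = sum(ok),
       recovery = if (nrow(m)) sum(ok) / nrow(m) else NA_real_,
       detail = m)
}
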