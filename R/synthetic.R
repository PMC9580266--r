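# Synthetic FTIR tissue spectra with known ground truth: Gaussian bands on a
# fingerprint-region grid, class-dependent amplitude differences at planted
# wavenumbers, multiplicative per-spectrum scale variation and additive noise.

#' Default synthetic band set
#'
#' Eleven Gaussian bands in the fingerprint region. Six are
#' class-independent background bands at common tissue positions (Amide I
#' 1656, Amide II 1545, CH2 1450, COO- 1400, carbohydrate/phosphate 1080 and
#' glycogen 1020 cm^-1). Five carry a class-dependent amplitude difference
#' (`class_delta`, added for class T) at 1684, 1656, 1614, 1575 and
#' 1236 cm^-1 — the planted discriminating wavenumbers the pipeline is
#' expected to recover.
#'
#' @param classDelta Amplitude difference (T minus NT) planted at the five
#'   discriminating bands (default 0.15).
#' @return A `data.frame` with columns `center`, `width` (Gaussian sigma,
#'   cm^-1), `amplitude` (mean peak absorbance) and `class_delta`.
#' @export
defaultBands <- function(classDelta = 0.15) {
  data.frame(
    center      = c(1656, 1545, 1450, 1400, 1080, 1020,
                    1684, 1656, 1614, 1575, 1236),
    width       = c(20, 22, 14, 14, 18, 14,
                    8, 8, 8, 8, 8),
    amplitude   = c(0.4, 0.8, 0.45, 0.40, 0.50, 0.45,
                    1.0, 1.0, 1.0, 1.0, 1.0),
    class_delta = c(0, 0, 0, 0, 0, 0,
                    rep(classDelta, 5))
  )
}

#' Synthetic dataset configuration
#'
#' Parameters of the synthetic spectrum generator. The defaults emulate the
#' study conditions of the pipeline's motivating application: 10 T and 7 NT
#' patients, fingerprint-region spectra on a 317-point grid over
#' 1000-1800 cm^-1 (so that the number of unordered wavenumber pairs is
#' C(317, 2) = 50,086 and a top-150 selection is 0.3% of all metrics),
#' 4 cm^-1 spectral resolution, and multiplicative per-spectrum scale
#' variation of 10% on the log scale.
#'
#' @param gridMin,gridMax Grid span in cm^-1 (defaults 1000, 1800).
#' @param nGrid Number of grid points (default 317).
#' @param bands Band table as returned by [defaultBands()].
#' @param nPatientsT,nPatientsNT Patients per class (defaults 10, 7).
#' @param spectraPerPatient Spectra (pixels) per patient (default 50).
#' @param noiseSd Additive noise sd in absorbance units (default 0.02).
#' @param scaleSd Sd of the per-spectrum multiplicative log-scale factor
#'   (default 0.1).
#' @param patientSd Sd of per-patient additive band-amplitude offsets
#'   (default 0; see the package vignette for why).
#' @param resolution Spectral resolution recorded on the dataset (cm^-1).
#' @param seed Integer RNG seed.
#' @return A list of class `SyntheticConfig`.
#' @seealso [defaultConfig()], [syntheticPreset()], [generateDataset()]
#' @export
syntheticConfig <- function(gridMin = 1000, gridMax = 1800, nGrid = 317,
                            bands = defaultBands(), nPatientsT = 10,
                            nPatientsNT = 7, spectraPerPatient = 50,
                            noiseSd = 0.02, scaleSd = 0.1, patientSd = 0,
                            resolution = 4, seed = 1) {
  cfg <- structure(list(gridMin = gridMin, gridMax = gridMax,
                        nGrid = as.integer(nGrid), bands = bands,
                        nPatientsT = as.integer(nPatientsT),
                        nPatientsNT = as.integer(nPatientsNT),
                        spectraPerPatient = as.integer(spectraPerPatient),
                        noiseSd = noiseSd, scaleSd = scaleSd,
                        patientSd = patientSd, resolution = resolution,
                        seed = as.integer(seed)),
                   class = "SyntheticConfig")
  validateSyntheticConfig(cfg)
  cfg
}

validateSyntheticConfig <- function(cfg) {
  if (cfg$nGrid < 2) stop("nGrid must be at least 2")
  if (cfg$gridMin >= cfg$gridMax) stop("gridMin must be below gridMax")
  if (cfg$nPatientsT < 1 || cfg$nPatientsNT < 1)
    stop("each class needs at least one patient")
  if (cfg$spectraPerPatient < 1) stop("spectraPerPatient must be >= 1")
  if (cfg$noiseSd < 0 || cfg$scaleSd < 0 || cfg$patientSd < 0)
    stop("noiseSd, scaleSd and patientSd must be non-negative")
  b <- cfg$bands
  need <- setdiff(c("center", "width", "amplitude", "class_delta"),
                  colnames(b))
  if (length(need))
    stop("bands table lacks column(s): ", paste(need, collapse = ", "))
  if (any(b$width <= 0)) stop("band widths must be positive")
  if (any(b$amplitude < 0)) stop("band amplitudes must be non-negative")
  invisible(TRUE)
}

#' Default synthetic configuration
#'
#' [syntheticConfig()] with all defaults: the five discriminating bands
#' planted at 1684, 1656, 1614, 1575 and 1236 cm^-1 with amplitude
#' difference 0.15, zero-delta background bands including 1020 cm^-1, 10 T
#' and 7 NT patients.
#'
#' @param seed Integer RNG seed.
#' @return A `SyntheticConfig`.
#' @export
defaultConfig <- function(seed = 1) syntheticConfig(seed = seed)

#' Named synthetic presets
#'
#' * `"default"` — planted class differences of 0.15 at the five
#'   discriminating bands (see [defaultBands()]).
#' * `"null"` — identical band structure with every `class_delta` set to 0:
#'   the two classes are exchangeable and any classifier's expected balanced
#'   accuracy is 50%.
#' * `"strong-signal"` — class differences of 0.5 with noise sd 0.005:
#'   essentially separable classes.
#'
#' @param preset One of `"default"`, `"null"`, `"strong-signal"`.
#' @param seed Integer RNG seed.
#' @return A `SyntheticConfig`.
#' @export
syntheticPreset <- function(preset = c("default", "null", "strong-signal"),
                            seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
         "default" = syntheticConfig(seed = seed),
         "null" = syntheticConfig(bands = defaultBands(classDelta = 0),
                                  seed = seed),
         "strong-signal" = syntheticConfig(
           bands = defaultBands(classDelta = 0.5), noiseSd = 0.005,
           seed = seed))
}

#' Generate a synthetic labelled spectral dataset
#'
#' Each spectrum is
#' `scale * sum_b (amplitude_b + class_delta_b * 1[T] + offset_pb) *
#' exp(-(nu - center_b)^2 / (2 width_b^2)) + noise`,
#' with `scale = exp(N(0, scaleSd))` per spectrum, `offset_pb ~
#' N(0, patientSd)` per patient and band, and iid `N(0, noiseSd)` additive
#' noise per grid point. Fully reproducible from `config$seed`.
#'
#' @param config A [syntheticConfig()].
#' @return A list with elements `dataset` (a [SpectraSet]) and `truth`, a
#'   `GroundTruth` list holding `planted_wavenumbers` (centers of bands with
#'   nonzero `class_delta`), `scale_factors` (per spectrum),
#'   `patient_offsets` (patients × bands) and the `bands` table.
#' @export
generateDataset <- function(config = defaultConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  validateSyntheticConfig(config)
  grid <- seq(config$gridMin, config$gridMax, length.out = config$nGrid)
  b <- config$bands
  nBands <- nrow(b)

  patientId <- c(sprintf("T%02d", seq_len(config$nPatientsT)),
                 sprintf("N%02d", seq_len(config$nPatientsNT)))
  patientLabel <- rep(c("T", "NT"), c(config$nPatientsT, config$nPatientsNT))
  nPat <- length(patientId)
  spp <- config$spectraPerPatient
  nSpec <- nPat * spp
  specPatient <- rep(patientId, each = spp)
  specLabel <- rep(patientLabel, each = spp)
  specId <- sprintf("S%04d", seq_len(nSpec))

  draws <- withSeed(config$seed, {
    list(offsets = matrix(rnorm(nPat * nBands, 0, config$patientSd),
                          nPat, nBands,
                          dimnames = list(patientId, NULL)),
         scales = exp(rnorm(nSpec, 0, config$scaleSd)),
         noise = matrix(rnorm(nSpec * config$nGrid, 0, config$noiseSd),
                        config$nGrid, nSpec))
  })

  # Gaussian basis: grid points x bands
  basis <- exp(-sweep(outer(grid, b$center, "-")^2, 2, 2 * b$width^2, "/"))
  # Per-spectrum band amplitudes: bands x spectra
  patIdx <- match(specPatient, patientId)
  amp <- matrix(b$amplitude, nBands, nSpec) +
    outer(b$class_delta, as.numeric(specLabel == "T")) +
    t(draws$offsets)[, patIdx, drop = FALSE]
  clean <- basis %*% amp
  a <- sweep(clean, 2, draws$scales, "*") + draws$noise

  dataset <- SpectraSet(t(a), grid, specId, specPatient, specLabel,
                        resolution = config$resolution)
  truth <- structure(list(
    planted_wavenumbers = b$center[b$class_delta != 0],
    scale_factors = stats::setNames(draws$scales, specId),
    patient_offsets = draws$offsets,
    bands = b
  ), class = "GroundTruth")
  list(dataset = dataset, truth = truth)
}

#' Reference key wavenumbers of the companion PCA-LDA model
#'
#' The six key wavenumbers reported by the PCA-LDA analysis of the same kind
#' of data, in their published (descending) order. Consumed as a fixed
#' reference input by the concordance stage; never re-fitted here.
#'
#' @return Numeric vector `c(1678, 1653, 1628, 1574, 1242, 1020)` (cm^-1).
#' @export
pcaLdaReference <- function() c(1678, 1653, 1628, 1574, 1242, 1020)

#' Annotation built from synthetic ground truth
#'
#' Builds a [ReferenceAnnotation] whose important intervals are the planted
#' discriminating band centers +/- one resolution element, for end-to-end
#' recovery checks on synthetic data.
#'
#' @param truth The `GroundTruth` returned by [generateDataset()].
#' @param resolution Tolerance half-width in cm^-1 (default 4).
#' @return A [ReferenceAnnotation].
#' @export
truthAnnotation <- function(truth, resolution = 4) {
  stopifnot(inherits(truth, "GroundTruth"))
  keys <- truth$planted_wavenumbers
  referenceAnnotation(important = cbind(keys - resolution, keys + resolution),
                      referenceKeys = keys, resolution = resolution)
}
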