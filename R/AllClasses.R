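#' SpectraSet: a labelled FTIR spectral dataset
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' set of infrared absorbance spectra with per-spectrum class and donor
#' metadata. Following Bioconductor convention the assay matrix stores
#' *wavenumbers in rows* and *spectra in columns*; the constructor accepts the
#' interchange layout (spectra in rows) and transposes.
#'
#' Invariants enforced by the validity method:
#' * the wavenumber grid (`rowData(x)$wavenumber`) is strictly increasing,
#'   finite, with no duplicates;
#' * every spectrum carries a unique id, a `patient_id` and a `label` that is
#'   exactly `"T"` (lesion underwent malignant transformation) or `"NT"`
#'   (did not);
#' * all absorbance values are finite.
#'
#' The spectral resolution (cm^-1, default 4) is kept in
#' `metadata(x)$resolution` and used downstream as the wavenumber-matching
#' tolerance.
#'
#' @param absorbance Numeric matrix, one row per spectrum, one column per
#'   wavenumber (dimensionless absorbance units).
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, one per column
#'   of `absorbance`. Need not be sorted; columns are reordered ascending.
#' @param spectrumIds Character vector of unique spectrum identifiers.
#' @param patientIds Character vector of donor identifiers, one per spectrum.
#' @param labels Character vector of class labels, each `"T"` or `"NT"`.
#' @param resolution Spectral resolution in cm^-1 (default 4).
#'
#' @return A `SpectraSet`.
#' @seealso [readSpectra()], [generateDataset()], [wavenumbers()],
#'   [absorbance()], [classLabels()]
#' @examples
#' a <- matrix(c(0.5, 0.6, 0.4, 0.5), nrow = 2)
#' ss <- SpectraSet(a, c(1000, 1004), c("s1", "s2"), c("p1", "p1"),
#'                  c("T", "NT"))
#' wavenumbers(ss)
#' @aliases SpectraSet-class
#' @export
SpectraSet <- function(absorbance, wavenumbers, spectrumIds, patientIds,
                       labels, resolution = 4) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  spectrumIds <- as.character(spectrumIds)
  patientIds <- as.character(patientIds)
  labels <- as.character(labels)
  if (ncol(absorbance) != length(wavenumbers))
    stop("absorbance has ", ncol(absorbance), " columns but ",
         length(wavenumbers), " wavenumbers were given")
  n <- nrow(absorbance)
  if (length(spectrumIds) != n || length(patientIds) != n ||
      length(labels) != n)
    stop("spectrumIds, patientIds and labels must each have one entry per ",
         "spectrum (", n, ")")
  dup <- unique(spectrumIds[duplicated(spectrumIds)])
  if (length(dup))
    stop("duplicate spectrum id(s): ", paste(dup, collapse = ", "))
  bad <- spectrumIds[!labels %in% c("T", "NT")]
  if (length(bad))
    stop("label must be 'T' or 'NT'; offending spectrum id(s): ",
         paste(bad, collapse = ", "))
  o <- order(wavenumbers)
  a <- t(absorbance)[o, , drop = FALSE]
  dimnames(a) <- list(NULL, spectrumIds)
  se <- SummarizedExperiment(
    assays = list(absorbance = a),
    rowData = DataFrame(wavenumber = wavenumbers[o]),
    colData = DataFrame(spectrum_id = spectrumIds, patient_id = patientIds,
                        label = labels, row.names = spectrumIds)
  )
  metadata(se)$resolution <- as.numeric(resolution)
  new("SpectraSet", se)
}

#' @exportClass SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"absorbance" %in% assayNames(object))
    return("assay 'absorbance' is missing")
  wn <- rowData(object)$wavenumber
  if (is.null(wn)) {
    msg <- c(msg, "rowData must contain a 'wavenumber' column")
  } else {
    if (any(!is.finite(wn)))
      msg <- c(msg, "wavenumbers must all be finite")
    else if (length(wn) > 1 && any(diff(wn) <= 0))
      msg <- c(msg, "wavenumbers must be strictly increasing (no duplicates)")
  }
  cd <- colData(object)
  for (col in c("spectrum_id", "patient_id", "label"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData must contain a '%s' column", col))
  if ("label" %in% colnames(cd) && !all(cd$label %in% c("T", "NT")))
    msg <- c(msg, "every label must be exactly 'T' or 'NT'")
  if ("spectrum_id" %in% colnames(cd) && anyDuplicated(cd$spectrum_id))
    msg <- c(msg, "spectrum ids must be unique")
  if (ncol(object) > 0 && any(!is.finite(assay(object, "absorbance"))))
    msg <- c(msg, "all absorbance values must be finite")
  res <- metadata(object)$resolution
  if (is.null(res) || !is.numeric(res) || length(res) != 1 || res <= 0)
    msg <- c(msg, "metadata resolution must be a positive number")
  if (length(msg)) msg else TRUE
})

#' TrainedMetrics: a batch of trained absorbance-ratio metrics
#'
#' Produced by [trainMetrics()]. One row of the metric table per wavenumber
#' pair, holding per-class ratio statistics, the trained decision threshold,
#' the polarity (which class lies above the threshold), the training balanced
#' accuracy, and — after [scoreMetrics()] — the test-set discrimination score.
#' See [metricTable()] for the column layout.
#'
#' @slot table `data.frame` of per-metric parameters.
#' @slot grid Numeric wavenumber grid the pair indices refer to.
#' @slot scored Logical; `TRUE` once test-set scores have been filled in.
#' @aliases TrainedMetrics
#' @exportClass TrainedMetrics
setClass("TrainedMetrics",
         slots = c(table = "data.frame", grid = "numeric", scored = "logical"),
         prototype = prototype(scored = FALSE))

setValidity("TrainedMetrics", function(object) {
  need <- c("i", "j", "wn_num", "wn_den", "n_T", "n_NT", "mean_T", "mean_NT",
            "sd_T", "sd_NT", "threshold", "polarity", "train_ba", "trainable",
            "score")
  missing <- setdiff(need, colnames(object@table))
  if (length(missing))
    return(paste("metric table lacks column(s):",
                 paste(missing, collapse = ", ")))
  if (nrow(object@table)) {
    if (any(object@table$i >= object@table$j))
      return("metric pairs must be canonical (i < j)")
    if (max(object@table$j) > length(object@grid))
      return("metric indices exceed the wavenumber grid")
    sc <- object@table$score
    if (any(!is.na(sc) & (sc < 0 | sc > 1)))
      return("scores must lie in [0, 1]")
  }
  TRUE
})

#' MetricRanking: the selected top-N metrics
#'
#' A [TrainedMetrics] whose table is restricted to the `nTop` best metrics in
#' descending score order (ties broken by class-mean separation, then by
#' canonical pair order). Produced by [rankAndSelect()]; consumed by
#' [classifySpectra()] and [wavenumberHistogram()].
#'
#' @slot nTop Integer selection size (default pipeline value 150).
#' @aliases MetricRanking
#' @exportClass MetricRanking
setClass("MetricRanking", contains = "TrainedMetrics",
         slots = c(nTop = "integer"))

#' RunResult: one train/test/validate pass
#'
#' Validation-set performance of a single pipeline pass, with the metric
#' ranking that produced it. Precision is `NA` when no spectrum was predicted
#' `T`.
#'
#' @slot repeatIndex Integer index of the repeat.
#' @slot sensitivity,specificity,precision Fractions in \[0, 1\]
#'   (precision may be `NA`).
#' @slot ranking The selected [MetricRanking].
#' @slot seed Integer seed used for the split.
#' @aliases RunResult
#' @exportClass RunResult
setClass("RunResult",
         slots = c(repeatIndex = "integer", sensitivity = "numeric",
                   specificity = "numeric", precision = "numeric",
                   ranking = "MetricRanking", seed = "integer"))

#' AggregateResult: repeated-run performance summary
#'
#' Holds the per-repeat [RunResult]s of [runRepeated()]. Use
#' [performanceTable()] for the mean ± sd summary and [runResults()] for the
#' individual runs.
#'
#' @slot runs List of [RunResult].
#' @slot nRepeats Integer number of repeats.
#' @aliases AggregateResult
#' @exportClass AggregateResult
setClass("AggregateResult",
         slots = c(runs = "list", nRepeats = "integer"))

setValidity("AggregateResult", function(object) {
  if (length(object@runs) != object@nRepeats)
    return("nRepeats must equal the number of stored runs")
  if (!all(vapply(object@runs, is, TRUE, class2 = "RunResult")))
    return("runs must all be RunResult objects")
  TRUE
})

#' WavenumberHistogram: frequency of wavenumbers among selected metrics
#'
#' Counts how often each grid wavenumber appears among the top-ranked metrics
#' (both members of every selected pair are counted), optionally annotated
#' with a category per wavenumber: `"discriminating"` (within a reference
#' model's important intervals, expanded by the spectral resolution),
#' `"reference"` (within a neutral interval: a wavenumber that carries little
#' class information but serves as a ratio denominator), or `"unassigned"`.
#'
#' @slot grid Numeric wavenumber grid (cm^-1).
#' @slot counts Non-negative counts, one per grid point.
#' @slot category Character category per grid point.
#' @aliases WavenumberHistogram
#' @exportClass WavenumberHistogram
setClass("WavenumberHistogram",
         slots = c(grid = "numeric", counts = "numeric",
                   category = "character"))

setValidity("WavenumberHistogram", function(object) {
  if (length(object@counts) != length(object@grid) ||
      length(object@category) != length(object@grid))
    return("grid, counts and category must have equal length")
  if (any(object@counts < 0))
    return("counts must be non-negative")
  if (!all(object@category %in% c("discriminating", "reference", "unassigned")))
    return("categories must be discriminating/reference/unassigned")
  TRUE
})

#' ReferenceAnnotation: a reference model's spectral regions
#'
#' User-supplied description of which wavenumber regions a reference model
#' (e.g. a PCA-LDA fit of the same data) weights as important and which it
#' treats as neutral, plus its list of key wavenumbers for concordance.
#' Construct with [referenceAnnotation()] or [defaultAnnotation()].
#'
#' @slot important Two-column matrix (lo, hi) of important intervals, cm^-1.
#' @slot neutral Two-column matrix (lo, hi) of neutral intervals, cm^-1.
#' @slot referenceKeys Numeric reference key wavenumbers, cm^-1.
#' @slot resolution Spectral resolution in cm^-1 used as match tolerance.
#' @aliases ReferenceAnnotation
#' @exportClass ReferenceAnnotation
setClass("ReferenceAnnotation",
         slots = c(important = "matrix", neutral = "matrix",
                   referenceKeys = "numeric", resolution = "numeric"))

setValidity("ReferenceAnnotation", function(object) {
  for (nm in c("important", "neutral")) {
    m <- slot(object, nm)
    if (ncol(m) != 2) return(sprintf("%s must have two columns (lo, hi)", nm))
    if (nrow(m) && any(m[, 1] > m[, 2]))
      return(sprintf("%s intervals must satisfy lo <= hi", nm))
  }
  if (length(object@resolution) != 1 || object@resolution <= 0)
    return("resolution must be a positive scalar")
  TRUE
})
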