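# Generics for the SpectraSet accessors and downstream containers.

#' Accessors for SpectraSet
#'
#' @param x A [SpectraSet].
#' @return `wavenumbers()`: the ascending wavenumber grid (cm^-1);
#'   `absorbance()`: the absorbance matrix, wavenumbers × spectra;
#'   `spectrumIds()`, `patientIds()`, `classLabels()`: per-spectrum character
#'   vectors; `spectralResolution()`: the resolution in cm^-1.
#' @name SpectraSet-accessors
#' @aliases wavenumbers absorbance spectrumIds patientIds classLabels
#'   spectralResolution
#' @examples
#' ds <- generateDataset(defaultConfig(1))$dataset
#' head(wavenumbers(ds))
#' table(classLabels(ds))
NULL

#' @rdname SpectraSet-accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("spectrumIds", function(x) standardGeneric("spectrumIds"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("spectralResolution",
           function(x) standardGeneric("spectralResolution"))

#' Extract the per-metric parameter table
#'
#' @param x A [TrainedMetrics] or [MetricRanking].
#' @return A `data.frame` with one row per metric: grid indices `i < j`,
#'   wavenumbers `wn_num` / `wn_den` (cm^-1), per-class defined-ratio counts
#'   `n_T` / `n_NT`, ratio means and sds, the decision `threshold`,
#'   `polarity` (`"T"` or `"NT"`: the class whose ratios lie above the
#'   threshold), training balanced accuracy `train_ba`, logical `trainable`,
#'   and the test-set `score` (NA before [scoreMetrics()]).
#' @export
setGeneric("metricTable", function(x) standardGeneric("metricTable"))

#' @rdname AggregateResult-class
#' @param x An [AggregateResult].
#' @export
setGeneric("runResults", function(x) standardGeneric("runResults"))

setMethod("wavenumbers", "SpectraSet", function(x) rowData(x)$wavenumber)
setMethod("absorbance", "SpectraSet", function(x) assay(x, "absorbance"))
setMethod("spectrumIds", "SpectraSet", function(x) colData(x)$spectrum_id)
setMethod("patientIds", "SpectraSet", function(x) colData(x)$patient_id)
setMethod("classLabels", "SpectraSet", function(x) colData(x)$label)
setMethod("spectralResolution", "SpectraSet",
          function(x) metadata(x)$resolution)

setMethod("metricTable", "TrainedMetrics", function(x) x@table)
setMethod("runResults", "AggregateResult", function(x) x@runs)

setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  cat(sprintf("SpectraSet: %d spectra x %d wavenumbers", ncol(object),
              nrow(object)))
  if (length(wn))
    cat(sprintf(" (%.6g-%.6g cm^-1, resolution %g cm^-1)", min(wn), max(wn),
                spectralResolution(object)))
  cat("\n")
  if (ncol(object)) {
    lab <- classLabels(object)
    cat(sprintf("  classes: T = %d, NT = %d; patients: %d\n",
                sum(lab == "T"), sum(lab == "NT"),
                length(unique(patientIds(object)))))
  }
  invisible(NULL)
})

setMethod("show", "TrainedMetrics", function(object) {
  tbl <- object@table
  cat(sprintf("TrainedMetrics: %d metrics (%d trainable) on a %d-point grid",
              nrow(tbl), sum(tbl$trainable), length(object@grid)), "\n")
  cat(if (object@scored) "  scored on a test set\n" else "  not yet scored\n")
  invisible(NULL)
})

setMethod("show", "MetricRanking", function(object) {
  tbl <- object@table
  cat(sprintf("MetricRanking: top %d metrics\n", object@nTop))
  n <- min(5L, nrow(tbl))
  if (n) {
    hd <- tbl[seq_len(n), c("wn_num", "wn_den", "score", "threshold",
                            "polarity")]
    rownames(hd) <- NULL
    print(hd)
    if (nrow(tbl) > n) cat(sprintf("  ... and %d more\n", nrow(tbl) - n))
  }
  invisible(NULL)
})

setMethod("show", "RunResult", function(object) {
  cat(sprintf(paste0("RunResult (repeat %d, seed %d): sensitivity %.3f, ",
                     "specificity %.3f, precision %s\n"),
              object@repeatIndex, object@seed, object@sensitivity,
              object@specificity,
              if (is.na(object@precision)) "undefined"
              else sprintf("%.3f", object@precision)))
  invisible(NULL)
})

setMethod("show", "AggregateResult", function(object) {
  cat(sprintf("AggregateResult over %d repeats\n", object@nRepeats))
  pt <- performanceTable(object)
  for (k in seq_len(nrow(pt)))
    cat(sprintf("  %-11s %s\n", pt$statistic[k],
                ifelse(is.na(pt$formatted[k]), "undefined", pt$formatted[k])))
  invisible(NULL)
})

setMethod("show", "WavenumberHistogram", function(object) {
  nz <- sum(object@counts > 0)
  cat(sprintf(paste0("WavenumberHistogram: %d grid points, %d with nonzero ",
                     "counts, total count %d\n"), length(object@grid), nz,
              as.integer(sum(object@counts))))
  tab <- table(factor(object@category[object@counts > 0],
                      levels = c("discriminating", "reference", "unassigned")))
  cat(sprintf("  nonzero bins: %d discriminating, %d reference, %d unassigned\n",
              tab[["discriminating"]], tab[["reference"]], tab[["unassigned"]]))
  invisible(NULL)
})
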