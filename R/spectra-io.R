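# Reading, writing, QC filtering and regridding of tabular spectral datasets.
#
# Interchange dialect: two comma-delimited UTF-8 files. The spectra file is a
# wide table with a leading spectrum-id column and one column per wavenumber,
# the header holding the wavenumbers as decimal cm^-1. The metadata file has
# columns spectrum_id, patient_id, label and defines the row order of the
# dataset.

#' Read a spectral dataset from delimited text
#'
#' Reads the wide spectra table and the metadata table and returns a
#' validated [SpectraSet]. Rows are arranged in metadata order and wavenumber
#' columns are sorted ascending regardless of file order.
#'
#' @param spectraPath Path to the spectra table: leading id column, then one
#'   numeric column per wavenumber with the wavenumber (cm^-1) as the column
#'   name.
#' @param metadataPath Path to the metadata table with columns
#'   `spectrum_id`, `patient_id`, `label` (each label `"T"` or `"NT"`).
#' @param resolution Spectral resolution in cm^-1 recorded on the dataset
#'   (default 4).
#' @return A [SpectraSet].
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(spectraPath, metadataPath, resolution = 4) {
  sp <- read.csv(spectraPath, check.names = FALSE, colClasses = "character")
  md <- read.csv(metadataPath, check.names = FALSE, colClasses = "character")
  need <- setdiff(c("spectrum_id", "patient_id", "label"), colnames(md))
  if (length(need))
    stop("metadata file lacks column(s): ", paste(need, collapse = ", "))
  if (ncol(sp) < 2)
    stop("spectra file must have an id column plus wavenumber columns")

  ids <- sp[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate spectrum id(s) in spectra file: ",
         paste(dup, collapse = ", "))
  dup <- unique(md$spectrum_id[duplicated(md$spectrum_id)])
  if (length(dup))
    stop("duplicate spectrum id(s) in metadata: ", paste(dup, collapse = ", "))
  miss <- setdiff(md$spectrum_id, ids)
  if (length(miss))
    stop("spectrum id(s) in metadata but missing from spectra file: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(ids, md$spectrum_id)
  if (length(extra))
    stop("spectrum id(s) in spectra file but missing from metadata: ",
         paste(extra, collapse = ", "))

  wn <- suppressWarnings(as.numeric(colnames(sp)[-1]))
  if (anyNA(wn))
    stop("non-numeric wavenumber column header(s): ",
         paste(colnames(sp)[-1][is.na(wn)], collapse = ", "))

  raw <- as.matrix(sp[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                 ncol = ncol(raw)))
  if (anyNA(num) && !all(is.na(raw[is.na(num)]))) {
    bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric absorbance value at spectrum '%s', wavenumber %s",
                 ids[bad[1]], colnames(sp)[-1][bad[2]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("missing absorbance value at spectrum '%s', wavenumber %s",
                 ids[bad[1]], colnames(sp)[-1][bad[2]]))
  }

  badLab <- md$spectrum_id[!md$label %in% c("T", "NT")]
  if (length(badLab))
    stop("label must be 'T' or 'NT'; offending spectrum id(s): ",
         paste(badLab, collapse = ", "))

  num <- num[match(md$spectrum_id, ids), , drop = FALSE]
  SpectraSet(num, wn, md$spectrum_id, md$patient_id, md$label,
             resolution = resolution)
}

#' Write a spectral dataset to delimited text
#'
#' Writes the two-file interchange format read by [readSpectra()]. Numeric
#' values are written with enough digits that a write/read round trip
#' reproduces the dataset to better than 1e-12 relative tolerance.
#'
#' @param x A [SpectraSet].
#' @param spectraPath,metadataPath Output file paths.
#' @return Invisibly, `NULL`.
#' @export
writeSpectra <- function(x, spectraPath, metadataPath) {
  stopifnot(is(x, "SpectraSet"))
  a <- t(absorbance(x))                       # spectra in rows for interchange
  df <- data.frame(spectrum_id = spectrumIds(x), stringsAsFactors = FALSE)
  vals <- as.data.frame(a)
  colnames(vals) <- sprintf("%.15g", wavenumbers(x))
  write.csv(cbind(df, vals), spectraPath, row.names = FALSE, quote = TRUE)
  md <- data.frame(spectrum_id = spectrumIds(x), patient_id = patientIds(x),
                   label = classLabels(x), stringsAsFactors = FALSE)
  write.csv(md, metadataPath, row.names = FALSE, quote = TRUE)
  invisible(NULL)
}

#' Quality-control parameters
#'
#' Bounds on the maximum absorbance inside a stated band, used by
#' [qualityFilter()] to reject empty or saturated spectra. The default band
#' is the Amide I region (1600-1700 cm^-1) with bounds \[0.1, 2.0\], a
#' standard coarse QC for FTIR tissue spectra. Filtering is not applied
#' anywhere unless requested.
#'
#' @param minPeakAbsorbance,maxPeakAbsorbance Lower/upper bound on the band
#'   maximum (dimensionless absorbance).
#' @param qcBand Length-2 numeric interval in cm^-1.
#' @return A list of class `QcParams`.
#' @export
qcParams <- function(minPeakAbsorbance = 0.1, maxPeakAbsorbance = 2.0,
                     qcBand = c(1600, 1700)) {
  if (!is.numeric(qcBand) || length(qcBand) != 2 || qcBand[1] >= qcBand[2])
    stop("qcBand must be an increasing length-2 interval in cm^-1")
  if (minPeakAbsorbance >= maxPeakAbsorbance)
    stop("minPeakAbsorbance must be smaller than maxPeakAbsorbance")
  structure(list(minPeakAbsorbance = minPeakAbsorbance,
                 maxPeakAbsorbance = maxPeakAbsorbance,
                 qcBand = as.numeric(qcBand)),
            class = "QcParams")
}

#' Filter spectra by peak absorbance in a QC band
#'
#' Retains spectra whose maximum absorbance inside `params$qcBand` lies in
#' `[minPeakAbsorbance, maxPeakAbsorbance]`; the order of survivors is
#' preserved.
#'
#' @param x A [SpectraSet].
#' @param params A [qcParams()] object.
#' @return A list with elements `dataset` (the filtered [SpectraSet]) and
#'   `rejected` (a `data.frame` of `spectrum_id` and the offending
#'   `peak_absorbance`).
#' @export
qualityFilter <- function(x, params = qcParams()) {
  stopifnot(is(x, "SpectraSet"), inherits(params, "QcParams"))
  wn <- wavenumbers(x)
  sel <- wn >= params$qcBand[1] & wn <= params$qcBand[2]
  if (!any(sel))
    stop("QC band [", params$qcBand[1], ", ", params$qcBand[2],
         "] cm^-1 does not overlap the wavenumber grid")
  a <- absorbance(x)[sel, , drop = FALSE]
  peak <- if (ncol(a)) apply(a, 2, max) else numeric(0)
  keep <- peak >= params$minPeakAbsorbance & peak <= params$maxPeakAbsorbance
  list(
    dataset = x[, keep],
    rejected = data.frame(spectrum_id = spectrumIds(x)[!keep],
                          peak_absorbance = unname(peak[!keep]),
                          stringsAsFactors = FALSE)
  )
}

#' Resample spectra onto a target wavenumber grid
#'
#' Linear interpolation of every spectrum onto `targetGrid`; metadata are
#' unchanged. No extrapolation: every target point must lie within the closed
#' span of the current grid.
#'
#' @param x A [SpectraSet].
#' @param targetGrid Strictly increasing numeric wavenumbers in cm^-1.
#' @return A [SpectraSet] on `targetGrid`.
#' @export
resampleToGrid <- function(x, targetGrid) {
  stopifnot(is(x, "SpectraSet"))
  targetGrid <- as.numeric(targetGrid)
  if (length(targetGrid) < 1 ||
      (length(targetGrid) > 1 && any(diff(targetGrid) <= 0)))
    stop("targetGrid must be non-empty and strictly increasing")
  wn <- wavenumbers(x)
  if (min(targetGrid) < min(wn) || max(targetGrid) > max(wn))
    stop(sprintf(paste0("target grid [%g, %g] extends beyond the data grid ",
                        "[%g, %g]; extrapolation is not supported"),
                 min(targetGrid), max(targetGrid), min(wn), max(wn)))
  if (length(targetGrid) == length(wn) &&
      all(abs(targetGrid - wn) <= 1e-6))
    return(x)
  a <- absorbance(x)
  out <- vapply(seq_len(ncol(a)),
                function(s) approx(wn, a[, s], xout = targetGrid)$y,
                numeric(length(targetGrid)))
  out <- matrix(out, nrow = length(targetGrid))
  SpectraSet(t(out), targetGrid, spectrumIds(x), patientIds(x),
             classLabels(x), resolution = spectralResolution(x))
}
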