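# Downstream reporting: wavenumber-frequency histograms of the selected
# metrics, three-way annotation against a reference model, grouping of
# neighbouring discriminating wavenumbers into key wavenumbers, and
# tolerance-based concordance with a reference key list.

#' Wavenumber-frequency histogram of selected metrics
#'
#' Counts how often each grid wavenumber appears among the selected top
#' metrics: every selected metric increments the count of *both* its
#' wavenumbers by one, so the counts always sum to twice the number of
#' selected metric instances. Rankings from multiple repeats are pooled.
#' Categories are initialised to `"unassigned"`; see [annotateHistogram()].
#'
#' @param rankings A [MetricRanking] or a list of them (one per repeat).
#' @param grid The wavenumber grid the rankings refer to.
#' @return A [WavenumberHistogram].
#' @export
wavenumberHistogram <- function(rankings, grid) {
  if (is(rankings, "MetricRanking")) rankings <- list(rankings)
  stopifnot(all(vapply(rankings, is, TRUE, class2 = "MetricRanking")))
  grid <- as.numeric(grid)
  counts <- numeric(length(grid))
  for (rk in rankings) {
    idx <- c(rk@table$i, rk@table$j)
    if (length(idx) && max(idx) > length(grid))
      stop("ranking indices exceed the wavenumber grid")
    counts <- counts + tabulate(idx, nbins = length(grid))
  }
  new("WavenumberHistogram", grid = grid, counts = counts,
      category = rep("unassigned", length(grid)))
}

#' Construct a reference-model annotation
#'
#' @param important Two-column matrix (lo, hi) of intervals, cm^-1, where the
#'   reference model carries positively or negatively weighted features; or
#'   `NULL` for none.
#' @param neutral Two-column matrix of intervals the reference model treats
#'   as neutral; or `NULL`.
#' @param referenceKeys Numeric key wavenumbers of the reference model.
#' @param resolution Spectral resolution in cm^-1 (default 4), used to expand
#'   important intervals when annotating and as the default concordance
#'   tolerance.
#' @return A [ReferenceAnnotation].
#' @export
referenceAnnotation <- function(important = NULL, neutral = NULL,
                                referenceKeys = numeric(), resolution = 4) {
  asIntervals <- function(m) {
    if (is.null(m)) return(matrix(numeric(0), ncol = 2))
    m <- as.matrix(m)
    if (ncol(m) != 2) stop("intervals must be a two-column (lo, hi) matrix")
    unname(m)
  }
  new("ReferenceAnnotation", important = asIntervals(important),
      neutral = asIntervals(neutral),
      referenceKeys = as.numeric(referenceKeys),
      resolution = as.numeric(resolution))
}

#' Packaged default annotation
#'
#' Encodes the companion PCA-LDA model's key wavenumbers
#' ([pcaLdaReference()]) +/- one resolution element as important intervals.
#' Neutral regions are not published as intervals and are left empty; supply
#' them via [referenceAnnotation()] when available.
#'
#' @param resolution Spectral resolution in cm^-1 (default 4).
#' @return A [ReferenceAnnotation].
#' @export
defaultAnnotation <- function(resolution = 4) {
  keys <- pcaLdaReference()
  referenceAnnotation(important = cbind(keys - resolution, keys + resolution),
                      referenceKeys = keys, resolution = resolution)
}

inAnyInterval <- function(x, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (k in seq_len(nrow(intervals)))
    hit <- hit | (x >= intervals[k, 1] & x <= intervals[k, 2])
  hit
}

#' Annotate a histogram against a reference model
#'
#' Assigns each grid wavenumber exactly one category: `"discriminating"` if
#' it lies within any important interval expanded by +/- the annotation's
#' resolution, else `"reference"` if within any neutral interval, else
#' `"unassigned"`. Counts are unchanged. Overlaps resolve to important, with
#' a warning.
#'
#' @param hist A [WavenumberHistogram].
#' @param ann A [ReferenceAnnotation].
#' @return The annotated [WavenumberHistogram].
#' @export
annotateHistogram <- function(hist, ann) {
  stopifnot(is(hist, "WavenumberHistogram"), is(ann, "ReferenceAnnotation"))
  expanded <- ann@important
  if (nrow(expanded)) {
    expanded[, 1] <- expanded[, 1] - ann@resolution
    expanded[, 2] <- expanded[, 2] + ann@resolution
  }
  imp <- inAnyInterval(hist@grid, expanded)
  neu <- inAnyInterval(hist@grid, ann@neutral)
  if (any(imp & neu))
    warning("important and neutral intervals overlap at ",
            sum(imp & neu), " grid point(s); important takes precedence")
  category <- rep("unassigned", length(hist@grid))
  category[neu] <- "reference"
  category[imp] <- "discriminating"
  hist@category <- category
  hist
}

#' Group neighbouring discriminating wavenumbers into key wavenumbers
#'
#' Restricts the histogram to discriminating wavenumbers with nonzero
#' counts, partitions them into maximal runs in which consecutive members
#' are at most `gap` cm^-1 apart, and reports each group's count-weighted
#' mean wavenumber, descending.
#'
#' @param hist An annotated [WavenumberHistogram].
#' @param gap Maximum within-group neighbour spacing in cm^-1 (default 4,
#'   one resolution element).
#' @return Numeric key wavenumbers in descending order (empty when no
#'   discriminating wavenumber has a count).
#' @export
groupKeyWavenumbers <- function(hist, gap = 4) {
  stopifnot(is(hist, "WavenumberHistogram"))
  sel <- hist@category == "discriminating" & hist@counts > 0
  if (!any(sel)) return(numeric(0))
  wn <- hist@grid[sel]
  ct <- hist@counts[sel]
  grp <- cumsum(c(1, diff(wn) > gap))
  keys <- vapply(split(seq_along(wn), grp),
                 function(ii) weighted.mean(wn[ii], ct[ii]), numeric(1))
  sort(unname(keys), decreasing = TRUE)
}

#' Concordance of two key-wavenumber lists
#'
#' Greedy nearest-pair matching: repeatedly match the globally closest
#' unmatched (mla, reference) pair whose difference is at most `tolerance`;
#' remaining keys become one-sided rows. Deterministic (ties resolve to the
#' earlier key in each supplied list).
#'
#' @param mlaKeys Key wavenumbers found by the metric pipeline, cm^-1.
#' @param referenceKeys Reference key wavenumbers, cm^-1.
#' @param tolerance Maximum matched difference in cm^-1 (default 4, one
#'   resolution element; use twice the resolution to reproduce the broader
#'   "comparable to the spectral resolution" reading).
#' @return A `data.frame` with columns `mla_key`, `reference_key` (NA for
#'   one-sided rows), `difference` and logical `matched`, ordered by
#'   descending wavenumber.
#' @export
concordanceTable <- function(mlaKeys, referenceKeys, tolerance = 4) {
  if (tolerance < 0) stop("tolerance must be non-negative")
  mla <- as.numeric(mlaKeys)
  ref <- as.numeric(referenceKeys)
  pair <- matrix(integer(0), ncol = 2)
  if (length(mla) && length(ref)) {
    d <- abs(outer(mla, ref, "-"))
    openM <- rep(TRUE, length(mla))
    openR <- rep(TRUE, length(ref))
    repeat {
      dd <- d
      dd[!openM, ] <- Inf
      dd[, !openR] <- Inf
      if (all(!is.finite(dd)) || min(dd) > tolerance) break
      hit <- which(dd == min(dd), arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
      pair <- rbind(pair, hit)
      openM[hit[1]] <- FALSE
      openR[hit[2]] <- FALSE
    }
  }
  rows <- data.frame(mla_key = numeric(0), reference_key = numeric(0),
                     difference = numeric(0), matched = logical(0))
  if (nrow(pair))
    rows <- data.frame(mla_key = mla[pair[, 1]],
                       reference_key = ref[pair[, 2]],
                       difference = abs(mla[pair[, 1]] - ref[pair[, 2]]),
                       matched = TRUE)
  um <- setdiff(seq_along(mla), pair[, 1])
  if (length(um))
    rows <- rbind(rows, data.frame(mla_key = mla[um], reference_key = NA_real_,
                                   difference = NA_real_, matched = FALSE))
  ur <- setdiff(seq_along(ref), pair[, 2])
  if (length(ur))
    rows <- rbind(rows, data.frame(mla_key = NA_real_, reference_key = ref[ur],
                                   difference = NA_real_, matched = FALSE))
  key <- ifelse(is.na(rows$mla_key), rows$reference_key, rows$mla_key)
  rows <- rows[order(-key), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Plot a wavenumber histogram
#'
#' Basic bar rendering with the conventional colouring: green for
#' discriminating, blue for reference, grey for unassigned wavenumbers.
#'
#' @param x A [WavenumberHistogram].
#' @param y Ignored.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
setMethod("plot", signature(x = "WavenumberHistogram", y = "missing"),
          function(x, y, ...) {
  col <- c(discriminating = "forestgreen", reference = "steelblue",
           unassigned = "grey60")[x@category]
  mids <- barplot(x@counts, col = col, border = NA,
                  names.arg = round(x@grid),
                  xlab = expression(wavenumber ~ (cm^-1)),
                  ylab = "count in top metrics", ...)
  legend("topright", fill = c("forestgreen", "steelblue", "grey60"),
         legend = c("discriminating", "reference", "unassigned"),
         bty = "n")
  invisible(mids)
})
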