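# The metric-engine core: stratified splitting, metric enumeration, threshold training
# on ratio distributions, test-set scoring, top-N selection and ensemble
# classification.

#' Split configuration
#'
#' Controls the random three-way division of a dataset into training,
#' testing and validation subsets. By default the split is stratified by
#' class (T and NT treated as two separate subsets) with fractions
#' 60/20/20, at the individual-spectrum level. `groupByPatient = TRUE`
#' instead assigns whole patients to subsets, which prevents spectra of one
#' donor from straddling the split.
#'
#' @param fractions Numeric (train, test, validation), each in (0, 1),
#'   summing to 1 within 1e-9.
#' @param stratifyByClass Stratify by class label (default `TRUE`).
#' @param groupByPatient Assign whole patients rather than spectra
#'   (default `FALSE`).
#' @param seed Integer RNG seed for the assignment.
#' @return A list of class `SplitConfig`.
#' @export
splitConfig <- function(fractions = c(train = 0.6, test = 0.2,
                                      validation = 0.2),
                        stratifyByClass = TRUE, groupByPatient = FALSE,
                        seed = 1) {
  if (length(fractions) != 3 || any(fractions <= 0) || any(fractions >= 1))
    stop("fractions must be three values, each strictly inside (0, 1)")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1")
  names(fractions) <- c("train", "test", "validation")
  structure(list(fractions = fractions, stratifyByClass = stratifyByClass,
                 groupByPatient = groupByPatient, seed = as.integer(seed)),
            class = "SplitConfig")
}

#' Split a dataset into training, testing and validation subsets
#'
#' Randomly partitions the spectra per stratum with largest-remainder
#' rounding, so that per-class subset sizes are the rounded fractions and sum
#' exactly to the class size. Reproducible from `config$seed`.
#'
#' @param x A [SpectraSet]; each class must have at least 3 spectra.
#' @param config A [splitConfig()].
#' @return A list of three [SpectraSet]s: `train`, `test`, `validation`.
#'   Together they partition `x`.
#' @export
splitDataset <- function(x, config = splitConfig()) {
  stopifnot(is(x, "SpectraSet"), inherits(config, "SplitConfig"))
  labs <- classLabels(x)
  strata <- if (config$stratifyByClass) {
    lapply(c("T", "NT"), function(cl) which(labs == cl))
  } else list(seq_along(labs))
  assignment <- rep(NA_integer_, length(labs))   # 1 train, 2 test, 3 val
  withSeed(config$seed, {
    for (idx in strata) {
      if (length(idx) < 3)
        stop("stratification error: a class has fewer than 3 spectra (",
             length(idx), ")")
      if (config$groupByPatient) {
        units <- unique(patientIds(x)[idx])
        perm <- sample(units)
        sizes <- largestRemainder(length(units), config$fractions)
        unitSubset <- rep(1:3, sizes)
        assignment[idx] <- unitSubset[match(patientIds(x)[idx], perm)]
      } else {
        perm <- sample(idx)
        sizes <- largestRemainder(length(idx), config$fractions)
        assignment[perm] <- rep(1:3, sizes)
      }
    }
  })
  list(train = x[, which(assignment == 1)],
       test = x[, which(assignment == 2)],
       validation = x[, which(assignment == 3)])
}

#' Enumerate all wavenumber-pair metrics
#'
#' All C(n, 2) canonical unordered pairs of grid indices, in lexicographic
#' order. A ratio and its reciprocal carry the same discrimination
#' information, so only pairs with `i < j` are kept.
#'
#' @param gridSize Number of wavenumbers (>= 2).
#' @return Integer matrix with columns `i`, `j` (1-based grid indices,
#'   `i < j`), one row per metric.
#' @examples
#' nrow(enumerateMetrics(317))  # 50086
#' @export
enumerateMetrics <- function(gridSize) {
  gridSize <- as.integer(gridSize)
  if (is.na(gridSize) || gridSize < 2)
    stop("gridSize must be an integer >= 2")
  i <- rep.int(seq_len(gridSize - 1L), (gridSize - 1L):1L)
  j <- sequence((gridSize - 1L):1L, from = 2:gridSize)
  cbind(i = i, j = j)
}

#' Absorbance ratio of a metric on one spectrum
#'
#' `A[i] / A[j]` for the pair `(i, j)`, or `NA` when the denominator
#' absorbance is smaller in magnitude than `epsilon` (an undefined ratio is a
#' value, not an error; it abstains in voting and counts as misclassified in
#' scoring).
#'
#' @param spectrum Numeric absorbance vector.
#' @param metric Length-2 integer vector of grid indices (numerator,
#'   denominator), or a two-column matrix of pairs.
#' @param epsilon Denominator guard in absorbance units (default 1e-6).
#' @return Numeric ratio(s); `NA` where undefined.
#' @export
metricValue <- function(spectrum, metric, epsilon = 1e-6) {
  m <- if (is.matrix(metric)) metric else matrix(metric, ncol = 2)
  num <- spectrum[m[, 1]]
  den <- spectrum[m[, 2]]
  ifelse(abs(den) >= epsilon, num / den, NA_real_)
}

#' Train ratio metrics on a training subset
#'
#' For every wavenumber pair, computes the per-class mean and sd of the
#' defined absorbance ratios and fits the decision rule: polarity is the
#' class with the higher ratio mean, and the threshold is the cut maximising
#' balanced accuracy over the training ratios (midpoints between adjacent
#' distinct sorted ratios, plus a cut below all of them; ties resolved to the
#' lowest cut). A metric with fewer than two defined ratios in either class
#' is marked untrainable and excluded downstream.
#'
#' @param train A [SpectraSet] containing both classes.
#' @param pairs Integer two-column matrix of grid-index pairs; by default all
#'   pairs from [enumerateMetrics()].
#' @param epsilon Denominator guard (default 1e-6).
#' @return A [TrainedMetrics].
#' @export
trainMetrics <- function(train, pairs = NULL, epsilon = 1e-6) {
  stopifnot(is(train, "SpectraSet"))
  labs <- classLabels(train)
  if (!all(c("T", "NT") %in% labs))
    stop("training set must contain both classes")
  wn <- wavenumbers(train)
  if (is.null(pairs)) pairs <- enumerateMetrics(length(wn))
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs) && (min(pairs) < 1 || max(pairs) > length(wn)))
    stop("pair indices must lie within the wavenumber grid")
  if (any(pairs[, 1] >= pairs[, 2]))
    stop("pairs must be canonical (i < j)")
  res <- cpp_train_metrics(t(absorbance(train)), as.integer(labs == "T"),
                           pairs, epsilon)
  tbl <- data.frame(
    i = pairs[, 1], j = pairs[, 2],
    wn_num = wn[pairs[, 1]], wn_den = wn[pairs[, 2]],
    n_T = as.integer(res[, 5]), n_NT = as.integer(res[, 6]),
    mean_T = res[, 1], mean_NT = res[, 2],
    sd_T = res[, 3], sd_NT = res[, 4],
    threshold = res[, 7],
    polarity = ifelse(is.na(res[, 8]), NA_character_,
                      ifelse(res[, 8] == 1, "T", "NT")),
    train_ba = res[, 9],
    trainable = res[, 10] == 1,
    score = NA_real_,
    stringsAsFactors = FALSE
  )
  new("TrainedMetrics", table = tbl, grid = wn, scored = FALSE)
}

#' Score trained metrics on a testing subset
#'
#' The score of a metric is the balanced accuracy of its threshold/polarity
#' rule on the test spectra; undefined ratios count as misclassified.
#' Untrainable metrics keep an `NA` score.
#'
#' @param tm A [TrainedMetrics] from [trainMetrics()].
#' @param test A [SpectraSet] containing both classes, on the same
#'   wavenumber grid.
#' @param epsilon Denominator guard (default 1e-6).
#' @return `tm` with the `score` column filled (each in \[0, 1\]).
#' @export
scoreMetrics <- function(tm, test, epsilon = 1e-6) {
  stopifnot(is(tm, "TrainedMetrics"), is(test, "SpectraSet"))
  labs <- classLabels(test)
  if (!all(c("T", "NT") %in% labs))
    stop("scoring error: test set must contain both classes")
  wn <- wavenumbers(test)
  if (length(wn) != length(tm@grid) || any(abs(wn - tm@grid) > 1e-6))
    stop("test set is not on the training wavenumber grid")
  tbl <- tm@table
  hiT <- ifelse(is.na(tbl$polarity), 0L, as.integer(tbl$polarity == "T"))
  sc <- cpp_score_metrics(t(absorbance(test)), as.integer(labs == "T"),
                          cbind(tbl$i, tbl$j), tbl$threshold, hiT,
                          tbl$trainable, epsilon)
  tm@table$score <- sc
  tm@scored <- TRUE
  tm
}

# Standardised class-mean separation used as the ranking tie-break.
metricSeparation <- function(tbl) {
  pooled <- sqrt((tbl$sd_T^2 + tbl$sd_NT^2) / 2)
  gap <- abs(tbl$mean_T - tbl$mean_NT)
  sep <- gap / pooled
  sep[pooled == 0 & gap > 0] <- Inf
  sep[pooled == 0 & gap == 0] <- 0
  sep
}

#' Select the top-N metrics by score
#'
#' Orders trainable metrics by descending test score, breaking ties by the
#' larger standardised class-mean separation
#' `|mean_T - mean_NT| / sqrt((sd_T^2 + sd_NT^2) / 2)` and then by canonical
#' pair order, and keeps the first `nTop`.
#'
#' @param tm A scored [TrainedMetrics].
#' @param nTop Selection size (default 150); must not exceed the number of
#'   trainable metrics.
#' @return A [MetricRanking].
#' @export
rankAndSelect <- function(tm, nTop = 150) {
  stopifnot(is(tm, "TrainedMetrics"))
  if (!tm@scored)
    stop("metrics must be scored before ranking (see scoreMetrics)")
  tbl <- tm@table[tm@table$trainable, , drop = FALSE]
  if (nTop > nrow(tbl))
    stop("selection error: nTop (", nTop, ") exceeds the ", nrow(tbl),
         " trainable metrics")
  o <- order(-tbl$score, -metricSeparation(tbl), tbl$i, tbl$j)
  sel <- tbl[o[seq_len(nTop)], , drop = FALSE]
  rownames(sel) <- NULL
  new("MetricRanking", table = sel, grid = tm@grid, scored = TRUE,
      nTop = as.integer(nTop))
}

#' Classify spectra by score-weighted metric voting
#'
#' Each selected metric votes for the class indicated by its
#' threshold/polarity rule, weighted by its score; an undefined ratio
#' abstains. The predicted label is the class with the larger vote sum, with
#' exact ties resolved to `NT` (a tie never asserts malignancy). A spectrum
#' on which every metric abstains is unclassifiable (`NA`), counted as
#' misclassified by [evaluatePredictions()].
#'
#' @param x A [SpectraSet] on the ranking's grid, or a numeric absorbance
#'   matrix (wavenumbers × spectra), or a single absorbance vector.
#' @param ranking A non-empty [MetricRanking].
#' @param epsilon Denominator guard (default 1e-6).
#' @return Character vector of `"T"` / `"NT"` / `NA` per spectrum.
#' @export
classifySpectra <- function(x, ranking, epsilon = 1e-6) {
  stopifnot(is(ranking, "MetricRanking"))
  tbl <- ranking@table
  if (!nrow(tbl)) stop("ranking is empty")
  a <- if (is(x, "SpectraSet")) {
    wn <- wavenumbers(x)
    if (length(wn) != length(ranking@grid) ||
        any(abs(wn - ranking@grid) > 1e-6))
      stop("spectra are not on the ranking's wavenumber grid")
    absorbance(x)
  } else if (is.matrix(x)) x else matrix(x, ncol = 1)
  num <- a[tbl$i, , drop = FALSE]
  den <- a[tbl$j, , drop = FALSE]
  defined <- abs(den) >= epsilon
  above <- (num / den) > tbl$threshold       # threshold recycles by metric row
  voteT <- (tbl$polarity == "T") == above
  w <- tbl$score
  wT <- colSums(w * (voteT & defined))
  wNT <- colSums(w * (!voteT & defined))
  ifelse(wT + wNT == 0, NA_character_, ifelse(wT > wNT, "T", "NT"))
}

#' Sensitivity, specificity and precision of predicted labels
#'
#' With T as the positive class: sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP). Unclassifiable (`NA`) predictions count
#' as wrong for their true class; precision is `NA` when nothing was
#' predicted `T`.
#'
#' @param predicted Character labels (`"T"`, `"NT"`, `NA`).
#' @param truth Character labels; must contain both classes.
#' @return Named numeric vector `sensitivity`, `specificity`, `precision`.
#' @export
evaluatePredictions <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!all(c("T", "NT") %in% truth))
    stop("truth must contain both classes")
  predT <- !is.na(predicted) & predicted == "T"
  predNT <- !is.na(predicted) & predicted == "NT"
  tp <- sum(predT & truth == "T")
  fp <- sum(predT & truth == "NT")
  tn <- sum(predNT & truth == "NT")
  c(sensitivity = tp / sum(truth == "T"),
    specificity = tn / sum(truth == "NT"),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
}
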