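# Orchestration: one full train -> test -> select -> validate pass, its
# ten-fold repetition with re-randomised splits, and mean +/- sd aggregation.

#' One full pipeline pass
#'
#' Splits the dataset per `split`, trains every wavenumber-pair metric on the
#' training subset, scores each on the testing subset, selects the top
#' `nTop`, classifies every validation spectrum by weighted voting and
#' returns the validation rates. Deterministic given `(x, split, nTop)`.
#'
#' @param x A [SpectraSet] containing both classes.
#' @param split A [splitConfig()].
#' @param nTop Number of metrics selected (default 150).
#' @param epsilon Denominator guard (default 1e-6).
#' @param repeatIndex Bookkeeping index stored on the result (default 1).
#' @return A [RunResult].
#' @export
runOnce <- function(x, split = splitConfig(), nTop = 150, epsilon = 1e-6,
                    repeatIndex = 1L) {
  stopifnot(is(x, "SpectraSet"))
  parts <- stageCall("split", splitDataset(x, split))
  tm <- stageCall("training", trainMetrics(parts$train, epsilon = epsilon))
  tm <- stageCall("testing", scoreMetrics(tm, parts$test, epsilon = epsilon))
  rk <- stageCall("selection", rankAndSelect(tm, nTop))
  pred <- stageCall("validation",
                    classifySpectra(parts$validation, rk, epsilon = epsilon))
  ev <- stageCall("validation",
                  evaluatePredictions(pred, classLabels(parts$validation)))
  new("RunResult", repeatIndex = as.integer(repeatIndex),
      sensitivity = unname(ev["sensitivity"]),
      specificity = unname(ev["specificity"]),
      precision = unname(ev["precision"]),
      ranking = rk, seed = split$seed)
}

#' Repeated pipeline runs with re-randomised splits
#'
#' Derives one child seed per repeat from `masterSeed`, re-randomises the
#' full three-way split each repeat, runs [runOnce()] and aggregates. The
#' whole repeated run is a pure function of `(x, split, nTop, masterSeed)`.
#'
#' @param x A [SpectraSet].
#' @param split A [splitConfig()]; its `seed` is replaced by the per-repeat
#'   child seed.
#' @param nTop Number of metrics selected per repeat (default 150).
#' @param nRepeats Number of repeats (default 10; must be >= 2 so that the
#'   sample sd is defined).
#' @param masterSeed Integer master seed (default 1).
#' @param epsilon Denominator guard (default 1e-6).
#' @return An [AggregateResult].
#' @export
runRepeated <- function(x, split = splitConfig(), nTop = 150, nRepeats = 10,
                        masterSeed = 1, epsilon = 1e-6) {
  if (nRepeats < 2)
    stop("nRepeats must be at least 2 (sample sd is undefined otherwise)")
  seeds <- withSeed(masterSeed, sample.int(.Machine$integer.max, nRepeats))
  runs <- lapply(seq_len(nRepeats), function(r) {
    cfg <- split
    cfg$seed <- seeds[r]
    runOnce(x, cfg, nTop = nTop, epsilon = epsilon, repeatIndex = r)
  })
  new("AggregateResult", runs = runs, nRepeats = as.integer(nRepeats))
}

runRates <- function(agg, what) {
  vapply(agg@runs, function(r) slot(r, what), numeric(1))
}

#' Performance table of a repeated run
#'
#' Mean and sample sd of sensitivity, specificity and precision across
#' repeats, with each row rendered in the whole-number-percentage convention
#' (`"84 ± 3%"`, rounded half-away-from-zero); the `mean` and `sd` columns
#' keep full precision. Runs with undefined precision are excluded from the
#' precision row (`n_runs` records how many were used).
#'
#' @param agg An [AggregateResult].
#' @return A `data.frame` with columns `statistic`, `mean`, `sd`, `n_runs`,
#'   `formatted`.
#' @export
performanceTable <- function(agg) {
  stopifnot(is(agg, "AggregateResult"))
  rows <- lapply(c("sensitivity", "specificity", "precision"), function(st) {
    v <- runRates(agg, st)
    v <- v[!is.na(v)]
    if (length(v) < 2)
      data.frame(statistic = st, mean = NA_real_, sd = NA_real_,
                 n_runs = length(v), formatted = NA_character_,
                 stringsAsFactors = FALSE)
    else
      data.frame(statistic = st, mean = mean(v), sd = sd(v),
                 n_runs = length(v), formatted = formatPct(mean(v), sd(v)),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
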