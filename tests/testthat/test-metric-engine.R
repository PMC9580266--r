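# Splitting, metric enumeration/training/scoring, selection, voting,
# evaluation.

test_that("stratified split sizes follow the 60/20/20 fractions exactly", {
  a <- matrix(runif(170 * 3, 0.5, 1.5), 170, 3)
  ds <- make_spectra(a, rep(c("T", "NT"), c(100, 70)))
  parts <- splitDataset(ds, splitConfig(seed = 2))
  sizes <- function(p) as.integer(table(classLabels(p))[c("T", "NT")])
  expect_identical(sizes(parts$train), c(60L, 42L))
  expect_identical(sizes(parts$test), c(20L, 14L))
  expect_identical(sizes(parts$validation), c(20L, 14L))
})

test_that("the three split outputs partition the input", {
  ds <- random_instance(21, nSpectra = 47, nWn = 5, zeros = 0)
  parts <- splitDataset(ds, splitConfig(seed = 8))
  ids <- c(spectrumIds(parts$train), spectrumIds(parts$test),
           spectrumIds(parts$validation))
  expect_identical(sort(ids), sort(spectrumIds(ds)))
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("splitting is deterministic in the seed and varies across seeds", {
  ds <- random_instance(3, nSpectra = 40, nWn = 4, zeros = 0)
  p1 <- splitDataset(ds, splitConfig(seed = 5))
  p2 <- splitDataset(ds, splitConfig(seed = 5))
  p3 <- splitDataset(ds, splitConfig(seed = 6))
  expect_identical(spectrumIds(p1$train), spectrumIds(p2$train))
  expect_false(identical(spectrumIds(p1$train), spectrumIds(p3$train)))
})

test_that("largest-remainder rounding sums to the class size", {
  for (n in c(3, 5, 7, 11, 170)) {
    a <- matrix(runif(2 * n * 2, 0.5, 1), 2 * n, 2)
    ds <- make_spectra(a, rep(c("T", "NT"), each = n))
    parts <- splitDataset(ds, splitConfig(seed = 1))
    nT <- vapply(parts, function(p) sum(classLabels(p) == "T"), 1L)
    expect_identical(sum(nT), as.integer(n))
    expect_true(all(diff(nT[c("test", "train")]) >= 0))  # train largest
  }
})

test_that("a class with fewer than 3 spectra cannot be stratified", {
  ds <- make_spectra(matrix(1, 5, 2), c("T", "T", "T", "NT", "NT"))
  expect_error(splitDataset(ds, splitConfig(seed = 1)), "stratification")
})

test_that("patient-grouped splitting keeps each donor in one subset", {
  set.seed(12)
  a <- matrix(runif(60 * 3, 0.5, 1.5), 60, 3)
  patients <- rep(sprintf("p%02d", 1:12), each = 5)
  labels <- rep(rep(c("T", "NT"), c(7, 5)), each = 5)
  ds <- make_spectra(a, labels, patients = patients)
  parts <- splitDataset(ds, splitConfig(groupByPatient = TRUE, seed = 3))
  sub <- lapply(parts, function(p) unique(patientIds(p)))
  expect_identical(anyDuplicated(unname(unlist(sub))), 0L)
  expect_identical(sort(unname(unlist(sub))), sort(unique(patients)))
})

test_that("metric enumeration yields canonical lexicographic pairs", {
  m3 <- enumerateMetrics(3)
  expect_equal(unname(m3), rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_identical(nrow(enumerateMetrics(2)), 1L)
  expect_identical(nrow(enumerateMetrics(317)), 50086L)  # n(n-1)/2
  expect_error(enumerateMetrics(1), ">= 2")
})

test_that("metric values are ratios, scale-invariant, with a denominator guard", {
  spec <- c(0.8, 0.4, 0, 1e-9)
  expect_equal(metricValue(spec, c(1, 2)), 2)
  expect_true(is.na(metricValue(spec, c(1, 3))))
  expect_true(is.na(metricValue(spec, c(1, 4), epsilon = 1e-6)))
  for (c_ in c(0.01, 1, 250))
    expect_equal(metricValue(c_ * spec, c(1, 2)), 2)
})

test_that("training recovers the separating threshold and polarity", {
  # T ratios {2.0, 2.1, 2.2}, NT ratios {1.0, 1.1, 1.2} on denominator 1
  a <- cbind(c(2.0, 2.1, 2.2, 1.0, 1.1, 1.2), 1)
  ds <- make_spectra(a, rep(c("T", "NT"), each = 3))
  tm <- metricTable(trainMetrics(ds, cbind(1L, 2L)))
  expect_identical(tm$polarity, "T")
  expect_gt(tm$threshold, 1.2)
  expect_lt(tm$threshold, 2.0)
  expect_identical(tm$train_ba, 1)
  # against the enumeration oracle
  or <- oracle_train(c(2.0, 2.1, 2.2), c(1.0, 1.1, 1.2))
  expect_equal(tm$threshold, or$threshold)
})

test_that("identical class distributions train to chance", {
  a <- cbind(rep(c(1, 2, 3), 2), 1)
  ds <- make_spectra(a, rep(c("T", "NT"), each = 3))
  tm <- metricTable(trainMetrics(ds, cbind(1L, 2L)))
  expect_identical(tm$train_ba, 0.5)
})

test_that("degenerate denominators make a metric untrainable", {
  a <- cbind(runif(6, 1, 2), 0)
  ds <- make_spectra(a, rep(c("T", "NT"), each = 3))
  tm <- metricTable(trainMetrics(ds, cbind(1L, 2L)))
  expect_false(tm$trainable)
  expect_true(is.na(tm$score))
})

test_that("scoring is balanced accuracy with undefined ratios misclassified", {
  train <- make_separable()
  tm <- trainMetrics(train, cbind(1L, 2L))
  # perfectly separated test set
  perfect <- make_separable(4, 4)
  expect_identical(metricTable(scoreMetrics(tm, perfect))$score, 1)
  # all T correct, half NT correct -> (1.0 + 0.5) / 2
  a <- matrix(0.5, 8, 4)
  a[, 1] <- c(2, 2, 2, 2, 1, 1, 2, 2)      # last two NT look like T
  mixed <- make_spectra(a, rep(c("T", "NT"), each = 4))
  expect_identical(metricTable(scoreMetrics(tm, mixed))$score, 0.75)
  # undefined test ratios count as wrong
  a0 <- matrix(0.5, 4, 4)
  a0[, 1] <- c(2, 2, 1, 1)
  a0[1, 2] <- 0                            # T spectrum with undefined ratio
  und <- make_spectra(a0, c("T", "T", "NT", "NT"))
  expect_identical(metricTable(scoreMetrics(tm, und))$score, 0.75)
})

test_that("labels independent of the ratios score about one half", {
  train <- make_separable(10, 10)
  tm <- trainMetrics(train, cbind(1L, 2L))
  set.seed(42)
  scores <- replicate(200, {
    a <- matrix(0.5, 40, 4)
    a[, 1] <- runif(40, 0.8, 2.2)
    null <- make_spectra(a, sample(rep(c("T", "NT"), 20)))
    metricTable(scoreMetrics(tm, null))$score
  })
  expect_lt(abs(mean(scores) - 0.5), 0.03)
})

test_that("a trained metric scores at least 0.5 on its own training set", {
  for (seed in 1:5) {
    ds <- random_instance(seed, nSpectra = 30, nWn = 6)
    tm <- scoreMetrics(trainMetrics(ds), ds)
    tbl <- metricTable(tm)
    expect_true(all(tbl$train_ba[tbl$trainable] >= 0.5))
    expect_true(all(tbl$score[tbl$trainable] >= 0.5))
  }
})

test_that("selection orders by score, separation, then canonical pair", {
  grid <- seq(1000, by = 4, length.out = 6)
  tbl <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                    score = c(0.9, 0.8, 0.7))
  rk <- make_ranking(tbl, grid)
  tm <- methods::new("TrainedMetrics", table = metricTable(rk), grid = grid,
                     scored = TRUE)
  sel <- rankAndSelect(tm, 2)
  expect_equal(metricTable(sel)$score, c(0.9, 0.8))

  # equal scores and separations: canonical metric order
  tbl2 <- data.frame(i = c(2L, 1L, 1L), j = c(3L, 3L, 2L), score = 0.8)
  tm2 <- methods::new("TrainedMetrics",
                      table = metricTable(make_ranking(tbl2, grid)),
                      grid = grid, scored = TRUE)
  sel2 <- metricTable(rankAndSelect(tm2, 3))
  expect_equal(sel2$i, c(1L, 1L, 2L))
  expect_equal(sel2$j, c(2L, 3L, 3L))

  expect_error(rankAndSelect(tm2, 10), "selection error")
})

test_that("ranking agrees with the brute-force sort oracle", {
  ds <- random_instance(31, nSpectra = 50, nWn = 11, zeros = 3)
  parts <- splitDataset(ds, splitConfig(seed = 4))
  tm <- scoreMetrics(trainMetrics(parts$train), parts$test)
  tbl <- metricTable(tm)
  tbl <- tbl[tbl$trainable, ]
  got <- metricTable(rankAndSelect(tm, 20))
  want <- oracle_rank(tbl, 20)
  expect_equal(got$i, want$i)
  expect_equal(got$j, want$j)
  expect_equal(got$score, want$score)
})

test_that("voting is score-weighted with a conservative NT tie-break", {
  grid <- seq(1000, by = 4, length.out = 4)
  # single metric, polarity T-high, threshold 1: ratio above -> T
  one <- make_ranking(data.frame(i = 1L, j = 2L, threshold = 1,
                                 polarity = "T", score = 0.9), grid)
  expect_identical(classifySpectra(c(2, 1, 1, 1), one), "T")
  expect_identical(classifySpectra(c(0.5, 1, 1, 1), one), "NT")
  # unanimity
  two <- make_ranking(data.frame(i = c(1L, 3L), j = c(2L, 4L),
                                 threshold = c(1, 1), polarity = "T",
                                 score = c(0.9, 0.8)), grid)
  expect_identical(classifySpectra(c(2, 1, 3, 1), two), "T")
  # equal scores voting oppositely -> NT
  tie <- make_ranking(data.frame(i = c(1L, 3L), j = c(2L, 4L),
                                 threshold = c(1, 1), polarity = c("T", "NT"),
                                 score = c(0.7, 0.7)), grid)
  expect_identical(classifySpectra(c(2, 1, 2, 1), tie), "NT")
  # all metrics abstain -> unclassifiable
  expect_true(is.na(classifySpectra(c(2, 0, 2, 0), two)))
})

test_that("evaluation implements sensitivity, specificity, precision", {
  p <- rep(c("T", "NT"), c(5, 5))
  expect_equal(unname(evaluatePredictions(p, p)), c(1, 1, 1))

  truth <- rep(c("T", "NT"), each = 10)
  pred <- c(rep("T", 8), rep("NT", 2), rep("NT", 7), rep("T", 3))
  ev <- evaluatePredictions(pred, truth)
  expect_equal(unname(ev), c(0.8, 0.7, 8 / 11))

  allNT <- evaluatePredictions(rep("NT", 20), truth)
  expect_equal(unname(allNT[1:2]), c(0, 1))
  expect_true(is.na(allNT["precision"]))

  # unclassifiable predictions count against their true class
  na2 <- evaluatePredictions(c(NA, rep("T", 9), rep("NT", 9), NA), truth)
  expect_equal(unname(na2[1:2]), c(0.9, 0.9))

  expect_error(evaluatePredictions(c("T", "NT"), c("T")), "equal length")
  expect_error(evaluatePredictions(c("T", "T"), c("T", "T")), "both classes")
})

test_that("classification is invariant to per-spectrum rescaling", {
  gen <- generateDataset(syntheticConfig(nGrid = 41, spectraPerPatient = 4,
                                         seed = 14))
  parts <- splitDataset(gen$dataset, splitConfig(seed = 14))
  rk <- rankAndSelect(scoreMetrics(trainMetrics(parts$train), parts$test), 30)
  a <- absorbance(parts$validation)
  base <- classifySpectra(a, rk)
  set.seed(15)
  scales <- runif(ncol(a), 0.2, 5)
  expect_identical(classifySpectra(sweep(a, 2, scales, "*"), rk), base)
})
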