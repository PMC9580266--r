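# Brute-force oracles, kept independent of the package's compiled training
# path: plain R enumeration of candidate thresholds and a plain stable sort
# for the ranking.

# Defined ratios of pair (i, j) over the spectra of a SpectraSet.
oracle_ratios <- function(x, i, j, epsilon = 1e-6) {
  a <- absorbance(x)                      # wavenumbers x spectra
  num <- a[i, ]
  den <- a[j, ]
  ifelse(abs(den) >= epsilon, num / den, NA_real_)
}

# Optimal balanced-accuracy midpoint cut by exhaustive enumeration.
# Candidates: midpoints of adjacent distinct sorted ratios, plus a cut below
# all of them. Ties in balanced accuracy resolve to the lowest cut; the
# class with the higher ratio mean lies above the cut (ties -> T).
oracle_train <- function(rT, rNT) {
  rT <- rT[!is.na(rT)]
  rNT <- rNT[!is.na(rNT)]
  if (length(rT) < 2 || length(rNT) < 2) return(NULL)
  hi <- if (mean(rT) >= mean(rNT)) "T" else "NT"
  rHi <- if (hi == "T") rT else rNT
  rLo <- if (hi == "T") rNT else rT
  vals <- sort(unique(c(rT, rNT)))
  cand <- c(vals[1] - 1,
            if (length(vals) > 1) (head(vals, -1) + tail(vals, -1)) / 2)
  nHi <- length(rHi)
  nLo <- length(rLo)
  # integer-valued score proportional to balanced accuracy: exact comparisons
  sc <- vapply(cand,
               function(t) sum(rHi > t) * nLo + sum(rLo <= t) * nHi,
               numeric(1))
  best <- which.max(sc)                    # first maximum = lowest cut
  list(threshold = cand[best], polarity = hi,
       ba = sc[best] / (2 * nHi * nLo))
}

# Balanced accuracy of a fixed rule on a labelled set of ratios; undefined
# ratios count as misclassified.
oracle_score <- function(r, labels, threshold, polarity) {
  above <- !is.na(r) & r > threshold
  predT <- if (polarity == "T") above else (!above & !is.na(r))
  (sum(predT & labels == "T") / sum(labels == "T") +
     sum(!predT & !is.na(r) & labels == "NT") / sum(labels == "NT")) / 2
}

# Ranking oracle: stable sort by (-score, -separation, i, j).
oracle_rank <- function(tbl, nTop) {
  pooled <- sqrt((tbl$sd_T^2 + tbl$sd_NT^2) / 2)
  sep <- abs(tbl$mean_T - tbl$mean_NT) / pooled
  sep[pooled == 0] <- ifelse(abs(tbl$mean_T - tbl$mean_NT)[pooled == 0] > 0,
                             Inf, 0)
  tbl[order(-tbl$score, -sep, tbl$i, tbl$j)[seq_len(nTop)], ]
}
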