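# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a SpectraSet from a spectra-by-wavenumber matrix with minimal fuss.
make_spectra <- function(a, labels, patients = NULL, wn = NULL, ids = NULL,
                         resolution = 4) {
  a <- as.matrix(a)
  n <- nrow(a)
  SpectraSet(a,
             wn %||% seq(1000, by = 4, length.out = ncol(a)),
             ids %||% sprintf("s%03d", seq_len(n)),
             patients %||% rep("p1", n),
             labels, resolution = resolution)
}

# A dataset whose single informative wavenumber (index 1) separates the
# classes perfectly when ratioed against the constant wavenumber (index 2).
make_separable <- function(nT = 6, nNT = 6, nWn = 4) {
  a <- matrix(0.5, nT + nNT, nWn)
  a[, 1] <- c(rep(2, nT), rep(1, nNT)) + seq_len(nT + nNT) * 1e-3
  make_spectra(a, c(rep("T", nT), rep("NT", nNT)))
}

# Hand-build a MetricRanking without going through training.
make_ranking <- function(df, grid) {
  defaults <- list(n_T = 5L, n_NT = 5L, mean_T = 1, mean_NT = 0,
                   sd_T = 0.1, sd_NT = 0.1, threshold = 0.5, polarity = "T",
                   train_ba = 1, trainable = TRUE, score = 1)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df$wn_num <- grid[df$i]
  df$wn_den <- grid[df$j]
  cols <- c("i", "j", "wn_num", "wn_den", "n_T", "n_NT", "mean_T", "mean_NT",
            "sd_T", "sd_NT", "threshold", "polarity", "train_ba", "trainable",
            "score")
  methods::new("MetricRanking", table = df[, cols], grid = grid,
               scored = TRUE, nTop = nrow(df))
}

# Random small training instance on well-conditioned absorbances (plus a few
# planted zero denominators to exercise the undefined-ratio guard).
random_instance <- function(seed, nSpectra = 60, nWn = 12, zeros = 2) {
  set.seed(seed)
  a <- matrix(runif(nSpectra * nWn, 0.1, 2), nSpectra, nWn)
  if (zeros > 0)
    a[sample(length(a), zeros)] <- 0
  labels <- sample(rep(c("T", "NT"), length.out = nSpectra))
  make_spectra(a, labels)
}
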