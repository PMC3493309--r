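# Independent brute-force oracles used to cross-check the package's own
# implementations. Deliberately naive: no shared code with R/.

# complete-linkage 1-D agglomeration by exhaustive pairwise recomputation:
# at each step evaluate every cluster pair's complete-linkage distance
# (max cross-member |difference|) relative to its tolerance budget
# (rel_tol * midpoint of the union), merge the smallest ratio while <= 1.
# Returns the partition as a list of sorted mz vectors.
brute_complete_linkage <- function(mz, rel_tol) {
  clusters <- as.list(sort(mz))
  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- NULL
    best_ratio <- Inf
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        d <- max(abs(outer(clusters[[a]], clusters[[b]], "-")))
        u <- c(clusters[[a]], clusters[[b]])
        ratio <- d / (rel_tol * (min(u) + max(u)) / 2)
        if (ratio < best_ratio) {
          best_ratio <- ratio
          best <- c(a, b)
        }
      }
    }
    if (best_ratio > 1) break
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  clusters[order(vapply(clusters, min, numeric(1)))]
}

# partition of a peak_clusters object as a list of sorted member mz vectors
partition_of <- function(cl) {
  out <- lapply(split(cl$members$mz, cl$members$cluster_id), sort)
  unname(out[order(vapply(out, min, numeric(1)))])
}

# AUC by exhaustive positive x negative pair counting, ties 0.5
auc_pairs <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels <= 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# exact two-sided Wilcoxon p by full enumeration of rank allocations
enum_wilcox_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)])
  allo <- combn(n, length(x))
  sums <- colSums(matrix(seq_len(n)[allo], nrow = length(x)))
  mu <- length(x) * (n + 1) / 2
  p <- if (W > mu) mean(sums >= W) else mean(sums <= W)
  min(1, 2 * p)
}

# a small synthetic cohort (one low-mass stream per chip, coarse grid) for
# fast end-to-end unit tests
small_cohort <- function(seed = 1, effect_size = 3, noise_sd = 0.3,
                         n_pos = 4, n_neg = 8) {
  streams <- list(
    CM10_low = list(chip = "CM10", mass_range = "low",
      spec = spectrum_spec(c(1000, 10000), grid_size = 600,
                           noise_sd = noise_sd),
      peaks = list(planted_peak(2000, 40), planted_peak(3500, 30),
                   planted_peak(6000, 25))),
    IMAC30_low = list(chip = "IMAC30", mass_range = "low",
      spec = spectrum_spec(c(1000, 10000), grid_size = 600,
                           noise_sd = noise_sd),
      peaks = list(planted_peak(1500, 35),
                   planted_peak(2700, 5, effect_size = effect_size,
                                cv = 0.05),
                   planted_peak(5000, 30))))
  generate_cohort(n_pos = n_pos, n_neg = n_neg, streams = streams,
                  seed = seed)
}

# wrap a plain feature matrix as a peak_matrix (for classifier-level tests
# that do not need real spectra)
as_peak_matrix <- function(X, chip = "CM10", mass_range = "low") {
  mzs <- 1000 + 100 * seq_len(ncol(X))
  colnames(X) <- sprintf("%s_%s_%.2f", chip, mass_range, mzs)
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%02d", seq_len(nrow(X)))
  cl <- data.frame(cluster_id = seq_len(ncol(X)), consensus_mz = mzs,
                   diameter = 0, n_samples = nrow(X), chip = chip,
                   mass_range = mass_range, column = colnames(X),
                   stringsAsFactors = FALSE)
  structure(list(intensity = X, clusters = cl), class = "peak_matrix")
}
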