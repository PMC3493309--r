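# exact null distribution of the Wilcoxon rank-sum statistic W (sum of the
# x-group ranks) for group sizes nx, ny without ties: classic counting
# recursion over which ranks 1..n the x group occupies
wilcox_exact_counts <- function(nx, n) {
  wmax <- sum((n - nx + 1):n)
  counts <- matrix(0, nrow = nx + 1, ncol = wmax + 1)  # [m+1, w+1]
  counts[1, 1] <- 1
  for (k in seq_len(n)) {
    for (m in rev(seq_len(min(k, nx)))) {
      w <- seq(k, wmax)
      counts[m + 1, w + 1] <- counts[m + 1, w + 1] + counts[m, w - k + 1]
    }
  }
  counts[nx + 1, ]  # counts[w+1] = number of allocations with rank sum w
}

#' Wilcoxon rank-sum test (Mann-Whitney)
#'
#' Two-sided test of a location difference between two samples. The exact
#' mode enumerates the full null distribution of the rank sum over all
#' `choose(nx+ny, nx)` rank allocations (no ties, `nx + ny <= 25`); the
#' normal mode uses the large-sample normal approximation with tie-corrected
#' variance and a 0.5 continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param mode `"normal"` (default) or `"exact"`.
#' @return List with `statistic` (W, the rank sum of `x`), `u` (the
#'   Mann-Whitney U of `x`), and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be non-empty",
                                     call. = FALSE)
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  comb <- c(x, y)
  if (length(unique(comb)) == 1L) {
    return(list(statistic = nx * (n + 1) / 2, u = nx * ny / 2, p_value = 1))
  }
  r <- rank(comb)
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  if (mode == "exact") {
    if (any(duplicated(comb))) {
      stop("exact mode requires untied data", call. = FALSE)
    }
    if (n > 25) stop("exact mode requires nx + ny <= 25", call. = FALSE)
    counts <- wilcox_exact_counts(nx, n)
    total <- choose(n, nx)
    w_vals <- seq_along(counts) - 1
    mu <- nx * (n + 1) / 2
    p_lo <- sum(counts[w_vals <= W]) / total
    p_hi <- sum(counts[w_vals >= W]) / total
    p <- min(1, 2 * if (W > mu) p_hi else p_lo)
  } else {
    mu <- nx * ny / 2
    ties <- table(comb)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tie_term)
    if (v <= 0) return(list(statistic = W, u = U, p_value = 1))
    cc <- sign(U - mu) * 0.5
    z <- (U - mu - cc) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = W, u = U, p_value = p)
}

#' @rdname wilcoxon_rank_sum
#' @export
mann_whitney <- wilcoxon_rank_sum

# normal-approximation Wilcoxon p for every column of X; pos is a logical
# row index of the positive class. Vectorized enough for repeated LOO use.
wilcox_p_columns <- function(X, pos) {
  nx <- sum(pos)
  ny <- sum(!pos)
  n <- nx + ny
  apply(X, 2, function(col) {
    if (length(unique(col)) == 1L) return(1)
    r <- rank(col)
    U <- sum(r[pos]) - nx * (nx + 1) / 2
    ties <- table(col)
    v <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (v <= 0) return(1)
    z <- (U - nx * ny / 2 - sign(U - nx * ny / 2) * 0.5) / sqrt(v)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
}

# column-concatenate one or more peak_matrix objects over shared samples
combine_peak_matrices <- function(matrices) {
  if (inherits(matrices, "peak_matrix")) matrices <- list(matrices)
  sids <- rownames(matrices[[1]]$intensity)
  for (m in matrices) sids <- intersect(sids, rownames(m$intensity))
  n_all <- max(vapply(matrices, function(m) nrow(m$intensity), integer(1)))
  if (!length(sids)) stop("stream matrices share no sample ids", call. = FALSE)
  if (length(sids) < n_all) {
    warning(n_all - length(sids),
            " sample(s) missing from some stream(s); using the ",
            length(sids), " samples present in every stream", call. = FALSE)
  }
  X <- do.call(cbind, lapply(matrices, function(m) m$intensity[sids, ,
                                                               drop = FALSE]))
  ann <- do.call(rbind, lapply(matrices, function(m)
    m$clusters[, c("column", "consensus_mz", "chip", "mass_range")]))
  rownames(ann) <- NULL
  list(X = X, annotation = ann)
}

#' Rank peak clusters by Wilcoxon significance
#'
#' Tests every cluster (pooled across the supplied streams) for a class
#' difference with the normal-approximation Wilcoxon rank-sum test. Clusters
#' with p below `alpha` are retained, sorted by ascending p (ties broken by
#' ascending consensus m/z) and ranked 1, 2, ...
#'
#' @param matrices A `peak_matrix` or list of per-stream `peak_matrix`.
#' @param labels Named (+1/-1) vector over the samples.
#' @param alpha Significance threshold (default 0.05).
#' @return Data.frame: `column`, `consensus_mz`, `chip`, `mass_range`,
#'   `p_value`, `direction` (sign of the median difference), `rank`.
#' @export
rank_peaks <- function(matrices, labels, alpha = 0.05) {
  comb <- combine_peak_matrices(matrices)
  X <- comb$X
  labels <- labels[rownames(X)]
  if (min(table(labels)) < 2) stop("need >= 2 samples per class",
                                   call. = FALSE)
  pos <- labels > 0
  p <- wilcox_p_columns(X, pos)
  direction <- apply(X, 2, function(col) {
    sign(stats::median(col[pos]) - stats::median(col[!pos]))
  })
  res <- comb$annotation
  res$p_value <- unname(p)
  res$direction <- unname(direction)
  res <- res[res$p_value < alpha, , drop = FALSE]
  res <- res[order(res$p_value, res$consensus_mz), , drop = FALSE]
  if (nrow(res)) res$rank <- seq_len(nrow(res))
  else res$rank <- integer(0)
  rownames(res) <- NULL
  res
}

#' Pearson chi-square test for a contingency table
#'
#' Pearson X-squared with expected counts from the row/column margins,
#' optionally with the Yates continuity correction (applied for 2x2 tables
#' only, as is standard).
#'
#' @param table Matrix of non-negative integer counts, at least 2x2.
#' @param yates Apply the continuity correction (2x2 tables only)?
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Two-sample t test
#'
#' Two-sided two-sample t test, pooled-variance by default, used for the
#' cohort-characteristics table.
#'
#' @param x,y Numeric vectors (>= 2 values each).
#' @param pooled Pooled-variance (Student) test if `TRUE`, Welch otherwise.
#' @return List with `t`, `df`, `p_value`.
#' @export
two_sample_t_test <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group",
                                           call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  res <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
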