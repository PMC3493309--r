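#' ROC curve, AUC and its standard error
#'
#' The AUC is the pairwise (Mann-Whitney) estimator: the fraction of
#' positive/negative score pairs in which the positive scores higher, ties
#' counted 0.5 (computed via midranks). The standard error is Hanley-McNeil.
#' ROC points are produced at every distinct threshold with the decision rule
#' `score >= threshold` = positive.
#'
#' @param scores Numeric decision values.
#' @param labels Class labels; positive class is `> 0` (or `TRUE`).
#' @return List with `roc` (data.frame: threshold, sensitivity, specificity,
#'   fpr), `auc`, `auc_se`.
#' @export
roc_and_auc <- function(scores, labels) {
  pos <- as.numeric(labels) > 0
  P <- sum(pos)
  N <- sum(!pos)
  if (P == 0 || N == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt((auc * (1 - auc) + (P - 1) * (q1 - auc^2) +
                    (N - 1) * (q2 - auc^2)) / (P * N))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               sensitivity = sum(pred & pos) / P,
               specificity = sum(!pred & !pos) / N,
               fpr = sum(pred & !pos) / N)
  }))
  list(roc = roc, auc = auc, auc_se = auc_se)
}

#' Operating point maximizing sensitivity + specificity
#'
#' Chooses the ROC threshold with the largest Youden index
#' (sensitivity + specificity); ties are broken toward the higher
#' specificity. Rank-based, hence invariant to monotone score transforms.
#'
#' @param roc ROC data.frame from [roc_and_auc()].
#' @return List with `threshold`, `sensitivity`, `specificity` (fractions).
#' @export
pick_operating_point <- function(roc) {
  youden <- roc$sensitivity + roc$specificity
  best <- which(youden == max(youden))
  best <- best[which.max(roc$specificity[best])]
  list(threshold = roc$threshold[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best])
}

#' Balanced error rate at a threshold
#'
#' `BER = (FN/P + FP/N) / 2` with positives predicted at `score >= threshold`.
#'
#' @param scores,labels As in [roc_and_auc()].
#' @param threshold Decision threshold.
#' @return The balanced error rate in `[0, 1]`.
#' @export
balanced_error_rate <- function(scores, labels, threshold) {
  pos <- as.numeric(labels) > 0
  pred <- scores >= threshold
  (sum(!pred & pos) / sum(pos) + sum(pred & !pos) / sum(!pos)) / 2
}

min_ber <- function(scores, labels) {
  score_stats(scores, as.numeric(labels) > 0)$ber
}

# vectorized AUC / min-BER / max-Youden over all thresholds, no data.frames;
# used inside the LOO selection loops where roc_and_auc would be wasteful
score_stats <- function(scores, pos) {
  P <- sum(pos)
  N <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
  ord <- order(scores, decreasing = TRUE)
  cpos <- cumsum(pos[ord])
  cneg <- cumsum(!pos[ord])
  last <- cumsum(rle(scores[ord])$lengths)        # last index per threshold
  sens <- c(0, cpos[last] / P)
  fpr <- c(0, cneg[last] / N)
  list(auc = auc,
       ber = min((1 - sens + fpr) / 2),
       youden = max(sens + (1 - fpr)))
}

#' Default regularization grid for LS-SVM tuning
#'
#' Fifteen values log-spaced over `[1e-3, 1e3]`, spanning under- to
#' over-regularized regimes.
#' @return Numeric vector of gamma values.
#' @export
lssvm_gamma_grid <- function() 10^seq(-3, 3, length.out = 15)

# fit on Xtr/ytr, return held-out decision value(s) for Xte; constant
# training columns are dropped (they carry no information and would make
# standardization degenerate). Returns NULL if no usable feature remains.
fit_and_score <- function(Xtr, ytr, Xte, gamma, weights, kernel, sigma) {
  sds <- apply(Xtr, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) return(NULL)
  m <- wlssvm(Xtr[, keep, drop = FALSE], ytr, gamma = gamma, kernel = kernel,
              sigma = sigma, weights = weights)
  predict(m, Xte[, keep, drop = FALSE])
}

#' Leave-one-out cross-validated weighted LS-SVM with peak selection
#'
#' Runs the full validation loop of the discovery workflow. The per-stream
#' peak matrices are column-concatenated into one feature table. In every
#' leave-one-out iteration the peaks are re-ranked by Wilcoxon significance
#' on the training samples only, and the top `k` significant peaks
#' (`k = 1..k_max`, in order of decreasing significance, pooled over all
#' streams) feed a weighted LS-SVM trained at each `gamma` in the grid.
#'
#' Two hyperparameter-selection modes are available:
#' \describe{
#'   \item{paper}{`(k, gamma)` is chosen globally as the pair maximizing the
#'     pooled outer LOO AUC, with ties broken by the smallest achievable
#'     balanced error rate, then the largest sensitivity + specificity at the
#'     operating point, then the smaller `k` and `gamma`. This reproduces the
#'     original selection procedure and inherits its optimism, since the
#'     held-out scores participate in the choice.}
#'   \item{nested}{`(k, gamma)` is chosen per iteration by an inner
#'     leave-one-out AUC within the training fold (closed-form LS-SVM LOO),
#'     and the held-out decision value is recorded once. Unbiased, at the
#'     price of a per-iteration hyperparameter.}
#' }
#' If a training fold contains no significant peak, the iteration falls back
#' to the single lowest-p peak with a warning.
#'
#' @param matrices A `peak_matrix` or list of per-stream `peak_matrix`
#'   sharing sample ids.
#' @param labels Named (+1/-1) vector over the samples.
#' @param k_max Maximum number of peaks per model (default 10).
#' @param gamma_grid Regularization grid (default [lssvm_gamma_grid()]).
#' @param selection_mode `"paper"` or `"nested"`.
#' @param alpha Peak-significance threshold (default 0.05).
#' @param kernel,sigma Kernel specification for [wlssvm()].
#' @param seed Stored for provenance; the procedure itself is deterministic.
#' @return Object of class `loo_result`: per-iteration records (held-out
#'   score, selected columns, `k`, `gamma`), pooled ROC/AUC with SE,
#'   operating-point sensitivity/specificity (percent), BER, and the
#'   median/mean/SD of the per-iteration peak count.
#' @export
loo_pipeline <- function(matrices, labels, k_max = 10,
                         gamma_grid = lssvm_gamma_grid(),
                         selection_mode = c("paper", "nested"),
                         alpha = 0.05, kernel = "linear", sigma = NULL,
                         seed = NULL) {
  selection_mode <- match.arg(selection_mode)
  comb <- combine_peak_matrices(matrices)
  X <- comb$X
  ann <- comb$annotation
  labels <- labels[rownames(X)]
  if (any(is.na(labels))) stop("labels missing for some samples",
                               call. = FALSE)
  y <- as.numeric(labels)
  n <- nrow(X)
  # per-fold Wilcoxon ranking on the training samples only
  ranked <- vector("list", n)
  fallback_folds <- integer(0)
  ord_cols <- function(p) order(p, ann$consensus_mz)
  for (i in seq_len(n)) {
    p <- wilcox_p_columns(X[-i, , drop = FALSE], y[-i] > 0)
    sig <- which(p < alpha)
    if (!length(sig)) {
      fallback_folds <- c(fallback_folds, i)
      ranked[[i]] <- ord_cols(p)[1L]
    } else {
      ranked[[i]] <- sig[order(p[sig], ann$consensus_mz[sig])]
    }
  }
  if (length(fallback_folds)) {
    warning("no significant peaks in training fold(s) ",
            paste(fallback_folds, collapse = ", "),
            "; using the single lowest-p peak", call. = FALSE)
  }
  feat_for <- function(i, k) ranked[[i]][seq_len(min(k, length(ranked[[i]])))]

  tie_pick <- function(cands) {
    # cands: data.frame with auc, ber, youden, k, gamma_idx (in enumeration
    # order k asc, gamma asc); returns the index of the winner
    best <- which(cands$auc == max(cands$auc))
    best <- best[cands$ber[best] == min(cands$ber[best])]
    best <- best[cands$youden[best] == max(cands$youden[best])]
    best[1L]  # enumeration order already prefers smaller k, then gamma
  }

  if (selection_mode == "paper") {
    grid <- expand.grid(gi = seq_along(gamma_grid), k = seq_len(k_max))
    grid <- grid[order(grid$k, grid$gi), ]
    score_tab <- matrix(NA_real_, nrow = nrow(grid), ncol = n)
    for (k in seq_len(k_max)) {
      for (i in seq_len(n)) {
        feat <- feat_for(i, k)
        Xtr <- X[-i, feat, drop = FALSE]
        Xte <- X[i, feat, drop = FALSE]
        ytr <- y[-i]
        wtr <- class_balance_weights(ytr)
        for (gi in seq_along(gamma_grid)) {
          sc <- fit_and_score(Xtr, ytr, Xte, gamma_grid[gi], wtr,
                              kernel, sigma)
          row <- which(grid$k == k & grid$gi == gi)
          score_tab[row, i] <- if (is.null(sc)) 0 else sc
        }
      }
    }
    stt <- apply(score_tab, 1, score_stats, pos = y > 0)
    cands <- data.frame(
      auc = vapply(stt, `[[`, numeric(1), "auc"),
      ber = vapply(stt, `[[`, numeric(1), "ber"),
      youden = vapply(stt, `[[`, numeric(1), "youden"))
    win <- tie_pick(cands)
    k_win <- grid$k[win]
    gamma_win <- gamma_grid[grid$gi[win]]
    scores <- score_tab[win, ]
    sel <- lapply(seq_len(n), function(i) colnames(X)[feat_for(i, k_win)])
    k_iter <- vapply(sel, length, integer(1))
    gamma_iter <- rep(gamma_win, n)
  } else {
    scores <- numeric(n)
    sel <- vector("list", n)
    k_iter <- integer(n)
    gamma_iter <- numeric(n)
    for (i in seq_len(n)) {
      ytr <- y[-i]
      wtr <- class_balance_weights(ytr)
      pos_tr <- ytr > 0
      cands <- expand.grid(gi = seq_along(gamma_grid), k = seq_len(k_max))
      cands <- cands[order(cands$k, cands$gi), ]
      cands$auc <- NA_real_
      cands$ber <- NA_real_
      cands$youden <- NA_real_
      for (k in unique(cands$k)) {
        feat <- feat_for(i, k)
        Xtr <- X[-i, feat, drop = FALSE]
        st <- standardize_fit(Xtr)
        rows <- which(cands$k == k)
        if (!length(st$keep)) {
          cands$auc[rows] <- 0.5; cands$ber[rows] <- 0.5
          cands$youden[rows] <- 1
          next
        }
        K <- kernel_matrix(standardize_apply(Xtr, st),
                           standardize_apply(Xtr, st), kernel, sigma)
        for (r in rows) {
          inner <- lssvm_loo_from_K(K, ytr, gamma_grid[cands$gi[r]], wtr)
          stt <- score_stats(inner, pos_tr)
          cands$auc[r] <- stt$auc
          cands$ber[r] <- stt$ber
          cands$youden[r] <- stt$youden
        }
      }
      win <- tie_pick(cands)
      feat <- feat_for(i, cands$k[win])
      gamma_iter[i] <- gamma_grid[cands$gi[win]]
      sel[[i]] <- colnames(X)[feat]
      k_iter[i] <- length(feat)
      sc <- fit_and_score(X[-i, feat, drop = FALSE], ytr,
                          X[i, feat, drop = FALSE], gamma_iter[i], wtr,
                          kernel, sigma)
      scores[i] <- if (is.null(sc)) 0 else sc
    }
    k_win <- NA_integer_
    gamma_win <- NA_real_
  }

  ra <- roc_and_auc(scores, y)
  op <- pick_operating_point(ra$roc)
  structure(list(
    records = data.frame(sample_id = rownames(X), label = y, score = scores,
                         k = k_iter, gamma = gamma_iter,
                         stringsAsFactors = FALSE),
    selected = sel,
    roc = ra$roc, auc = ra$auc, auc_se = ra$auc_se,
    threshold = op$threshold,
    sensitivity = 100 * op$sensitivity, specificity = 100 * op$specificity,
    ber = balanced_error_rate(scores, y, op$threshold),
    median_k = stats::median(k_iter), mean_k = mean(k_iter),
    sd_k = stats::sd(k_iter),
    k_chosen = k_win, gamma_chosen = gamma_win,
    selection_mode = selection_mode, k_max = k_max, gamma_grid = gamma_grid,
    alpha = alpha, annotation = ann, X = X, labels = y, seed = seed),
    class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf(
    "<loo_result> %s mode | AUC %.3f (SE %.3f) | sens %.1f%% spec %.1f%% | median k %g\n",
    x$selection_mode, x$auc, x$auc_se, x$sensitivity, x$specificity,
    x$median_k))
  invisible(x)
}

#' Peak occurrence table across LOO iterations
#'
#' Counts, for every peak cluster, the number of leave-one-out iterations in
#' which it was selected, sorted by descending occurrence, annotated with the
#' consensus m/z, chip, mass range and the full-data Wilcoxon p-value.
#'
#' @param loo A `loo_result`.
#' @return Data.frame: `column`, `consensus_mz`, `chip`, `mass_range`,
#'   `occurrence`, `p_value`.
#' @export
summarize_occurrences <- function(loo) {
  tab <- table(unlist(loo$selected))
  ann <- loo$annotation
  p_full <- wilcox_p_columns(loo$X, loo$labels > 0)
  res <- ann[match(names(tab), ann$column), , drop = FALSE]
  res$occurrence <- as.integer(tab)
  res$p_value <- unname(p_full[match(res$column, colnames(loo$X))])
  res <- res[order(-res$occurrence, res$p_value, res$consensus_mz), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
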