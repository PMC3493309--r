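#' Class-balancing sample weights
#'
#' Weights each sample inversely to its class frequency so the two classes
#' contribute equally to the squared-slack penalty: `v_i = N / (2 * N_+)` for
#' positives and `N / (2 * N_-)` for negatives. The weights always sum to N.
#' With 12 positives and 48 negatives this gives 2.5 and 0.625.
#'
#' @param labels Vector of class labels in `{-1, +1}`.
#' @return Numeric weight vector parallel to `labels`.
#' @export
class_balance_weights <- function(labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels > 0)
  n_neg <- sum(labels < 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present",
                                     call. = FALSE)
  n <- n_pos + n_neg
  ifelse(labels > 0, n / (2 * n_pos), n / (2 * n_neg))
}

kernel_matrix <- function(A, B, kernel, sigma) {
  if (kernel == "linear") return(tcrossprod(A, B))
  # rbf: exp(-||a-b||^2 / (2 sigma^2))
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- which(sdv > 0)
  list(mean = mu, sd = sdv, keep = keep)
}

standardize_apply <- function(X, st) {
  Xs <- sweep(sweep(X[, st$keep, drop = FALSE], 2, st$mean[st$keep], "-"),
              2, st$sd[st$keep], "/")
  Xs
}

#' Train a weighted least-squares support vector machine
#'
#' Solves the LS-SVM dual in one dense linear solve. With labels
#' `y in {-1,+1}`, kernel matrix `K`, regularization `gamma` and per-sample
#' weights `v`, the `(N+1)`-dimensional system is
#' \deqn{\begin{pmatrix} 0 & y^T \\ y & \Omega + D \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ 1 \end{pmatrix}}
#' with `Omega_ij = y_i y_j K(x_i, x_j)` and `D = diag(1 / (gamma * v_i))`.
#' The decision value is `f(x) = sum_i alpha_i y_i K(x, x_i) + b` and the
#' predicted class is `sign(f)`. Features are standardized to the training
#' mean 0 / SD 1 (constant features dropped); the standardization is stored
#' and re-applied to new data.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Labels in `{-1, +1}`.
#' @param gamma Regularization parameter (> 0).
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param sigma RBF bandwidth (required for `kernel = "rbf"`).
#' @param weights Positive per-sample weights; defaults to
#'   [class_balance_weights()].
#' @return Object of class `wlssvm` with elements `alpha`, `b`, `gamma`,
#'   `weights`, `kernel`, `sigma`, `standardize`, `X` (standardized training
#'   features), `y`, and `residual` (the linear-system residual norm, always
#'   < 1e-8).
#' @export
wlssvm <- function(X, y, gamma = 1, kernel = c("linear", "rbf"),
                   sigma = NULL, weights = NULL) {
  kernel <- match.arg(kernel)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1, +1}", call. = FALSE)
  if (nrow(X) < 2 || length(unique(y)) != 2) {
    stop("need >= 2 samples with both classes present", call. = FALSE)
  }
  if (kernel == "rbf" && is.null(sigma)) stop("rbf kernel requires sigma",
                                              call. = FALSE)
  if (is.null(weights)) weights <- class_balance_weights(y)
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  st <- standardize_fit(X)
  if (!length(st$keep)) stop("all features are constant", call. = FALSE)
  Xs <- standardize_apply(X, st)
  n <- nrow(Xs)
  K <- kernel_matrix(Xs, Xs, kernel, sigma)
  Omega <- (y %o% y) * K
  H <- rbind(c(0, y), cbind(y, Omega + diag(1 / (gamma * weights), n)))
  rhs <- c(0, rep(1, n))
  rc <- rcond(H)
  if (rc < .Machine$double.eps) {
    stop(sprintf("singular LS-SVM system (rcond = %.3g)", rc), call. = FALSE)
  }
  sol <- solve(H, rhs)
  residual <- sqrt(sum((H %*% sol - rhs)^2))
  if (residual >= 1e-8) {
    stop(sprintf("LS-SVM solve did not meet residual tolerance (%.3g)",
                 residual), call. = FALSE)
  }
  structure(list(alpha = unname(sol[-1]), b = unname(sol[1]), gamma = gamma,
                 weights = weights, kernel = kernel, sigma = sigma,
                 standardize = st, feature_names = colnames(X),
                 X = Xs, y = y, residual = residual),
            class = "wlssvm")
}

#' Decision values of a trained weighted LS-SVM
#'
#' @param object A `wlssvm` model.
#' @param newdata Matrix of new samples with the model's training feature
#'   columns (raw scale; the stored training standardization is applied).
#' @param ... Unused.
#' @return Numeric vector of decision values `f(x)`; classify by `sign`.
#' @export
predict.wlssvm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$standardize$mean)) {
    stop("feature-dimension mismatch: model expects ",
         length(object$standardize$mean), " features", call. = FALSE)
  }
  Xs <- standardize_apply(newdata, object$standardize)
  K <- kernel_matrix(Xs, object$X, object$kernel, object$sigma)
  as.numeric(K %*% (object$alpha * object$y) + object$b)
}

#' @export
print.wlssvm <- function(x, ...) {
  cat(sprintf("<wlssvm> %s kernel, gamma %.3g, %d samples, %d features\n",
              x$kernel, x$gamma, length(x$y), ncol(x$X)))
  invisible(x)
}

#' Serialize a weighted LS-SVM model to JSON
#'
#' @param model A `wlssvm` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wlssvm <- function(model, path) {
  jsonlite::write_json(
    list(alpha = model$alpha, b = model$b, gamma = model$gamma,
         weights = model$weights, kernel = model$kernel,
         sigma = model$sigma, y = model$y,
         feature_names = model$feature_names,
         standardize_mean = model$standardize$mean,
         standardize_sd = model$standardize$sd,
         standardize_keep = model$standardize$keep,
         X = model$X),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# Exact leave-one-out decision values of the weighted LS-SVM without
# retraining. In the equivalent parametrization C [b; a'] = [0; y] with
# C = [[0, 1'], [1, K + diag(1/(gamma v))]] and a'_i = y_i alpha_i, the
# partitioned-inverse identity gives f_loo_i = y_i - a'_i / (C^-1)_{ii}
# (diagonal taken over the a' block). Validated against explicit
# retraining in the test suite.
wlssvm_loo_scores <- function(X, y, gamma, weights, kernel = "linear",
                              sigma = NULL) {
  st <- standardize_fit(X)
  if (!length(st$keep)) return(rep(0, nrow(X)))
  Xs <- standardize_apply(X, st)
  lssvm_loo_from_K(kernel_matrix(Xs, Xs, kernel, sigma), y, gamma, weights)
}

# same identity, with the kernel precomputed (hot path of nested selection)
lssvm_loo_from_K <- function(K, y, gamma, weights) {
  n <- length(y)
  C <- rbind(c(0, rep(1, n)), cbind(1, K + diag(1 / (gamma * weights), n)))
  Ci <- solve(C)
  z <- Ci %*% c(0, y)
  y - z[-1] / diag(Ci)[-1]
}
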