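test_that("class-balancing weights follow N/(2 N_class) and sum to N", {
  y <- c(rep(1, 12), rep(-1, 48))
  w <- class_balance_weights(y)
  expect_equal(unique(w[y > 0]), 2.5)
  expect_equal(unique(w[y < 0]), 0.625)
  expect_equal(sum(w), 60)
  expect_equal(class_balance_weights(c(1, 1, -1, -1)), rep(1, 4))
  set.seed(1)
  for (np in c(3, 7, 20)) {
    y2 <- c(rep(1, np), rep(-1, 31 - np))
    expect_equal(sum(class_balance_weights(y2)), 31)
  }
  expect_error(class_balance_weights(c(1, 1, 1)), "both classes")
})

test_that("the symmetric two-point problem has zero bias and monotone scores", {
  X <- matrix(c(-1, 1), ncol = 1)
  y <- c(-1, 1)
  m <- wlssvm(X, y, gamma = 1, weights = c(1, 1))
  expect_lt(abs(m$b), 1e-10)
  expect_lt(abs(predict(m, matrix(0))), 1e-10)
  sc <- predict(m, matrix(c(-2, -1, 0, 1, 2), ncol = 1))
  expect_true(all(diff(sc) > 0))
  expect_equal(sc[2], -sc[4], tolerance = 1e-10)
})

test_that("every trained model satisfies its defining linear system", {
  set.seed(2)
  for (case in 1:10) {
    n <- sample(6:20, 1)
    X <- matrix(rnorm(n * 3), n)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
    m <- wlssvm(X, y, gamma = 10^runif(1, -2, 2))
    expect_lt(m$residual, 1e-8)
    # defining system re-checked independently from the stored pieces
    K <- tcrossprod(m$X)
    H <- rbind(c(0, m$y),
               cbind(m$y, (m$y %o% m$y) * K +
                       diag(1 / (m$gamma * m$weights), n)))
    resid <- H %*% c(m$b, m$alpha) - c(0, rep(1, n))
    expect_lt(sqrt(sum(resid^2)), 1e-8)
  }
})

test_that("equal-weight training equals an independent naive dense solve", {
  set.seed(3)
  n <- 14
  X <- matrix(rnorm(n * 2), n)
  y <- c(rep(-1, 7), rep(1, 7))
  gamma <- 3.7
  m <- wlssvm(X, y, gamma = gamma, weights = rep(1, n))
  # naive oracle on the standardized features stored by the model
  Xs <- m$X
  K <- Xs %*% t(Xs)
  A <- matrix(0, n + 1, n + 1)
  A[1, 2:(n + 1)] <- y
  A[2:(n + 1), 1] <- y
  A[2:(n + 1), 2:(n + 1)] <- diag(y) %*% K %*% diag(y) + diag(n) / gamma
  sol <- solve(A, c(0, rep(1, n)))
  expect_equal(m$b, sol[1], tolerance = 1e-9)
  expect_equal(m$alpha, sol[-1], tolerance = 1e-9)
})

test_that("a nearly unregularized model separates separable data", {
  set.seed(4)
  X <- rbind(matrix(rnorm(20, -3), 10, 2), matrix(rnorm(20, 3), 10, 2))
  y <- c(rep(-1, 10), rep(1, 10))
  m <- wlssvm(X, y, gamma = 1e6)
  expect_equal(sign(predict(m, X)), y)
})

test_that("negating the labels negates all decision values (linear kernel)", {
  set.seed(5)
  X <- matrix(rnorm(24 * 3), 24)
  y <- c(rep(1, 8), rep(-1, 16))
  probe <- matrix(rnorm(15), 5)
  a <- predict(wlssvm(X, y, gamma = 2), probe)
  b <- predict(wlssvm(X, -y, gamma = 2), probe)
  expect_equal(a, -b, tolerance = 1e-9)
})

test_that("linear-kernel decision values are affine along a line", {
  set.seed(6)
  X <- matrix(rnorm(20 * 2), 20)
  y <- rep(c(-1, 1), 10)
  m <- wlssvm(X, y, gamma = 1)
  dir <- c(1, 2); origin <- c(0.5, -0.5)
  t <- c(-1, 0, 1, 2)
  probes <- t(sapply(t, function(u) origin + u * dir))
  f <- predict(m, probes)
  expect_lt(max(abs(diff(diff(f)))), 1e-10)   # second differences vanish
  # duplicated probe rows give duplicated scores
  expect_equal(predict(m, probes[c(1, 1), ]), rep(f[1], 2))
})

test_that("raising a misclassified point's weight does not raise its slack", {
  set.seed(7)
  X <- matrix(rnorm(16), 16, 1)
  y <- sign(X[, 1] + rnorm(16, 0, 1.5))
  y[y == 0] <- 1
  if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
  w <- rep(1, 16)
  m1 <- wlssvm(X, y, gamma = 1, weights = w)
  mis <- which(sign(predict(m1, X)) != y)[1]
  skip_if(is.na(mis))
  e1 <- m1$alpha[mis] / (m1$gamma * w[mis])
  w2 <- w; w2[mis] <- 4
  m2 <- wlssvm(X, y, gamma = 1, weights = w2)
  e2 <- m2$alpha[mis] / (m2$gamma * w2[mis])
  expect_lte(abs(e2), abs(e1) + 1e-12)
})

test_that("input validation rejects bad labels, gamma and dimensions", {
  X <- matrix(rnorm(12), 6)
  y <- c(1, 1, 1, -1, -1, -1)
  expect_error(wlssvm(X, y, gamma = 0), "gamma")
  expect_error(wlssvm(X, c(0, 1, 1, -1, -1, -1)), "labels")
  m <- wlssvm(X, y)
  expect_error(predict(m, matrix(rnorm(3), 1)), "dimension")
})

test_that("closed-form LOO scores equal explicit retraining on a fixed kernel", {
  set.seed(8)
  n <- 12
  X <- matrix(rnorm(n * 2), n)
  y <- c(rep(1, 5), rep(-1, 7))
  w <- class_balance_weights(y)
  gamma <- 0.8
  fast <- seldiflow:::wlssvm_loo_scores(X, y, gamma, w)
  # oracle: standardize once, then solve each reduced system explicitly
  Xs <- scale(X)
  K <- Xs %*% t(Xs)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    ni <- length(idx)
    C <- rbind(c(0, rep(1, ni)),
               cbind(1, K[idx, idx] + diag(1 / (gamma * w[idx]), ni)))
    z <- solve(C, c(0, y[idx]))
    f_i <- sum(z[-1] * K[i, idx]) + z[1]
    expect_equal(fast[i], f_i, tolerance = 1e-8)
  }
})

test_that("model serialization writes valid JSON with the dual solution", {
  set.seed(9)
  X <- matrix(rnorm(20), 10)
  y <- rep(c(-1, 1), 5)
  m <- wlssvm(X, y, gamma = 2)
  f <- tempfile(fileext = ".json")
  write_wlssvm(m, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$alpha, m$alpha, tolerance = 1e-12)
  expect_equal(back$b, m$b, tolerance = 1e-12)
  expect_equal(back$gamma, 2)
  unlink(f)
})
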