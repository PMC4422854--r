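test_that("candidate building adds logs of positive metrics only", {
  m <- data.frame(a = c(1, 2, 3, 4), b = c(0, 1, 2, 3), cst = 5,
                  d = c(2, 4, 8, 16))
  cand <- build_candidates(m)
  expect_setequal(cand$names, c("a", "b", "d", "log.a", "log.d"))
  expect_equal(cand$values[, "log.d"], log(m$d), ignore_attr = TRUE)
  # k strictly positive non-constant metrics give 2k candidates
  k <- 6
  set.seed(2)
  mm <- as.data.frame(matrix(runif(10 * k, 1, 5), 10, k))
  expect_length(build_candidates(mm)$names, 2 * k)
  # non-finite rows are rejected with a warning
  m$a[2] <- NA
  expect_warning(c2 <- build_candidates(m), "non-finite")
  expect_identical(c2$kept, c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(nrow(c2$values), 3L)
})

test_that("OLS fit reproduces closed-form normal equations", {
  # 4-point bivariate fit, oracle via explicit normal equations
  X <- cbind(x1 = c(0, 1, 2, 3), x2 = c(1, 0, 1, 4))
  y <- c(0.5, 1.2, 2.1, 4.0)
  fit <- fit_model(y, X)
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(unname(fit$coefficients), unname(drop(beta)), tolerance = 1e-12)
  expect_equal(fit$mse, sum((y - Xd %*% beta)^2) / (4 - 2 - 1),
               tolerance = 1e-12)
  # perfect fit
  yp <- 1 + 2 * X[, 1]
  pf <- fit_model(yp, X[, 1, drop = FALSE])
  expect_equal(pf$adj_r2, 1)
  expect_equal(pf$mse, 0)
  expect_error(fit_model(y, cbind(X, x3 = X[, 1])), "rank-deficient")
})

test_that("adjusted R2 is near zero for pure noise", {
  set.seed(31)
  x <- matrix(rnorm(1000 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(1000)
  expect_lt(abs(fit_model(y, x)$adj_r2), 0.1)
})

test_that("subset selection recovers exact signals and screens collinearity", {
  set.seed(7)
  n <- 25
  X <- matrix(runif(n * 4, 1, 10), n, 4,
              dimnames = list(NULL, c("x1", "x2", "x3", "x4")))
  cand <- build_candidates(as.data.frame(X))
  y <- 2 + 3 * X[, "x1"]
  fit <- select_model(y, cand)
  expect_identical(fit$selected, "x1")
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-8)
  expect_equal(fit$mse, 0, tolerance = 1e-12)
  # duplicated predictor is never co-selected (infinite VIF)
  X2 <- cbind(X[, 1:2], x1b = X[, 1])
  y2 <- 1 + 2 * X2[, 1] + rnorm(n, 0, 0.1)
  c2 <- structure(list(names = colnames(X2), values = X2,
                       kept = rep(TRUE, n)), class = "candidate_set")
  f2 <- select_model(y2, c2)
  expect_false(all(c("x1", "x1b") %in% f2$selected))
  expect_true(all(f2$vif < 10))
})

test_that("compiled subset search matches exhaustive lm enumeration", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 30
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("m", 1:10)))
    # known 2-variable truth plus noise
    y <- 1 + 2 * X[, 3] - 1.5 * X[, 7] + rnorm(n, 0, 0.5)
    cand <- structure(list(names = colnames(X), values = X,
                           kept = rep(TRUE, n)), class = "candidate_set")
    fit <- select_model(y, cand)
    ref <- naive_best_subset(y, X)
    expect_setequal(fit$selected, ref$labels)
    expect_equal(fit$bic, ref$bic, tolerance = 1e-8)
  }
})

test_that("prediction applies the half-MSE bias correction", {
  fit0 <- structure(list(selected = "x", coefficients = c(0.3, 1.2), se = NULL,
                         mse = 0, adj_r2 = 1, vif = 1, bic = 0, n = 10),
                    class = "agb_fit")
  expect_equal(predict_agb(fit0, data.frame(x = 2)), exp(0.3 + 2.4))
  fit2 <- structure(list(selected = character(0), coefficients = 0, se = NULL,
                         mse = 2, adj_r2 = 0, vif = NULL, bic = 0, n = 10),
                    class = "agb_fit")
  expect_equal(predict_agb(fit2, data.frame(x = 1)), exp(1))
  # lognormal simulation: bias-corrected mean matches the arithmetic mean
  set.seed(13)
  n <- 1e4
  x <- runif(n, 0, 2)
  y <- exp(1 + 0.8 * x + rnorm(n, 0, 0.6))
  fit <- fit_model(log(y), cbind(x = x))
  pred <- predict_agb(fit, data.frame(x = x))
  expect_equal(mean(pred) / mean(y), 1, tolerance = 0.02)
})

test_that("LOOCV matches a manual fold-by-fold computation", {
  set.seed(55)
  n <- 6
  x1 <- c(1, 2, 3, 4, 5, 6)
  x2 <- c(2.2, 1.1, 3.7, 0.9, 4.4, 2.8)
  y <- exp(0.5 + 0.3 * x1 + rnorm(n, 0, 0.2))
  X <- cbind(x1 = x1, x2 = x2)
  cand <- structure(list(names = colnames(X), values = X,
                         kept = rep(TRUE, n)), class = "candidate_set")
  cv <- loocv(y, cand, selected = "x1")
  # manual oracle with lm()
  yhat <- sapply(seq_len(n), function(i) {
    f <- lm(log(y)[-i] ~ x1[-i])
    s2 <- sum(resid(f)^2) / (n - 1 - 2)
    exp(coef(f)[1] + s2 / 2 + coef(f)[2] * x1[i])
  })
  expect_equal(cv$predictions, unname(yhat), tolerance = 1e-10)
  expect_equal(cv$rmse_pct,
               sqrt(sum((y - yhat)^2) / n) / mean(y) * 100, tolerance = 1e-10)
  expect_equal(cv$mpe_pct,
               sum(y - yhat) / n / mean(y) * 100, tolerance = 1e-10)
  # permuting plots leaves RMSE% unchanged
  perm <- sample(n)
  candp <- structure(list(names = colnames(X), values = X[perm, ],
                          kept = rep(TRUE, n)), class = "candidate_set")
  cvp <- loocv(y[perm], candp, selected = "x1")
  expect_equal(cvp$rmse_pct, cv$rmse_pct, tolerance = 1e-10)
})

test_that("LOOCV edge behaviour: perfect predictions and sign convention", {
  n <- 8
  x <- seq_len(n)
  y <- exp(1 + 0.2 * x)  # exact log-linear, noise-free
  cand <- structure(list(names = "x", values = cbind(x = x),
                         kept = rep(TRUE, n)), class = "candidate_set")
  cv <- loocv(y, cand, selected = "x")
  expect_equal(cv$rmse_pct, 0, tolerance = 1e-8)
  expect_equal(cv$mpe_pct, 0, tolerance = 1e-8)
  # MPE% sign follows the y - yhat convention
  set.seed(1)
  y2 <- exp(1 + 0.2 * x + rnorm(n, 0, 0.05))
  cv2 <- loocv(y2, cand, selected = "x")
  expect_equal(sign(cv2$mpe_pct), sign(mean(y2 - cv2$predictions)))
})

test_that("fitted coefficients fall inside their confidence intervals", {
  # parameter recovery over replicates of a known log-linear model
  set.seed(77)
  truth <- c(1, 0.6, -0.4)
  hits <- matrix(FALSE, 200, 3)
  for (r in 1:200) {
    n <- 30
    X <- cbind(x1 = runif(n, 0, 3), x2 = runif(n, 0, 3))
    ylog <- truth[1] + truth[2] * X[, 1] + truth[3] * X[, 2] +
      rnorm(n, 0, 0.3)
    fit <- fit_model(ylog, X)
    ci <- qt(0.975, n - 3) * fit$se
    hits[r, ] <- abs(fit$coefficients - truth) <= ci
  }
  expect_true(all(colMeans(hits) >= 0.90))
})
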