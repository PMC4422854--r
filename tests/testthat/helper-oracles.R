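# Independent, deliberately naive implementations used as oracles.

# Linear-interpolation quantile written from the definition:
# h = (n - 1) * p + 1 over the sorted sample.
naive_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  sapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(x[n])
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  })
}

# Brute-force metric set for one echo-height vector (loops, no vectorised
# shortcuts shared with the package implementation).
naive_metrics_one <- function(heights, thr = 2) {
  canopy <- c()
  for (z in heights) if (z > thr) canopy <- c(canopy, z)
  n_tot <- length(heights)
  out <- list()
  if (length(canopy) == 0) {
    out$H <- rep(NA_real_, 9)
    out$D <- rep(NA_real_, 10)
    out$S <- rep(NA_real_, 5)
    return(out)
  }
  out$H <- naive_quantile(canopy, seq(0.1, 0.9, 0.1))
  lo <- min(canopy)
  up <- naive_quantile(canopy, 0.95)
  D <- numeric(10)
  for (i in 0:9) {
    t_i <- if (i == 0) thr else lo + i * (up - lo) / 10
    cnt <- 0
    for (z in heights) if (z > t_i) cnt <- cnt + 1
    D[i + 1] <- cnt / n_tot
  }
  out$D <- D
  m <- mean(canopy)
  n <- length(canopy)
  s <- if (n >= 2) sqrt(sum((canopy - m)^2) / (n - 1)) else NA_real_
  m2 <- sum((canopy - m)^2) / n
  m3 <- sum((canopy - m)^3) / n
  sk <- if (n >= 2 && m2 > 0) m3 / m2^1.5 else NA_real_
  out$S <- c(max(canopy), m, s, if (n >= 2) s / m else NA_real_, sk)
  out
}

# Small random echo cloud (mixture of ground and canopy echoes).
random_cloud <- function(n = 50) {
  z <- ifelse(runif(n) < 0.3, 0, runif(n, 0, 40))
  cls <- sample(c("single", "first_of_many", "last_of_many"), n,
                replace = TRUE)
  structure(list(echoes = data.frame(x = runif(n, -20, 20),
                                     y = runif(n, -20, 20),
                                     z = z, echo_class = cls),
                 source = "test"),
            class = "echo_cloud")
}

# Hand-built stand from explicit tree coordinates/attributes.
make_stand <- function(x, y, dbh, height = NULL, crown_radius = NULL,
                       agb = NULL, extent = c(100, 100)) {
  height <- if (is.null(height)) predict_height(dbh) else height
  crown_radius <- if (is.null(crown_radius)) pmin(0.5 + 0.08 * dbh, 12) else
    crown_radius
  agb <- if (is.null(agb)) tree_agb(dbh, height) else agb
  structure(list(
    trees = data.frame(tree_id = seq_along(x), x = x, y = y, dbh = dbh,
                       height = height, crown_radius = crown_radius,
                       agb = agb),
    extent = extent, seed = NA_integer_), class = "stand")
}

# Exhaustive best-subset search via lm(): the reference route for
# select_model. Same BIC formula and VIF screen, entirely in R.
naive_best_subset <- function(y, X, max_terms = 3, vif_limit = 10) {
  n <- length(y)
  best <- NULL
  best_bic <- Inf
  for (k in 1:max_terms) {
    for (sub in utils::combn(ncol(X), k, simplify = FALSE)) {
      Xs <- X[, sub, drop = FALSE]
      if (k > 1) {
        vif <- tryCatch(diag(solve(cor(Xs))), error = function(e) Inf)
        if (any(!is.finite(vif)) || any(vif >= vif_limit)) next
      }
      fit <- lm(y ~ ., data = as.data.frame(Xs))
      if (fit$rank < k + 1) next
      sse <- sum(resid(fit)^2)
      bic <- n * log(sse / n) + (k + 1) * log(n)
      if (bic < best_bic) {
        best_bic <- bic
        best <- colnames(X)[sub]
      }
    }
  }
  list(labels = best, bic = best_bic)
}
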