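make_cloud <- function(z, cls = "single") {
  structure(list(echoes = data.frame(x = seq_along(z), y = 0, z = z,
                                     echo_class = rep(cls, length.out = length(z))),
                 source = "test"), class = "echo_cloud")
}

test_that("echo pooling follows the single/first/last convention", {
  cloud <- make_cloud(c(10, 20, 30), "single")
  p <- pool_echoes(cloud)
  expect_equal(p$first, p$last)
  expect_identical(p$n_first, 3L)
  k <- 4L
  cloud2 <- make_cloud(c(1:k, 101:(100 + k)),
                       c(rep("first_of_many", k), rep("last_of_many", k)))
  p2 <- pool_echoes(cloud2)
  expect_identical(length(p2$first), k)
  expect_identical(length(p2$last), k)
  expect_length(intersect(p2$first, p2$last), 0)
  mixed <- make_cloud(1:6, c("single", "single", "first_of_many",
                             "last_of_many", "last_of_many", "first_of_many"))
  pm <- pool_echoes(mixed)
  expect_identical(pm$n_first, 4L)  # 2 single + 2 first_of_many
  expect_identical(pm$n_last, 4L)
  expect_error(pool_echoes(make_cloud(1, "second_of_many")), "unknown")
})

test_that("height percentiles use linear interpolation above 2 m", {
  h <- height_percentiles(0:100)  # canopy heights are 3..100 (98 values)
  expect_equal(unname(h["H50"]), 51.5)
  expect_equal(names(h), paste0("H", seq(10, 90, 10)))
  expect_true(all(rep(10, 9) == height_percentiles(rep(10, 5))))
  expect_true(all(is.na(height_percentiles(c(0, 1, 2)))))
  expect_true(all(diff(h) >= 0))
})

test_that("canopy densities match the fraction-threshold definition", {
  expect_equal(unname(canopy_densities(c(30, 31, 32))["D0"]), 1.0)
  half <- canopy_densities(c(0, 0, 40, 41))
  expect_equal(unname(half["D0"]), 0.5)
  # hand-computed table for {0, 3, 10, 20, 30}: L = 3, U = 28.5
  d <- canopy_densities(c(0, 3, 10, 20, 30))
  expect_equal(unname(d),
               c(0.8, 0.6, 0.6, 0.4, 0.4, 0.4, 0.4, 0.2, 0.2, 0.2))
  expect_true(all(is.na(canopy_densities(c(0, 1)))))
  # alternative denominator counts canopy echoes only
  d2 <- canopy_densities(c(0, 0, 40, 41), denominator = "canopy")
  expect_equal(unname(d2["D0"]), 1.0)
})

test_that("summary statistics use n-1 sd and moment skewness", {
  s <- summary_stats(c(3, 4, 5))
  expect_equal(unname(s), c(5, 4, 1, 0.25, 0))
  s2 <- summary_stats(c(3, 3, 12))
  expect_equal(unname(s2["Hsd"]), sqrt(27))
  expect_equal(unname(s2["Hskewness"]), 54 / 18^1.5)
  cst <- summary_stats(rep(7, 4))
  expect_equal(unname(cst[c("Hsd", "Hcv")]), c(0, 0))
  expect_true(is.na(cst["Hskewness"]))
  single <- summary_stats(5)
  expect_true(all(is.na(single[c("Hsd", "Hcv", "Hskewness")])))
})

test_that("metrics agree with a brute-force oracle on random clouds", {
  set.seed(101)
  for (rep in 1:100) {
    cloud <- random_cloud(sample(10:80, 1))
    spec <- plot_spec(c(0, 0), sample(c(200, 500, 1200), 1))
    mv <- metrics_for_plot(cloud, spec)
    pooled <- pool_echoes(echoes_in_plot(cloud, spec))
    for (side in c("first", "last")) {
      suf <- if (side == "first") ".F" else ".L"
      ref <- naive_metrics_one(pooled[[side]])
      got_h <- as.numeric(mv[paste0("H", seq(10, 90, 10), suf)])
      got_d <- as.numeric(mv[paste0("D", 0:9, suf)])
      got_s <- as.numeric(mv[paste0(c("Hmax", "Hmean", "Hsd", "Hcv",
                                      "Hskewness"), suf)])
      expect_equal(got_h, ref$H, tolerance = 1e-10)
      expect_equal(got_d, ref$D, tolerance = 1e-10)
      expect_equal(got_s, ref$S, tolerance = 1e-10)
    }
  }
})

test_that("percentile and density monotonicity hold on simulated plots", {
  cfg <- sim_config(extent_m = c(60, 60), seed = 21)
  stand <- generate_stand(cfg)
  cloud <- simulate_point_cloud(stand, cfg)
  for (a in c(200, 700, 1500)) {
    mv <- metrics_for_plot(cloud, plot_spec(c(30, 30), a))
    for (suf in c(".F", ".L")) {
      h <- as.numeric(mv[paste0("H", seq(10, 90, 10), suf)])
      d <- as.numeric(mv[paste0("D", 0:9, suf)])
      expect_true(all(diff(h) >= 0))
      expect_true(all(diff(d[-1]) <= 0))  # D1 >= D2 >= ... >= D9
      expect_gte(d[1], d[2])              # threshold(1) > 2 m, so D0 >= D1
      expect_true(all(d >= 0 & d <= 1))
    }
  }
})

test_that("height metrics are scale-equivariant above the threshold", {
  set.seed(5)
  z <- c(rep(0, 10), runif(40, 3, 35))  # no heights in (2/c, 2]
  cl <- 2.5
  base <- c(height_percentiles(z), summary_stats(z)[c("Hmax", "Hmean", "Hsd")])
  scaled <- c(height_percentiles(cl * z),
              summary_stats(cl * z)[c("Hmax", "Hmean", "Hsd")])
  expect_equal(scaled, cl * base, tolerance = 1e-12)
})

test_that("plots without echoes yield missing metrics deterministically", {
  empty <- structure(list(echoes = data.frame(x = numeric(), y = numeric(),
                                              z = numeric(),
                                              echo_class = character()),
                          source = "t"), class = "echo_cloud")
  mv <- metrics_for_plot(empty, plot_spec(c(0, 0), 200))
  metric_cols <- setdiff(names(mv), c("n_first", "n_last"))
  expect_true(all(is.na(mv[metric_cols])))
  expect_identical(mv$n_first, 0L)
  set.seed(3)
  cloud <- random_cloud(60)
  spec <- plot_spec(c(0, 0), 600)
  expect_identical(metrics_for_plot(cloud, spec), metrics_for_plot(cloud, spec))
})
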