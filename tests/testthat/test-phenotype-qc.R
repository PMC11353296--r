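test_that("growth-line fit equals the normal-equation solution", {
  # exactly collinear points recover the line with zero residuals
  rec <- data.frame(age_days = c(100, 120, 140), weight = c(92, 110, 128))
  f <- fit_growth_line(rec)
  expect_equal(f$a, 2.0, tolerance = 1e-12)
  expect_equal(f$b, 0.9, tolerance = 1e-12)
  expect_true(all(abs(f$residuals) < 1e-10))

  # random inputs match the closed-form normal equations to 1e-10
  set.seed(42)
  for (i in 1:10) {
    x <- sample(60:180, 8)
    y <- 5 + 0.8 * x + rnorm(8, 0, 3)
    f <- fit_growth_line(data.frame(age_days = x, weight = y))
    ab <- ols_normal_equations(x, y)
    expect_lt(abs(f$a - ab[1]), 1e-10)
    expect_lt(abs(f$b - ab[2]), 1e-10)
    expect_lt(abs(sum(f$residuals)), 1e-8)  # residuals sum to ~0
  }

  expect_error(fit_growth_line(data.frame(age_days = c(100, 100),
                                          weight = c(90, 95))),
               "degenerate")
})

test_that("outlier screening recovers planted bad growers", {
  # identical residual SDs: nothing excluded
  fits <- data.frame(animal = paste0("A", 1:5), resid_sd = rep(1.5, 5))
  expect_identical(flag_outlier_animals(fits)$excluded, character(0))

  # one extreme animal: exactly that one excluded
  fits$resid_sd[3] <- 150
  expect_identical(flag_outlier_animals(fits)$excluded, "A3")

  # planted outliers at 10x noise: recall >= 0.9 at n = 500
  g <- simulate_growth_records(500, noise_sd = 1, outlier_fraction = 0.05,
                               outlier_inflation = 10, seed = 13)
  fl <- flag_outlier_animals(fit_growth_lines(g$records))
  recall <- mean(g$truth$outliers %in% fl$excluded)
  expect_gte(recall, 0.9)

  # permutation invariance: shuffled record order, same exclusion set
  set.seed(1)
  shuf <- g$records[sample(nrow(g$records)), ]
  fl2 <- flag_outlier_animals(fit_growth_lines(shuf))
  expect_identical(fl$excluded, fl2$excluded)
})

test_that("trait description matches hand-computed summaries and a frozen
           external oracle for the omnibus normality statistic", {
  d <- data.frame(animal = c("a", "b", "c"), fcr = c(1, 2, 3))
  s <- describe_trait(d, "fcr")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)          # sample (n-1) convention
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_equal(s$n, 3)
  expect_true(is.na(s$normality_p))  # below the n >= 8 requirement

  expect_error(describe_trait(data.frame(fcr = c(1, 2)), "fcr"),
               "at least 3")

  # frozen oracle values computed independently (scipy.stats.normaltest)
  x <- c(2.591415, 2.188005, 2.725135, 2.782169, 1.914689, 2.109346,
         2.538352, 2.405127, 2.49496, 2.244087, 2.763819, 2.733338,
         2.519809, 2.838172, 2.640253, 2.242212, 2.610625, 2.212335,
         2.763535, 2.485022, 2.444541, 2.295721, 2.866762, 2.453641,
         2.371502, 2.39436, 2.659693, 2.609633, 2.62382, 2.629246,
         3.142494, 2.378075, 2.346327, 2.255868, 2.684794, 2.838692,
         2.465816, 2.247953, 2.252656, 2.695178)
  r <- dagostino_pearson_test(x)
  expect_equal(r$statistic, 0.11548204978053189, tolerance = 1e-10)
  expect_equal(r$p.value, 0.9438943609326264, tolerance = 1e-10)
  ry <- dagostino_pearson_test((1:20)^2 / 10)
  expect_equal(ry$statistic, 2.514697432414396, tolerance = 1e-10)
  expect_equal(ry$p.value, 0.28440707165007806, tolerance = 1e-10)
})

test_that("normality test is calibrated under the null and powered against
           a skewed alternative", {
  set.seed(101)
  p_null <- replicate(20, {
    describe_trait(data.frame(fcr = rnorm(5000)), "fcr")$normality_p
  })
  expect_gte(mean(p_null > 0.05), 0.9)
  p_alt <- replicate(10, {
    describe_trait(data.frame(fcr = rexp(5000)), "fcr")$normality_p
  })
  expect_true(all(p_alt < 0.01))
})

test_that("extreme-group selection is deterministic and order-invariant", {
  d <- data.frame(animal = c("p1", "p2", "p3", "p4"),
                  fcr = c(2.1, 2.5, 2.9, 3.3))
  e <- select_extremes(d, "fcr", 1)
  expect_identical(e$high, "p4")
  expect_identical(e$low, "p1")

  set.seed(3)
  d2 <- data.frame(animal = sprintf("a%02d", 1:20), fcr = rnorm(20))
  e2 <- select_extremes(d2, "fcr", 3)
  expect_length(e2$high, 3)
  expect_length(e2$low, 3)
  expect_length(intersect(e2$high, e2$low), 0)
  rest <- setdiff(d2$animal, c(e2$high, e2$low))
  expect_gte(min(d2$fcr[d2$animal %in% e2$high]),
             max(d2$fcr[d2$animal %in% rest]))

  # boundary tie: reproducible, id-ordered choice, shuffle-invariant
  d3 <- data.frame(animal = c("z", "a", "m"), fcr = c(1, 2, 2))
  e3 <- select_extremes(d3, "fcr", 1)
  expect_identical(e3$high, "a")
  d3s <- d3[c(3, 1, 2), ]
  expect_identical(select_extremes(d3s, "fcr", 1), e3)

  expect_error(select_extremes(d3, "fcr", 2), "at least 4")
})
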