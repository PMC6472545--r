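test_that("the six-statistic summary matches hand computation", {
  s <- summarize_distribution(c(1, 2, 3, 4, 5))
  expect_equal(s$min, 1)
  expect_equal(s$p25, 2)
  expect_equal(s$mean, 3)
  expect_equal(s$p75, 4)
  expect_equal(s$max, 5)
  expect_equal(s$cv_percent, 100 * sd(1:5) / 3, tolerance = 1e-12)
  expect_equal(s$cv_percent, 52.70, tolerance = 1e-3)

  expect_equal(summarize_distribution(rep(4, 6))$cv_percent, 0)
  expect_error(summarize_distribution(3), "at least 2")
})

test_that("percentiles agree with a sort-and-interpolate oracle", {
  type7 <- function(x, p) {
    # linear interpolation between order statistics at h = (n-1)p + 1
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  withr::with_seed(21, {
    for (i in 1:20) {
      x <- rnorm(sample(4:40, 1))
      s <- summarize_distribution(x)
      expect_equal(s$p25, type7(x, 0.25), tolerance = 1e-12)
      expect_equal(s$p75, type7(x, 0.75), tolerance = 1e-12)
    }
  })
})

test_that("two-group LSD is equivalent to the pooled-variance t-test", {
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- rnorm(12, 10, 2)
      b <- rnorm(9, 11, 2)
      res <- anova_lsd(c(a, b), rep(c("A", "B"), c(12, 9)))
      tt <- t.test(a, b, var.equal = TRUE)
      expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
      # the LSD call agrees with the t decision at alpha
      expect_equal(res$pairwise$significant, tt$p.value < 0.05)
    }
  })
})

test_that("LSD letters separate clearly distinct groups and merge identical ones", {
  x <- c(10, 10.1, 9.9, 20, 20.1, 19.9)
  g <- rep(c("lo", "hi"), each = 3)
  res <- anova_lsd(x, g)
  expect_false(res$groups$letter[1] == res$groups$letter[2])
  expect_equal(res$groups$group[1], "hi")   # ordered by descending mean

  same <- anova_lsd(c(5, 6, 7, 5, 6, 7), rep(c("A", "B"), each = 3))
  expect_equal(unique(same$groups$letter), "a")

  expect_error(anova_lsd(1:6, rep("A", 6)), "2 groups")
  expect_error(anova_lsd(1:3, c("A", "B", "B")), "at least 2 observations")
})

test_that("ANOVA F and MSE match the closed-form sums of squares", {
  withr::with_seed(41, {
    x <- rnorm(30, rep(c(5, 6, 8), each = 10))
    g <- rep(c("A", "B", "C"), each = 10)
    res <- anova_lsd(x, g)
    gm <- mean(x)
    means <- tapply(x, g, mean)
    ssb <- sum(10 * (means - gm)^2)
    ssw <- sum((x - means[g])^2)
    f_oracle <- (ssb / 2) / (ssw / 27)
    expect_equal(res$f_value, f_oracle, tolerance = 1e-12)
    expect_equal(res$mse, ssw / 27, tolerance = 1e-12)
  })
})

test_that("the linear fit agrees with the normal-equation oracle", {
  ols_oracle <- function(x, y) {
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
    yhat <- intercept + slope * x
    r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
    list(slope = slope, intercept = intercept, r2 = r2)
  }
  withr::with_seed(51, {
    for (i in 1:15) {
      n <- sample(5:60, 1)
      x <- rnorm(n)
      y <- 2 + 3 * x + rnorm(n)
      fit <- fit_linear(x, y)
      o <- ols_oracle(x, y)
      expect_equal(fit$slope, o$slope, tolerance = 1e-9)
      expect_equal(fit$intercept, o$intercept, tolerance = 1e-9)
      expect_equal(fit$r_squared, o$r2, tolerance = 1e-9)
    }
  })

  exact <- suppressWarnings(fit_linear(1:5, 2 * (1:5)))  # perfect-fit warning
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)

  # the three system means of energy input and output
  three <- fit_linear(c(27, 53, 36), c(113, 224, 195))
  o3 <- ols_oracle(c(27, 53, 36), c(113, 224, 195))
  expect_equal(three$slope, o3$slope, tolerance = 1e-12)
  expect_equal(three$slope, 3.936, tolerance = 0.001)

  expect_error(fit_linear(c(1, 1, 1), 1:3), "zero variance")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("three systems drawn at the benchmark GWPi means earn distinct letters", {
  withr::with_seed(61, {
    vals <- c(rnorm(80, 936, 0.04 * 936),
              rnorm(80, 1104, 0.04 * 1104),
              rnorm(80, 740, 0.02 * 740))
    g <- rep(c("MR", "DR", "RR"), each = 80)
    res <- anova_lsd(vals, g, alpha = 0.01)
    expect_equal(length(unique(res$groups$letter)), 3)
  })
})

test_that("summarize_systems assembles the per-indicator table", {
  sv <- generate_survey(n_fields = 20, seed = 13)
  ind <- compute_indicators(sv)
  sm <- summarize_systems(ind, c("annual_yield", "ner"))
  expect_equal(nrow(sm), 6)
  expect_true(all(sm$min <= sm$p25 & sm$p25 <= sm$p75 & sm$p75 <= sm$max))
  rr_ner <- sm[sm$indicator == "ner" & sm$system == "RR", ]
  expect_gt(rr_ner$mean, sm$mean[sm$indicator == "ner" & sm$system == "MR"])
})
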