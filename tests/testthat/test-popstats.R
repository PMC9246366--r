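# Per-fish aggregation, transforms, the weighted unity-slope test, t-tests,
# ANOVA with Tukey letters.

make_bout_rates <- function(pre, swim, duration = 0.3) {
  # synthetic score_bouts output with given window counts
  n <- length(pre)
  data.frame(onset_s = seq_len(n), offset_s = seq_len(n) + duration,
             duration_s = duration, usable = TRUE,
             pre_count = pre, swim_count = swim, post_count = pre,
             pre_rate = pre / duration, swim_rate = swim / duration,
             post_rate = pre / duration,
             retained = pre >= 1,
             relative_rate = ifelse(pre >= 1, swim / pre, NA),
             inhibition = ifelse(pre >= 1, 1 - swim / pre, NA),
             label = ifelse(pre < 1, NA,
                            ifelse(swim == 0, "quiescent",
                                   ifelse(swim < pre, "reduced", "non_reduced"))),
             stringsAsFactors = FALSE)
}

test_that("per-fish summaries average retained bouts and weight by sqrt(n)", {
  br <- make_bout_rates(pre = rep(4L, 100), swim = rep(1L, 100))
  md <- session_metadata(fish_id = "f1", population = "surface")
  fs <- summarize_fish(br, spontaneous_rate = 12.4, metadata = md)
  expect_equal(fs$n_swims, 100)
  expect_equal(fs$weight, 10)
  expect_equal(fs$mean_pre_rate, 4 / 0.3)
  expect_equal(fs$mean_inhibition, 0.75)

  one <- summarize_fish(make_bout_rates(3L, 2L), 10, md)
  expect_equal(one$mean_swim_rate, 2 / 0.3)
  expect_equal(one$weight, 1)

  none <- make_bout_rates(pre = c(0L, 0L), swim = c(1L, 0L))
  expect_error(summarize_fish(none, 10, md),
               class = "lateralline_no_retained_bouts")
})

test_that("mean-variance screening log-transforms Poisson-like variables only", {
  set.seed(9)
  groups <- factor(rep(1:12, each = 15))
  mu <- rep(seq(2, 50, length.out = 12), each = 15)

  # variance proportional to mean: should transform nearly always
  pois_hits <- replicate(20, {
    d <- data.frame(v = rpois(length(mu), mu))
    maybe_log_transform(d, groups)$transformed[["v"]]
  })
  expect_gt(mean(pois_hits), 0.9)

  # homoscedastic Gaussian: false-flag rate near alpha
  null_hits <- replicate(200, {
    d <- data.frame(v = rnorm(length(mu), mu, 5))
    maybe_log_transform(d, groups)$transformed[["v"]]
  })
  expect_lt(mean(null_hits), 0.12)

  # constant variable: never transformed
  d3 <- data.frame(v = rep(1, length(mu)))
  expect_false(maybe_log_transform(d3, groups)$transformed[["v"]])

  # zeros handled with the half-minimum offset
  d4 <- data.frame(v = c(rpois(90, 0.5), rpois(90, 30)))
  g4 <- factor(rep(1:12, each = 15))
  res4 <- maybe_log_transform(d4, g4)
  if (res4$transformed[["v"]]) expect_true(all(is.finite(res4$data$v)))

  expect_error(maybe_log_transform(data.frame(v = 1:6), factor(rep(1:3, 2))))
})

test_that("weighted unity test matches the closed-form WLS oracle", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    x <- rnorm(n, 15, 3)
    y <- 0.4 * x + rnorm(n, 0, 2)
    w <- runif(n, 0.5, 10)
    ut <- weighted_unity_test(x, y, w)
    # closed-form WLS: beta = (X'WX)^{-1} X'Wy, CI from t(n-2)
    X <- cbind(1, x)
    XtW <- t(X * w)
    beta <- solve(XtW %*% X, XtW %*% y)
    e <- y - X %*% beta
    s2 <- sum(w * e^2) / (n - 2)
    se_slope <- sqrt(s2 * solve(XtW %*% X)[2, 2])
    expect_equal(ut$slope, beta[2], tolerance = 1e-10)
    expect_equal(ut$intercept, beta[1], tolerance = 1e-10)
    tcrit <- qt(0.975, n - 2)
    expect_equal(ut$slope_ci_low, beta[2] - tcrit * se_slope, tolerance = 1e-8)
    expect_equal(ut$slope_ci_high, beta[2] + tcrit * se_slope, tolerance = 1e-8)
    expect_identical(ut$excludes_unity,
                     (ut$slope_ci_low > 1) || (ut$slope_ci_high < 1))
  }
})

test_that("unit weights reduce WLS to OLS and edge cases error", {
  set.seed(11)
  x <- rnorm(10, 10, 2)
  y <- x + rnorm(10, 0, 0.5)
  ut_w <- weighted_unity_test(x, y, rep(1, 10))
  ols <- lm(y ~ x)
  expect_equal(ut_w$slope, unname(coef(ols)[2]), tolerance = 1e-12)
  expect_equal(unname(c(ut_w$slope_ci_low, ut_w$slope_ci_high)),
               unname(confint(ols)[2, ]), tolerance = 1e-12)

  # identity data: slope exactly 1, unity not excluded (exact fit warns)
  ut_id <- suppressWarnings(weighted_unity_test(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(ut_id$slope, 1)
  expect_false(ut_id$excludes_unity)

  expect_error(weighted_unity_test(c(1, 2), c(1, 2)))
  expect_error(weighted_unity_test(rep(2, 5), rnorm(5)))
})

test_that("paired test matches hand computation and handles identical pairs", {
  id <- paired_swim_test(c(3, 5, 7), c(3, 5, 7))
  expect_equal(unname(id$statistic), 0)
  expect_equal(id$p.value, 1)

  # hand-computed 5-pair case: d = (1, 2, 0, 3, -1), mean 1, sd sqrt(2.5)
  swim <- c(11, 12, 10, 14, 9)
  rest <- c(10, 10, 10, 11, 10)
  ht <- paired_swim_test(swim, rest)
  t_hand <- 1 / (sqrt(2.5) / sqrt(5))
  expect_equal(unname(ht$statistic), t_hand, tolerance = 1e-12)
  expect_equal(ht$p.value, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)

  expect_error(paired_swim_test(1:4, 1:3))
  expect_error(paired_swim_test(1, 1))
})

test_that("paired and unpaired tests hold their nominal type-I error", {
  set.seed(12)
  p_paired <- replicate(4000, paired_swim_test(rnorm(8, 10, 2),
                                               rnorm(8, 10, 2))$p.value)
  expect_lt(abs(mean(p_paired < 0.05) - 0.05), 0.015)

  p_unpaired <- replicate(4000, unpaired_test(rnorm(6, 5, 2),
                                              rnorm(12, 5, 2))$p.value)
  expect_lt(abs(mean(p_unpaired < 0.05) - 0.05), 0.015)
})

test_that("unpaired test matches the pooled-variance closed form", {
  a <- c(4, 6, 8)
  b <- c(1, 2, 3, 6)
  ht <- unpaired_test(a, b)
  sp2 <- ((3 - 1) * var(a) + (4 - 1) * var(b)) / (3 + 4 - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 4))
  expect_equal(unname(ht$statistic), t_hand, tolerance = 1e-12)
  expect_equal(unname(ht$parameter), 5)

  same <- unpaired_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_error(unpaired_test(1, c(1, 2)))
})

test_that("one-way ANOVA matches a brute-force sum-of-squares computation", {
  set.seed(13)
  d <- data.frame(y = rnorm(12, rep(c(5, 9, 6), each = 4), 1),
                  pop = rep(c("a", "b", "c"), each = 4),
                  trt = "control")
  gc <- group_comparison(d, "y", "pop")
  # brute force
  grand <- mean(d$y)
  ssb <- sum(tapply(d$y, d$pop, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(d$y, d$pop, function(v) sum((v - mean(v))^2)))
  f_brute <- (ssb / 2) / (ssw / 9)
  expect_equal(gc$anova[["F value"]][1], f_brute, tolerance = 1e-10)
  expect_equal(gc$anova[["Df"]], c(2, 9))
})

test_that("Tukey letters partition groups consistently with pairwise p-values", {
  set.seed(14)
  # two well-separated groups get distinct letters
  d <- data.frame(y = c(rnorm(10, 0, 1), rnorm(10, 10, 1)),
                  g = rep(c("low", "high"), each = 10))
  gc <- group_comparison(d, "y", "g")
  expect_false(gc$letters[["low"]] == gc$letters[["high"]])

  # a single population yields one shared letter in most simulations
  single <- replicate(20, {
    dd <- data.frame(y = rnorm(40, 5, 1), g = rep(letters[1:4], each = 10))
    all(group_comparison(dd, "y", "g")$letters == "a")
  })
  expect_gte(mean(single), 0.9)

  # consistency invariant on heterogeneous data: no letter shared by a
  # significantly different pair; every pair not significantly different
  # that shares no letter would be a miss of the display
  for (i in 1:10) {
    dd <- data.frame(y = rnorm(50, rep(runif(5, 0, 6), each = 10), 1),
                     g = rep(letters[1:5], each = 10))
    gc2 <- group_comparison(dd, "y", "g")
    for (k in seq_len(nrow(gc2$tukey))) {
      pair <- strsplit(gc2$tukey$comparison[k], "-", fixed = TRUE)[[1]]
      shared <- intersect(strsplit(gc2$letters[[pair[1]]], "")[[1]],
                          strsplit(gc2$letters[[pair[2]]], "")[[1]])
      if (gc2$tukey$p_adj[k] < 0.05) {
        expect_length(shared, 0)
      } else {
        expect_gt(length(shared), 0)
      }
    }
  }

  # singleton group is named in the error
  ds <- data.frame(y = rnorm(5), g = c("a", "a", "b", "b", "solo"))
  expect_error(group_comparison(ds, "y", "g"), "solo")
})

test_that("combined-factor ANOVA reproduces the 8-cell degrees of freedom", {
  set.seed(15)
  d <- expand.grid(rep = 1:7, population = c("surface", "pachon"),
                   treatment = c("control", "ablated"),
                   period = c("pre", "swim"))
  d$y <- rnorm(nrow(d), 15, 3)
  gc <- group_comparison(d, "y", c("population", "treatment", "period"),
                         factorial = TRUE)
  expect_equal(gc$anova[["Df"]][1], 7)   # 8 cells
  expect_equal(length(gc$letters), 8)
  expect_true(!is.null(gc$factorial))
})
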