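test_that("lipid-to-vesicle conversion follows the 90,000-lipid rule", {
  comp <- lipid_composition(c(PtdChol = 1))
  expect_equal(vesicle_concentration(90e-6, comp), 1e-9)
  expect_equal(vesicle_concentration(0, comp), 0)
  ## 270 uM lipid sits at the top of the 0.3-3 nM vesicle regime
  expect_equal(vesicle_concentration(270e-6, comp), 3e-9)
  expect_error(vesicle_concentration(-1e-6, comp), class = "invalid_argument")
})

test_that("noiseless single-exponential is recovered to machine precision", {
  t <- seq(0, 2, length.out = 100)
  fit <- fit_monoexponential(kinetic_trace(t, 2 + 3 * exp(-5 * t)))
  expect_equal(fit$F0, 2, tolerance = 1e-9)
  expect_equal(fit$A_obs, 3, tolerance = 1e-9)
  expect_equal(fit$k_obs, 5, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-18)
})

test_that("exponential fit handles noise, degeneracy and the grid oracle", {
  tr <- simulate_stopped_flow(1e11, 20, 1e-9,
                              list(F0 = 1, amplitude = 0.5, duration = 0.04,
                                   n_points = 150),
                              noise_model(0.01, 42))[[1]]
  fit <- fit_monoexponential(tr)
  expect_lt(abs(fit$k_obs - tr$meta$k_obs), 3 * fit$se[["k_obs"]])
  ## brute-force grid over log10 k with linear LS never beats the fitter
  expect_lte(fit$rss, grid_rss_exponential(tr$t, tr$F) * (1 + 1e-8))

  expect_error(fit_monoexponential(kinetic_trace(1:10, rep(2, 10))),
               class = "degenerate_signal")
  expect_error(kinetic_trace(c(1, 2, 2, 3), 1:4), class = "invalid_trace")
  expect_error(kinetic_trace(1:3, 1:3), class = "invalid_trace")
})

test_that("exponential fit is invariant to affine rescaling of the signal", {
  t <- seq(0, 1, length.out = 80)
  set.seed(9)
  F <- 2 + 3 * exp(-4 * t) + rnorm(80, 0, 0.02)
  f1 <- fit_monoexponential(kinetic_trace(t, F))
  f2 <- fit_monoexponential(kinetic_trace(t, 10 * F - 7))
  expect_equal(f2$k_obs, f1$k_obs, tolerance = 1e-6)
  expect_equal(f2$F0, 10 * f1$F0 - 7, tolerance = 1e-6)
  expect_equal(f2$A_obs, 10 * f1$A_obs, tolerance = 1e-6)
})

test_that("rate law fit reproduces exact lines and propagates noise", {
  v <- c(0.5, 1, 2, 3) * 1e-9
  rc <- fit_rate_law(kinetic_series(v, 1e11 * v + 20))
  expect_equal(rc$k_on, 1e11, tolerance = 1e-9)
  expect_equal(rc$k_off, 20, tolerance = 1e-9)
  expect_equal(rc$K_d, 2e-10, tolerance = 1e-9)

  two <- fit_rate_law(kinetic_series(c(1e-9, 2e-9), c(120, 220)))
  expect_equal(sum(residuals(two$fit)^2), 0, tolerance = 1e-20)

  set.seed(31)
  v8 <- seq(0.3e-9, 3e-9, length.out = 8)
  k8 <- 1e11 * v8 + 20 + rnorm(8, 0, 5)
  rc8 <- fit_rate_law(kinetic_series(v8, k8))
  expect_lt(abs(rc8$K_d - 2e-10), 3 * rc8$se[["K_d"]])

  expect_error(kinetic_series(c(1e-9, 1e-9), c(1, 2)), class = "invalid_series")
})

test_that("K_d identity and negative-intercept warning hold on all outputs", {
  set.seed(12)
  for (i in 1:10) {
    v <- sort(runif(6, 1e-10, 3e-9))
    k <- runif(1, 1e10, 1e11) * v + runif(1, 0, 30) + rnorm(6, 0, 2)
    rc <- suppressWarnings(fit_rate_law(kinetic_series(v, k)))
    expect_identical(rc$K_d, rc$k_off / rc$k_on)
  }
  ## strongly negative intercept -> warning, unclamped value
  v <- c(1, 2, 3, 4) * 1e-9
  expect_warning(rc <- fit_rate_law(kinetic_series(v, 1e11 * v - 50)),
                 class = "negative_k_off")
  expect_lt(rc$k_off, 0)
})

test_that("zero-k_off data give intercept CIs covering zero >= 90% of the time", {
  v <- seq(0.3e-9, 3e-9, length.out = 8)
  hits <- vapply(1:100, function(r) {
    set.seed(5000 + r)
    k <- 1e11 * v + rnorm(8, 0, 8)
    rc <- suppressWarnings(fit_rate_law(kinetic_series(v, k)))
    ci <- rc$k_off + c(-1, 1) * qt(0.975, 6) * rc$se[["k_off"]]
    ci[1] <= 0 && ci[2] >= 0
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("ANOVA and Fisher LSD match algebraic identities and a SS oracle", {
  ## two groups: F equals the square of the pooled t statistic
  g2 <- list(a = c(1.1, 2.0, 1.4, 1.7), b = c(2.1, 2.6, 2.2))
  out <- compare_conditions(g2)
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(out$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$anova$p, tt$p.value, tolerance = 1e-10)

  ## identical groups: F = 0, p = 1
  same <- compare_conditions(list(a = c(3, 3), b = c(3, 3), c = c(3, 3)))
  expect_equal(same$anova$F, 0)
  expect_equal(same$anova$p, 1)

  ## 3-group oracle: direct sum-of-squares decomposition
  set.seed(8)
  g3 <- list(x = rnorm(5, 0), y = rnorm(6, 1), z = rnorm(4, 0.5))
  out3 <- compare_conditions(g3)
  y <- unlist(g3); n <- length(y); k <- 3
  gm <- mean(y)
  ssb <- sum(vapply(g3, function(g) length(g) * (mean(g) - gm)^2, 1.0))
  ssw <- sum(vapply(g3, function(g) sum((g - mean(g))^2), 1.0))
  Fo <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(out3$anova$F, Fo, tolerance = 1e-10)
  expect_equal(out3$anova$p, pf(Fo, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)
  ## LSD pairwise p for one pair, recomputed from the pooled MSE
  mse <- ssw / (n - k)
  d <- mean(g3$x) - mean(g3$y)
  se <- sqrt(mse * (1 / 5 + 1 / 6))
  p_or <- 2 * pt(-abs(d / se), n - k)
  row <- out3$pairwise[out3$pairwise$group1 == "x" & out3$pairwise$group2 == "y", ]
  expect_equal(row$p, p_or, tolerance = 1e-10)

  expect_error(compare_conditions(list(a = 1, b = c(1, 2))),
               class = "invalid_groups")
})
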