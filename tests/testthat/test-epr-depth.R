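test_that("saturation fit recovers exact parameters and scales correctly", {
  P <- saturation_powers()
  cur <- simulate_power_saturation(c(O2 = 9), eps = 1.2, scale = 2,
                                   powers = P)$O2
  fit <- fit_saturation(cur)
  expect_equal(fit$P_half, 9, tolerance = 1e-6)
  expect_equal(fit$eps, 1.2, tolerance = 1e-5)
  expect_equal(fit$I, 2, tolerance = 1e-6)

  doubled <- saturation_curve(cur$P, 2 * cur$A, "O2")
  f2 <- fit_saturation(doubled)
  expect_equal(f2$P_half, fit$P_half, tolerance = 1e-6)
  expect_equal(f2$eps, fit$eps, tolerance = 1e-5)
  expect_equal(f2$I, 2 * fit$I, tolerance = 1e-6)
})

test_that("saturation fit RSS never exceeds a (P_half, eps) grid oracle", {
  cur <- simulate_power_saturation(c(NiEDDA = 5), eps = 1.4, scale = 1,
                                   noise = noise_model(0.004, 13))$NiEDDA
  fit <- fit_saturation(cur)
  grid <- expand.grid(Ph = exp(seq(log(0.5), log(100), length.out = 60)),
                      eps = seq(0.5, 1.5, length.out = 21))
  rss_grid <- min(vapply(seq_len(nrow(grid)), function(i) {
    shape <- sqrt(cur$P) *
      (1 + (2^(1 / grid$eps[i]) - 1) * cur$P / grid$Ph[i])^(-grid$eps[i])
    I <- sum(shape * cur$A) / sum(shape^2)  # exact LS in the linear scale
    sum((cur$A - I * shape)^2)
  }, 1.0))
  expect_lte(fit$rss, rss_grid * (1 + 1e-8))
})

test_that("unsaturated curves raise the unbounded-fit warning", {
  cur <- simulate_power_saturation(c(N2 = 2000), powers = saturation_powers())$N2
  expect_warning(fit <- fit_saturation(cur), class = "unbounded_fit")
  expect_true(fit$unbounded)
  expect_gt(fit$P_half, max(cur$P))
})

test_that("depth parameter is the log ratio of relaxant-induced shifts", {
  expect_equal(depth_parameter(8, 8, 2)$phi, 0)
  expect_equal(depth_parameter(2 + 2 * exp(1), 4, 2)$phi, 1)
  expect_error(depth_parameter(2, 5, 3), class = "invalid_accessibility")
  ## error propagation: pure O2 uncertainty
  dp <- depth_parameter(10, 4, 2, se = c(O2 = 0.8, NiEDDA = 0, N2 = 0))
  expect_equal(dp$phi_err, 0.8 / 8)
})

test_that("the measured depth table orders insertion depths as expected", {
  tab <- spin_label_depths()
  expect_equal(nrow(tab), 15)
  ps20 <- tab[tab$composition == "20% PtdSer", ]
  phi173 <- ps20$phi[ps20$site == 173]
  phi304 <- ps20$phi[ps20$site == 304]
  expect_equal(phi173, 1.20)
  expect_gt(phi173, phi304)  # Ca-loop site 173 buried deeper than 304
})

test_that("tanh calibration recovers exact parameters and inverts", {
  x <- seq(-10, 12, length.out = 12)
  phi <- 3 * tanh(0.12 * (x - 1)) + 0.5
  cal <- fit_calibration(data.frame(phi = phi, distance_A = x))
  expect_equal(cal$form, "tanh")
  expect_equal(cal$pars$A, 3, tolerance = 1e-6)
  expect_equal(cal$pars$B, 0.12, tolerance = 1e-6)
  expect_equal(cal$pars$C, 1, tolerance = 1e-5)
  expect_equal(cal$pars$D, 0.5, tolerance = 1e-6)
  ## phi at the curve midpoint maps back to the centre parameter
  expect_equal(depth_from_phi(0.5, cal)$x, 1, tolerance = 1e-6)
  ## round trip phi -> x -> phi inside the monotone domain
  for (ph in seq(-2, 3, by = 0.5)) {
    expect_equal(predict(cal, depth_from_phi(ph, cal)$x), ph,
                 tolerance = 1e-6)
  }
  ## monotone: x1 < x2 => phi(x1) < phi(x2)
  xs <- seq(-15, 15, length.out = 50)
  expect_true(all(diff(predict(cal, xs)) > 0))
})

test_that("the measured pairs fit the calibration with sub-Angstrom residuals", {
  tab <- spin_label_depths()
  cal <- fit_calibration(data.frame(phi = tab$phi, distance_A = tab$distance_A))
  pred_x <- depth_from_phi(tab$phi, cal)$x
  expect_true(all(abs(pred_x - tab$distance_A) < 1))
})

test_that("non-monotone pairs are rejected and misfit falls back to a spline", {
  bad <- data.frame(phi = c(-2, 1.5, -1, 2, -0.5, 0.1),
                    distance_A = c(-6, -3, 0, 3, 6, 9))
  expect_error(fit_calibration(bad), class = "calibration_rejected")

  tab <- spin_label_depths()
  cal <- fit_calibration(data.frame(phi = tab$phi,
                                    distance_A = tab$distance_A),
                         fallback_rms = 1e-9)
  expect_equal(cal$form, "spline")
  ## spline calibration still inverts inside its data range
  for (ph in c(-1.8, -0.5, 0.9)) {
    expect_equal(predict(cal, depth_from_phi(ph, cal)$x), ph,
                 tolerance = 1e-6)
  }
})

test_that("out-of-range phi values are clamped with a warning", {
  tab <- spin_label_depths()
  cal <- fit_calibration(data.frame(phi = tab$phi, distance_A = tab$distance_A))
  expect_warning(res <- depth_from_phi(8, cal), class = "phi_clamped")
  expect_true(is.finite(res$x))
})

test_that("uncertainty propagates through the local calibration slope", {
  tab <- spin_label_depths()
  cal <- fit_calibration(data.frame(phi = tab$phi, distance_A = tab$distance_A))
  r <- depth_from_phi(0.2, cal, phi_err = 0.1)
  ## finite-difference slope check
  h <- 1e-5
  slope <- (0.2 + h - 0.2) /
    (depth_from_phi(0.2 + h, cal)$x - depth_from_phi(0.2, cal)$x)
  expect_equal(r$x_err, 0.1 / abs(slope), tolerance = 1e-3)
})

test_that("saturation-to-depth chain recovers a planted depth profile", {
  tab <- spin_label_depths()
  cal <- fit_calibration(data.frame(phi = tab$phi, distance_A = tab$distance_A))
  x_true <- 6.5
  phi_true <- predict(cal, x_true)
  ## choose P_half values consistent with that phi
  ph <- c(N2 = 1.5, NiEDDA = 1.5 + 2, O2 = 1.5 + 2 * exp(phi_true))
  curves <- simulate_power_saturation(ph, noise = noise_model(0.002, 29))
  fits <- lapply(curves, fit_saturation)
  dp <- depth_parameter(fits$O2$P_half, fits$NiEDDA$P_half, fits$N2$P_half)
  est <- depth_from_phi(dp$phi, cal)
  expect_equal(est$x, x_true, tolerance = 0.5)
})
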