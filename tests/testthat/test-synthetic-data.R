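test_that("lipid composition enforces its invariants", {
  comp <- lipid_composition(c(PtdChol = 0.88, PtdSer = 0.10, PtdInsP2 = 0.02))
  expect_s3_class(comp, "lipid_composition")
  expect_error(lipid_composition(c(a = 0.5, b = 0.4)), class = "invalid_composition")
  expect_error(lipid_composition(c(a = 1.2, b = -0.2)), class = "invalid_composition")
  expect_error(lipid_composition(c(a = 1), accessible_fraction = 0),
               class = "invalid_composition")
  expect_error(lipid_composition(c(a = 1), lipids_per_vesicle = -1),
               class = "invalid_argument")
})

test_that("stopped-flow generator is the exact inverse of the rate model", {
  ## k_on [v] + k_off = 1e11 * 1e-9 + 5 = 105 s^-1 at any resolution
  for (np in c(10, 200)) {
    tr <- simulate_stopped_flow(1e11, 5, 1e-9,
                                trace_params = list(F0 = 2, amplitude = 3,
                                                    duration = 0.05,
                                                    n_points = np))[[1]]
    expect_equal(tr$meta$k_obs, 105)
    expect_equal(tr$F, 2 + 3 * exp(-105 * tr$t))
  }
  expect_error(simulate_stopped_flow(1e11, 5, 1e-9,
                                     trace_params = list(n_points = 3)),
               class = "invalid_protocol")
  expect_error(simulate_stopped_flow(1e11, 5, 1e-9,
                                     trace_params = list(duration = -1)),
               class = "invalid_protocol")
  expect_error(simulate_stopped_flow(1e11, 5, 0), class = "invalid_protocol")
})

test_that("identical seeds give bitwise-identical synthetic data", {
  a <- simulate_stopped_flow(1e11, 5, c(1e-9, 2e-9), noise = noise_model(0.01, 7))
  b <- simulate_stopped_flow(1e11, 5, c(1e-9, 2e-9), noise = noise_model(0.01, 7))
  expect_identical(a, b)
  c <- simulate_stopped_flow(1e11, 5, c(1e-9, 2e-9), noise = noise_model(0.01, 8))
  expect_false(identical(a[[1]]$F, c[[1]]$F))

  prot <- titration_protocol(1.4e-3, 50e-6, 1e-3, rep(10e-6, 10))
  expect_identical(simulate_itc(1, 14e-6, -30, prot, noise_model(1e-5, 3))$q,
                   simulate_itc(1, 14e-6, -30, prot, noise_model(1e-5, 3))$q)
  expect_identical(simulate_sedimentation(1e4, c(1e-5, 1e-4), noise_model(0.02, 3)),
                   simulate_sedimentation(1e4, c(1e-5, 1e-4), noise_model(0.02, 3)))
})

test_that("seeded generators leave the caller's RNG stream untouched", {
  set.seed(99)
  expected <- runif(3)
  set.seed(99)
  invisible(simulate_sedimentation(1e4, c(1e-5, 1e-4), noise_model(0.02, 3)))
  expect_identical(runif(3), expected)
})

test_that("ITC generator obeys its limiting cases", {
  prot <- titration_protocol(1.4e-3, 50e-6, 1e-3, rep(10e-6, 25))
  expect_equal(simulate_itc(1, 14e-6, 0, prot)$q, rep(0, 25))

  ## stoichiometric limit: constant heats per injected mole until the
  ## equivalence point, then ~0
  h <- predict_heats(1, 1e-12, -30, prot)
  mol_inj <- 1e-3 * 10e-6
  pre <- which(h$molar_ratio < 0.85)
  post <- which(h$molar_ratio > 1.3)
  expect_equal(h$q[pre] / (-30 * mol_inj), rep(1, length(pre)), tolerance = 1e-3)
  expect_lt(max(abs(h$q[post])), 0.01 * abs(-30 * mol_inj))
})

test_that("sedimentation generator hits half-saturation and clips noise", {
  K <- 4.7e4
  expect_equal(simulate_sedimentation(K, 1 / K)$f_b, 0.5)
  expect_equal(simulate_sedimentation(K, 0)$f_b, 0)
  noisy <- simulate_sedimentation(K, rep(c(1e-7, 1e-1), 20),
                                  noise_model(0.5, 11))
  expect_true(all(noisy$f_b >= 0 & noisy$f_b <= 1))
})

test_that("power-saturation generator matches the rollover model", {
  curves <- simulate_power_saturation(c(N2 = 2, O2 = 12, NiEDDA = 5),
                                      powers = saturation_powers())
  expect_named(curves, c("N2", "O2", "NiEDDA"))
  ## low-power limit: A / sqrt(P) -> I
  lowP <- 1e-6
  c0 <- simulate_power_saturation(c(N2 = 2), scale = 3,
                                  powers = c(lowP, 1, 2, 3, 4))$N2
  expect_equal(c0$A[1] / sqrt(lowP), 3, tolerance = 1e-5)
  ## equal P_half for O2 and NiEDDA => phi = 0 downstream
  eq <- simulate_power_saturation(c(N2 = 2, O2 = 8, NiEDDA = 8))
  f <- lapply(eq, fit_saturation)
  expect_equal(depth_parameter(f$O2$P_half, f$NiEDDA$P_half, f$N2$P_half)$phi,
               0, tolerance = 1e-6)
})

test_that("HSQC generator plants perturbations exactly", {
  base <- base_hsqc_peaks()
  clean <- simulate_hsqc_shifts(base)
  expect_identical(clean$reference, clean$titrated)
  one <- simulate_hsqc_shifts(base, list("326" = c(0.1, 0.5)))
  prof <- csp_profile(one$reference, one$titrated)
  expect_identical(prof$residue[prof$csp > 0], 326L)
  expect_error(simulate_hsqc_shifts(base, list("9999" = c(0.1, 0.5))),
               class = "invalid_protocol")
})

test_that("toy domain is deterministic, compact and complete", {
  a <- make_toy_domain(24, geometry_seed = 5)
  b <- make_toy_domain(24, geometry_seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, make_toy_domain(24, geometry_seed = 6)))
  rg <- radius_of_gyration(a)
  expect_gt(rg, 5); expect_lt(rg, 20)
  counts <- table(a$atoms$residue)
  expect_true(all(counts == 2))  # CA + CB everywhere
  expect_error(make_toy_domain(3), class = "invalid_protocol")
})

test_that("fitter recovery error grows monotonically with noise", {
  sigmas <- c(0.005, 0.03, 0.12)
  K <- 2.2e4
  L <- 10^seq(-6, -2.5, length.out = 12)
  med_err_K <- vapply(seq_along(sigmas), function(si) {
    errs <- vapply(1:20, function(r) {
      d <- simulate_sedimentation(K, L, noise_model(sigmas[si], 100 * si + r))
      abs(fit_partition(d)$K - K) / K
    }, 1.0)
    median(errs)
  }, 1.0)
  expect_true(all(diff(med_err_K) > 0))

  tp <- list(F0 = 1, amplitude = 0.5, duration = 0.05, n_points = 120)
  med_err_k <- vapply(seq_along(sigmas), function(si) {
    errs <- vapply(1:20, function(r) {
      tr <- simulate_stopped_flow(1e11, 20, 1e-9, tp,
                                  noise_model(sigmas[si], 200 * si + r))[[1]]
      abs(fit_monoexponential(tr)$k_obs - tr$meta$k_obs) / tr$meta$k_obs
    }, 1.0)
    median(errs)
  }, 1.0)
  expect_true(all(diff(med_err_k) > 0))
})
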