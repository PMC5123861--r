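#' Simulate pseudo-first-order stopped-flow binding traces
#'
#' Generates single-exponential fluorescence traces
#' F(t) = F0 + A exp(-(k_on [v] + k_off) t) plus additive Gaussian noise,
#' one trace per vesicle concentration. The generator is the exact inverse
#' of [fit_monoexponential()] / [fit_rate_law()] at zero noise, and each
#' trace's metadata records the generating ground truth.
#'
#' @param k_on Association rate constant, M^-1 s^-1.
#' @param k_off Dissociation rate constant, s^-1.
#' @param vesicle_concs Vesicle concentrations, molar (all > 0).
#' @param trace_params List with `F0` (offset), `amplitude`, `duration`
#'   (seconds; `NULL` auto-selects 5/k_obs per trace) and `n_points`.
#' @param noise A [noise_model()] in fluorescence units.
#' @return List of [kinetic_trace()] objects.
#' @export
simulate_stopped_flow <- function(k_on, k_off, vesicle_concs,
                                  trace_params = list(F0 = 1, amplitude = 0.5,
                                                      duration = NULL,
                                                      n_points = 200),
                                  noise = noise_model(0)) {
  stopifnot_scalar_pos(k_on, "k_on")
  stopifnot_scalar_pos(k_off, "k_off")
  if (any(vesicle_concs <= 0)) {
    cm_stop("vesicle concentrations must be > 0", "invalid_protocol")
  }
  np <- trace_params$n_points %||% 200
  if (np < 4) cm_stop("n_points must be >= 4", "invalid_protocol")
  if (!is.null(trace_params$duration) && trace_params$duration <= 0) {
    cm_stop("duration must be positive", "invalid_protocol")
  }
  F0 <- trace_params$F0 %||% 1
  A <- trace_params$amplitude %||% 0.5
  with_seed(noise$seed, {
    lapply(vesicle_concs, function(v) {
      k_obs <- k_on * v + k_off
      dur <- trace_params$duration %||% (5 / k_obs)
      t <- seq(0, dur, length.out = np)
      Fsig <- perturb(F0 + A * exp(-k_obs * t), noise)
      kinetic_trace(t, Fsig, meta = list(
        vesicle_M = v, k_on = k_on, k_off = k_off, k_obs = k_obs,
        F0 = F0, amplitude = A, sigma = noise$sigma))
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an ITC titration from the single-site isotherm
#'
#' Computes exact finite-concentration per-injection heats with
#' [predict_heats()] (perfusion dilution bookkeeping included) and perturbs
#' them with additive Gaussian noise in kJ. The generator inverts
#' [fit_isotherm()] exactly at zero noise.
#'
#' @inheritParams predict_heats
#' @param noise A [noise_model()]; `sigma` in kJ.
#' @return An `injection_heats` object whose `truth` element records the
#'   generating parameters.
#' @export
simulate_itc <- function(n, K_d, dH, protocol, noise = noise_model(0)) {
  h <- predict_heats(n, K_d, dH, protocol)
  h$q <- with_seed(noise$seed, perturb(h$q, noise))
  h$truth <- list(n = n, K_d = K_d, dH = dH, sigma = noise$sigma)
  h
}

#' Simulate a vesicle-sedimentation partitioning dataset
#'
#' Fraction bound from f_b = K L / (1 + K L) plus additive Gaussian noise,
#' clipped back to `[0, 1]`.
#'
#' @param K Reciprocal molar partition coefficient, M^-1.
#' @param lipid_concs Accessible lipid concentrations, molar.
#' @param noise A [noise_model()] in fraction-bound units.
#' @return A [partition_dataset()] whose metadata records the truth.
#' @export
simulate_sedimentation <- function(K, lipid_concs, noise = noise_model(0)) {
  stopifnot_scalar_pos(K, "K")
  fb <- fraction_bound(K, lipid_concs)
  fb <- with_seed(noise$seed, perturb(fb, noise))
  partition_dataset(lipid_concs, pmin(pmax(fb, 0), 1),
                    meta = list(K = K, sigma = noise$sigma))
}

#' Simulate EPR power-saturation curves
#'
#' Amplitudes follow A(P) = I sqrt(P) (1 + (2^(1/eps) - 1) P / P_half)^(-eps)
#' for each relaxant condition, sampled at the supplied powers and perturbed
#' with additive Gaussian noise.
#'
#' @param P_half Named vector of half-saturation powers in mW, e.g.
#'   `c(N2 = 2, O2 = 12, NiEDDA = 5)`.
#' @param eps Homogeneity exponent shared across conditions (default 1.5).
#' @param scale Unsaturated amplitude scale I.
#' @param powers Microwave powers in mW (default [saturation_powers()]).
#' @param noise A [noise_model()] in amplitude units.
#' @return Named list of [saturation_curve()] objects.
#' @export
simulate_power_saturation <- function(P_half, eps = 1.5, scale = 1,
                                      powers = saturation_powers(),
                                      noise = noise_model(0)) {
  if (is.null(names(P_half)) ||
      !all(names(P_half) %in% c("N2", "O2", "NiEDDA"))) {
    cm_stop("`P_half` must be named with conditions N2/O2/NiEDDA",
            "invalid_protocol")
  }
  if (any(P_half <= 0)) cm_stop("P_half values must be > 0", "invalid_protocol")
  stopifnot_scalar_pos(eps, "eps")
  stopifnot_scalar_pos(scale, "scale")
  with_seed(noise$seed, {
    out <- lapply(names(P_half), function(cond) {
      A <- scale * sqrt(powers) *
        (1 + (2^(1 / eps) - 1) * powers / P_half[[cond]])^(-eps)
      saturation_curve(powers, perturb(A, noise), cond)
    })
    stats::setNames(out, names(P_half))
  })
}

#' Simulate a pair of HSQC peak lists with planted perturbations
#'
#' Returns a reference peak list and a titrated list in which the supplied
#' residues are displaced by the given (dH, dN) ppm changes; both lists are
#' then perturbed with additive Gaussian noise in ppm.
#'
#' @param base_peaks Data frame with columns `residue`, `dH_ppm`, `dN_ppm`
#'   (absolute peak positions).
#' @param perturbed_residues Named list mapping residue number to
#'   `c(dH, dN)` ppm displacements, e.g. `list("326" = c(0.08, 0.5))`.
#' @param noise A [noise_model()] in ppm.
#' @return List with elements `reference` and `titrated` (data frames) and
#'   `truth`.
#' @export
simulate_hsqc_shifts <- function(base_peaks, perturbed_residues = list(),
                                 noise = noise_model(0)) {
  stopifnot(is.data.frame(base_peaks),
            all(c("residue", "dH_ppm", "dN_ppm") %in% names(base_peaks)))
  tit <- base_peaks
  for (res in names(perturbed_residues)) {
    i <- which(tit$residue == as.integer(res))
    if (!length(i)) {
      cm_stop(sprintf("perturbed residue %s not in base peaks", res),
              "invalid_protocol")
    }
    d <- perturbed_residues[[res]]
    tit$dH_ppm[i] <- tit$dH_ppm[i] + d[1]
    tit$dN_ppm[i] <- tit$dN_ppm[i] + d[2]
  }
  with_seed(noise$seed, {
    ref <- base_peaks
    ref$dH_ppm <- perturb(ref$dH_ppm, noise)
    ref$dN_ppm <- perturb(ref$dN_ppm, noise)
    tit$dH_ppm <- perturb(tit$dH_ppm, noise)
    tit$dN_ppm <- perturb(tit$dN_ppm, noise)
    list(reference = ref, titrated = tit,
         truth = list(perturbed = perturbed_residues, sigma = noise$sigma))
  })
}

#' Generate a compact synthetic toy domain
#'
#' Deterministic fold-like point set standing in for a real C2 domain in
#' docking tests: Calpha atoms laid out on a gently bent helix with seeded
#' jitter, plus Cbeta atoms offset 1.53 A outward from the local helix
#' axis. Identical seeds give identical coordinates. Labelled synthetic —
#' the geometry carries no relation to any deposited structure.
#'
#' @param n_residues Number of residues (>= 4).
#' @param geometry_seed Integer seed controlling the jitter.
#' @return A [structure_model()].
#' @export
make_toy_domain <- function(n_residues = 24, geometry_seed = 1) {
  if (n_residues < 4) cm_stop("need >= 4 residues", "invalid_protocol")
  with_seed(geometry_seed, {
    i <- seq_len(n_residues)
    phase <- 100 * pi / 180 * i           # ~3.6 residues/turn
    bend <- 0.015 * (i - n_residues / 2)^2
    ca <- cbind(2.3 * cos(phase) + bend,
                2.3 * sin(phase),
                1.5 * i)
    ca <- ca + matrix(stats::rnorm(3 * n_residues, 0, 0.15), ncol = 3)
    axis_pt <- cbind(bend, 0, 1.5 * i)    # local helix axis
    u <- ca - axis_pt
    u <- u / sqrt(rowSums(u^2))
    cb <- ca + 1.53 * u
    atoms <- rbind(
      data.frame(residue = i, atom = "CA", x = ca[, 1], y = ca[, 2], z = ca[, 3]),
      data.frame(residue = i, atom = "CB", x = cb[, 1], y = cb[, 2], z = cb[, 3]))
    atoms <- atoms[order(atoms$residue, atoms$atom), ]
    ## centre at the Calpha centroid so poses are rotations about the origin
    ctr <- colMeans(ca)
    atoms$x <- atoms$x - ctr[1]; atoms$y <- atoms$y - ctr[2]
    atoms$z <- atoms$z - ctr[3]
    structure_model(atoms)
  })
}

#' Radius of gyration of a structure's Calpha trace
#'
#' @param structure A [structure_model()].
#' @return Radius of gyration in Angstroms.
#' @export
radius_of_gyration <- function(structure) {
  a <- structure$atoms
  xyz <- as.matrix(a[a$atom == "CA", c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}
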