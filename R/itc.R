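#' ITC titration protocol
#'
#' Injection schedule for an isothermal titration calorimetry experiment:
#' ligand from the syringe titrated into macromolecule in a fixed-volume
#' (perfusion) cell.
#'
#' @param cell_volume Cell volume in litres.
#' @param cell_conc Macromolecule concentration in the cell, molar.
#' @param syringe_conc Ligand concentration in the syringe, molar.
#' @param injection_volumes Vector of injection volumes in litres (>= 3).
#' @param temperature Temperature in kelvin (default 298.15).
#' @return An object of class `titration_protocol`.
#' @export
#' @examples
#' titration_protocol(1.4e-3, 50e-6, 1e-3, rep(10e-6, 25))
titration_protocol <- function(cell_volume, cell_conc, syringe_conc,
                               injection_volumes, temperature = 298.15) {
  stopifnot_scalar_pos(cell_volume, "cell_volume")
  stopifnot_scalar_pos(cell_conc, "cell_conc")
  if (!is.numeric(syringe_conc) || length(syringe_conc) != 1L ||
      !is.finite(syringe_conc) || syringe_conc <= 0) {
    cm_stop("syringe concentration must be a positive scalar",
            "invalid_protocol")
  }
  stopifnot_scalar_pos(temperature, "temperature")
  if (length(injection_volumes) < 3L || any(injection_volumes <= 0) ||
      any(!is.finite(injection_volumes))) {
    cm_stop("need >= 3 positive injection volumes", "invalid_protocol")
  }
  structure(
    list(cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc,
         injection_volumes = as.numeric(injection_volumes),
         temperature = temperature),
    class = "titration_protocol"
  )
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat(sprintf(
    "ITC protocol: %.3g uM cell (%.3g mL), %.3g mM syringe, %d injections, %.2f K\n",
    x$cell_conc * 1e6, x$cell_volume * 1e3, x$syringe_conc * 1e3,
    length(x$injection_volumes), x$temperature))
  invisible(x)
}

## Single-site mass-action closure: bound complex concentration from total
## protein P, total ligand L, per-site Kd and stoichiometry n.
bound_concentration <- function(n, K_d, P, L) {
  b <- n * P + L + K_d
  disc <- b^2 - 4 * n * P * L
  if (any(disc < -1e-12 * b^2)) {
    cm_stop("negative discriminant in mass-action closure", "numerical_guard")
  }
  (b - sqrt(pmax(disc, 0))) / 2
}

#' Predict per-injection ITC heats from the single-site isotherm
#'
#' Computes the heat evolved at each injection for a 1:n single-site binding
#' model at finite concentrations. Dilution follows the perfusion (overflow)
#' model for a fixed-volume cell: each injection of volume v displaces a
#' fraction v/V0 of the cell contents, so both total protein and total ligand
#' concentrations track cumulative dilution. Bound ligand is solved from the
#' exact mass-action quadratic
#' B = ((n P + L + Kd) - sqrt((n P + L + Kd)^2 - 4 n P L)) / 2,
#' and the heat of injection i is dH * V0 * (B_i - B_{i-1} (1 - v_i/V0)).
#'
#' @param n Stoichiometry (sites per macromolecule).
#' @param K_d Per-site dissociation constant, molar.
#' @param dH Binding enthalpy, kJ/mol of ligand bound.
#' @param protocol A [titration_protocol()].
#' @return An object of class `injection_heats`: `q` (kJ per injection),
#'   `molar_ratio` (total ligand : total protein in the cell after each
#'   injection), and the running total concentrations.
#' @export
predict_heats <- function(n, K_d, dH, protocol) {
  stopifnot(inherits(protocol, "titration_protocol"))
  stopifnot_scalar_pos(n, "n")
  stopifnot_scalar_pos(K_d, "K_d")
  stopifnot(is.numeric(dH), length(dH) == 1L, is.finite(dH))
  V0 <- protocol$cell_volume
  vols <- protocol$injection_volumes
  m <- length(vols)
  P <- protocol$cell_conc; L <- 0; B_prev <- 0
  q <- mr <- P_t <- L_t <- numeric(m)
  for (i in seq_len(m)) {
    dil <- 1 - vols[i] / V0
    if (dil <= 0) cm_stop("injection volume exceeds cell volume",
                          "invalid_protocol")
    P <- P * dil
    L <- L * dil + protocol$syringe_conc * vols[i] / V0
    B <- bound_concentration(n, K_d, P, L)
    q[i] <- dH * V0 * (B - B_prev * dil)
    B_prev <- B
    mr[i] <- L / P; P_t[i] <- P; L_t[i] <- L
  }
  structure(list(q = q, molar_ratio = mr, P_total = P_t, L_total = L_t,
                 protocol = protocol),
            class = "injection_heats")
}

#' @export
print.injection_heats <- function(x, ...) {
  cat(sprintf("Injection heats: %d injections, total %.4g kJ, final molar ratio %.3g\n",
              length(x$q), sum(x$q), max(x$molar_ratio)))
  invisible(x)
}

#' Fit the single-site binding isotherm to injection heats
#'
#' Least-squares fit of (n, K_d, dH) — optionally with n fixed — to measured
#' per-injection heats, using the same finite-concentration perfusion model
#' as [predict_heats()]. A constant per-injection offset absorbing residual
#' heats of dilution is fitted by default (`offset = TRUE`); set
#' `offset = FALSE` when control titrations have already been subtracted and
#' no offset should be estimated. K_d is fitted on a log scale. Gibbs energy
#' and entropy are derived at the protocol temperature via [derive_thermo()].
#'
#' The Wiseman c-value, n * cell_conc / K_d, controls how much curvature the
#' titration carries; a warning is attached when it falls outside the
#' informative window of roughly 1 to 1000.
#'
#' @param heats An [injection_heats()] object or numeric vector of heats (kJ)
#'   matching the protocol.
#' @param protocol A [titration_protocol()].
#' @param fix_n Fix the stoichiometry at this value (e.g. 1) instead of
#'   fitting it; `NULL` (default) fits n.
#' @param exclude_first Drop the first injection from the fit (common
#'   practice for diffusion across the syringe tip); default `FALSE`.
#' @param offset Fit a constant per-injection dilution-heat offset; default
#'   `TRUE`.
#' @return An object of class `isotherm_fit` with `n`, `K_d`, `dH`, `dG`,
#'   `minus_TdS` (all energies kJ/mol), `se`, `rss`, `c_value`,
#'   `c_value_warning`, `offset`.
#' @export
fit_isotherm <- function(heats, protocol, fix_n = NULL,
                         exclude_first = FALSE, offset = TRUE) {
  if (inherits(heats, "injection_heats")) {
    if (is.null(protocol)) protocol <- heats$protocol
    q <- heats$q
  } else q <- as.numeric(heats)
  stopifnot(inherits(protocol, "titration_protocol"))
  if (length(q) != length(protocol$injection_volumes)) {
    cm_stop("number of heats does not match the protocol", "invalid_protocol")
  }
  keep <- seq_along(q)
  if (exclude_first) keep <- keep[-1]
  if (length(keep) < 5L) {
    cm_stop("need >= 5 informative injections to fit the isotherm",
            "invalid_protocol")
  }
  q_obs <- q[keep]

  model_q <- function(n, K_d, dH, q0) {
    predict_heats(n, K_d, dH, protocol)$q[keep] + q0
  }
  ## crude starts: enthalpy scale from the largest heats, Kd from cell conc
  dH_0 <- {
    mol_inj <- protocol$syringe_conc * protocol$injection_volumes[keep[1]]
    s <- q_obs[which.max(abs(q_obs))] / mol_inj
    if (!is.finite(s) || s == 0) -10 else s
  }
  n_0 <- 1
  starts_Kd <- protocol$cell_conc * c(0.3, 1, 0.03, 3)

  dat <- data.frame(q_obs = q_obs)
  best <- NULL
  for (K0 in starts_Kd) {
    fit <- tryCatch({
      if (is.null(fix_n) && offset) {
        minpack.lm::nlsLM(
          q_obs ~ model_q(exp(ln), exp(lK), dH, q0), data = dat,
          start = list(ln = log(n_0), lK = log(K0), dH = dH_0, q0 = 0),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else if (is.null(fix_n)) {
        minpack.lm::nlsLM(
          q_obs ~ model_q(exp(ln), exp(lK), dH, 0), data = dat,
          start = list(ln = log(n_0), lK = log(K0), dH = dH_0),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else if (offset) {
        minpack.lm::nlsLM(
          q_obs ~ model_q(fix_n, exp(lK), dH, q0), data = dat,
          start = list(lK = log(K0), dH = dH_0, q0 = 0),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          q_obs ~ model_q(fix_n, exp(lK), dH, 0), data = dat,
          start = list(lK = log(K0), dH = dH_0),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || sum(stats::resid(fit)^2) < sum(stats::resid(best)^2)) {
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    cm_stop("isotherm fit failed to converge from all starts", "fit_failure")
  }
  co <- stats::coef(best)
  V <- tryCatch(stats::vcov(best), error = function(e) NULL)
  n_hat <- if (is.null(fix_n)) exp(unname(co["ln"])) else fix_n
  K_hat <- exp(unname(co["lK"]))
  dH_hat <- unname(co["dH"])
  q0_hat <- if (offset) unname(co["q0"]) else 0
  ## delta method back from the log scale
  se <- c(n = NA_real_, K_d = NA_real_, dH = NA_real_)
  if (!is.null(V)) {
    sd_of <- function(p) if (p %in% rownames(V)) sqrt(V[p, p]) else NA_real_
    if (is.null(fix_n)) se["n"] <- n_hat * sd_of("ln")
    se["K_d"] <- K_hat * sd_of("lK")
    se["dH"] <- sd_of("dH")
  }
  thermo <- derive_thermo(K_hat, dH_hat, protocol$temperature)
  c_value <- n_hat * protocol$cell_conc / K_hat
  c_warn <- c_value < 1 || c_value > 1000
  if (c_warn) {
    cm_warn(sprintf("c-value %.3g outside the informative window [1, 1000]",
                    c_value), "c_value_window")
  }
  structure(
    list(n = n_hat, K_d = K_hat, dH = dH_hat,
         dG = thermo$dG, minus_TdS = thermo$minus_TdS,
         T = protocol$temperature, se = se, offset = q0_hat,
         rss = sum(stats::resid(best)^2), c_value = c_value,
         c_value_warning = c_warn, fit = best),
    class = "isotherm_fit"
  )
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf(
    "Isotherm fit: n = %.3g, K_d = %.4g M, dH = %.4g kJ/mol, dG = %.4g, -TdS = %.4g kJ/mol (c = %.3g)\n",
    x$n, x$K_d, x$dH, x$dG, x$minus_TdS, x$c_value))
  invisible(x)
}

#' Decompose binding thermodynamics from K_d and dH
#'
#' dG = R T ln(K_d) (association convention: dG < 0 for K_d < 1 M) and
#' -T dS = dG - dH, with R = 8.314e-3 kJ/mol/K.
#'
#' @param K_d Dissociation constant, molar.
#' @param dH Binding enthalpy, kJ/mol.
#' @param T Temperature in kelvin.
#' @return List with `dG` and `minus_TdS` in kJ/mol.
#' @export
#' @examples
#' derive_thermo(14e-6, -30, 298.15)
derive_thermo <- function(K_d, dH, T = 298.15) {
  stopifnot_scalar_pos(K_d, "K_d")
  stopifnot_scalar_pos(T, "T")
  dG <- R_KJ * T * log(K_d)
  list(dG = dG, minus_TdS = dG - dH)
}
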