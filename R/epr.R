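#' EPR power-saturation curve
#'
#' Peak-to-peak amplitude of the central EPR line as a function of incident
#' microwave power, recorded under one relaxant condition: nitrogen-purged
#' (no relaxant), air/O2 (lipid-phase relaxant) or NiEDDA (aqueous-phase
#' relaxant).
#'
#' @param P Incident microwave power in mW, strictly increasing, length >= 5.
#' @param A Peak-to-peak amplitudes, same length as `P`.
#' @param condition One of `"N2"`, `"O2"`, `"NiEDDA"`.
#' @return An object of class `saturation_curve`.
#' @export
saturation_curve <- function(P, A, condition = c("N2", "O2", "NiEDDA")) {
  condition <- match.arg(condition)
  if (length(P) != length(A) || length(P) < 5L) {
    cm_stop("`P` and `A` must have equal length >= 5", "invalid_curve")
  }
  if (any(P <= 0) || any(diff(P) <= 0)) {
    cm_stop("`P` must be positive and strictly increasing", "invalid_curve")
  }
  structure(list(P = as.numeric(P), A = as.numeric(A), condition = condition),
            class = "saturation_curve")
}

#' Microwave power steps for a saturation experiment
#'
#' Log-spaced powers mirroring a typical progressive power-saturation
#' protocol (12 steps from 0.6 to 36 mW by default).
#'
#' @param n Number of steps.
#' @param min,max Power range in mW.
#' @return Numeric vector of powers in mW.
#' @export
saturation_powers <- function(n = 12, min = 0.6, max = 36) {
  exp(seq(log(min), log(max), length.out = n))
}

#' Fit the saturation rollover model to a power-saturation curve
#'
#' Least-squares fit of
#' A(P) = I sqrt(P) (1 + (2^(1/eps) - 1) P / P_half)^(-eps),
#' where P_half is the power at which the amplitude falls to half its
#' unsaturated value and eps is the (in)homogeneity exponent (1.5 for a
#' purely homogeneous line). When the curve shows no curvature inside the
#' scanned power range (fitted P_half far beyond max(P)) an unbounded-fit
#' warning is raised and the fit flagged, with max(P) as a lower bound.
#'
#' @param curve A [saturation_curve()].
#' @param fix_eps Fix eps at this value (e.g. 1.5) instead of fitting it;
#'   `NULL` (default) fits eps within `[0.5, 1.5]`.
#' @return An object of class `saturation_fit` with `P_half` (mW), `eps`,
#'   `I`, `se`, `rss`, `unbounded` flag and `condition`.
#' @export
fit_saturation <- function(curve, fix_eps = NULL) {
  stopifnot(inherits(curve, "saturation_curve"))
  P <- curve$P; A <- curve$A
  I0 <- A[1] / sqrt(P[1])
  ## heuristic P_half start: power where A/(I0 sqrt(P)) first drops to 1/2
  ratio <- A / (I0 * sqrt(P))
  below <- which(ratio <= 0.5)
  P0 <- if (length(below)) P[below[1]] else max(P)
  dat <- data.frame(P = P, A = A)
  make_fit <- function(P0) {
    if (is.null(fix_eps)) {
      minpack.lm::nlsLM(
        A ~ I * sqrt(P) * (1 + (2^(1 / eps) - 1) * P / Ph)^(-eps), data = dat,
        start = list(I = I0, Ph = P0, eps = 1.2),
        lower = c(1e-12, 1e-6, 0.5), upper = c(Inf, Inf, 1.5),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      eps <- fix_eps
      minpack.lm::nlsLM(
        A ~ I * sqrt(P) * (1 + (2^(1 / eps) - 1) * P / Ph)^(-eps), data = dat,
        start = list(I = I0, Ph = P0), lower = c(1e-12, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    }
  }
  fit <- NULL
  for (p0 in unique(c(P0, stats::median(P), max(P) * 3))) {
    f <- tryCatch(make_fit(p0), error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) ||
                        sum(stats::resid(f)^2) < sum(stats::resid(fit)^2))) {
      fit <- f
    }
  }
  if (is.null(fit)) cm_stop("saturation fit failed", "fit_failure")
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(co)), names(co)))
  P_half <- unname(co["Ph"])
  unbounded <- P_half > 10 * max(P)
  if (unbounded) {
    cm_warn(sprintf(
      "no saturation inside the scanned range; P_half > %.3g mW (lower bound)",
      max(P)), "unbounded_fit")
  }
  structure(
    list(P_half = P_half,
         eps = if (is.null(fix_eps)) unname(co["eps"]) else fix_eps,
         I = unname(co["I"]),
         se = c(P_half = unname(se["Ph"]), eps = unname(se["eps"]),
                I = unname(se["I"])),
         rss = sum(stats::resid(fit)^2), unbounded = unbounded,
         condition = curve$condition, fit = fit),
    class = "saturation_fit"
  )
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation fit (%s): P_half = %.4g mW, eps = %.3g, I = %.4g\n",
              x$condition, x$P_half, x$eps, x$I))
  invisible(x)
}

#' Membrane depth parameter from half-saturation powers
#'
#' Phi = ln(dP_half(O2) / dP_half(NiEDDA)), where dP_half is the shift in
#' half-saturation power relative to the nitrogen-purged baseline. O2
#' partitions into the hydrocarbon interior and NiEDDA into the aqueous
#' phase, so Phi increases monotonically with insertion depth. Uncertainty
#' is propagated to first order from the supplied P_half standard errors.
#'
#' @param P_half_O2,P_half_NiEDDA,P_half_N2 Half-saturation powers (mW).
#' @param se Optional named vector of standard errors
#'   (`O2`, `NiEDDA`, `N2`).
#' @return List with `phi` and `phi_err` (NA when no SEs given).
#' @export
#' @examples
#' depth_parameter(10, 4, 2)  # ln(8/2) = ln 4
depth_parameter <- function(P_half_O2, P_half_NiEDDA, P_half_N2,
                            se = NULL) {
  stopifnot_scalar_pos(P_half_O2, "P_half_O2")
  stopifnot_scalar_pos(P_half_NiEDDA, "P_half_NiEDDA")
  stopifnot_scalar_pos(P_half_N2, "P_half_N2")
  dO2 <- P_half_O2 - P_half_N2
  dNi <- P_half_NiEDDA - P_half_N2
  if (dO2 <= 0 || dNi <= 0) {
    cm_stop("non-positive delta-P_half; accessibility not resolvable",
            "invalid_accessibility")
  }
  phi <- log(dO2 / dNi)
  phi_err <- NA_real_
  if (!is.null(se)) {
    ## d(phi)/dO2 = 1/dO2, d/dNi = -1/dNi, d/dN2 = 1/dNi - 1/dO2
    g <- c(O2 = 1 / dO2, NiEDDA = -1 / dNi, N2 = 1 / dNi - 1 / dO2)
    s <- se[names(g)]; s[is.na(s)] <- 0
    phi_err <- sqrt(sum((g * s)^2))
  }
  list(phi = phi, phi_err = phi_err)
}

#' Measured spin-label depth parameters for membrane-bound C2AB
#'
#' Depth parameters (Phi) and calibrated distances to the lipid phosphate
#' plane for nitroxide labels at five sites on the Ca2+-binding loops and
#' polybasic patch of the synaptotagmin-1 C2AB fragment, each measured on
#' bilayers of three compositions. Positive distances lie on the hydrocarbon
#' side of the phosphate plane, negative on the aqueous side. Shipped as a
#' plain-text fixture; these pairs are the empirical material from which the
#' depth calibration is fitted.
#'
#' @return Data frame with columns `site`, `composition`, `phi`, `phi_err`,
#'   `distance_A`.
#' @export
spin_label_depths <- function() {
  path <- system.file("extdata", "spin_label_depths.csv",
                      package = "c2membrane", mustWork = TRUE)
  read_table(path, schema = c(site = "integer", composition = "character",
                              phi = "numeric", phi_err = "numeric",
                              distance_A = "numeric"))
}

#' Fit the empirical depth calibration Phi(x)
#'
#' Fits Phi(x) = A tanh(B (x - C)) + D to measured (Phi, distance) pairs by
#' nonlinear least squares. The sigmoid form captures the saturation of the
#' relaxant concentration gradients far from the phosphate plane on either
#' side. If the tanh fit leaves a root-mean-square Phi residual above
#' `fallback_rms`, a monotone piecewise-cubic (Hyman-filtered spline)
#' interpolant through the pairs is used instead. Calibrations that are not
#' strictly monotone over the data range are rejected.
#'
#' @param pairs Data frame with columns `phi` and `distance_A` (>= 6 rows
#'   spanning both signs of distance), e.g. from [spin_label_depths()].
#' @param fallback_rms RMS Phi-residual threshold above which the spline
#'   fallback replaces the tanh form (default 0.25).
#' @return An object of class `calibration_curve` with the fitted form,
#'   parameters, residuals and monotone domain.
#' @export
fit_calibration <- function(pairs, fallback_rms = 0.25) {
  stopifnot(is.data.frame(pairs), all(c("phi", "distance_A") %in% names(pairs)))
  x <- pairs$distance_A; phi <- pairs$phi
  if (length(x) < 6L || !any(x > 0) || !any(x < 0)) {
    cm_stop("need >= 6 (phi, distance) pairs spanning both signs of distance",
            "invalid_calibration")
  }
  if (stats::cor(x, phi, method = "spearman") < 0.8) {
    cm_stop("pairs are not monotone beyond noise tolerance; calibration rejected",
            "calibration_rejected")
  }
  d <- data.frame(x = x, phi = phi)
  st <- list(A = diff(range(phi)) / 2, B = 0.15, C = mean(x),
             D = mean(range(phi)))
  fit <- tryCatch(
    stats::nls(phi ~ A * tanh(B * (x - C)) + D, data = d, start = st,
               control = stats::nls.control(maxiter = 500, warnOnly = TRUE)),
    error = function(e) NULL)
  use_tanh <- FALSE
  if (!is.null(fit)) {
    pars <- as.list(stats::coef(fit))
    rms <- sqrt(mean(stats::resid(fit)^2))
    use_tanh <- is.finite(rms) && rms <= fallback_rms && pars$A * pars$B > 0
  }
  if (use_tanh) {
    obj <- structure(
      list(form = "tanh", pars = pars,
           residuals = stats::resid(fit),
           domain_phi = sort(pars$D + pars$A * c(-1, 1)),
           data = d, rms = rms),
      class = "calibration_curve")
  } else {
    ## monotone spline through composition-averaged pairs (duplicate x
    ## collapsed to their mean phi)
    agg <- stats::aggregate(phi ~ x, data = d, FUN = mean)
    agg <- agg[order(agg$x), ]
    if (any(diff(agg$phi) <= 0)) {
      cm_stop("pairs are not monotone beyond noise tolerance; calibration rejected",
              "calibration_rejected")
    }
    sf <- stats::splinefun(agg$x, agg$phi, method = "hyman")
    obj <- structure(
      list(form = "spline", spline = sf,
           residuals = d$phi - sf(d$x),
           domain_phi = range(agg$phi), domain_x = range(agg$x),
           data = d, rms = sqrt(mean((d$phi - sf(d$x))^2))),
      class = "calibration_curve")
  }
  obj
}

#' @export
print.calibration_curve <- function(x, ...) {
  if (x$form == "tanh") {
    cat(sprintf(
      "Depth calibration: phi = %.3g tanh(%.3g (x - %.3g)) + %.3g (RMS %.3g)\n",
      x$pars$A, x$pars$B, x$pars$C, x$pars$D, x$rms))
  } else {
    cat(sprintf("Depth calibration: monotone spline over x in [%.3g, %.3g] A\n",
                x$domain_x[1], x$domain_x[2]))
  }
  invisible(x)
}

#' Evaluate a depth calibration at given distances
#'
#' @param object A `calibration_curve`.
#' @param x Distances to the phosphate plane, Angstrom.
#' @param ... Unused.
#' @return Predicted depth parameters Phi.
#' @export
predict.calibration_curve <- function(object, x, ...) {
  if (object$form == "tanh") {
    p <- object$pars
    p$A * tanh(p$B * (x - p$C)) + p$D
  } else {
    object$spline(x)
  }
}

#' Distance to the phosphate plane from a depth parameter
#'
#' Inverts the fitted calibration. Phi values beyond the invertible range
#' (the tanh asymptotes, or the spline's data range) are clamped to just
#' inside it with a warning. Uncertainty is propagated through the local
#' slope: x_err = phi_err / |dPhi/dx|.
#'
#' @param phi Depth parameter (scalar or vector).
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @param phi_err Optional standard error(s) on `phi`.
#' @return List with `x` (Angstrom, signed; positive = hydrocarbon side) and
#'   `x_err`.
#' @export
depth_from_phi <- function(phi, curve, phi_err = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$form == "tanh") {
    p <- curve$pars
    u <- (phi - p$D) / p$A
    if (any(abs(u) >= 1)) {
      cm_warn("phi outside the invertible range; clamped at saturation",
              "phi_clamped")
      u <- pmin(pmax(u, -(1 - 1e-9)), 1 - 1e-9)
    }
    x <- p$C + atanh(u) / p$B
    slope <- p$A * p$B * (1 - u^2)
  } else {
    lo <- curve$domain_x[1]; hi <- curve$domain_x[2]
    phi_lo <- curve$spline(lo); phi_hi <- curve$spline(hi)
    cl <- pmin(pmax(phi, phi_lo + 1e-12), phi_hi - 1e-12)
    if (any(cl != phi)) {
      cm_warn("phi outside the invertible range; clamped at saturation",
              "phi_clamped")
    }
    x <- vapply(cl, function(ph) {
      stats::uniroot(function(z) curve$spline(z) - ph, lower = lo,
                     upper = hi, tol = 1e-10)$root
    }, 1.0)
    slope <- curve$spline(x, deriv = 1)
  }
  x_err <- if (is.null(phi_err)) rep(NA_real_, length(x))
           else abs(phi_err) / abs(slope)
  list(x = x, x_err = x_err)
}
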