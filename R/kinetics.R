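#' Stopped-flow kinetic trace
#'
#' A time-resolved fluorescence trace from a pseudo-first-order vesicle
#' binding experiment, F(t) = F0 + A_obs * exp(-k_obs * t), together with the
#' experimental metadata needed downstream (protein and lipid concentrations,
#' lipid composition, temperature, free Ca2+).
#'
#' @param t Time in seconds, strictly increasing, length >= 4.
#' @param F Fluorescence signal (arbitrary units), same length as `t`.
#' @param meta Named list of metadata (protein_M, lipid_M, composition,
#'   temp_K, ca_free_M, and any generator ground truth).
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(t, F, meta = list()) {
  if (length(t) != length(F) || length(t) < 4L) {
    cm_stop("`t` and `F` must have equal length >= 4", "invalid_trace")
  }
  if (any(!is.finite(t)) || any(!is.finite(F))) {
    cm_stop("trace contains non-finite values", "invalid_trace")
  }
  if (any(diff(t) <= 0)) {
    cm_stop("`t` must be strictly increasing", "invalid_trace")
  }
  structure(list(t = as.numeric(t), F = as.numeric(F), meta = meta),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace: %d points over %.3g s\n",
              length(x$t), max(x$t) - min(x$t)))
  invisible(x)
}

#' Fit a single-exponential decay to a kinetic trace
#'
#' Least-squares fit of F(t) = F0 + A_obs * exp(-k_obs * t), the
#' pseudo-first-order binding model in which F0 is the final-fluorescence
#' offset, A_obs the amplitude and k_obs the observed rate constant.
#'
#' Starting values: k_obs from a log-linear regression of |F - F_inf| against
#' t (F_inf estimated as the mean of the last decile of points), F0 from the
#' same last-decile mean, and A_obs from the first point minus F0. On
#' non-convergence the fit is restarted from k_obs scaled by factors of
#' 10^(+-1/2, +-1, +2).
#'
#' @param trace A [kinetic_trace()].
#' @return An object of class `exponential_fit` with elements `F0`, `A_obs`,
#'   `k_obs`, `se` (named vector of standard errors), `rss`, and the
#'   underlying `nls` fit.
#' @export
fit_monoexponential <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$t; F <- trace$F
  if (stats::sd(F) == 0) {
    cm_stop("trace signal is constant; no amplitude to fit",
            "degenerate_signal")
  }
  n_tail <- max(2L, ceiling(length(F) / 10))
  F0_0 <- mean(utils::tail(F, n_tail))
  A_0 <- F[1] - F0_0
  if (abs(A_0) < 1e-12 * max(abs(F), 1)) A_0 <- F[which.max(abs(F - F0_0))] - F0_0
  dev <- abs(F - F0_0)
  ok <- dev > 1e-10 * max(dev)
  k_0 <- if (sum(ok) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(dev[ok]) ~ t[ok]))[2])
    if (is.finite(sl) && sl < 0) -sl else 1 / diff(range(t))
  } else 1 / diff(range(t))

  dat <- data.frame(t = t, F = F)
  fit <- NULL
  for (fac in c(1, 10^-0.5, 10^0.5, 0.1, 10, 100)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(F ~ F0 + A * exp(-k * t), data = dat,
                        start = list(F0 = F0_0, A = A_0, k = k_0 * fac),
                        lower = c(-Inf, -Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    cm_stop(sprintf(
      "single-exponential fit failed after restarts (k start %.3g)", k_0),
      "fit_failure")
  }
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  structure(
    list(F0 = unname(co["F0"]), A_obs = unname(co["A"]),
         k_obs = unname(co["k"]),
         se = c(F0 = unname(se[1]), A_obs = unname(se[2]),
                k_obs = unname(se[3])),
         rss = sum(stats::resid(fit)^2), fit = fit),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: F0 = %.4g, A_obs = %.4g, k_obs = %.4g s^-1 (SE %.2g)\n",
              x$F0, x$A_obs, x$k_obs, x$se["k_obs"]))
  invisible(x)
}

#' Observed-rate series across vesicle concentrations
#'
#' @param v Vesicle concentrations in molar (>= 2 distinct values).
#' @param k_obs Observed rate constants in s^-1, one per concentration.
#' @param k_obs_se Optional standard errors of `k_obs`.
#' @return An object of class `kinetic_series`.
#' @export
kinetic_series <- function(v, k_obs, k_obs_se = NULL) {
  if (length(v) != length(k_obs) ||
      (!is.null(k_obs_se) && length(k_obs_se) != length(v))) {
    cm_stop("`v`, `k_obs` (and `k_obs_se`) must have equal lengths",
            "invalid_series")
  }
  if (length(unique(v)) < 2L) {
    cm_stop("need >= 2 distinct vesicle concentrations", "invalid_series")
  }
  if (any(v < 0)) cm_stop("vesicle concentrations must be >= 0", "invalid_series")
  structure(list(v = as.numeric(v), k_obs = as.numeric(k_obs),
                 k_obs_se = if (is.null(k_obs_se)) NULL else as.numeric(k_obs_se)),
            class = "kinetic_series")
}

#' Fit the pseudo-first-order rate law k_obs = k_on [v] + k_off
#'
#' Linear regression of observed rates against vesicle concentration. The
#' slope is the apparent bimolecular association rate constant k_on
#' (M^-1 s^-1), the intercept the dissociation rate constant k_off (s^-1),
#' and their ratio k_off/k_on the apparent vesicle dissociation constant K_d.
#' A negative fitted intercept is physically k_off >= 0; it is reported
#' unclamped with a warning flag so that error propagation to K_d stays
#' honest.
#'
#' @param series A [kinetic_series()] (or data frame with columns `v`,
#'   `k_obs` and optionally `k_obs_se`).
#' @param weighted If `TRUE` and standard errors are present, use weights
#'   1/SE^2; default unweighted.
#' @return An object of class `rate_constants` with `k_on`, `k_off`, `K_d`,
#'   standard errors (`se`, K_d by the delta method from the parameter
#'   covariance), the 2x2 covariance `cov`, and `negative_k_off` flag.
#' @export
fit_rate_law <- function(series, weighted = FALSE) {
  if (is.data.frame(series)) {
    series <- kinetic_series(series$v, series$k_obs, series$k_obs_se)
  }
  stopifnot(inherits(series, "kinetic_series"))
  d <- data.frame(v = series$v, k_obs = series$k_obs)
  w <- NULL
  if (weighted) {
    if (is.null(series$k_obs_se)) {
      cm_stop("weighted fit requested but no k_obs standard errors supplied",
              "invalid_series")
    }
    w <- 1 / series$k_obs_se^2
  }
  fit <- stats::lm(k_obs ~ v, data = d, weights = w)
  co <- stats::coef(fit)
  k_off <- unname(co[1]); k_on <- unname(co[2])
  V <- stats::vcov(fit)
  if (k_on <= 0) {
    cm_warn("fitted k_on is non-positive; K_d is not physically meaningful",
            "nonpositive_k_on")
  }
  negative_k_off <- k_off < 0
  if (negative_k_off) {
    cm_warn("fitted intercept (k_off) is negative; reported unclamped",
            "negative_k_off")
  }
  K_d <- k_off / k_on
  ## delta method: g = koff/kon, grad = (1/kon, -koff/kon^2) over (koff, kon)
  gr <- c(1 / k_on, -k_off / k_on^2)
  K_d_se <- sqrt(drop(t(gr) %*% V %*% gr))
  se_co <- sqrt(diag(V))
  structure(
    list(k_on = k_on, k_off = k_off, K_d = K_d,
         se = c(k_on = unname(se_co[2]), k_off = unname(se_co[1]),
                K_d = K_d_se),
         cov = V[c(2, 1), c(2, 1)], negative_k_off = negative_k_off,
         fit = fit),
    class = "rate_constants"
  )
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf(
    "Rate constants: k_on = %.4g M^-1 s^-1, k_off = %.4g s^-1, K_d = %.4g M\n",
    x$k_on, x$k_off, x$K_d))
  invisible(x)
}

#' One-way ANOVA with protected Fisher LSD post hoc comparisons
#'
#' Compares parameter estimates across experimental conditions with a one-way
#' ANOVA followed by Fisher's least-significant-difference pairwise tests
#' using the pooled ANOVA mean square. The LSD is protected: pairwise
#' comparisons are only flagged significant when the omnibus F test itself
#' has p < alpha.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level, default 0.05.
#' @return List with `anova` (data frame: F, df1, df2, p) and `pairwise`
#'   (data frame: group1, group2, diff, se, t, p, significant).
#' @export
compare_conditions <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups))) {
    cm_stop("`groups` must be a named list of >= 2 numeric vectors",
            "invalid_groups")
  }
  n_i <- vapply(groups, length, 1L)
  if (any(n_i < 2L)) {
    cm_stop("every group needs n >= 2 observations", "invalid_groups")
  }
  d <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), n_i), levels = names(groups))
  )
  fit <- stats::aov(y ~ g, data = d)
  tab <- summary(fit)[[1]]
  Fval <- tab[["F value"]][1]
  pval <- tab[["Pr(>F)"]][1]
  mse <- tab[["Mean Sq"]][2]
  df2 <- tab[["Df"]][2]
  ## All observations identical: zero between- and within-variance makes the
  ## F ratio 0/0 (numerically arbitrary); the data carry no evidence against
  ## equality, report F = 0, p = 1.
  if (!is.finite(Fval) || stats::var(d$y) == 0) { Fval <- 0; pval <- 1 }
  means <- tapply(d$y, d$g, mean)
  cmb <- utils::combn(names(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    diff <- means[[a]] - means[[b]]
    se <- sqrt(mse * (1 / n_i[[a]] + 1 / n_i[[b]]))
    tstat <- if (se > 0) diff / se else ifelse(diff == 0, 0, sign(diff) * Inf)
    p <- 2 * stats::pt(-abs(tstat), df2)
    data.frame(group1 = a, group2 = b, diff = diff, se = se, t = tstat, p = p)
  }))
  pw$significant <- is.finite(pval) & pval < alpha & pw$p < alpha
  rownames(pw) <- NULL
  list(anova = data.frame(F = Fval, df1 = tab[["Df"]][1], df2 = df2, p = pval),
       pairwise = pw)
}
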