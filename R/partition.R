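#' Equilibrium vesicle-partitioning dataset
#'
#' Fraction of protein bound to sucrose-loaded vesicles as a function of the
#' accessible lipid concentration, as measured by a sedimentation assay.
#'
#' @param L Accessible lipid concentrations, molar, >= 0.
#' @param f_b Fraction bound, in `[0, 1]`, same length as `L`.
#' @param meta Named list of condition metadata (composition, Ca2+ state,
#'   protein variant, generator ground truth).
#' @return An object of class `partition_dataset`.
#' @export
partition_dataset <- function(L, f_b, meta = list()) {
  if (length(L) != length(f_b)) {
    cm_stop("`L` and `f_b` must have equal length", "invalid_dataset")
  }
  if (any(L < 0) || any(!is.finite(L))) {
    cm_stop("`L` must be finite and >= 0", "invalid_dataset")
  }
  if (any(f_b < 0) || any(f_b > 1) || any(!is.finite(f_b))) {
    cm_stop("`f_b` must lie in [0, 1]", "invalid_dataset")
  }
  structure(list(L = as.numeric(L), f_b = as.numeric(f_b), meta = meta),
            class = "partition_dataset")
}

#' Read a sedimentation dataset from CSV
#'
#' Accepts either the reduced layout (`lipid_total_M, f_b`) or the raw
#' layout (`lipid_total_M, protein_sup_M, protein_total_M`), in which case
#' the fraction bound is computed by supernatant depletion,
#' f_b = 1 - P_sup / P_total. Total lipid is converted to accessible lipid
#' when a composition is supplied.
#'
#' @param path CSV file path.
#' @param composition Optional [lipid_composition()]; when given, `L` is
#'   `lipid_total_M * accessible_fraction`, otherwise the lipid column is
#'   taken as already accessible.
#' @return A [partition_dataset()].
#' @export
read_partition_data <- function(path, composition = NULL) {
  header <- tolower(names(utils::read.csv(path, nrows = 1,
                                          check.names = FALSE)))
  if ("f_b" %in% header) {
    d <- read_table(path, c(lipid_total_M = "numeric", f_b = "numeric"))
    fb <- d$f_b
  } else {
    d <- read_table(path, c(lipid_total_M = "numeric",
                            protein_sup_M = "numeric",
                            protein_total_M = "numeric"))
    if (any(d$protein_total_M <= 0)) {
      cm_stop("protein_total_M must be positive", "schema_error")
    }
    fb <- 1 - d$protein_sup_M / d$protein_total_M
  }
  L <- if (is.null(composition)) d$lipid_total_M
       else accessible_lipid(d$lipid_total_M, composition)
  partition_dataset(L, pmin(pmax(fb, 0), 1))
}

#' Fraction bound at an accessible lipid concentration
#'
#' The hyperbolic partitioning model f_b = K L / (1 + K L), where K is the
#' reciprocal molar partition coefficient (M^-1). Its reciprocal 1/K is the
#' accessible lipid concentration at which half the protein is membrane
#' bound.
#'
#' @param K Reciprocal molar partition coefficient, M^-1, > 0.
#' @param L Accessible lipid concentration(s), molar, >= 0.
#' @return Fraction bound (vectorised over `L`).
#' @export
#' @examples
#' fraction_bound(4.7e4, 1 / 4.7e4)  # 0.5 at the half-binding concentration
fraction_bound <- function(K, L) {
  stopifnot_scalar_pos(K, "K")
  if (any(L < 0)) cm_stop("`L` must be >= 0", "invalid_argument")
  K * L / (1 + K * L)
}

#' Fit the reciprocal molar partition coefficient
#'
#' Nonlinear least-squares fit of f_b = K L / (1 + K L) to a
#' sedimentation dataset; the standard error of K comes from the fit
#' covariance.
#'
#' @param data A [partition_dataset()] (or data frame with columns `L`,
#'   `f_b`). Needs >= 4 points spanning at least one decade of L.
#' @return An object of class `partition_fit` with `K` (M^-1), `se`,
#'   `half_binding_L` = 1/K (molar) and `rss`.
#' @export
fit_partition <- function(data) {
  if (is.data.frame(data)) data <- partition_dataset(data$L, data$f_b)
  stopifnot(inherits(data, "partition_dataset"))
  pos <- data$L[data$L > 0]
  if (length(data$L) < 4L || length(pos) < 2L ||
      max(pos) / min(pos) < 10) {
    cm_stop("need >= 4 points spanning at least one decade of L",
            "invalid_dataset")
  }
  if (all(data$f_b < 0.02) || all(data$f_b > 0.98)) {
    cm_stop("fraction bound carries no binding information (all ~0 or ~1)",
            "degenerate_data")
  }
  d <- data.frame(L = data$L, f_b = data$f_b)
  K0 <- 1 / stats::median(pos)
  fit <- minpack.lm::nlsLM(f_b ~ K * L / (1 + K * L), data = d,
                           start = list(K = K0), lower = 1e-12,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  K <- unname(stats::coef(fit)["K"])
  se <- tryCatch(sqrt(stats::vcov(fit)[1, 1]), error = function(e) NA_real_)
  structure(list(K = K, se = se, half_binding_L = 1 / K,
                 rss = sum(stats::resid(fit)^2), fit = fit),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("Partition fit: K = %.4g M^-1 (SE %.2g), 1/K = %.4g uM\n",
              x$K, x$se, 1e6 * x$half_binding_L))
  invisible(x)
}

#' Binding free-energy difference between two conditions
#'
#' Delta-Delta-G = R T ln(K_a / K_b) for two reciprocal molar partition
#' coefficients. Positive values mean condition `a` binds more tightly
#' (larger K); the function is antisymmetric in its arguments.
#'
#' @param K_a,K_b Partition coefficients, M^-1.
#' @param T Temperature in kelvin, default 298.15 (room-temperature assay).
#' @return Free-energy difference, kJ/mol.
#' @export
#' @examples
#' delta_delta_G(2.2e4, 1.1e3)  # ~7.4 kJ/mol
delta_delta_G <- function(K_a, K_b, T = 298.15) {
  stopifnot_scalar_pos(K_a, "K_a")
  stopifnot_scalar_pos(K_b, "K_b")
  stopifnot_scalar_pos(T, "T")
  R_KJ * T * log(K_a / K_b)
}

#' Effective accessible-lipid concentration seen by a tethered domain
#'
#' Order-of-magnitude estimate of the local lipid concentration experienced
#' by a membrane-tethered domain confined to a slab of thickness
#' `tether_range_nm` above the bilayer. The bilayer carries 2/a lipids per
#' unit area (both leaflets, a = area per lipid), of which a fraction
#' `accessible_fraction` faces the domain; distributing that areal density
#' through the slab gives a number density of
#' 2 * accessible_fraction / (a * t), converted to molar units.
#'
#' @param tether_range_nm Slab thickness in nm (default 4).
#' @param area_per_lipid_nm2 Area per lipid in nm^2 (default 0.65).
#' @param accessible_fraction Fraction of total lipid facing the domain
#'   (default 0.5, the outer leaflet).
#' @return Effective concentration in molar.
#' @export
#' @examples
#' effective_local_concentration()  # ~0.64 M with the defaults
effective_local_concentration <- function(tether_range_nm = 4,
                                          area_per_lipid_nm2 = 0.65,
                                          accessible_fraction = 0.5) {
  stopifnot_scalar_pos(tether_range_nm, "tether_range_nm")
  stopifnot_scalar_pos(area_per_lipid_nm2, "area_per_lipid_nm2")
  if (accessible_fraction <= 0 || accessible_fraction > 1) {
    cm_stop("`accessible_fraction` must be in (0, 1]", "invalid_argument")
  }
  ## number density in nm^-3; 1 M = N_A / 1e24 molecules per nm^3
  density_nm3 <- 2 * accessible_fraction /
    (area_per_lipid_nm2 * tether_range_nm)
  density_nm3 / (N_AVOGADRO / 1e24)
}
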