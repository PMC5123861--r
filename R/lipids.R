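#' Lipid composition of a vesicle preparation
#'
#' Describes the mole fractions of the lipid species in a liposome prep,
#' the assumed number of phospholipid molecules per vesicle (used to convert
#' total lipid concentration to vesicle concentration for pseudo-first-order
#' kinetics), and the fraction of total lipid exposed on the outer leaflet
#' (the lipid actually accessible to added protein in a sedimentation assay).
#'
#' @param species Named numeric vector of mole fractions, e.g.
#'   `c(PtdChol = 0.88, PtdSer = 0.10, PtdInsP2 = 0.02)`. Must be
#'   non-negative and sum to 1.
#' @param lipids_per_vesicle Phospholipid molecules per vesicle; default
#'   90000, appropriate for ~100 nm large unilamellar vesicles.
#' @param accessible_fraction Fraction of total lipid on the outer
#'   (protein-accessible) leaflet; default 0.5.
#' @return An object of class `lipid_composition`.
#' @export
#' @examples
#' lipid_composition(c(PtdChol = 0.8, PtdSer = 0.2))
lipid_composition <- function(species,
                              lipids_per_vesicle = 90000,
                              accessible_fraction = 0.5) {
  if (!is.numeric(species) || length(species) < 1L || is.null(names(species)) ||
      any(!nzchar(names(species)))) {
    cm_stop("`species` must be a named numeric vector of mole fractions",
            "invalid_composition")
  }
  if (any(species < 0)) {
    cm_stop("mole fractions must be non-negative", "invalid_composition")
  }
  if (abs(sum(species) - 1) > 1e-9) {
    cm_stop(sprintf("mole fractions must sum to 1 (got %.12g)", sum(species)),
            "invalid_composition")
  }
  stopifnot_scalar_pos(lipids_per_vesicle, "lipids_per_vesicle")
  if (!is.numeric(accessible_fraction) || length(accessible_fraction) != 1L ||
      accessible_fraction <= 0 || accessible_fraction > 1) {
    cm_stop("`accessible_fraction` must be in (0, 1]", "invalid_composition")
  }
  structure(
    list(species = species,
         lipids_per_vesicle = lipids_per_vesicle,
         accessible_fraction = accessible_fraction),
    class = "lipid_composition"
  )
}

#' @export
print.lipid_composition <- function(x, ...) {
  cat("Lipid composition:",
      paste(sprintf("%s %.3g", names(x$species), x$species), collapse = ", "),
      "\n")
  cat(sprintf("  %g lipids/vesicle, accessible fraction %.2f\n",
              x$lipids_per_vesicle, x$accessible_fraction))
  invisible(x)
}

#' Convert total lipid concentration to vesicle concentration
#'
#' Stopped-flow observed rates are linear in the *vesicle* concentration, so
#' total lipid is converted by dividing by the number of phospholipids per
#' vesicle (90,000 for ~100 nm LUVs by default).
#'
#' @param total_lipid Total lipid concentration in molar (scalar or vector).
#' @param composition A [lipid_composition()].
#' @return Vesicle concentration in molar.
#' @export
#' @examples
#' comp <- lipid_composition(c(PtdChol = 1))
#' vesicle_concentration(90e-6, comp)  # 1 nM
vesicle_concentration <- function(total_lipid, composition) {
  stopifnot(inherits(composition, "lipid_composition"))
  if (any(total_lipid < 0)) {
    cm_stop("`total_lipid` must be non-negative", "invalid_argument")
  }
  total_lipid / composition$lipids_per_vesicle
}

#' Accessible lipid concentration
#'
#' Only the outer leaflet of a unilamellar vesicle is available to protein
#' added from outside; equilibrium partition coefficients are expressed per
#' accessible lipid.
#'
#' @inheritParams vesicle_concentration
#' @return Accessible lipid concentration in molar.
#' @export
accessible_lipid <- function(total_lipid, composition) {
  stopifnot(inherits(composition, "lipid_composition"))
  if (any(total_lipid < 0)) {
    cm_stop("`total_lipid` must be non-negative", "invalid_argument")
  }
  total_lipid * composition$accessible_fraction
}
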