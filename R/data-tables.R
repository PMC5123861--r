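#' Measured reciprocal molar partition coefficients for C2AB variants
#'
#' Sedimentation-assay partition coefficients K (M^-1) for the wild-type
#' synaptotagmin-1 C2AB fragment and its polybasic-patch mutants (K326A and
#' the K326A/K327A "KAKA" double mutant) on bilayers of varying
#' PtdSer/PtdIns(4,5)P2 content, with (`with_Ca`) and without (`no_Ca`)
#' calcium. 1/K is the accessible lipid concentration at half binding;
#' `K_err` is the regression standard error. Shipped as a plain-text
#' fixture for the free-energy and half-binding worked examples.
#'
#' @return Data frame with columns `composition`, `calcium`, `variant`,
#'   `K`, `K_err`.
#' @export
partition_coefficients <- function() {
  path <- system.file("extdata", "partition_coefficients.csv",
                      package = "c2membrane", mustWork = TRUE)
  read_table(path, schema = c(composition = "character",
                              calcium = "character", variant = "character",
                              K = "numeric", K_err = "numeric"))
}
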