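#' Averaged-weighted chemical-shift perturbation
#'
#' Combines amide 1H and 15N chemical-shift changes into the standard
#' weighted average CSP = sqrt(dH^2 + (alpha dN)^2). The 15N weight alpha
#' compensates for the wider 15N ppm scale; 0.2 (the common /5 convention)
#' by default.
#'
#' @param dH 1H shift changes, ppm (vectorised).
#' @param dN 15N shift changes, ppm.
#' @param alpha 15N weighting factor (default 0.2).
#' @return Non-negative CSP values, ppm.
#' @export
#' @examples
#' weighted_csp(0.1, 0.5)  # sqrt(0.01 + 0.01)
weighted_csp <- function(dH, dN, alpha = 0.2) {
  if (length(dH) != length(dN)) {
    cm_stop("`dH` and `dN` must have equal length", "invalid_argument")
  }
  stopifnot_scalar_pos(alpha, "alpha", strict = FALSE)
  sqrt(dH^2 + (alpha * dN)^2)
}

#' Per-residue CSP profile between two HSQC peak lists
#'
#' Matches peaks by residue assignment (never by ppm proximity), computes
#' the weighted CSP for every residue present in both lists, and flags
#' residues present in only one list (candidates for exchange broadening)
#' rather than dropping them silently.
#'
#' @param reference_peaks,titrated_peaks Data frames with columns `residue`,
#'   `dH_ppm`, `dN_ppm`.
#' @param alpha 15N weighting factor.
#' @return Data frame with columns `residue`, `dH`, `dN`, `csp`, `matched`;
#'   unmatched residues carry NA shifts and `matched = FALSE`. The unmatched
#'   residue ids are also attached as attribute `"unmatched"`.
#' @export
csp_profile <- function(reference_peaks, titrated_peaks, alpha = 0.2) {
  req <- c("residue", "dH_ppm", "dN_ppm")
  stopifnot(all(req %in% names(reference_peaks)),
            all(req %in% names(titrated_peaks)))
  m <- merge(reference_peaks[req], titrated_peaks[req], by = "residue",
             suffixes = c("_ref", "_tit"), all = TRUE)
  matched <- stats::complete.cases(m)
  out <- data.frame(
    residue = m$residue,
    dH = m$dH_ppm_tit - m$dH_ppm_ref,
    dN = m$dN_ppm_tit - m$dN_ppm_ref)
  out$csp <- ifelse(matched, weighted_csp(
    ifelse(matched, out$dH, 0), ifelse(matched, out$dN, 0), alpha), NA_real_)
  out$matched <- matched
  out <- out[order(out$residue), ]
  rownames(out) <- NULL
  attr(out, "unmatched") <- out$residue[!matched]
  if (any(!matched)) {
    cm_warn(sprintf("%d residue(s) present in only one condition: %s",
                    sum(!matched),
                    paste(out$residue[!matched], collapse = ", ")),
            "unmatched_residues")
  }
  out
}

#' Rank residues by chemical-shift perturbation
#'
#' Orders matched residues by descending CSP and applies a cutoff: either
#' the mean + 1 SD threshold rule or a fixed top-k. Ties preserve input
#' order (stable ranking).
#'
#' @param records A [csp_profile()] data frame (or any frame with `residue`
#'   and `csp`).
#' @param method `"threshold"` (mean + 1 SD of the matched CSPs) or
#'   `"top_k"`.
#' @param k Number of residues for `method = "top_k"`.
#' @return Data frame of the selected residues, ordered by descending CSP,
#'   with the applied `cutoff` as an attribute (NA for top-k).
#' @export
rank_perturbed <- function(records, method = c("threshold", "top_k"),
                           k = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("residue", "csp") %in% names(records)))
  rec <- records[!is.na(records$csp), , drop = FALSE]
  ord <- order(-rec$csp)                 # order() is stable for ties
  rec <- rec[ord, , drop = FALSE]
  if (method == "threshold") {
    cutoff <- mean(rec$csp) + stats::sd(rec$csp)
    sel <- rec[rec$csp > cutoff, , drop = FALSE]
  } else {
    if (is.null(k)) cm_stop("`k` required for top_k ranking", "invalid_argument")
    cutoff <- NA_real_
    sel <- utils::head(rec, k)
  }
  rownames(sel) <- NULL
  attr(sel, "cutoff") <- cutoff
  sel
}
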