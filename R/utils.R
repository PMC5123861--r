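#' @keywords internal
"_PACKAGE"

## Gas constant in kJ mol^-1 K^-1
R_KJ <- 8.314e-3
## Avogadro's number, molecules per mole
N_AVOGADRO <- 6.02214076e23

cm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "c2membrane_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

cm_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "c2membrane_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded simulations never disturb an enclosing random stream.
#' A `NULL` seed evaluates the code against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    cm_stop(sprintf("`%s` must be a %s finite numeric scalar",
                    name, if (strict) "positive" else "non-negative"),
            "invalid_argument")
  }
  invisible(x)
}
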