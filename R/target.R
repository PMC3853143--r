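#' Target steady-state specification
#'
#' The dynamics a functional circuit must produce: a target steady-state
#' concentration `z` per gene, a relative tolerance (a run is functional only
#' if every gene's steady state lies within `tolerance * z` of its target),
#' and a sentinel deviation value assigned to ill-behaved runs (aborted, or
#' outside tolerance). The sentinel must exceed any deviation a well-behaved
#' run can attain so that `deviation < sentinel` cleanly separates the two.
#'
#' @param z Named (or topology-ordered) numeric vector of target
#'   concentrations in nM, all > 0.
#' @param tolerance Relative tolerance, in (0, 1) (default 0.20).
#' @param sentinel Sentinel deviation value (default 15).
#' @return A list of class `kin_target` with elements `z`, `tolerance`,
#'   `sentinel`.
#' @examples
#' target_spec(c(TetR = 1000, LacI = 30000, CI = 300, Eyfp = 30000))
#' @export
target_spec <- function(z, tolerance = 0.20, sentinel = 15) {
  z <- unlist(z)
  if (!is.numeric(z) || any(!is.finite(z)) || any(z <= 0)) {
    abort("`z` must be a numeric vector of positive target concentrations.")
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1 ||
      tolerance <= 0 || tolerance >= 1) {
    abort("`tolerance` must be a single value in (0, 1).")
  }
  if (!is.numeric(sentinel) || length(sentinel) != 1 || sentinel <= 0) {
    abort("`sentinel` must be a single positive value.")
  }
  structure(
    list(
      z = setNames(as.numeric(z), names(z)),
      tolerance = as.numeric(tolerance),
      sentinel = as.numeric(sentinel)
    ),
    class = "kin_target"
  )
}

assert_target <- function(target) {
  if (!inherits(target, "kin_target")) {
    abort("Expected a `kin_target` object; see `target_spec()`.")
  }
  invisible(target)
}
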