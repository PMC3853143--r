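#' Kinetic parameters for a circuit
#'
#' Per-gene rate constants of the production/degradation model: `p0` is the
#' basal (promoter-independent) production rate in nM per time step, `p` the
#' regulated production rate constant in nM per time step, and `d` the
#' first-order degradation rate constant per time step.
#'
#' @param topology A `kin_topology`.
#' @param p0,p,d Numeric vectors, one value per gene (recycled if scalar).
#' @return A tibble of class `kin_params` with columns `gene`, `p0`, `p`, `d`.
#' @examples
#' kinetic_params(cascade_demo(), p0 = 0, p = c(100, 6000, 18, 3000), d = 0.1)
#' @export
kinetic_params <- function(topology, p0 = 0, p, d) {
  assert_topology(topology)
  G <- n_genes(topology)
  p0 <- rep_len(as.numeric(p0), G)
  p <- rep_len(as.numeric(p), G)
  d <- rep_len(as.numeric(d), G)
  if (any(!is.finite(p0)) || any(p0 < 0)) abort("`p0` must be finite and >= 0.")
  if (any(!is.finite(p)) || any(p < 0)) abort("`p` must be finite and >= 0.")
  if (any(!is.finite(d)) || any(d <= 0)) abort("`d` must be finite and > 0.")
  structure(
    tibble(gene = topology$gene, p0 = p0, p = p, d = d),
    class = c("kin_params", class(tibble()))
  )
}

#' Noise amplitudes for stochastic simulation
#'
#' Standard deviations of the per-step random perturbations of each kinetic
#' parameter (`dp0`, `dp`, `dd`), plus the standard deviation
#' `extrinsic_sigma` of the additive extrinsic noise term. At each time step
#' the stochastic rate is
#' \deqn{g_i = f_i + (\Delta p_{i,0} + \Delta p_i r_i - \Delta d_i y_i) n_i + v_i,}
#' where \eqn{f_i} is the deterministic rate and \eqn{n_i},
#' \eqn{v_i/\sigma_v} are independent standard-normal draws, fresh for every
#' gene at every step.
#'
#' @param topology A `kin_topology`.
#' @param dp0,dp,dd Numeric vectors (one per gene, recycled): perturbation
#'   standard deviations for the basal production, production and degradation
#'   parameters, in the units of the parameter they perturb.
#' @param extrinsic_sigma Numeric (recycled): standard deviation of the
#'   additive extrinsic noise, in nM per time step.
#' @return A tibble of class `kin_noise` with one row per gene.
#' @seealso [noise_from_params()] for the relative (fraction-of-nominal) form.
#' @export
noise_spec <- function(topology, dp0 = 0, dp = 0, dd = 0, extrinsic_sigma = 0) {
  assert_topology(topology)
  G <- n_genes(topology)
  out <- tibble(
    gene = topology$gene,
    dp0 = rep_len(as.numeric(dp0), G),
    dp = rep_len(as.numeric(dp), G),
    dd = rep_len(as.numeric(dd), G),
    extrinsic_sigma = rep_len(as.numeric(extrinsic_sigma), G)
  )
  bad <- vapply(out[-1], function(x) any(!is.finite(x)) || any(x < 0), logical(1))
  if (any(bad)) abort("All noise standard deviations must be finite and >= 0.")
  structure(out, class = c("kin_noise", class(tibble())))
}

#' Derive noise amplitudes as a fraction of the nominal parameters
#'
#' Sets each parameter perturbation to `rel` times the nominal value of the
#' parameter it perturbs, the usual way perturbation strength is specified for
#' a parameter scan where nominal values differ between parameter sets.
#'
#' @param params A `kin_params`.
#' @param topology The matching `kin_topology`.
#' @param rel Fraction of the nominal parameter used as its perturbation
#'   standard deviation (default 0.1).
#' @param extrinsic_sigma Additive extrinsic noise standard deviation in
#'   nM/step (default 10).
#' @return A `kin_noise` tibble.
#' @export
noise_from_params <- function(params, topology, rel = 0.1, extrinsic_sigma = 10) {
  if (!is.numeric(rel) || length(rel) != 1 || rel < 0) {
    abort("`rel` must be a single non-negative number.")
  }
  noise_spec(
    topology,
    dp0 = rel * params$p0,
    dp = rel * params$p,
    dd = rel * params$d,
    extrinsic_sigma = extrinsic_sigma
  )
}
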