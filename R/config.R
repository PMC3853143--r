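#' Assemble a run configuration
#'
#' Bundles everything a scan needs: the circuit topology, the level-binning
#' scheme, the target specification, fixed basal production rates, the noise
#' model, simulation settings, clustering settings, and the master seed.
#'
#' @param topology A `kin_topology`.
#' @param scheme A `kin_scheme` over the same genes.
#' @param target A `kin_target` with one entry per gene.
#' @param p0 Basal production rates (nM/step), one per gene (recycled).
#' @param noise Either a list `list(rel =, extrinsic_sigma =)` giving
#'   perturbation amplitudes as a fraction of each parameter's nominal value
#'   (the form used in a scan, where nominal values differ per set), or an
#'   absolute `kin_noise` table.
#' @param simulation List with elements `T` (recorded steps, default 100),
#'   `substeps` (default 1), `abort_ceiling` (nM, default `1e6`), and `x0`
#'   (initial concentrations; default the target `z`).
#' @param clustering List with `linkage` (default `"average"`), `cut_height`
#'   (Hamming dendrogram cut, default 2.5), `threshold` (consensus share for
#'   a non-wildcard logo position, default 0.9), `min_size` (handbook
#'   flagging cut, default 10).
#' @param seed Master RNG seed (default 1).
#' @return A list of class `kin_config`.
#' @seealso [demo_config()] for the calibrated four-gene demo fixture,
#'   [read_run_config()] to load a configuration file.
#' @export
run_config <- function(topology, scheme, target, p0 = 0,
                       noise = list(rel = 0.1, extrinsic_sigma = 10),
                       simulation = list(), clustering = list(), seed = 1) {
  assert_topology(topology)
  assert_scheme(scheme)
  assert_target(target)
  G <- n_genes(topology)
  if (!setequal(scheme$gene, topology$gene)) {
    abort("`scheme` and `topology` must cover the same genes.")
  }
  if (length(target$z) != G) {
    abort("`target$z` must have one entry per gene.")
  }
  zn <- names(target$z)
  if (!is.null(zn) && !identical(zn, topology$gene)) {
    if (!setequal(zn, topology$gene)) {
      abort("Names of `target$z` do not match the topology's genes.")
    }
    target$z <- target$z[topology$gene]
  }
  p0 <- rep_len(as.numeric(p0), G)
  if (any(!is.finite(p0)) || any(p0 < 0)) abort("`p0` must be finite and >= 0.")

  sim <- modifyList(
    list(T = 100L, substeps = 1L, abort_ceiling = 1e6, x0 = NULL),
    simulation
  )
  if (is.null(sim$x0)) sim$x0 <- as.numeric(target$z)
  sim$x0 <- rep_len(as.numeric(sim$x0), G)
  sim$T <- as.integer(sim$T)
  sim$substeps <- as.integer(sim$substeps)
  sim$abort_ceiling <- as.numeric(sim$abort_ceiling)
  if (sim$T < 2) abort("`simulation$T` must be >= 2.")
  if (sim$substeps < 1) abort("`simulation$substeps` must be >= 1.")
  if (sim$abort_ceiling <= 0) abort("`simulation$abort_ceiling` must be > 0.")

  clus <- modifyList(
    list(linkage = "average", cut_height = 2.5, threshold = 0.9, min_size = 10L),
    clustering
  )
  clus$cut_height <- as.numeric(clus$cut_height)
  clus$threshold <- as.numeric(clus$threshold)
  clus$min_size <- as.integer(clus$min_size)
  if (!clus$linkage %in% c("average", "complete", "single")) {
    abort("`clustering$linkage` must be one of 'average', 'complete', 'single'.")
  }

  if (inherits(noise, "kin_noise")) {
    # absolute per-gene amplitudes
  } else if (is.list(noise)) {
    noise <- modifyList(list(rel = 0.1, extrinsic_sigma = 10), noise)
    noise$rel <- as.numeric(noise$rel)
    noise$extrinsic_sigma <- as.numeric(noise$extrinsic_sigma)
    if (noise$rel < 0 || noise$extrinsic_sigma < 0) {
      abort("`noise$rel` and `noise$extrinsic_sigma` must be >= 0.")
    }
  } else {
    abort("`noise` must be a `kin_noise` or a list(rel =, extrinsic_sigma =).")
  }

  structure(
    list(
      topology = topology, scheme = scheme, target = target, p0 = p0,
      noise = noise, simulation = sim, clustering = clus,
      seed = as.integer(seed)
    ),
    class = "kin_config"
  )
}

assert_config <- function(config) {
  if (!inherits(config, "kin_config")) {
    abort("Expected a `kin_config`; see `run_config()` / `demo_config()`.")
  }
  config
}

# absolute kin_noise for a concrete parameter set
resolve_noise <- function(noise, params, topology) {
  if (inherits(noise, "kin_noise")) return(noise)
  noise_from_params(params, topology,
    rel = noise$rel, extrinsic_sigma = noise$extrinsic_sigma
  )
}

#' The calibrated four-gene cascade demo configuration
#'
#' The TetR -| LacI -| CI -| Eyfp repression cascade with target steady states
#' `z = (1000, 30000, 300, 30000) nM`, 20% tolerance, sentinel 15, `T = 100`
#' steps, abort ceiling `1e6` nM, and initial concentrations at the target.
#' Per-gene level ranges are calibrated so that level-matched production /
#' degradation pairs place each gene's fixed point on its target:
#' \itemize{
#'   \item TetR (unregulated): `p` in `[0, 200]`, `d` in `[0, 0.2]`, so
#'     matched levels give `p/d = 1000` nM.
#'   \item LacI (repressed by TetR at ~1000 nM, Hill factor 1/2): `p` in
#'     `[0, 12000]`, so matched levels give `0.5 p/d = 30000` nM.
#'   \item CI (repressed by LacI at ~30000 nM, Hill factor 1/901): production
#'     is effectively silenced, so its level is inconsequential; a basal rate
#'     of 6.5 nM/step with `d` in `[0.018, 0.0255]` keeps `p0/d` within 20%
#'     of 300 nM across the whole degradation range.
#'   \item Eyfp (repressed by CI at ~300 nM, Hill factor ~1/1.09): `p` in
#'     `[0, 6540]`, so matched levels give ~30000 nM.
#' }
#' Noise defaults to 10% of each nominal parameter plus 10 nM/step extrinsic
#' noise.
#'
#' @param n_levels Levels per slot (default 5; use 2 or 3 for fast
#'   reduced-scale runs of the full pipeline).
#' @param looped If `TRUE`, use the looped wiring (Eyfp represses TetR).
#' @param seed Master seed (default 1).
#' @param ... Additional arguments forwarded to [run_config()]
#'   (`noise`, `simulation`, `clustering`).
#' @return A `kin_config`.
#' @examples
#' cfg <- demo_config(n_levels = 2)
#' evaluate_set(rep(1, 8), cfg)
#' @export
demo_config <- function(n_levels = 5, looped = FALSE, seed = 1, ...) {
  topo <- cascade_demo(looped = looped)
  scheme <- level_scheme(
    topo,
    production = list(
      TetR = c(0, 200), LacI = c(0, 12000), CI = c(0, 200), Eyfp = c(0, 6540)
    ),
    degradation = list(CI = c(0.018, 0.0255)),
    n_levels = n_levels,
    .default_degradation = c(0, 0.2)
  )
  target <- target_spec(
    c(TetR = 1000, LacI = 30000, CI = 300, Eyfp = 30000),
    tolerance = 0.20, sentinel = 15
  )
  run_config(
    topology = topo, scheme = scheme, target = target,
    p0 = c(0, 0, 6.5, 0), seed = seed, ...
  )
}

#' @export
print.kin_config <- function(x, ...) {
  cat("<kin_config>\n")
  cat("  genes:", paste(x$topology$gene, collapse = ", "), "\n")
  cat("  levels per slot:", x$scheme$n_levels[1],
      "| grid size:", format(x$scheme$n_levels[1]^nrow(x$scheme), big.mark = ","), "\n")
  cat("  target z:", paste(x$target$z, collapse = ", "), "nM",
      "| tolerance:", x$target$tolerance,
      "| sentinel:", x$target$sentinel, "\n")
  cat("  T:", x$simulation$T, "| substeps:", x$simulation$substeps,
      "| ceiling:", x$simulation$abort_ceiling, "nM\n")
  if (inherits(x$noise, "kin_noise")) {
    cat("  noise: absolute per-gene amplitudes\n")
  } else {
    cat("  noise: rel =", x$noise$rel,
        "| extrinsic sigma =", x$noise$extrinsic_sigma, "nM/step\n")
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
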