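#' Hill repression function
#'
#' Fraction of promoter activity remaining under a repressor at concentration
#' `x`: \eqn{r(x) = 1/(1 + (x/K)^n)}. Equals 1 with no repressor present
#' (`x = 0`) and falls to 1/2 at `x = K`.
#'
#' @param x Repressor concentration, nM (vectorised, all values >= 0).
#' @param K Hill constant, nM (> 0). Default 1000.
#' @param n Hill coefficient (> 0). Default 2.
#' @return Numeric in (0, 1], same length as `x`.
#' @examples
#' hill_repression(0)              # 1: unrepressed
#' hill_repression(1000)           # 0.5: half repression at x == K
#' hill_repression(30000)          # 1/901: essentially silenced
#' @export
hill_repression <- function(x, K = 1000, n = 2) {
  if (any(!is.finite(x)) || any(x < 0)) abort("`x` must be finite and >= 0.")
  if (!is.numeric(K) || any(K <= 0)) abort("`K` must be > 0.")
  if (!is.numeric(n) || any(n <= 0)) abort("`n` must be > 0.")
  1 / (1 + (x / K)^n)
}

# per-gene repression factors for a state vector (r = 1 where unregulated).
# kept as a gene-indexed loop so the scalar and batch engines share arithmetic.
repression_factors <- function(state, topology, rep_idx = repressor_index(topology)) {
  r <- rep(1, length(state))
  for (g in seq_along(state)) {
    j <- rep_idx[g]
    if (!is.na(j)) {
      r[g] <- 1 / (1 + (state[j] / topology$hill_K[g])^topology$hill_n[g])
    }
  }
  r
}

#' Deterministic rate of change
#'
#' The per-gene rate \eqn{\dot x_i = p_{i,0} + p_i r_i(x_j) - d_i x_i}, where
#' \eqn{x_j} is the concentration of gene *i*'s repressor and \eqn{r_i} its
#' Hill repression function (1 for unregulated genes).
#'
#' @param state Numeric vector of current concentrations (nM), one per gene in
#'   topology order.
#' @param params A `kin_params`.
#' @param topology A `kin_topology`.
#' @return Numeric vector of rates, nM per time step.
#' @examples
#' topo <- cascade_demo()
#' pars <- kinetic_params(topo, p0 = 0, p = 100, d = 0.1)
#' deterministic_rate(c(0, 0, 0, 0), pars, topo)  # p0 + p everywhere
#' @export
deterministic_rate <- function(state, params, topology) {
  assert_topology(topology)
  if (length(state) != n_genes(topology)) {
    abort("`state` length must match the number of genes in the topology.")
  }
  r <- repression_factors(state, topology)
  params$p0 + params$p * r - params$d * state
}

#' Noise-perturbed rate of change
#'
#' The stochastic counterpart of [deterministic_rate()]: the deterministic
#' rate plus a parametric perturbation term scaled by a fresh standard-normal
#' draw \eqn{n_i} per gene, plus additive extrinsic noise \eqn{v_i}:
#' \deqn{g_i = f_i + (\Delta p_{i,0} + \Delta p_i r_i - \Delta d_i y_i) n_i + v_i.}
#' Two blocks of standard-normal draws are consumed from the current RNG
#' stream (first all \eqn{n_i}, then all \eqn{v_i}), so results are
#' reproducible under `set.seed()`.
#'
#' @inheritParams deterministic_rate
#' @param noise A `kin_noise`.
#' @return Numeric vector of rates, nM per time step.
#' @examples
#' topo <- cascade_demo()
#' pars <- kinetic_params(topo, p0 = 0, p = 100, d = 0.1)
#' quiet <- noise_spec(topo)   # all amplitudes zero
#' set.seed(1)
#' stochastic_rate(c(0, 0, 0, 0), pars, topo, quiet)  # equals the deterministic rate
#' @export
stochastic_rate <- function(state, params, topology, noise) {
  G <- n_genes(topology)
  f <- deterministic_rate(state, params, topology)
  r <- repression_factors(state, topology)
  ndraw <- rnorm(G)
  vdraw <- rnorm(G)
  a <- noise$dp0 + noise$dp * r - noise$dd * state
  f + a * ndraw + noise$extrinsic_sigma * vdraw
}

#' Simulate a circuit trajectory
#'
#' Advances the concentrations with an explicit Euler scheme (Euler–Maruyama
#' in stochastic mode), recording the state after each of `T` unit time steps.
#' Each recorded step may be subdivided into `substeps` Euler substeps of size
#' `1/substeps`; in stochastic mode the noise terms are scaled by
#' `sqrt(1/substeps)` and fresh draws are used per substep. Negative
#' intermediate concentrations are clamped to 0. If any concentration exceeds
#' `abort_ceiling` (or turns non-finite) at a recorded step, the run stops and
#' the trajectory is flagged as aborted.
#'
#' @inheritParams deterministic_rate
#' @param x0 Initial concentrations (nM), one per gene.
#' @param T Number of recorded time steps (>= 2).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param noise A `kin_noise`; required in stochastic mode.
#' @param seed Optional integer seed for the stochastic draws; if `NULL` the
#'   current RNG stream is used.
#' @param substeps Euler substeps per recorded step (default 1, the plain
#'   per-time-step update of the model).
#' @param abort_ceiling Concentration ceiling in nM (default `1e6`).
#' @return A tibble of class `kin_trajectory` with column `time` (0..T or up
#'   to the abort step) and one concentration column per gene. Attributes:
#'   `mode`, `aborted`, `abort_time` (NA when not aborted).
#' @examples
#' topo <- circuit_topology(data.frame(gene = "A", repressor = NA))
#' pars <- kinetic_params(topo, p0 = 0, p = 100, d = 0.1)
#' tr <- simulate_circuit(topo, pars, x0 = 1000, T = 10)
#' tr  # constant at the fixed point p/d = 1000
#' @export
simulate_circuit <- function(topology, params, x0, T = 100,
                             mode = c("deterministic", "stochastic"),
                             noise = NULL, seed = NULL, substeps = 1,
                             abort_ceiling = 1e6) {
  assert_topology(topology)
  mode <- match.arg(mode)
  G <- n_genes(topology)
  x0 <- rep_len(as.numeric(x0), G)
  if (!is.numeric(T) || T < 2) abort("`T` must be >= 2.")
  T <- as.integer(T)
  if (!is.numeric(abort_ceiling) || abort_ceiling <= 0) {
    abort("`abort_ceiling` must be > 0.")
  }
  substeps <- as.integer(substeps)
  if (substeps < 1) abort("`substeps` must be >= 1.")
  if (mode == "stochastic" && is.null(noise)) {
    abort("Stochastic mode requires a `noise` specification (see `noise_spec()`).")
  }

  rep_idx <- repressor_index(topology)
  h <- 1 / substeps
  sh <- sqrt(h)
  p0 <- params$p0; p <- params$p; d <- params$d

  nmat <- vmat <- NULL
  if (mode == "stochastic") {
    if (!is.null(seed)) set.seed(as.integer(seed))
    # canonical draw order: the full intrinsic block, then the extrinsic block
    nmat <- matrix(rnorm(T * substeps * G), T * substeps, G)
    vmat <- matrix(rnorm(T * substeps * G), T * substeps, G)
  }

  conc <- matrix(NA_real_, T + 1, G)
  conc[1, ] <- pmax(x0, 0)
  x <- conc[1, ]
  aborted <- FALSE
  abort_time <- NA_integer_

  for (t in seq_len(T)) {
    for (s in seq_len(substeps)) {
      r <- repression_factors(x, topology, rep_idx)
      f <- p0 + p * r - d * x
      if (mode == "stochastic") {
        k <- (t - 1L) * substeps + s
        a <- noise$dp0 + noise$dp * r - noise$dd * x
        x <- x + h * f + sh * (a * nmat[k, ] + noise$extrinsic_sigma * vmat[k, ])
      } else {
        x <- x + h * f
      }
      x[x < 0] <- 0
    }
    if (any(!is.finite(x)) || any(x > abort_ceiling)) {
      aborted <- TRUE
      abort_time <- t
      x[!is.finite(x)] <- abort_ceiling
      conc[t + 1, ] <- x
      break
    }
    conc[t + 1, ] <- x
  }

  keep <- if (aborted) seq_len(abort_time + 1L) else seq_len(T + 1L)
  out <- as_tibble(as.data.frame(conc[keep, , drop = FALSE]), .name_repair = "minimal")
  names(out) <- topology$gene
  out <- dplyr::bind_cols(tibble(time = keep - 1L), out)
  structure(
    out,
    class = c("kin_trajectory", class(tibble())),
    mode = mode, aborted = aborted, abort_time = abort_time,
    T_requested = T
  )
}

#' Was a trajectory aborted?
#' @param traj A `kin_trajectory`.
#' @return Logical scalar.
#' @export
is_aborted <- function(traj) isTRUE(attr(traj, "aborted"))

# concentration matrix (steps x genes) for recorded steps t = 1..T (drops t=0)
trajectory_conc <- function(traj) {
  m <- as.matrix(traj[traj$time > 0, setdiff(names(traj), "time"), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Steady-state concentrations of a trajectory
#'
#' The operational steady state used throughout the pipeline: the per-gene
#' arithmetic mean over the second half of the recorded steps (the last
#' `ceiling(T/2)` of steps 1..T).
#'
#' @param traj A non-aborted `kin_trajectory`.
#' @return Named numeric vector of concentrations (nM), one per gene.
#' @examples
#' topo <- circuit_topology(data.frame(gene = "A", repressor = NA))
#' pars <- kinetic_params(topo, p0 = 0, p = 30, d = 0.1)
#' steady_state(simulate_circuit(topo, pars, x0 = 300, T = 20))
#' @export
steady_state <- function(traj) {
  if (!inherits(traj, "kin_trajectory")) abort("Expected a `kin_trajectory`.")
  if (is_aborted(traj)) {
    abort("Trajectory was aborted; no steady state is defined (use `score_run()`).")
  }
  conc <- trajectory_conc(traj)
  T <- nrow(conc)
  half_len <- ceiling(T / 2)
  half <- conc[(T - half_len + 1L):T, , drop = FALSE]
  colMeans(half)
}

#' Analytic fixed point of an open cascade
#'
#' Solves the steady-state equations gene by gene in dependency
#' (topological) order for an acyclic circuit:
#' \eqn{x_i^* = (p_{i,0} + p_i r_i(x_j^*)) / d_i}. This is a closed-form
#' route, independent of the Euler integrator, and is the reference the
#' simulated steady state is validated against.
#'
#' @inheritParams deterministic_rate
#' @return Named numeric vector of fixed-point concentrations (nM).
#' @export
fixed_point <- function(params, topology) {
  assert_topology(topology)
  rep_idx <- repressor_index(topology)
  G <- n_genes(topology)
  x <- rep(NA_real_, G)
  remaining <- seq_len(G)
  while (length(remaining)) {
    ready <- remaining[vapply(
      remaining, function(g) is.na(rep_idx[g]) || !is.na(x[rep_idx[g]]),
      logical(1)
    )]
    if (!length(ready)) {
      abort("Circuit contains a feedback loop; the gene-by-gene fixed point is only defined for open (acyclic) cascades.")
    }
    for (g in ready) {
      r <- if (is.na(rep_idx[g])) 1 else {
        1 / (1 + (x[rep_idx[g]] / topology$hill_K[g])^topology$hill_n[g])
      }
      x[g] <- (params$p0[g] + params$p[g] * r) / params$d[g]
    }
    remaining <- setdiff(remaining, ready)
  }
  setNames(x, topology$gene)
}
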