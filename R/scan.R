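# Batch Euler / Euler-Maruyama integration of many parameter sets at once.
# Arithmetic per element is kept in exactly the same order as the scalar
# path in simulate_circuit()/deviation()/steady_state(), so a batch scan and
# per-set evaluate_set() calls agree bit-for-bit.
#
# P, D, P0: S x G rate matrices; X0: S x G initial state; z: length-G target.
# noise: NULL (deterministic) or list(dP0, dP, dD, SIG (S x G), seeds (S)).
# Returns list(dev, ss (S x G), aborted).
run_batch <- function(P, D, P0, X0, rep_idx, K, nhill, z, T, substeps,
                      abort_ceiling, noise = NULL) {
  S <- nrow(P); G <- ncol(P)
  h <- 1 / substeps
  sh <- sqrt(h)
  half_len <- ceiling(T / 2)
  half_start <- T - half_len + 1L

  Narr <- Varr <- NULL
  if (!is.null(noise)) {
    # per-set substreams in canonical order: intrinsic block then extrinsic
    Narr <- array(NA_real_, c(S, T * substeps, G))
    Varr <- array(NA_real_, c(S, T * substeps, G))
    for (i in seq_len(S)) {
      set.seed(noise$seeds[i])
      Narr[i, , ] <- matrix(rnorm(T * substeps * G), T * substeps, G)
      Varr[i, , ] <- matrix(rnorm(T * substeps * G), T * substeps, G)
    }
  }

  X <- X0
  X[X < 0] <- 0
  Zm <- matrix(z, S, G, byrow = TRUE)
  dev <- numeric(S)
  half <- matrix(0, S, G)
  aborted <- rep(FALSE, S)

  for (t in seq_len(T)) {
    for (s in seq_len(substeps)) {
      Rm <- matrix(1, S, G)
      for (g in seq_len(G)) {
        j <- rep_idx[g]
        if (!is.na(j)) Rm[, g] <- 1 / (1 + (X[, j] / K[g])^nhill[g])
      }
      Fm <- P0 + P * Rm - D * X
      if (!is.null(noise)) {
        k <- (t - 1L) * substeps + s
        Am <- noise$dP0 + noise$dP * Rm - noise$dD * X
        X <- X + h * Fm + sh * (Am * Narr[, k, ] + noise$SIG * Varr[, k, ])
      } else {
        X <- X + h * Fm
      }
      X[X < 0] <- 0
    }
    bad <- !is.finite(X) | X > abort_ceiling
    if (any(bad)) {
      newly <- !aborted & (rowSums(bad) > 0)
      if (any(newly)) {
        aborted <- aborted | newly
        X[newly, ] <- 0  # freeze; accumulators for these rows are ignored
      }
    }
    dev <- dev + rowSums(abs(X - Zm))
    if (t >= half_start) half <- half + X
  }
  list(dev = dev, ss = half / half_len, aborted = aborted)
}

#' Scan the full level grid
#'
#' Evaluates every level sequence of the grid: one deterministic and one
#' stochastic simulation per set, scored into the deterministic deviation
#' `DD`, the stochastic deviation `DS`, and the four-quadrant class
#' (`both_ok` / `det_only` / `stoch_only` / `both_fail`). Each set's noise
#' stream is a substream derived from the master seed and the set's
#' lexicographic grid index, so results are reproducible and independent of
#' chunking.
#'
#' @param config A `kin_config`.
#' @param seed Master seed; defaults to `config$seed`.
#' @param chunk_size Number of sets integrated per stochastic batch
#'   (memory/speed trade-off; does not affect results).
#' @param progress Print a progress line every 10,000 sets.
#' @return A tibble of class `kin_scan` with one row per grid point:
#'   `level_string`, `DD`, `DS`, `class`; rows in lexicographic grid order.
#'   Attribute `quadrants` holds the named class counts; `glance()` returns
#'   them as a tibble.
#' @examples
#' cfg <- demo_config(n_levels = 2)
#' sc <- scan_grid(cfg)
#' glance(sc)
#' @export
scan_grid <- function(config, seed = NULL, chunk_size = 4096, progress = FALSE) {
  config <- assert_config(config)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  topo <- config$topology
  scheme <- config$scheme
  sim <- config$simulation
  G <- n_genes(topo)
  n_lev <- scheme$n_levels[1]

  grid <- enumerate_grid(G, n_lev)
  S <- nrow(grid)

  # level -> representative value, per slot
  vals <- matrix(NA_real_, S, ncol(grid))
  for (s in seq_len(ncol(grid))) {
    vals[, s] <- level_to_value(grid[, s], scheme$lo[s], scheme$hi[s], n_lev)
  }
  P <- vals[, scheme$role == "production", drop = FALSE]
  D <- vals[, scheme$role == "degradation", drop = FALSE]
  P0 <- matrix(config$p0, S, G, byrow = TRUE)
  X0 <- matrix(sim$x0, S, G, byrow = TRUE)
  rep_idx <- repressor_index(topo)
  z <- as.numeric(config$target$z)
  sentinel <- config$target$sentinel
  tol <- config$target$tolerance

  score_batch <- function(res) {
    ok <- !res$aborted
    devok <- abs(res$ss - matrix(z, nrow(res$ss), G, byrow = TRUE)) <=
      tol * matrix(z, nrow(res$ss), G, byrow = TRUE)
    ok <- ok & (rowSums(devok) == G)
    out <- rep(sentinel, length(res$dev))
    out[ok] <- ifelse(res$dev[ok] == 0, DEVIATION_FLOOR, log(res$dev[ok]))
    out
  }

  det <- run_batch(P, D, P0, X0, rep_idx, topo$hill_K, topo$hill_n, z,
    sim$T, sim$substeps, sim$abort_ceiling,
    noise = NULL
  )
  DD <- score_batch(det)

  DS <- numeric(S)
  rel_noise <- !inherits(config$noise, "kin_noise")
  starts <- seq(1L, S, by = chunk_size)
  done <- 0L
  for (st in starts) {
    idx <- st:min(st + chunk_size - 1L, S)
    if (rel_noise) {
      dP0 <- config$noise$rel * P0[idx, , drop = FALSE]
      dP <- config$noise$rel * P[idx, , drop = FALSE]
      dD <- config$noise$rel * D[idx, , drop = FALSE]
      SIG <- matrix(config$noise$extrinsic_sigma, length(idx), G)
    } else {
      dP0 <- matrix(config$noise$dp0, length(idx), G, byrow = TRUE)
      dP <- matrix(config$noise$dp, length(idx), G, byrow = TRUE)
      dD <- matrix(config$noise$dd, length(idx), G, byrow = TRUE)
      SIG <- matrix(config$noise$extrinsic_sigma, length(idx), G, byrow = TRUE)
    }
    seeds <- vapply(idx, function(i) derive_seed(seed, i), integer(1))
    sto <- run_batch(
      P[idx, , drop = FALSE], D[idx, , drop = FALSE],
      P0[idx, , drop = FALSE], X0[idx, , drop = FALSE],
      rep_idx, topo$hill_K, topo$hill_n, z,
      sim$T, sim$substeps, sim$abort_ceiling,
      noise = list(dP0 = dP0, dP = dP, dD = dD, SIG = SIG, seeds = seeds)
    )
    DS[idx] <- score_batch(sto)
    done <- done + length(idx)
    if (progress && (done %% 10000L < chunk_size)) {
      message(format(done, big.mark = ","), " / ",
              format(S, big.mark = ","), " sets evaluated")
    }
  }

  klass <- outcome_class(DD, DS, sentinel)
  quad <- table(factor(klass,
    levels = c("both_ok", "det_only", "stoch_only", "both_fail")
  ))
  out <- tibble(
    level_string = do.call(paste0, lapply(seq_len(ncol(grid)), function(j) grid[, j])),
    DD = DD, DS = DS, class = klass
  )
  structure(
    out,
    class = c("kin_scan", class(tibble())),
    quadrants = c(quad),
    n_levels = n_lev, n_genes = G, seed = seed
  )
}

#' Quadrant summary of a scan
#'
#' @param x A `kin_scan`.
#' @param ... Unused.
#' @return One-row tibble with the four class counts, the grid size and the
#'   functional fraction.
#' @method glance kin_scan
#' @export
glance.kin_scan <- function(x, ...) {
  q <- attr(x, "quadrants")
  tibble(
    n_sets = nrow(x),
    both_ok = unname(q["both_ok"]),
    det_only = unname(q["det_only"]),
    stoch_only = unname(q["stoch_only"]),
    both_fail = unname(q["both_fail"]),
    functional_fraction = unname(q["both_ok"]) / nrow(x)
  )
}

#' Functional (both-condition) records of a scan
#'
#' @param scan A `kin_scan`.
#' @return The `both_ok` rows as a tibble.
#' @export
functional_records <- function(scan) {
  if (!inherits(scan, "kin_scan")) abort("Expected a `kin_scan`.")
  dplyr::filter(as_tibble(scan), .data$class == "both_ok")
}

# decode a vector of level strings into an integer matrix
decode_level_strings <- function(x) {
  m <- do.call(rbind, lapply(strsplit(x, ""), as.integer))
  dimnames(m) <- NULL
  m
}
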