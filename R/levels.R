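#' Efficiency-level binning scheme
#'
#' Each gene contributes two kinetic slots — production (`p`) and degradation
#' (`d`) — and each slot's value range `[lo, hi]` is divided into `n_levels`
#' uniform bins ("efficiency levels", level 1 weakest to level `n_levels`
#' strongest). The representative value of a level is the midpoint of its
#' bin. Slots are ordered `(p_1, d_1, p_2, d_2, ...)` following the gene
#' order of the topology.
#'
#' @param topology A `kin_topology`.
#' @param production,degradation Either a length-2 numeric `c(lo, hi)` shared
#'   by all genes, or a named list of per-gene `c(lo, hi)` ranges (genes not
#'   named fall back to the shared default given in `.default_production` /
#'   `.default_degradation`).
#' @param n_levels Number of levels per slot (default 5).
#' @param .default_production,.default_degradation Fallback shared ranges used
#'   for genes absent from a per-gene list.
#' @return A tibble of class `kin_scheme` with columns `slot`, `gene`, `role`
#'   (`"production"`/`"degradation"`), `lo`, `hi`, `n_levels`.
#' @examples
#' level_scheme(cascade_demo())
#' level_scheme(cascade_demo(), production = list(TetR = c(0, 200)))
#' @export
level_scheme <- function(topology, production = c(0, 6000),
                         degradation = c(0, 0.2), n_levels = 5,
                         .default_production = c(0, 6000),
                         .default_degradation = c(0, 0.2)) {
  assert_topology(topology)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) abort("`n_levels` must be >= 2.")
  range_for <- function(spec, default, gene) {
    rng <- if (is.list(spec)) {
      if (!is.null(spec[[gene]])) spec[[gene]] else default
    } else spec
    rng <- as.numeric(rng)
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[2] <= rng[1] || rng[1] < 0) {
      abort(paste0("Invalid range for gene ", gene, ": need hi > lo >= 0."))
    }
    rng
  }
  G <- n_genes(topology)
  rows <- vector("list", 2L * G)
  for (g in seq_len(G)) {
    gn <- topology$gene[g]
    pr <- range_for(production, .default_production, gn)
    dr <- range_for(degradation, .default_degradation, gn)
    rows[[2 * g - 1]] <- tibble(
      slot = 2L * g - 1L, gene = gn, role = "production",
      lo = pr[1], hi = pr[2], n_levels = n_levels
    )
    rows[[2 * g]] <- tibble(
      slot = 2L * g, gene = gn, role = "degradation",
      lo = dr[1], hi = dr[2], n_levels = n_levels
    )
  }
  structure(
    dplyr::bind_rows(rows),
    class = c("kin_scheme", class(tibble()))
  )
}

assert_scheme <- function(scheme) {
  if (!inherits(scheme, "kin_scheme")) {
    abort("Expected a `kin_scheme` object; see `level_scheme()`.")
  }
  invisible(scheme)
}

#' Representative rate value of an efficiency level
#'
#' The midpoint of the level's uniform bin:
#' `lo + (level - 0.5) * (hi - lo) / n_levels`.
#'
#' @param level Integer level(s) in `1..n_levels`.
#' @param lo,hi Bin-range start and end.
#' @param n_levels Number of uniform bins.
#' @return Numeric value(s) in `(lo, hi)`.
#' @examples
#' level_to_value(1:5, lo = 0, hi = 1, n_levels = 5)
#' @export
level_to_value <- function(level, lo, hi, n_levels = 5) {
  level <- as.integer(level)
  if (any(is.na(level)) || any(level < 1) || any(level > n_levels)) {
    abort(paste0("`level` must be in 1..", n_levels, "."))
  }
  lo + (level - 0.5) * (hi - lo) / n_levels
}

#' Efficiency level of a rate value
#'
#' Inverse of the binning: the 1-based index of the uniform bin containing
#' `value`. Bins are right-open except the last, which is closed so that
#' `value = hi` maps to `n_levels`.
#'
#' @param value Numeric value(s) in `[lo, hi]`.
#' @inheritParams level_to_value
#' @return Integer level(s).
#' @examples
#' value_to_level(c(0.05, 0.5, 1), lo = 0, hi = 1, n_levels = 5)
#' @export
value_to_level <- function(value, lo, hi, n_levels = 5) {
  if (any(!is.finite(value)) || any(value < lo) || any(value > hi)) {
    abort(paste0("`value` must lie within [", lo, ", ", hi, "]."))
  }
  lev <- pmin(n_levels, floor((value - lo) / ((hi - lo) / n_levels)) + 1)
  as.integer(lev)
}

#' Enumerate the full level grid
#'
#' Every combination of efficiency levels over the `2 * n_genes` kinetic
#' slots, in lexicographic order (last slot varies fastest), so scan outputs
#' are stable and a sequence's position in the grid is its lexicographic
#' index.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_levels Levels per slot (default 5).
#' @return An integer matrix with `n_levels^(2 * n_genes)` rows and
#'   `2 * n_genes` columns; row `i` is the `i`-th level sequence.
#' @examples
#' enumerate_grid(1, 2)
#' nrow(enumerate_grid(4, 5))  # 390625
#' @export
enumerate_grid <- function(n_genes, n_levels = 5) {
  if (!is.numeric(n_genes) || n_genes < 1) abort("`n_genes` must be >= 1.")
  L <- 2L * as.integer(n_genes)
  n_levels <- as.integer(n_levels)
  # expand.grid varies the first factor fastest; feed slots reversed so the
  # LAST slot varies fastest, then restore column order
  g <- expand.grid(rep(list(seq_len(n_levels)), L), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g)[, L:1, drop = FALSE]
  dimnames(m) <- list(NULL, paste0("s", seq_len(L)))
  storage.mode(m) <- "integer"
  m
}

#' Lexicographic index of a level sequence
#'
#' Position of `levels` in the [enumerate_grid()] ordering (1-based). Used to
#' derive the per-set RNG substream in a scan.
#'
#' @param levels Integer vector, one level per slot.
#' @param n_levels Levels per slot.
#' @return Integer index in `1..n_levels^length(levels)`.
#' @export
grid_index <- function(levels, n_levels = 5) {
  L <- length(levels)
  sum((levels - 1) * n_levels^((L - 1):0)) + 1
}

#' Convert a level sequence to kinetic parameters
#'
#' Maps each slot's level to the midpoint value of its bin under the scheme,
#' producing a `kin_params` (basal rates `p0` supplied separately, as they are
#' not part of the scanned grid).
#'
#' @param levels Integer vector of levels, length `2 * n_genes`, ordered
#'   `(p_1, d_1, p_2, d_2, ...)`.
#' @param scheme A `kin_scheme`.
#' @param topology The matching `kin_topology`.
#' @param p0 Basal production rates, one per gene (default 0).
#' @return A `kin_params` tibble.
#' @export
levels_to_params <- function(levels, scheme, topology, p0 = 0) {
  assert_scheme(scheme)
  if (length(levels) != nrow(scheme)) {
    abort(paste0("`levels` must have length ", nrow(scheme), "."))
  }
  vals <- level_to_value(levels, scheme$lo, scheme$hi, scheme$n_levels[1])
  kinetic_params(
    topology,
    p0 = p0,
    p = vals[scheme$role == "production"],
    d = vals[scheme$role == "degradation"]
  )
}

#' Level-sequence string forms
#'
#' A level sequence is serialised either as a digit string (`"33514221"`) or
#' the human-readable paired form `"(3,3);(5,1);(2,4);(2,1)"` pairing each
#' gene's production and degradation levels.
#'
#' @param levels Integer vector of levels (length `2 * n_genes`).
#' @return `levels_to_string()`: a single digit string.
#' @examples
#' levels_to_string(c(3, 3, 5, 1, 2, 4, 2, 1))
#' levels_to_paired(c(3, 3, 5, 1, 2, 4, 2, 1))
#' parse_levels("(3,3);(5,1);(2,4);(2,1)")
#' @export
levels_to_string <- function(levels) paste(levels, collapse = "")

#' @rdname levels_to_string
#' @return `levels_to_paired()`: the paired form string.
#' @export
levels_to_paired <- function(levels) {
  stopifnot(length(levels) %% 2 == 0)
  pairs <- matrix(levels, nrow = 2)
  paste0("(", pairs[1, ], ",", pairs[2, ], ")", collapse = ";")
}

#' @rdname levels_to_string
#' @param x A digit string or paired-form string (wildcards `*` allowed, in
#'   which case a character vector is returned).
#' @return `parse_levels()`: an integer vector, or character vector when `x`
#'   contains wildcards.
#' @export
parse_levels <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  chars <- strsplit(gsub("[();,\\s]", "", x, perl = TRUE), "")[[1]]
  if (!length(chars) || !all(grepl("^[0-9*]$", chars))) {
    abort(paste0(
      "Cannot parse level sequence from \"", x,
      "\"; expected digits/'*' as e.g. \"33514221\" or \"(3,3);(5,1);(2,4);(2,1)\"."
    ))
  }
  if (any(chars == "*")) chars else as.integer(chars)
}
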