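#' Simulate a configured circuit and export the trajectory
#'
#' Pipeline stage one: run a single deterministic or stochastic simulation of
#' the configured circuit, for a level sequence (converted to rates through
#' the config's level scheme) or explicit rates, and write the trajectory as
#' CSV.
#'
#' @param config A `kin_config` or path to a configuration file.
#' @param levels Level sequence (integer vector or digit string). Exactly one
#'   of `levels` / `params` must be given.
#' @param params A `kin_params` with explicit rates.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param out Output CSV path, or `NULL` to skip writing.
#' @param seed Seed for the stochastic draws (default: the config seed).
#' @return The `kin_trajectory`, invisibly when `out` is written.
#' @export
run_simulate <- function(config, levels = NULL, params = NULL,
                         mode = c("deterministic", "stochastic"),
                         out = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- assert_config(config)
  mode <- match.arg(mode)
  if (is.null(levels) == is.null(params)) {
    abort("Supply exactly one of `levels` or `params`.")
  }
  if (!is.null(levels)) {
    if (is.character(levels)) levels <- parse_levels(levels)
    if (length(levels) != nrow(config$scheme)) {
      abort(paste0(
        "`levels` has length ", length(levels), "; expected ",
        nrow(config$scheme), " (two slots per gene)."
      ))
    }
    params <- levels_to_params(levels, config$scheme, config$topology,
      p0 = config$p0
    )
  }
  seed <- seed %||% config$seed
  noise <- if (mode == "stochastic") {
    resolve_noise(config$noise, params, config$topology)
  }
  sim <- config$simulation
  traj <- simulate_circuit(
    config$topology, params,
    x0 = sim$x0, T = sim$T, mode = mode, noise = noise, seed = seed,
    substeps = sim$substeps, abort_ceiling = sim$abort_ceiling
  )
  if (!is.null(out)) {
    write_trajectory_csv(traj, out, config = config, seed = seed)
    return(invisible(traj))
  }
  traj
}

#' Scan the grid and export the solution map
#'
#' Pipeline stage two: evaluate every level sequence of the configured grid
#' and write the solution-map table (plus quadrant summary footer) to
#' `out_dir/solution_map.tsv`.
#'
#' @inheritParams run_simulate
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param delim Field delimiter for the exported table.
#' @param ... Passed to [scan_grid()] (`chunk_size`, `progress`).
#' @return The `kin_scan`, invisibly when written.
#' @export
run_scan <- function(config, out_dir = NULL, seed = NULL, delim = "\t", ...) {
  if (is.character(config)) config <- read_run_config(config)
  config <- assert_config(config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    probe <- file.path(out_dir, ".kinmotif-write-test")
    ok <- tryCatch({ file.create(probe); file.remove(probe); TRUE },
      warning = function(w) FALSE, error = function(e) FALSE
    )
    if (!ok) abort(paste0("Output directory not writable: ", out_dir))
  }
  scan <- scan_grid(config, seed = seed, ...)
  if (!is.null(out_dir)) {
    write_scan_tsv(
      scan, file.path(out_dir, "solution_map.tsv"),
      config = config, seed = seed %||% config$seed, delim = delim
    )
    return(invisible(scan))
  }
  scan
}

#' Cluster a scan into the ranked motif handbook
#'
#' Pipeline stages three and four: take the functional (`both_ok`) records of
#' a scan, cluster them by Hamming distance, build consensus logos, rank the
#' motifs, and optionally export the handbook TSV and the dendrogram in
#' Newick format. With zero functional records a warning is emitted and a
#' header-only handbook is written.
#'
#' @inheritParams run_simulate
#' @param scan A `kin_scan`, or path to a solution-map TSV.
#' @param out Output TSV path, or `NULL` to skip writing.
#' @param newick_out Optional path for the Newick dendrogram.
#' @return The `kin_handbook`, invisibly when written.
#' @export
run_handbook <- function(scan, config, out = NULL, newick_out = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- assert_config(config)
  if (is.character(scan)) scan <- read_scan_tsv(scan)
  fun <- functional_records(scan)
  cl <- config$clustering
  n_lev <- config$scheme$n_levels[1]
  if (nrow(fun) == 0) {
    warn("Scan contains no functional (both_ok) records; handbook is empty.")
    hb <- structure(
      tibble(
        rank = integer(), logo = character(), logo_paired = character(),
        size = integer(), mean_DD = double(), mean_DS = double(),
        score = double(), sub_threshold = logical(), members = list()
      ),
      class = c("kin_handbook", class(tibble())),
      tree = NULL, min_size = cl$min_size, threshold = cl$threshold,
      provenance = list(seed = seed %||% config$seed)
    )
  } else {
    clustered <- cluster_functional(fun,
      linkage = cl$linkage, cut_height = cl$cut_height
    )
    hb <- rank_handbook(clustered,
      min_size = cl$min_size, threshold = cl$threshold, n_levels = n_lev,
      provenance = list(
        seed = seed %||% config$seed,
        config_hash = rlang::hash(unclass(config)),
        linkage = cl$linkage, cut_height = cl$cut_height
      )
    )
  }
  if (!is.null(newick_out) && !is.null(attr(hb, "tree"))) {
    export_dendrogram(hb, newick_out)
  }
  if (!is.null(out)) {
    write_handbook_tsv(hb, out, config = config, seed = seed %||% config$seed)
    return(invisible(hb))
  }
  hb
}

#' Query a handbook for repair or improvement routes
#'
#' Pipeline stage five: given a design's level sequence, either find the
#' nearest functional motifs and the substitution routes that repair a
#' non-functional design (`mode = "repair"`), or list routes to
#' better-ranked motifs for an already functional design
#' (`mode = "improve"`). Results are printed as a human-readable report and
#' optionally written as TSV.
#'
#' @param handbook A `kin_handbook` or path to a handbook TSV.
#' @param design Level sequence (integer vector, digit string, or paired
#'   form).
#' @param mode `"repair"` or `"improve"`.
#' @param library Optional `kin_library` or path to a parts TSV.
#' @param topology Optional `kin_topology` for gene names in routes.
#' @param k Number of nearest motifs considered in repair mode (default 5).
#' @param max_distance Maximum substitutions per route (default 2).
#' @param out Optional TSV path for the route table.
#' @param quiet Suppress the printed report.
#' @return A list with elements `nearest` (tibble) and `routes` (list of
#'   `kin_route`), invisibly when `quiet = FALSE`.
#' @export
run_advise <- function(handbook, design, mode = c("repair", "improve"),
                       library = NULL, topology = NULL, k = 5,
                       max_distance = 2, out = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  if (is.character(handbook) && length(handbook) == 1 && file.exists(handbook)) {
    handbook <- read_handbook_tsv(handbook)
  }
  if (!inherits(handbook, "kin_handbook")) abort("Expected a `kin_handbook` (or a path to one).")
  if (is.character(library) && length(library) == 1) {
    library <- read_part_library(library)
  }
  design <- if (is.character(design)) parse_levels(design) else as.integer(design)
  if (is.character(design)) {
    abort("Design sequence may not contain wildcards.")
  }
  L <- nchar(handbook$logo[1])
  if (length(design) != L) {
    abort(paste0(
      "Design has ", length(design), " positions; expected ", L,
      " (e.g. \"33514221\" for a 4-gene circuit)."
    ))
  }

  if (mode == "repair") {
    near <- nearest_motifs(design, handbook, k = k)
    routes <- lapply(seq_len(nrow(near)), function(i) {
      repair_routes(design, near[i, ], topology = topology, library = library)
    })
  } else {
    routes <- improvement_routes(design, handbook,
      max_distance = max_distance,
      topology = topology, library = library
    )
    near <- nearest_motifs(design, handbook, k = nrow(handbook)) |>
      dplyr::filter(.data$distance == 0)
  }

  if (!quiet) {
    cat("design: ", levels_to_string(design), " ",
      levels_to_paired(design), "\n",
      sep = ""
    )
    if (mode == "improve" && !length(routes)) {
      cat("no improvement available: no better-ranked motif within distance ",
        max_distance, "\n",
        sep = ""
      )
    }
    for (r in routes) print(r)
  }
  if (!is.null(out)) {
    flat <- purrr::map_dfr(routes, function(r) {
      if (nrow(r) == 0) return(tibble())
      dplyr::mutate(
        as_tibble(r),
        parts = purrr::map_chr(.data$parts, paste, collapse = ","),
        motif_rank = attr(r, "motif_rank"),
        motif_logo = attr(r, "motif_logo"),
        distance = attr(r, "distance")
      )
    })
    write_table_with_header(flat, out, provenance_header())
  }
  res <- list(nearest = near, routes = routes)
  if (quiet) res else invisible(res)
}
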