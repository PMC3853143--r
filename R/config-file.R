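#' Read a run configuration from a YAML or JSON file
#'
#' The file has sections `genes`, `params`, `levels`, `target`, `noise`,
#' `simulation`, `clustering` and a top-level `seed`; see the file shipped at
#' `system.file("extdata", "demo_config.yaml", package = "kinmotif")` for the
#' schema. Files ending in `.json` are parsed as JSON, anything else as YAML.
#' Malformed configurations produce an error naming the offending section and
#' field.
#'
#' @param path Path to the configuration file.
#' @return A `kin_config`.
#' @examples
#' cfg <- read_run_config(
#'   system.file("extdata", "demo_config.yaml", package = "kinmotif")
#' )
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  build_config_from_list(raw, path)
}

build_config_from_list <- function(raw, path = "<config>") {
  fail <- function(section, field, msg) {
    abort(paste0(
      "Invalid config ", path, ": section `", section, "`",
      if (nzchar(field)) paste0(", field `", field, "`"), ": ", msg
    ))
  }
  if (is.null(raw$genes)) fail("genes", "", "section is required")
  genes <- purrr::map_dfr(raw$genes, function(g) {
    if (is.null(g$name)) fail("genes", "name", "every gene needs a name")
    tibble(
      gene = g$name,
      repressor = if (length(g$repressor) == 1 && !is.na(g$repressor)) {
        as.character(g$repressor)
      } else NA_character_,
      hill_K = g$hill_K %||% 1000,
      hill_n = g$hill_n %||% 2
    )
  })
  topo <- tryCatch(circuit_topology(genes), error = function(e) {
    fail("genes", "", conditionMessage(e))
  })

  lv <- raw$levels %||% list()
  n_levels <- lv$n_levels %||% 5
  pick_ranges <- function(section_name) {
    sec <- lv[[section_name]] %||% list()
    default <- sec$default
    per_gene <- sec[setdiff(names(sec), "default")]
    bad <- setdiff(names(per_gene), topo$gene)
    if (length(bad)) {
      fail("levels", section_name, paste0("unknown gene(s): ", paste(bad, collapse = ", ")))
    }
    list(default = default, per_gene = per_gene)
  }
  pr <- pick_ranges("production")
  dr <- pick_ranges("degradation")
  scheme <- tryCatch(
    level_scheme(
      topo,
      production = if (length(pr$per_gene)) pr$per_gene else pr$default %||% c(0, 6000),
      degradation = if (length(dr$per_gene)) dr$per_gene else dr$default %||% c(0, 0.2),
      n_levels = n_levels,
      .default_production = pr$default %||% c(0, 6000),
      .default_degradation = dr$default %||% c(0, 0.2)
    ),
    error = function(e) fail("levels", "", conditionMessage(e))
  )

  tg <- raw$target
  if (is.null(tg) || is.null(tg$z)) fail("target", "z", "target concentrations are required")
  z <- unlist(tg$z)
  if (!is.null(names(z))) {
    missing <- setdiff(topo$gene, names(z))
    if (length(missing)) {
      fail("target", "z", paste0("no target for gene(s): ", paste(missing, collapse = ", ")))
    }
    z <- z[topo$gene]
  }
  target <- tryCatch(
    target_spec(z,
      tolerance = tg$tolerance %||% 0.20,
      sentinel = tg$sentinel %||% 15
    ),
    error = function(e) fail("target", "", conditionMessage(e))
  )

  p0 <- raw$params$p0 %||% 0
  if (!is.null(names(p0)) && length(p0) > 1) {
    p0 <- unlist(p0)[topo$gene]
    if (any(is.na(p0))) fail("params", "p0", "must name every gene (or be a single value)")
  } else {
    p0 <- unlist(p0)
  }

  nz <- raw$noise %||% list()
  noise <- if (!is.null(nz$genes)) {
    tab <- purrr::map_dfr(nz$genes, as_tibble)
    tryCatch(
      {
        tab <- tab[match(topo$gene, tab$gene), ]
        noise_spec(topo,
          dp0 = tab$dp0, dp = tab$dp, dd = tab$dd,
          extrinsic_sigma = tab$extrinsic_sigma
        )
      },
      error = function(e) fail("noise", "genes", conditionMessage(e))
    )
  } else {
    list(rel = nz$rel %||% 0.1, extrinsic_sigma = nz$extrinsic_sigma %||% 10)
  }

  tryCatch(
    run_config(
      topology = topo, scheme = scheme, target = target, p0 = p0,
      noise = noise,
      simulation = raw$simulation %||% list(),
      clustering = raw$clustering %||% list(),
      seed = raw$seed %||% 1
    ),
    error = function(e) fail("(top level)", "", conditionMessage(e))
  )
}
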