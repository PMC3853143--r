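# provenance comment lines prepended to every exported table
provenance_header <- function(config = NULL, seed = NULL, extra = character(0)) {
  lines <- c(
    paste0("# generated-by: kinmotif ",
           as.character(utils::packageVersion("kinmotif"))),
    if (!is.null(config)) paste0("# config-hash: ", rlang::hash(unclass(config))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    extra
  )
  lines
}

write_table_with_header <- function(df, path, header, delim = "\t") {
  writeLines(header, path)
  readr::write_delim(df, path, delim = delim, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' Columns `time` and one concentration column per gene; the abort flag and
#' provenance are recorded as leading `#` comment lines.
#'
#' @param traj A `kin_trajectory`.
#' @param path Output path.
#' @param config Optional `kin_config` recorded in the provenance header.
#' @param seed Optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, config = NULL, seed = NULL) {
  if (!inherits(traj, "kin_trajectory")) abort("Expected a `kin_trajectory`.")
  header <- provenance_header(
    config, seed,
    extra = c(
      paste0("# mode: ", attr(traj, "mode")),
      paste0("# aborted: ", is_aborted(traj)),
      if (is_aborted(traj)) paste0("# abort-time: ", attr(traj, "abort_time"))
    )
  )
  write_table_with_header(as_tibble(traj), path, header, delim = ",")
}

#' Read a trajectory CSV back
#'
#' @param path Path written by [write_trajectory_csv()].
#' @return A `kin_trajectory` tibble (mode/abort attributes restored from the
#'   header comments).
#' @export
read_trajectory_csv <- function(path) {
  headers <- grep("^#", readLines(path, n = 20), value = TRUE)
  pick <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), headers, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1]) else NA_character_
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  structure(
    df,
    class = c("kin_trajectory", class(tibble())),
    mode = pick("mode"),
    aborted = identical(pick("aborted"), "TRUE"),
    abort_time = suppressWarnings(as.integer(pick("abort-time")))
  )
}

#' Export a scan's solution map
#'
#' One row per grid point (`level_string`, `DD`, `DS`, `class`); the quadrant
#' summary is appended as commented footer lines.
#'
#' @param scan A `kin_scan`.
#' @param path Output path.
#' @param config,seed Recorded in the provenance header.
#' @param delim Field delimiter (default tab; use `","` for CSV).
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path, config = NULL, seed = NULL, delim = "\t") {
  if (!inherits(scan, "kin_scan")) abort("Expected a `kin_scan`.")
  header <- provenance_header(config, seed %||% attr(scan, "seed"))
  write_table_with_header(as_tibble(scan), path, header, delim = delim)
  q <- attr(scan, "quadrants")
  footer <- c(
    "# quadrant summary:",
    paste0(
      "#   ", names(q), ": ", q, " (",
      sprintf("%.1f%%", 100 * q / sum(q)), ")"
    )
  )
  cat(footer, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Read a solution map back
#'
#' @param path Path written by [write_scan_tsv()].
#' @param delim Field delimiter.
#' @return A `kin_scan` tibble (quadrant counts recomputed from the rows).
#' @export
read_scan_tsv <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, comment = "#", show_col_types = FALSE)
  need <- c("level_string", "DD", "DS", "class")
  if (!all(need %in% names(df))) {
    abort("Not a solution-map table: expected columns level_string, DD, DS, class.")
  }
  df$level_string <- as.character(df$level_string)
  q <- table(factor(df$class,
    levels = c("both_ok", "det_only", "stoch_only", "both_fail")
  ))
  structure(df,
    class = c("kin_scan", class(tibble())),
    quadrants = c(q)
  )
}

#' Export a handbook table
#'
#' The machine-readable motif handbook: rank, logo (compact and paired
#' forms), member count, mean deviations, score and sub-threshold flag. The
#' `members` list-column is not serialised.
#'
#' @param handbook A `kin_handbook`.
#' @param path Output path.
#' @param config,seed Recorded in the provenance header.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_handbook_tsv <- function(handbook, path, config = NULL, seed = NULL,
                               delim = "\t") {
  if (!inherits(handbook, "kin_handbook")) abort("Expected a `kin_handbook`.")
  write_table_with_header(tidy(handbook), path,
    provenance_header(config, seed),
    delim = delim
  )
}

#' Read a handbook table back
#'
#' @param path Path written by [write_handbook_tsv()].
#' @param delim Field delimiter.
#' @return A `kin_handbook` (without the `members` list-column).
#' @export
read_handbook_tsv <- function(path, delim = "\t") {
  df <- readr::read_delim(path,
    delim = delim, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(logo = readr::col_character())
  )
  need <- c("rank", "logo", "size", "mean_DD", "mean_DS", "score")
  if (!all(need %in% names(df))) {
    abort("Not a handbook table: expected columns rank, logo, size, mean_DD, mean_DS, score.")
  }
  structure(df, class = c("kin_handbook", class(tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
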