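#' Wildcard-aware Hamming distance to a motif logo
#'
#' Counts the non-wildcard logo positions at which the design differs;
#' wildcard (`"*"`) positions accept any level and contribute 0.
#'
#' @param design Integer level sequence (or digit string).
#' @param logo Motif logo: character vector of symbols, or a logo string in
#'   either compact or paired form.
#' @return Integer distance.
#' @examples
#' wildcard_hamming("33514221", "(3,3);(1,1);(*,*);(1,1)")  # 2
#' @export
wildcard_hamming <- function(design, logo) {
  if (is.character(design) && length(design) == 1) design <- parse_levels(design)
  if (length(logo) == 1) logo <- parse_logo(logo)
  logo <- as.character(logo)
  if (length(design) != length(logo)) abort("Design and logo must have equal length.")
  sum(logo != "*" & as.character(design) != logo)
}

#' Nearest handbook motifs to a design
#'
#' Ranks the handbook's motifs by wildcard-aware Hamming distance to the
#' design; ties are broken by better (smaller) handbook rank.
#'
#' @param design Integer level sequence or digit string.
#' @param handbook A `kin_handbook`.
#' @param k Number of motifs to return (default 5; capped at the handbook
#'   size).
#' @return A tibble of the `k` nearest motifs with a `distance` column,
#'   ordered by `(distance, rank)`.
#' @export
nearest_motifs <- function(design, handbook, k = 5) {
  if (!inherits(handbook, "kin_handbook")) abort("Expected a `kin_handbook`.")
  if (nrow(handbook) == 0) abort("Handbook is empty.")
  if (is.character(design) && length(design) == 1) design <- parse_levels(design)
  out <- as_tibble(handbook) |>
    dplyr::mutate(
      distance = purrr::map_int(.data$logo, ~ as.integer(wildcard_hamming(design, .x)))
    ) |>
    dplyr::arrange(.data$distance, .data$rank) |>
    dplyr::select(-dplyr::any_of("members"))
  head(out, min(k, nrow(out)))
}

#' Read a genetic component library
#'
#' A parts table mapping ribosome binding sites (role `RBS`, setting a gene's
#' production efficiency level) and protein degradation tags (role `PDT`,
#' setting its degradation level) to efficiency levels. Format: TSV with
#' columns `part_id`, `role`, `level`, `genes` (comma-separated gene names or
#' `*` for any gene).
#'
#' @param path Path to the TSV file.
#' @return A tibble of class `kin_library`.
#' @export
read_part_library <- function(path) {
  lib <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  part_library(lib)
}

#' @rdname read_part_library
#' @param parts A data frame with columns `part_id`, `role`, `level`,
#'   `genes`.
#' @export
part_library <- function(parts) {
  need <- c("part_id", "role", "level", "genes")
  if (!is.data.frame(parts) || !all(need %in% names(parts))) {
    abort("A part library needs columns part_id, role, level, genes.")
  }
  parts <- as_tibble(parts)
  parts$level <- as.integer(parts$level)
  if (anyDuplicated(parts$part_id)) abort("`part_id` values must be unique.")
  if (!all(parts$role %in% c("RBS", "PDT"))) {
    abort("`role` must be 'RBS' or 'PDT'.")
  }
  structure(parts, class = c("kin_library", class(tibble())))
}

# candidate part ids for (role, level, gene); empty chr if none
library_candidates <- function(library, role, level, gene) {
  if (is.null(library)) return(character(0))
  hits <- library[library$role == role & library$level == level, , drop = FALSE]
  if (nrow(hits) == 0) return(character(0))
  compat <- vapply(hits$genes, function(g) {
    g == "*" || gene %in% trimws(strsplit(g, ",")[[1]])
  }, logical(1))
  hits$part_id[compat]
}

#' Substitution route from a design to a motif
#'
#' One substitution per mismatched non-wildcard position: a production-slot
#' mismatch is fixed by swapping the gene's RBS to a part of the motif's
#' level, a degradation-slot mismatch by swapping its PDT. The number of
#' substitutions therefore equals the wildcard-aware Hamming distance. If a
#' component library is supplied, candidate parts are listed per
#' substitution; a substitution with no available part makes the route
#' unrealizable (flagged, with the missing slots named in attribute
#' `missing_slots`).
#'
#' @param design Integer level sequence or digit string.
#' @param motif A one-row slice of a `kin_handbook`, or a logo string.
#' @param topology Optional `kin_topology` used to name genes in the route
#'   (gene numbers are used otherwise).
#' @param library Optional `kin_library` of parts.
#' @return A tibble of class `kin_route` with one row per substitution:
#'   `position`, `gene`, `role`, `old_level`, `new_level`, `parts`
#'   (list-column of candidate part ids), `realizable`. Attributes:
#'   `motif_logo`, `motif_rank`, `distance`, `realizable`, `missing_slots`,
#'   `symmetry_note`.
#' @examples
#' repair_routes("33514221", "(3,3);(1,1);(*,*);(1,1)")
#' @export
repair_routes <- function(design, motif, topology = NULL, library = NULL) {
  if (is.character(design) && length(design) == 1) design <- parse_levels(design)
  if (is.data.frame(motif)) {
    motif_rank <- motif$rank[1]
    logo <- parse_logo(motif$logo[1])
  } else {
    motif_rank <- NA_integer_
    logo <- if (length(motif) == 1) parse_logo(motif) else as.character(motif)
  }
  if (length(design) != length(logo)) abort("Design and motif must have equal length.")
  gene_names <- if (!is.null(topology)) topology$gene else {
    paste0("gene", seq_len(length(design) / 2))
  }

  mismatch <- which(logo != "*" & as.character(design) != logo)
  rows <- lapply(mismatch, function(pos) {
    g <- ceiling(pos / 2)
    role <- if (pos %% 2 == 1) "RBS" else "PDT"
    new_level <- as.integer(logo[pos])
    cand <- library_candidates(library, role, new_level, gene_names[g])
    tibble(
      position = as.integer(pos), gene = gene_names[g], role = role,
      old_level = as.integer(design[pos]), new_level = new_level,
      parts = list(cand),
      realizable = is.null(library) || length(cand) > 0
    )
  })
  route <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
    position = integer(), gene = character(), role = character(),
    old_level = integer(), new_level = integer(), parts = list(),
    realizable = logical()
  )
  missing_slots <- if (nrow(route)) {
    with(route[!route$realizable, ], paste0(gene, ":", role, ":level", new_level))
  } else character(0)

  # resulting sequence after applying the route
  result <- as.integer(design)
  result[route$position] <- route$new_level

  # advisory note where the modified design breaks p/d level symmetry
  pairs <- matrix(result, nrow = 2)
  asym <- which(pairs[1, ] != pairs[2, ])
  symmetry_note <- if (length(asym)) {
    paste0(
      "Route leaves unmatched production/degradation levels for: ",
      paste(gene_names[asym], collapse = ", "),
      ". Matched levels for the same protein tend to perform best."
    )
  } else {
    "Route preserves production/degradation level symmetry for all genes."
  }

  structure(
    route,
    class = c("kin_route", class(tibble())),
    motif_logo = paste(logo, collapse = ""),
    motif_rank = motif_rank,
    distance = length(mismatch),
    result_levels = result,
    realizable = all(route$realizable),
    missing_slots = missing_slots,
    symmetry_note = symmetry_note
  )
}

#' Improvement routes for an already functional design
#'
#' For a design that matches some handbook motif (wildcard-aware distance 0),
#' lists substitution routes to every motif with a strictly better rank,
#' reachable within `max_distance` substitutions, sorted by `(rank,
#' distance)`. Errors if the design matches no motif — use [repair_routes()]
#' via [nearest_motifs()] in that case.
#'
#' @inheritParams nearest_motifs
#' @param max_distance Maximum number of substitutions per route (default 2).
#' @param topology,library Passed to [repair_routes()].
#' @return A list of `kin_route` objects (possibly empty, when the design is
#'   already in the top-ranked motif or nothing better is reachable).
#' @export
improvement_routes <- function(design, handbook, max_distance = 2,
                               topology = NULL, library = NULL) {
  if (!inherits(handbook, "kin_handbook")) abort("Expected a `kin_handbook`.")
  if (is.character(design) && length(design) == 1) design <- parse_levels(design)
  dists <- vapply(handbook$logo, function(l) wildcard_hamming(design, l),
    numeric(1), USE.NAMES = FALSE
  )
  matches <- which(dists == 0)
  if (!length(matches)) {
    abort(paste0(
      "Design matches no handbook motif; it is not (known to be) functional. ",
      "Use `nearest_motifs()` + `repair_routes()` to repair it."
    ))
  }
  current_rank <- min(handbook$rank[matches])
  better <- which(handbook$rank < current_rank & dists <= max_distance)
  better <- better[order(handbook$rank[better], dists[better])]
  lapply(better, function(i) {
    repair_routes(design, handbook[i, ], topology = topology, library = library)
  })
}

#' @export
print.kin_route <- function(x, ...) {
  cat("<kin_route> to motif ",
    if (!is.na(attr(x, "motif_rank"))) paste0("rank ", attr(x, "motif_rank"), " ") else "",
    attr(x, "motif_logo"),
    " (distance ", attr(x, "distance"), ")\n",
    sep = ""
  )
  if (nrow(x) == 0) {
    cat("  no substitutions needed\n")
  } else {
    for (i in seq_len(nrow(x))) {
      cand <- x$parts[[i]]
      cat(
        "  ", x$gene[i], " ", x$role[i], ": level ", x$old_level[i],
        " -> ", x$new_level[i],
        if (length(cand)) paste0("  [", paste(cand, collapse = ", "), "]") else
          if (!x$realizable[i]) "  [no part available]" else "",
        "\n",
        sep = ""
      )
    }
  }
  cat("  ", attr(x, "symmetry_note"), "\n", sep = "")
  invisible(x)
}
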