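#' Hamming distance between level sequences
#'
#' Number of positions at which two equal-length level sequences differ.
#'
#' @param a,b Integer vectors (or digit strings) of equal length.
#' @return Integer count of differing positions.
#' @examples
#' hamming(c(3, 3, 5, 1, 2, 4, 2, 1), c(3, 3, 1, 1, 2, 4, 1, 1))  # 2
#' @export
hamming <- function(a, b) {
  if (is.character(a)) a <- parse_levels(a)
  if (is.character(b)) b <- parse_levels(b)
  if (length(a) != length(b)) abort("Sequences must have equal length.")
  sum(a != b)
}

# full pairwise Hamming matrix of an n x L integer matrix, accumulated one
# position at a time (no installed distance supports categorical mismatch
# counts directly)
hamming_matrix <- function(m) {
  n <- nrow(m)
  dm <- matrix(0, n, n)
  for (s in seq_len(ncol(m))) {
    dm <- dm + outer(m[, s], m[, s], "!=")
  }
  dm
}

#' Cluster functional level sequences into motifs
#'
#' Agglomerative hierarchical clustering of the functional sequences on their
#' pairwise Hamming distances, with flat clusters obtained by cutting the
#' dendrogram at `cut_height`. Every record is assigned to exactly one
#' cluster.
#'
#' @param records A data frame with a `level_string` column — typically
#'   [functional_records()] of a scan.
#' @param linkage Agglomeration method: `"average"` (default), `"complete"`
#'   or `"single"`.
#' @param cut_height Dendrogram cut height in Hamming units (default 2.5).
#' @return The input tibble with an integer `cluster` column added; the
#'   `hclust` tree is attached as attribute `tree` (NULL for a single
#'   record).
#' @examples
#' recs <- tibble::tibble(level_string = c("11111111", "11111112", "55555555"))
#' table(cluster_functional(recs, cut_height = 2)$cluster)
#' @export
cluster_functional <- function(records, linkage = "average", cut_height = 2.5) {
  if (!is.data.frame(records) || !"level_string" %in% names(records)) {
    abort("`records` must be a data frame with a `level_string` column.")
  }
  if (nrow(records) == 0) abort("No functional records to cluster.")
  records <- as_tibble(records)
  if (nrow(records) == 1) {
    records$cluster <- 1L
    return(structure(records, tree = NULL))
  }
  m <- decode_level_strings(records$level_string)
  dm <- hamming_matrix(m)
  tree <- hclust(as.dist(dm), method = linkage)
  if (is.unsorted(tree$height)) {
    # average-linkage merge heights can show tiny floating-point inversions;
    # enforce monotonicity so the flat cut is well defined
    tree$height <- cummax(tree$height)
  }
  records$cluster <- unname(cutree(tree, h = cut_height))
  structure(records, tree = tree)
}

#' Consensus logo of a motif
#'
#' Per position, the modal level if its share among members reaches
#' `threshold`, otherwise the wildcard `"*"`. Per-position level-frequency
#' vectors are retained as an attribute for rendering.
#'
#' @param members Character vector of member level strings, or an integer
#'   matrix (rows = members).
#' @param threshold Minimum share for a consensus level (default 0.9).
#' @param n_levels Number of levels (default 5).
#' @return Character vector of per-position symbols (`"1"`..`"5"` or `"*"`)
#'   with attribute `freq`, an `n_levels x L` share matrix.
#' @examples
#' consensus_logo(c("11331233", "11334533", "11332133"))
#' @export
consensus_logo <- function(members, threshold = 0.9, n_levels = 5) {
  m <- if (is.character(members)) decode_level_strings(members) else members
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (nrow(m) == 0) abort("`members` must be non-empty.")
  L <- ncol(m)
  freq <- matrix(0, n_levels, L, dimnames = list(seq_len(n_levels), NULL))
  logo <- character(L)
  for (s in seq_len(L)) {
    tab <- tabulate(m[, s], nbins = n_levels) / nrow(m)
    freq[, s] <- tab
    top <- which.max(tab)
    logo[s] <- if (tab[top] >= threshold) as.character(top) else "*"
  }
  structure(logo, freq = freq)
}

#' Format a logo as a paired string
#'
#' @param logo Character vector of per-position symbols.
#' @return The paired form, e.g. `"(3,3);(1,1);(*,*);(1,1)"`.
#' @export
logo_to_paired <- function(logo) {
  pairs <- matrix(as.character(logo), nrow = 2)
  paste0("(", pairs[1, ], ",", pairs[2, ], ")", collapse = ";")
}

#' Parse a motif logo
#'
#' Accepts the compact form (`"3311**11"`) or paired form
#' (`"(3,3);(1,1);(*,*);(1,1)"`).
#'
#' @param x A single logo string.
#' @return Character vector of per-position symbols.
#' @export
parse_logo <- function(x) {
  out <- parse_levels(x)
  as.character(out)
}

#' Build the performance-ranked motif handbook
#'
#' Scores each cluster by the sum of its mean deterministic and mean
#' stochastic deviations (`mean_DD + mean_DS`); rank 1 is the
#' best-performing (lowest) score. Ties are broken by larger size, then by
#' logo string. Clusters smaller than `min_size` are retained but flagged as
#' sub-threshold.
#'
#' @param clustered Output of [cluster_functional()] (needs columns
#'   `level_string`, `DD`, `DS`, `cluster`).
#' @param min_size Member-count cut below which a motif is flagged
#'   (default 10).
#' @param threshold Consensus share for logo positions (default 0.9).
#' @param n_levels Number of levels (default 5).
#' @param provenance Optional list recorded as an attribute (seed, config
#'   hash, ...).
#' @return A tibble of class `kin_handbook` with columns `rank`, `logo`,
#'   `logo_paired`, `size`, `mean_DD`, `mean_DS`, `score`, `sub_threshold`
#'   and a `members` list-column; dendrogram (if any) in attribute `tree`.
#' @examples
#' recs <- tibble::tibble(
#'   level_string = c("11111111", "11111111", "33333333"),
#'   DD = c(8, 8.2, 6), DS = c(8.1, 8.3, 6.2)
#' )
#' rank_handbook(cluster_functional(recs), min_size = 2)
#' @export
rank_handbook <- function(clustered, min_size = 10, threshold = 0.9,
                          n_levels = 5, provenance = list()) {
  need <- c("level_string", "DD", "DS", "cluster")
  if (!all(need %in% names(clustered))) {
    abort("`clustered` must have columns level_string, DD, DS, cluster (see `cluster_functional()`).")
  }
  hb <- clustered |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      size = dplyr::n(),
      mean_DD = mean(.data$DD),
      mean_DS = mean(.data$DS),
      members = list(.data$level_string),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      score = .data$mean_DD + .data$mean_DS,
      logo = purrr::map_chr(
        .data$members,
        ~ paste(consensus_logo(.x, threshold = threshold, n_levels = n_levels),
          collapse = ""
        )
      ),
      logo_paired = purrr::map_chr(
        .data$members,
        ~ logo_to_paired(consensus_logo(.x, threshold = threshold, n_levels = n_levels))
      ),
      sub_threshold = .data$size < min_size
    ) |>
    dplyr::arrange(.data$score, dplyr::desc(.data$size), .data$logo) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(
      "rank", "logo", "logo_paired", "size", "mean_DD", "mean_DS",
      "score", "sub_threshold", "members"
    )
  structure(
    hb,
    class = c("kin_handbook", class(tibble())),
    tree = attr(clustered, "tree"),
    min_size = min_size, threshold = threshold,
    provenance = provenance
  )
}

#' Tidy a handbook
#'
#' @param x A `kin_handbook`.
#' @param ... Unused.
#' @return The motif table without the `members` list-column.
#' @method tidy kin_handbook
#' @export
tidy.kin_handbook <- function(x, ...) {
  dplyr::select(as_tibble(x), -"members")
}

#' Handbook summary
#'
#' @param x A `kin_handbook`.
#' @param ... Unused.
#' @return One-row tibble: motif count, members total, count passing the
#'   size cut, best score.
#' @method glance kin_handbook
#' @export
glance.kin_handbook <- function(x, ...) {
  tibble(
    n_motifs = nrow(x),
    n_members = sum(x$size),
    n_above_min_size = sum(!x$sub_threshold),
    best_score = if (nrow(x)) min(x$score) else NA_real_
  )
}

#' Export a handbook dendrogram in Newick format
#'
#' @param handbook A `kin_handbook` built from more than one record.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(handbook, path) {
  tree <- attr(handbook, "tree")
  if (is.null(tree)) {
    abort("Handbook has no dendrogram (built from a single record).")
  }
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
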