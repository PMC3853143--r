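#' Define a gene-circuit topology
#'
#' A topology is an ordered table of genes, each transcriptionally repressed by
#' at most one other gene in the same circuit. Repression acts through a Hill
#' function \eqn{r(x) = 1/(1 + (x/K)^n)} of the repressor concentration
#' \eqn{x}; a gene with no repressor has \eqn{r = 1} (fully active promoter).
#'
#' @param genes A data frame with one row per gene and columns:
#'   \describe{
#'     \item{gene}{character, unique gene/protein name.}
#'     \item{repressor}{character, name of the repressing gene, or `NA` for an
#'       unregulated gene.}
#'     \item{hill_K}{numeric, Hill constant in nM (default 1000 if absent).}
#'     \item{hill_n}{numeric, Hill coefficient (default 2 if absent).}
#'   }
#'
#' @return A tibble of class `kin_topology` with columns `gene`, `repressor`,
#'   `hill_K`, `hill_n`, in circuit order.
#'
#' @examples
#' circuit_topology(data.frame(
#'   gene = c("A", "B"), repressor = c(NA, "A")
#' ))
#' @export
circuit_topology <- function(genes) {
  if (!is.data.frame(genes) || nrow(genes) == 0) {
    abort("`genes` must be a data frame with at least one row.")
  }
  genes <- as_tibble(genes)
  if (!all(c("gene", "repressor") %in% names(genes))) {
    abort("`genes` must have columns `gene` and `repressor`.")
  }
  if (!("hill_K" %in% names(genes))) genes$hill_K <- 1000
  if (!("hill_n" %in% names(genes))) genes$hill_n <- 2
  genes <- genes[, c("gene", "repressor", "hill_K", "hill_n")]
  genes$gene <- as.character(genes$gene)
  genes$repressor <- as.character(genes$repressor)
  genes$hill_K <- as.numeric(genes$hill_K)
  genes$hill_n <- as.numeric(genes$hill_n)

  if (anyDuplicated(genes$gene)) {
    abort("Gene names must be unique.")
  }
  has_rep <- !is.na(genes$repressor)
  unresolved <- setdiff(genes$repressor[has_rep], genes$gene)
  if (length(unresolved)) {
    abort(paste0(
      "Repressor(s) not defined in the topology: ",
      paste(unresolved, collapse = ", ")
    ))
  }
  if (any(!is.finite(genes$hill_K)) || any(genes$hill_K <= 0)) {
    abort("`hill_K` must be positive and finite for every gene.")
  }
  if (any(!is.finite(genes$hill_n)) || any(genes$hill_n <= 0)) {
    abort("`hill_n` must be positive and finite for every gene.")
  }
  structure(genes, class = c("kin_topology", class(genes)))
}

#' The four-gene repression cascade demo circuit
#'
#' The TetR -| LacI -| CI -| Eyfp transcriptional repression cascade built in
#' *E. coli*, with all Hill constants at 1000 nM and Hill coefficient 2. By
#' default TetR is unregulated (open cascade); `looped = TRUE` closes the loop
#' by letting Eyfp repress TetR.
#'
#' @param looped Logical; if `TRUE`, Eyfp represses TetR.
#' @return A `kin_topology` tibble with genes TetR, LacI, CI, Eyfp.
#' @examples
#' cascade_demo()
#' @export
cascade_demo <- function(looped = FALSE) {
  circuit_topology(tibble(
    gene      = c("TetR", "LacI", "CI", "Eyfp"),
    repressor = c(if (looped) "Eyfp" else NA_character_, "TetR", "LacI", "CI"),
    hill_K    = 1000,
    hill_n    = 2
  ))
}

n_genes <- function(topology) nrow(topology)

# integer index of each gene's repressor (NA when unregulated)
repressor_index <- function(topology) {
  match(topology$repressor, topology$gene)
}

assert_topology <- function(topology) {
  if (!inherits(topology, "kin_topology")) {
    abort("Expected a `kin_topology` object; see `circuit_topology()`.")
  }
  invisible(topology)
}
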