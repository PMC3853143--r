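# shared fixtures built in code

# single unregulated gene
one_gene_topo <- function() {
  circuit_topology(data.frame(gene = "A", repressor = NA))
}

# A -| B open two-gene cascade
two_gene_topo <- function() {
  circuit_topology(data.frame(gene = c("A", "B"), repressor = c(NA, "A")))
}

# reduced demo config for fast pipeline runs
small_demo <- function(n_levels = 2, ...) demo_config(n_levels = n_levels, ...)

# random kinetic parameters for an open cascade, guaranteed to converge
# comfortably within T steps (d not too small) and stay far below the ceiling
random_params <- function(topology, rng = NULL) {
  G <- nrow(topology)
  kinetic_params(
    topology,
    p0 = runif(G, 0, 5),
    p = runif(G, 10, 2000),
    d = runif(G, 0.05, 0.3)
  )
}

# independent brute-force wildcard distance used against the advisor
brute_wildcard_distance <- function(design, logo) {
  n <- 0L
  for (i in seq_along(logo)) {
    if (logo[i] != "*" && as.character(design[i]) != logo[i]) n <- n + 1L
  }
  n
}

# toy handbook built directly from member blocks (bypasses clustering)
toy_handbook <- function(blocks, DDs, DSs, min_size = 1) {
  recs <- tibble::tibble(
    level_string = unlist(blocks),
    DD = rep(DDs, lengths(blocks)),
    DS = rep(DSs, lengths(blocks)),
    cluster = rep(seq_along(blocks), lengths(blocks))
  )
  rank_handbook(recs, min_size = min_size)
}
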