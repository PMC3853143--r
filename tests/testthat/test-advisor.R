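# the worked repair example: a non-functional design two substitutions away
# from two different functional motifs
scenario_design <- "(3,3);(5,1);(2,4);(2,1)"
motif_47_logo <- "(3,3);(1,1);(*,*);(1,1)"
motif_12_logo <- "(3,3);(5,5);(*,*);(2,2)"

# members identical except at the CI positions (5-6), which spread uniformly
# over all levels so the consensus logo carries wildcards there
varied_block <- function(prefix, suffix) {
  paste0(prefix, c("11", "22", "33", "44", "55"), suffix)
}

# handbook holding the two published motifs plus decoys at larger distance
scenario_handbook <- function() {
  toy_handbook(
    blocks = list(
      varied_block("3355", "33"),  # rank 1 decoy "3355**33", distance 3
      varied_block("3355", "22"),  # motif No. 12 analogue "3355**22"
      varied_block("3311", "11"),  # motif No. 47 analogue "3311**11"
      varied_block("1111", "11")   # bottom decoy, distance 4
    ),
    DDs = c(3.0, 4.0, 7.0, 8.0),
    DSs = c(3.0, 4.2, 7.2, 8.0)
  )
}

test_that("wildcard positions contribute nothing to the design-motif distance", {
  expect_identical(wildcard_hamming(scenario_design, motif_47_logo), 2L)
  expect_identical(wildcard_hamming(scenario_design, motif_12_logo), 2L)
  expect_identical(wildcard_hamming("33514221", "********"), 0L)
  expect_identical(wildcard_hamming("33514221", "33514221"), 0L)
  expect_error(wildcard_hamming("123", "12"), "equal length")
})

test_that("wildcard_hamming equals plain hamming restricted to non-wildcard positions", {
  set.seed(21)
  for (i in 1:40) {
    design <- sample(5, 8, replace = TRUE)
    logo <- as.character(sample(5, 8, replace = TRUE))
    logo[sample(8, sample(0:4, 1))] <- "*"
    keep <- logo != "*"
    expected <- if (any(keep)) {
      hamming(design[keep], as.integer(logo[keep]))
    } else 0L
    expect_identical(wildcard_hamming(design, logo), expected)
    expect_identical(brute_wildcard_distance(design, logo), as.integer(expected))
  }
})

test_that("nearest_motifs finds both published motifs at distance 2, ordered by rank", {
  hb <- scenario_handbook()
  near <- nearest_motifs(parse_levels(scenario_design), hb, k = 4)
  expect_identical(near$distance, c(2L, 2L, 3L, 4L))
  expect_identical(near$logo[1:2], c("3355**22", "3311**11"))
  expect_lt(near$rank[1], near$rank[2])  # distance tie broken by better rank
  # exact member of a motif: that motif first at distance 0
  near0 <- nearest_motifs("33552222", hb, k = 1)
  expect_identical(near0$distance, 0L)
  expect_identical(near0$logo, "3355**22")
  # k larger than the handbook returns everything, ordered
  expect_identical(nrow(nearest_motifs("11111111", hb, k = 50)), 4L)
})

test_that("repair routes reproduce the two published substitution paths", {
  topo <- cascade_demo()
  lib <- read_part_library(
    system.file("extdata", "parts_demo.tsv", package = "kinmotif")
  )
  # RBS route: production of genes 2 and 4 down to level 1
  r47 <- repair_routes(scenario_design, motif_47_logo, topology = topo, library = lib)
  expect_identical(nrow(r47), 2L)
  expect_identical(attr(r47, "distance"), 2L)
  expect_identical(r47$gene, c("LacI", "Eyfp"))
  expect_identical(r47$role, c("RBS", "RBS"))
  expect_identical(r47$new_level, c(1L, 1L))
  expect_true(all(c("R1") %in% unlist(r47$parts)))
  # PDT route: degradation of gene 2 to level 5 and gene 4 to level 2
  r12 <- repair_routes(scenario_design, motif_12_logo, topology = topo, library = lib)
  expect_identical(r12$gene, c("LacI", "Eyfp"))
  expect_identical(r12$role, c("PDT", "PDT"))
  expect_identical(r12$new_level, c(5L, 2L))
  # applying either route lands exactly on its motif
  for (r in list(r47, r12)) {
    expect_identical(
      wildcard_hamming(attr(r, "result_levels"), attr(r, "motif_logo")), 0L
    )
  }
})

test_that("routes are sound and minimal on random design/motif pairs", {
  set.seed(8)
  for (i in 1:30) {
    design <- sample(5, 8, replace = TRUE)
    logo <- as.character(sample(5, 8, replace = TRUE))
    logo[sample(8, sample(0:5, 1))] <- "*"
    r <- repair_routes(design, paste(logo, collapse = ""))
    expect_identical(nrow(r), as.integer(wildcard_hamming(design, logo)))
    expect_identical(
      wildcard_hamming(attr(r, "result_levels"), logo), 0L
    )
    # production slots are odd positions (RBS), degradation even (PDT)
    expect_true(all(r$role[r$position %% 2 == 1] == "RBS"))
    expect_true(all(r$role[r$position %% 2 == 0] == "PDT"))
  }
})

test_that("a design already matching the motif needs no substitutions", {
  r <- repair_routes("33511121", "(3,3);(5,1);(*,*);(2,1)")
  expect_identical(nrow(r), 0L)
  expect_identical(attr(r, "distance"), 0L)
})

test_that("missing library parts flag the route unrealizable and name the slot", {
  lib <- part_library(tibble::tibble(
    part_id = c("R2", "T3"), role = c("RBS", "PDT"),
    level = c(2L, 3L), genes = "*"
  ))
  r <- repair_routes("11111111", "21311111",
    topology = cascade_demo(), library = lib
  )
  # position 1 -> RBS level 2 (available), position 3 -> RBS level 3 (missing)
  expect_identical(r$realizable, c(TRUE, FALSE))
  expect_false(attr(r, "realizable"))
  expect_match(attr(r, "missing_slots"), "LacI:RBS:level3")
})

test_that("gene-restricted parts only serve their genes", {
  lib <- part_library(tibble::tibble(
    part_id = c("Ra", "Rb"), role = "RBS", level = 2L,
    genes = c("TetR", "LacI,CI")
  ))
  r <- repair_routes("11111111", "21211111", topology = cascade_demo(), library = lib)
  expect_identical(r$parts[[1]], "Ra")  # TetR slot
  expect_identical(r$parts[[2]], "Rb")  # LacI slot
})

test_that("improvement routes lead only to strictly better-ranked motifs", {
  hb <- toy_handbook(
    blocks = list(
      varied_block("5555", "55"),  # rank 1, far away
      varied_block("1122", "11"),  # rank 2, two substitutions from the design
      varied_block("1111", "11")   # rank 3, holds the design
    ),
    DDs = c(3, 5, 7), DSs = c(3, 5, 7)
  )
  routes <- improvement_routes("11111111", hb, max_distance = 2)
  expect_identical(length(routes), 1L)
  expect_identical(attr(routes[[1]], "motif_logo"), "1122**11")
  expect_identical(attr(routes[[1]], "motif_rank"), 2L)
  expect_identical(attr(routes[[1]], "distance"), 2L)
  # the route's substitutions land the design exactly on the better motif
  expect_identical(
    wildcard_hamming(attr(routes[[1]], "result_levels"), "1122**11"), 0L
  )
  # design in the rank-1 motif: nothing better exists
  expect_identical(improvement_routes("55551155", hb, max_distance = 8), list())
  # max_distance 0: only better motifs the design already matches (none)
  expect_identical(improvement_routes("11111111", hb, max_distance = 0), list())
  # non-matching design is routed to repair instead
  expect_error(improvement_routes("44444444", hb), "repair")
})

test_that("routes note broken production/degradation symmetry", {
  # repairing to (5,1) for gene 2 leaves an asymmetric pair -> advisory note
  r <- repair_routes("33112221", "(3,3);(5,1);(*,*);(2,1)")
  expect_match(attr(r, "symmetry_note"), "unmatched")
  r_sym <- repair_routes("33112221", "(3,3);(1,1);(*,*);(2,2)")
  expect_match(attr(r_sym, "symmetry_note"), "preserves")
})
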