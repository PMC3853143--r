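demo_yaml <- function() {
  system.file("extdata", "demo_config.yaml", package = "kinmotif")
}

test_that("the shipped YAML config reproduces the in-code demo fixture", {
  cfg_file <- read_run_config(demo_yaml())
  cfg_code <- demo_config()
  expect_identical(as.data.frame(cfg_file$topology), as.data.frame(cfg_code$topology))
  expect_identical(as.data.frame(cfg_file$scheme), as.data.frame(cfg_code$scheme))
  expect_identical(cfg_file$target, cfg_code$target)
  expect_identical(cfg_file$p0, cfg_code$p0)
  expect_identical(cfg_file$noise, cfg_code$noise)
  expect_identical(cfg_file$simulation, cfg_code$simulation)
  # constants of the demo: z, T, ceiling, tolerance, sentinel
  expect_identical(unname(cfg_file$target$z), c(1000, 30000, 300, 30000))
  expect_identical(cfg_file$simulation$T, 100L)
  expect_identical(cfg_file$simulation$abort_ceiling, 1e6)
  expect_identical(cfg_file$target$tolerance, 0.2)
  expect_identical(cfg_file$target$sentinel, 15)
})

test_that("JSON configs parse like YAML ones", {
  raw <- yaml::read_yaml(demo_yaml())
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- read_run_config(path)
  expect_identical(cfg$target, demo_config()$target)
  expect_identical(as.data.frame(cfg$scheme), as.data.frame(demo_config()$scheme))
})

test_that("malformed configs fail with a diagnostic naming the section", {
  raw <- yaml::read_yaml(demo_yaml())
  broken <- raw
  broken$target$z <- NULL
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(broken, path)
  expect_error(read_run_config(path), "target")
  broken2 <- raw
  broken2$levels$production$NoSuchGene <- c(0, 1)
  yaml::write_yaml(broken2, path)
  expect_error(read_run_config(path), "NoSuchGene")
  expect_error(read_run_config("/nonexistent/path.yaml"), "not found")
})

test_that("run_simulate writes a 101-row trajectory CSV that round-trips", {
  cfg <- demo_config()
  out <- withr::local_tempfile(fileext = ".csv")
  tr <- run_simulate(cfg, levels = rep(3, 8), out = out)
  df <- read_trajectory_csv(out)
  expect_identical(nrow(df), 101L)
  expect_identical(names(df), c("time", "TetR", "LacI", "CI", "Eyfp"))
  expect_equal(as.matrix(df), as.matrix(tr))
  expect_false(is_aborted(df))
})

test_that("run_simulate validates the level string length", {
  cfg <- demo_config()
  expect_error(run_simulate(cfg, levels = "3351"), "expected 8")
  expect_error(run_simulate(cfg), "exactly one")
  expect_error(
    run_simulate(cfg, levels = rep(3, 8), params = kinetic_params(
      cfg$topology, p = 1, d = 0.1
    )),
    "exactly one"
  )
})

test_that("stochastic trajectories with a fixed seed are file-identical across runs", {
  cfg <- demo_config()
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  run_simulate(cfg, levels = rep(2, 8), mode = "stochastic", out = out1, seed = 99)
  run_simulate(cfg, levels = rep(2, 8), mode = "stochastic", out = out2, seed = 99)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("run_scan writes the solution map with a quadrant footer and round-trips", {
  cfg <- small_demo()
  dir <- withr::local_tempdir()
  sc <- run_scan(cfg, out_dir = dir)
  path <- file.path(dir, "solution_map.tsv")
  expect_true(file.exists(path))
  lines <- readLines(path)
  expect_true(any(grepl("^# quadrant summary:", lines)))
  back <- read_scan_tsv(path)
  expect_identical(nrow(back), 256L)
  expect_equal(back$DD, sc$DD)
  expect_identical(attr(back, "quadrants"), attr(sc, "quadrants"))
})

test_that("repeated scans with one seed produce byte-identical tables", {
  cfg <- small_demo()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_scan(cfg, out_dir = d1, seed = 7)
  run_scan(cfg, out_dir = d2, seed = 7)
  expect_identical(
    readLines(file.path(d1, "solution_map.tsv")),
    readLines(file.path(d2, "solution_map.tsv"))
  )
})

test_that("run_handbook clusters a scan file into a handbook whose sizes partition the functional set", {
  cfg <- small_demo()
  dir <- withr::local_tempdir()
  run_scan(cfg, out_dir = dir)
  hb_path <- file.path(dir, "handbook.tsv")
  nwk_path <- file.path(dir, "dendrogram.nwk")
  hb <- run_handbook(file.path(dir, "solution_map.tsv"), cfg,
    out = hb_path, newick_out = nwk_path
  )
  expect_true(file.exists(hb_path))
  n_fun <- nrow(functional_records(read_scan_tsv(file.path(dir, "solution_map.tsv"))))
  expect_gt(n_fun, 0)
  expect_identical(sum(hb$size), n_fun)
  back <- read_handbook_tsv(hb_path)
  expect_identical(nrow(back), nrow(hb))
  expect_equal(back$score, hb$score)
  expect_true(file.exists(nwk_path))
})

test_that("a scan with no functional records yields a warned, empty handbook file", {
  cfg <- small_demo()
  sc <- scan_grid(cfg)
  sc$class <- "both_fail"  # simulate a hopeless target
  out <- withr::local_tempfile(fileext = ".tsv")
  expect_warning(hb <- run_handbook(sc, cfg, out = out), "no functional")
  expect_identical(nrow(hb), 0L)
  lines <- readLines(out)
  expect_true(any(grepl("^rank\\t", lines)))  # header present
})

test_that("run_advise reports repair routes from a handbook file", {
  hb <- toy_handbook(
    blocks = list(
      paste0("3311", c("11", "22", "33", "44", "55"), "11"),
      paste0("3355", c("11", "22", "33", "44", "55"), "22")
    ),
    DDs = c(7, 4), DSs = c(7, 4)
  )
  hb_path <- withr::local_tempfile(fileext = ".tsv")
  write_handbook_tsv(hb, hb_path)
  out <- withr::local_tempfile(fileext = ".tsv")
  res <- run_advise(hb_path, "33514221",
    mode = "repair",
    library = system.file("extdata", "parts_demo.tsv", package = "kinmotif"),
    k = 2, out = out, quiet = TRUE
  )
  expect_identical(nrow(res$nearest), 2L)
  expect_identical(res$nearest$distance, c(2L, 2L))
  expect_identical(length(res$routes), 2L)
  routes_tab <- readr::read_tsv(out, comment = "#", show_col_types = FALSE)
  expect_identical(nrow(routes_tab), 4L)  # two routes x two substitutions
  # malformed design string
  expect_error(run_advise(hb, "3351", quiet = TRUE), "expected 8")
})

test_that("improve mode reports when nothing better is reachable", {
  hb <- toy_handbook(
    blocks = list(paste0("3311", c("11", "22", "33", "44", "55"), "11")),
    DDs = 5, DSs = 5
  )
  res <- run_advise(hb, "33112211", mode = "improve", quiet = TRUE)
  expect_identical(res$routes, list())
})

test_that("the command-line wrapper runs the pipeline end to end", {
  cli <- system.file("cli", "kinmotif.R", package = "kinmotif")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- system2("Rscript",
    c(cli, "simulate",
      "--config", demo_yaml(), "--levels", "33333333",
      "--mode", "deterministic", "--out", file.path(dir, "traj.csv")
    ),
    env = env, stdout = TRUE, stderr = TRUE
  )
  expect_identical(attr(out, "status"), NULL)  # exit 0
  expect_true(file.exists(file.path(dir, "traj.csv")))
  # config error path: nonzero exit with a message
  bad <- suppressWarnings(system2("Rscript",
    c(cli, "simulate", "--config", "/no/such.yaml",
      "--levels", "33333333", "--out", file.path(dir, "x.csv")
    ),
    env = env, stdout = TRUE, stderr = TRUE
  ))
  expect_identical(attr(bad, "status"), 1L)
})
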