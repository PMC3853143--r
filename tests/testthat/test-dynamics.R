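test_that("hill_repression matches the closed form and rejects bad domains", {
  expect_identical(hill_repression(0, 1000, 2), 1)
  expect_identical(hill_repression(1000, 1000, 2), 0.5)
  expect_equal(hill_repression(30000, 1000, 2), 1 / 901)
  expect_error(hill_repression(-1), "finite and >= 0")
  expect_error(hill_repression(1, K = 0), "`K`")
  expect_error(hill_repression(1, n = -2), "`n`")
})

test_that("hill_repression is strictly decreasing in x and increasing in K", {
  x <- sort(runif(50, 1, 1e5))
  r <- hill_repression(x, K = 500, n = 2)
  expect_true(all(diff(r) < 0))
  K <- sort(runif(50, 1, 1e4))
  rk <- vapply(K, function(k) hill_repression(700, K = k, n = 2), numeric(1))
  expect_true(all(diff(rk) > 0))
})

test_that("deterministic_rate implements p0 + p*r - d*x", {
  topo <- two_gene_topo()
  pars <- kinetic_params(topo, p0 = 0, p = 100, d = 0.1)
  # B's repressor A is at 1000 = K, so r_B = 0.5: 100*0.5 - 0.1*500 = 0
  rate <- deterministic_rate(c(1000, 500), pars, topo)
  expect_equal(rate[2], 0)
  # all-zero state: rate = p0 + p for every gene
  pars2 <- kinetic_params(topo, p0 = c(1, 2), p = c(100, 200), d = 0.1)
  expect_equal(deterministic_rate(c(0, 0), pars2, topo), c(101, 202))
  expect_error(deterministic_rate(c(1, 2, 3), pars, topo), "length")
})

test_that("the rate vanishes at the analytic fixed point", {
  set.seed(42)
  for (i in 1:10) {
    topo <- cascade_demo()
    pars <- random_params(topo)
    fp <- fixed_point(pars, topo)
    expect_equal(deterministic_rate(fp, pars, topo), rep(0, 4),
      tolerance = 1e-12, ignore_attr = TRUE
    )
  }
})

test_that("stochastic_rate reduces to the deterministic rate at zero noise and is seed-reproducible", {
  topo <- cascade_demo()
  pars <- random_params(topo)
  quiet <- noise_spec(topo)
  st <- c(100, 5000, 40, 8000)
  set.seed(7)
  expect_identical(
    stochastic_rate(st, pars, topo, quiet),
    deterministic_rate(st, pars, topo)
  )
  loud <- noise_spec(topo, dp0 = 1, dp = 5, dd = 0.01, extrinsic_sigma = 10)
  set.seed(123)
  a <- stochastic_rate(st, pars, topo, loud)
  set.seed(123)
  b <- stochastic_rate(st, pars, topo, loud)
  expect_identical(a, b)
})

test_that("stochastic_rate is unbiased: large-sample mean approaches the deterministic rate", {
  topo <- one_gene_topo()
  pars <- kinetic_params(topo, p0 = 5, p = 100, d = 0.1)
  noise <- noise_spec(topo, dp0 = 0.5, dp = 10, dd = 0.01, extrinsic_sigma = 10)
  st <- 400
  set.seed(99)
  draws <- replicate(1e5, stochastic_rate(st, pars, topo, noise))
  det <- deterministic_rate(st, pars, topo)
  # noise sd per draw ~ sqrt((0.5+10*1-0.01*400)^2 + 100) ~ 12 -> se ~ 0.04
  expect_lt(abs(mean(draws) - det), 0.2)
})

test_that("simulate_circuit holds a fixed point and reports steady state", {
  topo <- one_gene_topo()
  pars <- kinetic_params(topo, p0 = 0, p = 100, d = 0.1)
  tr <- simulate_circuit(topo, pars, x0 = 1000, T = 20)
  expect_false(is_aborted(tr))
  expect_equal(nrow(tr), 21)
  expect_true(all(abs(tr$A - 1000) < 1e-9))
  expect_equal(unname(steady_state(tr)), 1000)
})

test_that("runaway production trips the abort ceiling", {
  topo <- one_gene_topo()
  pars <- kinetic_params(topo, p0 = 0, p = 2e5, d = 0.1)  # fixed point 2e6
  tr <- simulate_circuit(topo, pars, x0 = 0, T = 100, abort_ceiling = 1e6)
  expect_true(is_aborted(tr))
  expect_true(attr(tr, "abort_time") <= 100)
  expect_error(steady_state(tr), "aborted")
})

test_that("simulated steady states agree with the analytic fixed point within 1%", {
  set.seed(2024)
  for (i in 1:15) {
    topo <- cascade_demo()
    pars <- random_params(topo)
    fp <- fixed_point(pars, topo)
    tr <- simulate_circuit(topo, pars, x0 = fp * runif(4, 0.5, 1.5), T = 400)
    expect_false(is_aborted(tr))
    conc <- as.matrix(tr[, -1])
    last10 <- conc[nrow(conc) - 0:9, , drop = FALSE]
    drift <- apply(last10, 2, function(x) diff(range(x)) / max(mean(x), 1e-9))
    if (all(drift < 1e-3)) {  # converged per the documented criterion
      ss <- steady_state(tr)
      expect_true(all(abs(ss - fp) <= 0.01 * pmax(fp, 1e-12)))
    }
  }
})

test_that("recorded concentrations are never negative, in either mode", {
  topo <- cascade_demo()
  pars <- kinetic_params(topo, p0 = 0, p = c(5, 5, 5, 5), d = 0.9)
  noise <- noise_spec(topo, dp0 = 5, dp = 5, dd = 0.2, extrinsic_sigma = 50)
  det <- simulate_circuit(topo, pars, x0 = c(10, 0, 5, 0), T = 50)
  sto <- simulate_circuit(topo, pars,
    x0 = c(10, 0, 5, 0), T = 50,
    mode = "stochastic", noise = noise, seed = 5
  )
  expect_true(all(as.matrix(det[, -1]) >= 0))
  expect_true(all(as.matrix(sto[, -1]) >= 0))
})

test_that("zero-noise stochastic trajectories are bit-identical to deterministic ones", {
  topo <- cascade_demo()
  pars <- random_params(topo)
  quiet <- noise_spec(topo)
  det <- simulate_circuit(topo, pars, x0 = c(1, 10, 100, 1000), T = 60)
  sto <- simulate_circuit(topo, pars,
    x0 = c(1, 10, 100, 1000), T = 60,
    mode = "stochastic", noise = quiet, seed = 11
  )
  expect_identical(as.matrix(det), as.matrix(sto))
})

test_that("odd T uses the last ceiling(T/2) steps for the steady state", {
  topo <- one_gene_topo()
  pars <- kinetic_params(topo, p0 = 0, p = 100, d = 0.1)
  tr <- simulate_circuit(topo, pars, x0 = 1000, T = 5)
  # constant trajectory: mean over any window is 1000; check window length
  # via a hand-built trajectory with known values
  fake <- tr
  fake$A <- c(0, 10, 20, 30, 40, 50)  # steps 1..5 recorded
  # last ceiling(5/2) = 3 recorded steps are 30, 40, 50
  expect_equal(unname(steady_state(fake)), 40)
})

test_that("looped wiring resolves and the fixed-point solver refuses cycles", {
  topo <- cascade_demo(looped = TRUE)
  expect_identical(topo$repressor[1], "Eyfp")
  pars <- kinetic_params(topo, p0 = 0, p = 100, d = 0.1)
  expect_error(fixed_point(pars, topo), "feedback loop")
  tr <- simulate_circuit(topo, pars, x0 = rep(0, 4), T = 30)
  expect_false(is_aborted(tr))
})

test_that("topology validation catches bad wiring", {
  expect_error(
    circuit_topology(data.frame(gene = c("A", "A"), repressor = NA)),
    "unique"
  )
  expect_error(
    circuit_topology(data.frame(gene = "A", repressor = "Z")),
    "not defined"
  )
  expect_error(
    circuit_topology(data.frame(gene = "A", repressor = NA, hill_K = -1)),
    "hill_K"
  )
})
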