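test_that("state enumeration matches the combinatorics of the topology", {
  expect_equal(nrow(enumerate_states(circuit_spec())), 4L)
  expect_equal(nrow(enumerate_states(circuit_spec(include_noncognate = TRUE))), 6L)
  expect_equal(nrow(enumerate_states(circuit_spec(n_binding_sites = 5))), 12L)
  # (N_B+1)(N_B+2)/2 * (N_A+1) with mixed occupancies
  expect_equal(nrow(enumerate_states(
    circuit_spec(n_binding_sites = 3, n_activation_steps = 2,
                 include_noncognate = TRUE))), 10 * 3)
  st <- enumerate_states(circuit_spec())
  expect_equal(st$label, c("c0w0m0", "c1w0m0", "c0w0m1", "c1w0m1"))
  expect_equal(st$on, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("four-state rates follow the labeled reaction scheme", {
  m <- build_rate_matrix(circuit_spec(), rate_params(), concentrations())
  off <- m$Q; diag(off) <- 0
  expect_equal(sort(off[off > 0]), rep(1, 8))       # all eight rates equal 1
  expect_equal(unname(rowSums(m$Q)), rep(0, 4))
  # eta_ab only boosts bound-state activation
  m2 <- build_rate_matrix(circuit_spec(), rate_params(eta_ab = 2),
                          concentrations())
  d <- m2$Q - m$Q
  diag(d) <- 0
  expect_equal(d[2, 4], 1)          # bound OFF -> bound ON doubled
  expect_equal(sum(d != 0), 1L)
  # concentration enters binding edges only
  m3 <- build_rate_matrix(circuit_spec(), rate_params(), concentrations(c = 3))
  expect_equal(m3$Q[1, 2], 3)
  expect_equal(m3$Q[3, 4], 3)
  expect_equal(m3$Q[2, 1], 1)
})

test_that("general builder is edge-for-edge identical to the hand-coded four-state circuit", {
  set.seed(101)
  for (i in 1:20) {
    p <- rand_params()
    cc <- concentrations(c = 10^runif(1, -1, 1))
    mg <- build_rate_matrix(circuit_spec(), p, cc)
    mh <- four_state_matrix(p, cc)
    expect_equal(mg$Q, mh$Q, tolerance = 1e-14)
  }
})

test_that("six-state model reduces to the four-state one at w = 0", {
  set.seed(7)
  p <- rand_params()
  m6 <- build_rate_matrix(circuit_spec(include_noncognate = TRUE), p,
                          concentrations(c = 1.3, w = 0))
  m4 <- build_rate_matrix(circuit_spec(), p, concentrations(c = 1.3))
  pi6 <- stationary_distribution(m6)
  pi4 <- stationary_distribution(m4)
  cog <- m6$states$n_w == 0
  expect_equal(sum(pi6[!cog]), 0)
  expect_equal(pi6[cog], pi4, tolerance = 1e-12)
  expect_equal(burst_cycle_time(m6, pi6), burst_cycle_time(m4, pi4),
               tolerance = 1e-12)
})

test_that("six-state model is symmetric under swapping cognate and noncognate labels when alpha = 1", {
  set.seed(13)
  spec <- circuit_spec(include_noncognate = TRUE, affinity_factor = 1)
  p <- rand_params()
  cc <- 10^runif(1, -0.5, 0.5)
  m <- build_rate_matrix(spec, p, concentrations(c = cc, w = cc))
  pi <- stationary_distribution(m)
  st <- m$states
  swap <- match(sprintf("c%dw%dm%d", st$n_w, st$n_c, st$m), st$label)
  expect_equal(pi, pi[swap], tolerance = 1e-12)
})

test_that("cycle affinity of the four-state circuit equals the eta log-ratio", {
  set.seed(23)
  for (i in 1:20) {
    p <- rand_params()
    m <- build_rate_matrix(circuit_spec(), p, concentrations())
    expect_equal(detailed_balance_residual(m),
                 abs(log(p$eta_ab * p$eta_ua / (p$eta_ib * p$eta_ba))),
                 tolerance = 1e-10)
  }
  m10 <- build_rate_matrix(circuit_spec(), rate_params(eta_ab = 10),
                           concentrations())
  expect_equal(detailed_balance_residual(m10), log(10), tolerance = 1e-12)
})

test_that("spanning-tree residual agrees with brute-force cycle enumeration", {
  set.seed(31)
  for (i in 1:5) {
    spec <- circuit_spec(include_noncognate = TRUE)
    m <- build_rate_matrix(spec, rand_params(), concentrations(c = 1, w = 2))
    expect_equal(detailed_balance_residual(m), bruteforce_residual(m),
                 tolerance = 1e-9)
  }
  # on larger lattices long cycles compose several elementary squares, so the
  # basis maximum is a lower bound on the all-cycles maximum and both vanish
  # together at equilibrium
  spec <- circuit_spec(n_binding_sites = 2, n_activation_steps = 2)
  p <- rand_params()
  m <- build_rate_matrix(spec, p, concentrations())
  expect_lte(detailed_balance_residual(m), bruteforce_residual(m) + 1e-9)
  meq <- build_rate_matrix(spec, equilibrium_params(spec, p), concentrations())
  expect_lt(bruteforce_residual(meq), 1e-10)
  expect_lt(detailed_balance_residual(meq), 1e-10)
})

test_that("energy/barrier construction is at equilibrium with Boltzmann stationary weights", {
  set.seed(47)
  spec <- circuit_spec()
  # all energies and barriers zero: every rate is 1
  m0 <- equilibrium_sample(spec, rep(0, 4), rep(0, 4), concentrations())
  off <- m0$Q; diag(off) <- 0
  expect_equal(sort(off[off > 0]), rep(1, 8))
  for (i in 1:25) {
    cc <- concentrations(c = 10^runif(1, -1, 1))
    m <- rand_equilibrium(spec, cc)
    expect_lt(detailed_balance_residual(m), 1e-10)
    expect_lt(entropy_production(m), 1e-10)
  }
  # explicit Boltzmann check
  E <- c(0.3, -1.2, 0.8, 0.4)
  B <- c(0.1, -0.5, 1.1, -0.2)
  cc <- concentrations(c = 1.7)
  m <- equilibrium_sample(spec, E, B, cc)
  pi <- stationary_distribution(m)
  boltz <- exp(-E) * cc$c^m$states$n_c
  expect_equal(pi, boltz / sum(boltz), tolerance = 1e-12)
  # eta inversion reproduces the same generator
  p <- attr(m, "eta_params")
  expect_equal(build_rate_matrix(spec, p, cc)$Q, m$Q, tolerance = 1e-12)
})

test_that("invalid specifications and parameters are rejected", {
  expect_error(rate_params(k_b = -1))
  expect_error(rate_params(eta_ab = 0))
  expect_error(rate_params(eta_ab = 0.5, check_activator = TRUE))
  expect_error(circuit_spec(n_binding_sites = 0))
  expect_error(concentrations(c = 0))
  expect_error(equilibrium_sample(circuit_spec(), rep(400, 4), rep(-400, 4)))
})
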