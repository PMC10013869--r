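test_that("telegraph circuit attains S = 1 and P = 1/2 exactly", {
  set.seed(3)
  for (i in 1:10) {
    kon <- 10^runif(1, -1, 1)
    koff <- 10^runif(1, -1, 1)
    cc <- concentrations(c = 10^runif(1, -1, 1))
    rs <- response_summary(telegraph_matrix(kon, koff, cc))
    expect_equal(rs$S, 1, tolerance = 1e-9)
    expect_equal(rs$P, 0.5, tolerance = 1e-9)
    # telegraph closed form for the burst-unit variance rate
    pi <- rs$pi_a
    expect_equal(rs$v, 2 * pi^2 * (1 - pi)^2, tolerance = 1e-9)
  }
})

test_that("analytic sharpness matches central finite differences", {
  set.seed(9)
  spec6 <- circuit_spec(include_noncognate = TRUE)
  for (i in 1:6) {
    p <- rand_params()
    conc <- concentrations(c = 1, w = 10^runif(1, 0, 2))
    s <- sharpness(spec6, p, conc)
    expect_equal(s, fd_sharpness(spec6, p, conc), tolerance = 1e-5)
  }
  spec <- circuit_spec(n_binding_sites = 2, n_activation_steps = 2)
  p <- rand_params()
  expect_equal(sharpness(spec, p, concentrations()),
               fd_sharpness(spec, p, concentrations()), tolerance = 1e-5)
})

test_that("normalizations cancel: S * P = s * p for any circuit", {
  set.seed(15)
  for (i in 1:10) {
    rs <- response_summary(circuit_spec(include_noncognate = TRUE),
                           rand_params(), concentrations(c = 1, w = 5))
    expect_equal(rs$S * rs$P, rs$s * rs$p, tolerance = 1e-10)
  }
})

test_that("burst-unit metrics are invariant under global rate rescaling", {
  set.seed(21)
  p <- rand_params()
  lam <- 12.3
  ps <- rate_params(k_b = lam * p$k_b, k_u = lam * p$k_u, k_a = lam * p$k_a,
                    k_i = lam * p$k_i, eta_ab = p$eta_ab, eta_ib = p$eta_ib,
                    eta_ua = p$eta_ua, eta_ba = p$eta_ba)
  r1 <- response_summary(circuit_spec(), p, concentrations())
  r2 <- response_summary(circuit_spec(), ps, concentrations())
  for (col in c("pi_a", "s", "v", "p", "S", "P", "IR_bits", "phi_per_burst"))
    expect_equal(r1[[col]], r2[[col]], tolerance = 1e-8)
})

test_that("equilibrium six-state circuits have specificity pinned at alpha", {
  set.seed(27)
  spec <- circuit_spec(include_noncognate = TRUE)
  for (i in 1:50) {
    p <- equilibrium_params(spec, rand_params())
    m <- build_rate_matrix(spec, p, concentrations(c = 1, w = 10^runif(1, 0, 3)))
    f <- specificity(m)
    expect_equal(as.numeric(f), 100, tolerance = 1e-8)
  }
})

test_that("specificity handles the w -> 0 limit analytically", {
  spec <- circuit_spec(include_noncognate = TRUE)
  p <- equilibrium_params(spec, rate_params(k_b = 2, eta_ab = 3, eta_ib = 0.5))
  m0 <- build_rate_matrix(spec, p, concentrations(c = 1, w = 0))
  f <- specificity(m0)
  expect_true(isTRUE(attr(f, "limit")))
  expect_equal(as.numeric(f), 100, tolerance = 1e-6)
  expect_error(specificity(build_rate_matrix(circuit_spec(), rate_params(),
                                             concentrations())))
})

test_that("cognate fraction reproduces the competition benchmarks", {
  # alpha = 100 against increasing noncognate loads
  expect_equal(cognate_fraction(100, 47), 100 / 147)
  expect_equal(cognate_fraction(100, 698), 100 / 798)
  expect_equal(cognate_fraction(100, 1426), 100 / 1526)
  expect_lt(abs(cognate_fraction(100, 47) - 2 / 3), 0.02)
  expect_lt(abs(cognate_fraction(100, 698) - 1 / 8), 0.01)
  expect_lt(abs(cognate_fraction(100, 1426) - 1 / 15), 0.01)
})

test_that("sharpness envelope evaluates its anchor points", {
  expect_equal(sharpness_envelope(1, 100, 1000), 100 / 1100)
  expect_equal(sharpness_envelope(1, 1e4, 1e3), 1e4 / 1.1e4)
  expect_equal(sharpness_envelope(0.7, 50, 0), 0.7)   # no interference
})

test_that("intrinsic sharpness equals S for cognate-only circuits and respects w = 0 semantics", {
  set.seed(33)
  p <- rand_params()
  spec4 <- circuit_spec()
  rs <- response_summary(spec4, p, concentrations())
  expect_equal(intrinsic_sharpness(spec4, p, concentrations()), rs$S,
               tolerance = 1e-10)
  # for the six-state circuit, S0 is S of the cognate-only reduction
  spec6 <- circuit_spec(include_noncognate = TRUE)
  s0 <- intrinsic_sharpness(spec6, p, concentrations(c = 1, w = 100))
  expect_equal(s0, rs$S, tolerance = 1e-10)
})

test_that("achievable sharpness never exceeds the envelope over the tradeoff endpoints", {
  # the envelope bounds the *achievable region ceiling*: swept maxima approach
  # but do not cross the analytic limits at w/c = 1000
  spec <- circuit_spec(include_noncognate = TRUE)
  conc <- concentrations(c = 1, w = 1000)
  rne <- maximize_metric(spec, "S",
                         sweep_config(n_init = 4000, n_generations = 250,
                                      n_mutants = 30, seed = 71), conc)
  bound_ne <- max(sharpness_envelope(2, 100, 1000),
                  sharpness_envelope(1, 100^2, 1000))
  expect_lte(rne$value, bound_ne * (1 + 1e-4))
  expect_gt(rne$value, 0.85 * bound_ne)
  req <- maximize_metric(spec, "S",
                         sweep_config(n_init = 3000, n_generations = 150,
                                      n_mutants = 24, seed = 72,
                                      equilibrium_only = TRUE), conc)
  bound_eq <- sharpness_envelope(1, 100, 1000)
  expect_lte(req$value, bound_eq * (1 + 1e-4))
  expect_gt(req$value, 0.85 * bound_eq)
})

test_that("response_summary bundles noncognate metrics when applicable", {
  rs <- response_summary(circuit_spec(include_noncognate = TRUE),
                         rate_params(), concentrations(c = 1, w = 47))
  expect_true(all(c("f", "p_c", "S0") %in% names(rs)))
  expect_equal(rs$p_c, cognate_fraction(rs$f, 47), tolerance = 1e-12)
})
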