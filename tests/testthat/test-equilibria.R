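test_that("binding polynomial matches the two-state partition function", {
  m2 <- binding_model(list(binding_state(1e-9, -1, 1),
                           binding_state(100e-9, -1, 1)))
  # 1 + 10 + 0.1 + 1 at S = 10 nM (hand arithmetic)
  expect_equal(binding_polynomial(m2, 10e-9), 12.1)
  expect_equal(binding_polynomial(m2, 0), 1)
  m1 <- simple_model()
  expect_equal(binding_polynomial(m1, 0), 1)
  expect_equal(binding_polynomial(m1, 1e-6), 2)
  # vanishing affinity: Sigma -> 1 at any concentration
  weak <- binding_model(list(binding_state(1e10, -1, 1),
                             binding_state(1e10, -1, 1)))
  expect_equal(binding_polynomial(weak, 1), 1, tolerance = 1e-9)
  expect_error(binding_polynomial(m1, -1e-9), "non-negative")
})

test_that("binding polynomial is monotone non-decreasing in free ligand", {
  set.seed(11)
  for (k in 1:20) {
    m <- random_model(sample(1:2, 1))
    s <- sort(10^runif(30, -12, -3))
    expect_true(all(diff(binding_polynomial(m, s)) >= 0))
  }
})

test_that("fraction bound reproduces printed parameter arithmetic", {
  md <- ref_models$nacl_500mM
  # at S = kd2: state 1 is 97.9% occupied, state 2 half-occupied
  expect_equal(fraction_bound(md, 60.8e-9), 0.6266 + 0.1100,
               tolerance = 1e-3)
  # saturation limit equals the summed apparent stoichiometries
  expect_equal(fraction_bound(md, 1), 0.64 + 0.22, tolerance = 1e-6)
  m1 <- simple_model(kd = 2e-6, n = 0.8)
  expect_equal(fraction_bound(m1, 2e-6), 0.4)
})

test_that("fraction bound is monotone, bounded, and reduces to one state", {
  set.seed(12)
  for (k in 1:20) {
    m <- random_model(sample(1:2, 1))
    ntot <- sum(sapply(m$states, `[[`, "n"))
    s <- sort(10^runif(40, -12, -2))
    fb <- fraction_bound(m, s)
    expect_true(all(diff(fb) > 0))
    expect_true(all(fb >= 0 & fb <= ntot))
  }
  # identical substates behave as a single state with summed n
  twin <- binding_model(list(binding_state(5e-8, -4, 0.3),
                             binding_state(5e-8, -4, 0.6)))
  single <- binding_model(binding_state(5e-8, -4, 0.9))
  s <- 10^seq(-10, -5, length.out = 50)
  expect_equal(fraction_bound(twin, s), fraction_bound(single, s),
               tolerance = 1e-12)
})

test_that("free-ligand solve matches the closed-form quadratic root", {
  m <- simple_model(kd = 1e-6, n = 1)
  # s^2 + 6s - 5 = 0 in uM units
  expect_equal(solve_free_ligand(m, 5e-6, 10e-6) * 1e6,
               (-6 + sqrt(56)) / 2, tolerance = 1e-9)
  expect_equal(solve_free_ligand(m, 5e-6, 0), 5e-6)
  # stoichiometric sink: a very tight binder consumes sub-capacity ligand
  tight <- simple_model(kd = 1e-15, n = 1)
  expect_lt(solve_free_ligand(tight, 5e-6, 10e-6) / 5e-6, 1e-4)
})

test_that("free-ligand solve satisfies mass balance and a bisection oracle", {
  set.seed(13)
  for (k in 1:100) {
    m <- random_model(sample(1:2, 1))
    p <- 10^runif(1, -6, -4)
    st <- 10^runif(1, -7, -3)
    s <- solve_free_ligand(m, st, p)
    expect_lt(abs(s + p * fraction_bound(m, s) - st), 1e-9 * st)
    oracle <- uniroot(function(x) x + p * fraction_bound(m, x) - st,
                      c(0, st), tol = 1e-18 * st)$root
    expect_equal(s, oracle, tolerance = 1e-9)
  }
})

test_that("competitive solve reduces to the plain solve at zero inhibitor", {
  m <- binding_model(list(binding_state(1e-9, -3, 0.6),
                          binding_state(50e-9, -7, 0.4)),
                     competitor = list(kd_inh = c(5e-9, 5e-8),
                                       dh_inh = c(-4, -2)))
  sol <- solve_competitive(m, 2e-5, 0, 4e-5)
  expect_equal(sol$i_free, 0)
  expect_equal(sol$s_free, solve_free_ligand(m, 2e-5, 4e-5),
               tolerance = 1e-9)
})

test_that("an overwhelming tight competitor abolishes substrate binding", {
  m <- binding_model(binding_state(1e-8, -3, 1),
                     competitor = list(kd_inh = 1e-15, dh_inh = -5))
  sol <- solve_competitive(m, 1e-5, 1e-3, 4e-5)
  occ <- 1e8 * sol$s_free / (1 + 1e8 * sol$s_free + 1e15 * sol$i_free)
  expect_lt(occ, 1e-4)
})

test_that("competitive solve matches a 2-D grid-refinement oracle", {
  set.seed(14)
  for (k in 1:8) {
    m <- binding_model(
      list(binding_state(10^runif(1, -9, -7), -3, runif(1, 0.3, 1)),
           binding_state(10^runif(1, -7, -6), -7, runif(1, 0.3, 1))),
      competitor = list(kd_inh = 10^runif(2, -9, -6),
                        dh_inh = runif(2, -8, -1)))
    st <- 10^runif(1, -6, -4.5)
    it <- 10^runif(1, -6, -4.5)
    p <- 10^runif(1, -5.5, -4.5)
    sol <- solve_competitive(m, st, it, p)
    orc <- grid_oracle_competitive(m, st, it, p)
    expect_equal(sol$s_free, orc$s_free, tolerance = 1e-6)
    expect_equal(sol$i_free, orc$i_free, tolerance = 1e-6)
  }
})

test_that("per-state competitive occupancies are a valid partition", {
  set.seed(15)
  m <- binding_model(list(binding_state(1e-9, -3, 0.6),
                          binding_state(5e-8, -7, 0.4)),
                     competitor = list(kd_inh = c(2e-9, 2e-8),
                                       dh_inh = c(-4, -2)))
  for (k in 1:20) {
    sol <- solve_competitive(m, 10^runif(1, -7, -4), 10^runif(1, -7, -4),
                             4e-5)
    for (j in 1:2) {
      K <- 1 / m$states[[j]]$kd
      Ki <- 1 / m$competitor$kd_inh[j]
      den <- 1 + K * sol$s_free + Ki * sol$i_free
      expect_lte(K * sol$s_free / den + Ki * sol$i_free / den, 1)
    }
  }
})

test_that("state ordering is canonical and constructors validate input", {
  m <- binding_model(list(binding_state(1e-7, -7, 0.2),
                          binding_state(1e-9, -3, 0.6)))
  expect_equal(m$states[[1]]$kd, 1e-9)  # reordered ascending kd
  expect_equal(m$states[[1]]$dh, -3)
  expect_error(binding_state(-1e-9, -3, 1), "positive")
  expect_error(binding_state(1e-9, -3, -0.1), "non-negative")
  expect_error(binding_model(list()), "one or two")
  expect_error(binding_model(list(binding_state(1e-9, -3, 1)),
                             competitor = list(kd_inh = c(1e-9, 1e-9),
                                               dh_inh = c(-1, -1))),
               "pair per state")
})
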