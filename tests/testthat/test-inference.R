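test_that("noiseless single-state fits recover the generating parameters", {
  iso <- simulate_injection_heats(ref_models$nacl_50mM, default_proto)
  fit <- itc_fit(iso, "single", n_starts = 5, seed = 1)
  expect_equal(unname(coef(fit)[c("kd", "dh", "n")]),
               c(917e-9, -2.3, 1.18), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
  expect_true(fit$convergence)
})

test_that("noiseless two-state fits recover the generating parameters", {
  iso <- simulate_injection_heats(ref_models$nacl_500mM, default_proto)
  fit <- itc_fit(iso, "two", n_starts = 20, seed = 2)
  expect_equal(unname(coef(fit)[c("kd1", "kd2", "dh1", "dh2", "n1", "n2")]),
               c(1.3e-9, 60.8e-9, -3.3, -7.1, 0.64, 0.22),
               tolerance = 1e-3)
  expect_lt(fit$rss, 1e-8)
})

test_that("noiseless fits are exact across random well-conditioned draws", {
  set.seed(31)
  for (k in 1:10) {
    m <- random_model(1)
    iso <- simulate_injection_heats(m, default_proto)
    fit <- itc_fit(iso, "single", n_starts = 4, seed = k)
    expect_equal(coef(fit)[["kd"]], m$states[[1]]$kd, tolerance = 1e-3)
    expect_equal(coef(fit)[["n"]], m$states[[1]]$n, tolerance = 1e-3)
  }
  for (k in 1:6) {
    m <- random_model(2)
    iso <- simulate_injection_heats(m, default_proto)
    fit <- itc_fit(iso, "two", n_starts = 10, seed = 100 + k)
    truth <- c(m$states[[1]]$kd, m$states[[2]]$kd,
               m$states[[1]]$n, m$states[[2]]$n)
    expect_equal(unname(coef(fit)[c("kd1", "kd2", "n1", "n2")]), truth,
                 tolerance = 1e-3)
  }
})

test_that("fitted two-state output is always in canonical kd order", {
  set.seed(32)
  for (k in 1:4) {
    iso <- generate_isotherm(ref_models$nano3_500mM, default_proto,
                             noise_spec(seed = 40 + k))
    fit <- itc_fit(iso, "two", n_starts = 10, seed = k)
    expect_lte(coef(fit)[["kd1"]], coef(fit)[["kd2"]])
  }
})

test_that("a flat isotherm yields near-zero enthalpy and an
           unidentifiability flag", {
  iso <- simulate_injection_heats(binding_model(binding_state(1e-7, 0, 1)),
                                  default_proto)
  fit <- itc_fit(iso, "single", n_starts = 4, seed = 3)
  expect_lt(abs(coef(fit)[["dh"]] * coef(fit)[["n"]]), 1e-3)
  expect_true(any(grepl("unidentifiable", fit$flags)))
})

test_that("fitted stoichiometry sums stay in the observed envelope when
           the truth is one site per protomer", {
  total <- sapply(1:8, function(k) {
    m <- binding_model(list(binding_state(1e-9, -2.5, 0.63),
                            binding_state(40e-9, -6.5, 0.37)))
    iso <- generate_isotherm(m, default_proto, noise_spec(seed = 50 + k))
    fit <- itc_fit(iso, "two", n_starts = 12, seed = k)
    sum(coef(fit)[c("n1", "n2")])
  })
  expect_true(all(total > 0.74 & total < 1.53))
})

test_that("model comparison prefers the generating model class", {
  iso2 <- generate_isotherm(ref_models$nacl_500mM, default_proto,
                            noise_spec(seed = 3))
  f1 <- itc_fit(iso2, "single", n_starts = 8, seed = 1)
  f2 <- itc_fit(iso2, "two", n_starts = 15, seed = 1)
  cmp <- compare_models(f1, f2)
  expect_identical(cmp$preferred, "two")
  expect_lt(cmp$f_test$p_value, 1e-6)

  iso1 <- generate_isotherm(ref_models$nacl_50mM, default_proto,
                            noise_spec(seed = 4))
  g1 <- itc_fit(iso1, "single", n_starts = 8, seed = 1)
  g2 <- itc_fit(iso1, "two", n_starts = 15, seed = 1)
  cmp <- compare_models(g1, g2)
  expect_identical(cmp$preferred, "single")

  # equal RSS, unequal complexity: simpler model wins
  expect_identical(compare_models(g1, g1)$preferred, "single")
  expect_error(compare_models(f1, g1), "same isotherm")
})

test_that("a two-state fit of single-state data is degenerate and loses
           the model comparison", {
  iso <- simulate_injection_heats(ref_models$nacl_50mM, default_proto)
  f2 <- itc_fit(iso, "two", n_starts = 12, seed = 2)
  expect_true(length(f2$flags) > 0)
  f1 <- itc_fit(iso, "single", n_starts = 5, seed = 2)
  expect_identical(compare_models(f1, f2)$preferred, "single")
})

test_that("identifiability scan shows a sharp minimum at the true kd for
           informative data", {
  iso <- generate_isotherm(ref_models$nacl_50mM, default_proto,
                           noise_spec(seed = 4))
  sc <- scan_identifiability(iso, default_proto, model = "single",
                             constrained = list(kd = c(450e-9, 917e-9,
                                                       1800e-9)),
                             n_starts = 6, seed = 9)
  expect_false(sc$flat)
  expect_equal(which.min(sc$grid$rss), 2L)
  # constrained re-fits can never beat the unconstrained optimum
  expect_true(all(sc$grid$rss >= sc$rss_unconstrained * (1 - 1e-6)))
})

test_that("identifiability scan validates its grid argument", {
  iso <- simulate_injection_heats(ref_models$nacl_50mM, default_proto)
  expect_error(scan_identifiability(iso, default_proto, model = "single",
                                    constrained = list()),
               "non-empty")
  expect_error(scan_identifiability(iso, default_proto, model = "single",
                                    constrained = list(bogus = 1)),
               "unknown parameter")
})

test_that("substate fraction reports the lower-affinity population", {
  fit <- structure(list(model = ref_models$nano3_500mM,
                        model_type = "two"), class = "itc_fit")
  expect_equal(substate_fraction(fit), 100 * 0.37 / 0.99,
               tolerance = 1e-9)  # 37.4%
  zero2 <- structure(list(model = binding_model(list(
    binding_state(1e-9, -3, 0.5), binding_state(1e-8, -5, 1e-9))),
    model_type = "two"), class = "itc_fit")
  expect_equal(substate_fraction(zero2), 0, tolerance = 1e-6)
  single <- structure(list(model = ref_models$nacl_50mM,
                           model_type = "single"), class = "itc_fit")
  expect_error(substate_fraction(single), "two-state")
})

test_that("fit accessors are coherent", {
  iso <- generate_isotherm(ref_models$nacl_50mM, default_proto,
                           noise_spec(seed = 6))
  fit <- itc_fit(iso, "single", n_starts = 5, seed = 1)
  expect_equal(fitted(fit) + residuals(fit),
               iso$normalized_heat_kcal_per_mol)
  expect_equal(sum(residuals(fit)^2), fit$rss, tolerance = 1e-8)
  expect_equal(attr(logLik(fit), "df"), fit$n_par + 1)
  pred <- predict(fit)
  expect_s3_class(pred, "isotherm")
  expect_equal(pred$normalized_heat_kcal_per_mol, fitted(fit),
               tolerance = 1e-9)
  reps <- simulate(fit, nsim = 2, seed = 7)
  expect_length(reps, 2)
  expect_s3_class(reps[[1]], "isotherm")
})
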