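test_that("component densities are normalized and match closed forms", {
  # uniform and symmetric beta closed forms
  expect_equal(component_pdf(beta_component(1, 1), 0.37), 1.0)
  expect_equal(component_pdf(beta_component(2, 2), 0.5), 1.5)
  # quadrature normalization oracle, independent of the grid machinery
  for (cp in list(beta_component(2.3, 3.7),
                  beta_component(1.8, 4.2),
                  beta_component(5, 2, scale_max = 0.6),
                  triangular_component(0.1, 0.25, 0.7))) {
    total <- stats::integrate(function(y) component_pdf(cp, y), 0, 1,
                              rel.tol = 1e-11)$value
    expect_equal(total, 1, tolerance = 1e-9)
  }
  # compressed beta is a linear rescaling of the standard beta
  cp <- beta_component(2.3, 3.7, scale_max = 0.5)
  y <- c(0.05, 0.2, 0.45)
  expect_equal(component_pdf(cp, y), dbeta(y / 0.5, 2.3, 3.7) / 0.5)
  expect_equal(component_pdf(cp, 0.7), 0)  # outside compressed support
})

test_that("invalid component and prior parameters are rejected", {
  expect_error(beta_component(-1, 2), "positive")
  expect_error(beta_component(2, 2, scale_max = 1.2), "scale_max")
  expect_error(triangular_component(0.5, 0.4, 0.9), "lower <= mode")
  expect_error(triangular_component(0.5, 0.5, 0.5), "lower < upper")
  expect_error(prior_spec(0.5, list(beta_component(2, 2, weight = 0.4))),
               "sum to 1")
  expect_error(component_pdf(beta_component(2, 2), 1), "\\[0, 1\\)")
  expect_error(example_prior("example9"))
  expect_error(build_prior(example_prior("example1"), 32), ">= 64")
})

test_that("example presets carry the published parameterizations", {
  e1 <- example_prior("example1")
  expect_equal(e1$sterile_fraction, 0.05)
  expect_equal(e1$components[[1]][c("alpha", "beta", "weight")],
               list(alpha = 2.3, beta = 3.7, weight = 0.95))
  e3 <- example_prior("example3")
  expect_equal(e3$sterile_fraction, 0.01)
  expect_equal(e3$components[[1]][c("alpha", "beta", "weight")],
               list(alpha = 11, beta = 22, weight = 0.99))
  e4 <- example_prior("example4")
  w <- vapply(e4$components, `[[`, numeric(1), "weight")
  expect_equal(e4$sterile_fraction + sum(w), 1)
  expect_equal(w, c(0.85, 0.10))
})

test_that("discretized priors conserve mass and reproduce analytic means", {
  # degenerate all-sterile prior
  d0 <- build_prior(prior_spec(1, list()), 256)
  expect_equal(d0$atom_mass, 1)
  expect_equal(sum(d0$mass), 0)

  # mass and mean for each preset; grid mean is exact by construction
  means <- c(example1 = 0.95 * 2.3 / 6, example2 = 0.95 * 1.8 / 6,
             example3 = 0.99 * 11 / 33,
             example4 = 0.85 * 11 / 33 + 0.10 * 4 / 80)
  for (nm in names(means)) {
    d <- build_prior(example_prior(nm))
    expect_equal(d$atom_mass + sum(d$mass), 1, tolerance = 1e-9)
    expect_equal(sum(d$mass * d$nodes), means[[nm]], tolerance = 1e-9)
  }
  # published leading metrics implied by those means
  expect_lt(abs(sum(build_prior(example_prior("example1"), 4097)$mass *
                      build_prior(example_prior("example1"), 4097)$nodes) -
                  0.364), 1e-3)
  expect_lt(abs(means[["example4"]] - 0.288), 1e-3)

  # pure-beta grid mean matches alpha / (alpha + beta)
  for (ab in list(c(2.3, 3.7), c(11, 22), c(0.8, 3))) {
    d <- build_prior(prior_spec(0, list(beta_component(ab[1], ab[2]))), 4097)
    expect_equal(sum(d$mass * d$nodes), ab[1] / sum(ab), tolerance = 1e-6)
  }
  # mixed continuous types also conserve mass
  d <- build_prior(prior_spec(
    0.1, list(beta_component(3, 5, weight = 0.5, scale_max = 0.8),
              triangular_component(0, 0.2, 0.6, weight = 0.4))), 1024)
  expect_equal(d$atom_mass + sum(d$mass), 1, tolerance = 1e-9)
  expect_equal(sum(d$mass * d$nodes),
               0.5 * 0.8 * 3 / 8 + 0.4 * (0 + 0.2 + 0.6) / 3,
               tolerance = 1e-9)
})

test_that("the second preset population is stochastically less fertile than the first", {
  d1 <- build_prior(prior_spec(0, list(beta_component(2.3, 3.7))))
  d2 <- build_prior(prior_spec(0, list(beta_component(1.8, 4.2))))
  q <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(rate_percentile(d2, q) < rate_percentile(d1, q)))
})

test_that("prior and ageing specifications round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  spec <- prior_spec(0.07, list(
    beta_component(2.3, 3.7, weight = 0.63),
    beta_component(4, 76, weight = 0.2, scale_max = 0.85),
    triangular_component(0.05, 0.2, 0.55, weight = 0.1)))
  write_prior_spec(spec, path)
  back <- read_prior_spec(path)
  expect_equal(back, spec, tolerance = 0)

  apath <- withr::local_tempfile(fileext = ".yaml")
  aspec <- ageing_spec(peak_alpha = 2.5, peak_beta = 9, decline_years = 10,
                       anchors = data.frame(age = c(25, 45, 60),
                                            fraction = c(0.02, 0.5, 1)))
  write_ageing_spec(aspec, apath)
  aback <- read_ageing_spec(apath)
  expect_equal(aback$anchors, aspec$anchors, tolerance = 0)
  expect_equal(aback$peak_alpha, 2.5)
  expect_equal(aback$decline_years, 10)

  expect_error(read_prior_spec(withr::local_tempfile(lines = "components: []",
                                                     fileext = ".yaml")),
               "sterile_fraction")
})
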