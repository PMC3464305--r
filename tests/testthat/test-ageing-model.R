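# anchors placing every sterility age far above the ages reached in a run,
# so rates stay at peak: the ageing machinery must then reduce to the
# static engine
static_limit_anchors <- data.frame(age = c(25, 55, 56),
                                   fraction = c(0.01, 0.01, 1))

test_that("the per-age rate follows the linear decline geometry", {
  expect_equal(intrinsic_rate_at_age(0.23, 45, 32.5), 0.23)
  expect_equal(intrinsic_rate_at_age(0.23, 45, 25), 0.23)
  expect_equal(intrinsic_rate_at_age(0.23, 45, 45), 0)
  expect_equal(intrinsic_rate_at_age(0.23, 45, 50), 0)
  expect_equal(intrinsic_rate_at_age(0.2, 45, 38.75), 0.1)  # halfway down
  # vectorized over ages, continuous at both window ends
  ages <- seq(30, 47, by = 0.25)
  r <- intrinsic_rate_at_age(0.3, 45, ages)
  expect_true(all(diff(r) <= 0))
  expect_error(intrinsic_rate_at_age(1, 45, 30), "\\[0, 1\\)")
})

test_that("sterility-age CDFs interpolate their anchors monotonically", {
  F3 <- build_sterility_age_cdf(data.frame(age = c(25, 44.5, 59),
                                           fraction = c(0.01, 0.5, 1)))
  expect_equal(F3(c(25, 44.5, 59)), c(0.01, 0.5, 1))
  expect_equal(F3(20), 0.01)  # clamped outside the anchor range
  expect_equal(F3(70), 1)
  expect_true(all(diff(F3(seq(25, 59, by = 0.1))) >= 0))
  expect_error(build_sterility_age_cdf(
    data.frame(age = c(30, 25), fraction = c(0.1, 0.5))), "increasing")
  expect_error(build_sterility_age_cdf(
    data.frame(age = c(25, 30), fraction = c(0.5, 0.1))), "increasing")

  # default schedule is pinned at the published population summaries
  Fd <- build_sterility_age_cdf()
  expect_equal(Fd(c(25, 30, 35, 40, 44.5, 59)),
               c(0.01, 0.02, 0.051, 0.166, 0.5, 1))
})

test_that("cohort initialization conserves mass and absorbs the already sterile", {
  spec <- ageing_spec()
  st <- initialize_cohort(spec, 25, grid_sizes = c(129, 12))
  expect_equal(st$sterile_mass + sum(st$weights), 1, tolerance = 1e-9)
  expect_equal(st$sterile_mass, 0.010, tolerance = 1e-3)
  expect_identical(st$survival, 1)
  expect_true(all(st$sterility_age_nodes > 25))

  st40 <- initialize_cohort(spec, 40, grid_sizes = c(257, 12))
  expect_equal(st40$sterile_mass, 0.166, tolerance = 2e-3)
  tab40 <- aged_metrics_table(spec, 40, n_max = 1, grid_sizes = c(257, 12),
                              horizons = integer())
  expect_lt(abs(tab40$p_next_cycle[1] - 0.087), 5e-3)

  # an all-sterile schedule leaves nothing to conceive
  dead <- ageing_spec(anchors = data.frame(age = c(25, 59),
                                           fraction = c(1, 1)))
  tab <- aged_metrics_table(dead, 30, n_max = 1, grid_sizes = c(65, 12),
                            horizons = integer())
  expect_equal(tab$p_next_cycle, c(0, 0))
  expect_equal(tab$prop_sterile, c(1, 1))

  expect_error(initialize_cohort(spec, 24), "start_age")
  expect_error(initialize_cohort(spec, 30, grid_sizes = c(32, 12)), "coarse")
})

test_that("advancing a cycle applies the geometric update", {
  spec <- ageing_spec()
  # a single-cell cohort with constant rate 0.2 survives (1 - 0.2)^2
  st <- structure(list(peak_nodes = 0.2, sterility_age_nodes = 200,
                       weights = matrix(1, 1, 1), sterile_mass = 0,
                       start_age = 30, current_age = 30,
                       cycles_elapsed = 0L, survival = 1),
                  class = "aged_cohort_state")
  st2 <- advance_cycle(advance_cycle(st, spec), spec)
  expect_equal(st2$survival, 0.64)
  expect_equal(st2$cycles_elapsed, 2L)
  expect_equal(st2$current_age, 30 + 2 / 12)
  expect_equal(sum(st2$weights), 1)

  # an all-sterile cohort is unchanged apart from age and cycle count
  dead <- structure(list(peak_nodes = 0.2, sterility_age_nodes = 28,
                         weights = matrix(0, 1, 1), sterile_mass = 1,
                         start_age = 30, current_age = 30,
                         cycles_elapsed = 0L, survival = 1),
                    class = "aged_cohort_state")
  dead2 <- advance_cycle(dead, spec)
  expect_equal(dead2$survival, 1)
  expect_equal(dead2$sterile_mass, 1)
})

test_that("with sterility far above all modelled ages the ageing engine reduces to the static one", {
  spec <- ageing_spec(anchors = static_limit_anchors)
  kp <- 513
  aged <- aged_metrics_table(spec, 30, n_max = 18, grid_sizes = c(kp, 12),
                             horizons = 12)
  static <- metrics_table(prior_spec(0.01, list(beta_component(3, 10,
                                                               weight = 0.99))),
                          n_max = 18, grid_size = kp, horizons = 12)
  for (col in c("prop_sterile", "p_next_cycle", "p_next_12", "cumulative"))
    expect_equal(aged[[col]], static[[col]], tolerance = 1e-6)
  # quantiles share the same grid cells but different interpolation
  # conventions, so agree to within a cell width
  expect_equal(aged$median_rate, static$median_rate, tolerance = 2 / kp)
  expect_equal(aged$p90_rate, static$p90_rate, tolerance = 2 / kp)

  # no ageing during the attempt means frozen and unfrozen scans coincide
  pol <- threshold_policy("p_next_cycle", 0.1)
  expect_equal(frozen_ageing_delta(spec, 30, pol, n_max = 30,
                                   grid_sizes = c(129, 12)), 0L)
})

test_that("fertility metrics deteriorate with starting age", {
  spec <- ageing_spec()
  tabs <- lapply(c(25, 30, 35, 40), function(a)
    aged_metrics_table(spec, a, n_max = 12, grid_sizes = c(129, 12),
                       horizons = 12))
  for (n in c(0, 6, 12)) {
    for (col in c("p_next_cycle", "p_next_12")) {
      vals <- vapply(tabs, function(tb) tb[[col]][tb$cycles_elapsed == n],
                     numeric(1))
      expect_true(all(diff(vals) < 0))
    }
  }
  cum12 <- vapply(tabs, function(tb) tb$cumulative[tb$cycles_elapsed == 12],
                  numeric(1))
  expect_true(all(diff(cum12) < 0))
})
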