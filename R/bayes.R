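#' Cumulative conception probability for a known rate
#'
#' Probability that a couple with intrinsic conception rate `y` conceives
#' within `n` cycles: `1 - (1 - y)^n`, the geometric CDF.
#'
#' @param y Intrinsic conception rate(s) in `[0, 1)`.
#' @param n Number of cycles (non-negative integer(s)).
#' @return Probabilities in `[0, 1)`.
#' @examples
#' conception_cdf(0.2, 2)  # 0.36
#' @export
conception_cdf <- function(y, n) {
  if (any(y < 0 | y >= 1)) stop("'y' must lie in [0, 1)", call. = FALSE)
  if (any(n < 0) || any(n != floor(n)))
    stop("'n' must be a non-negative integer", call. = FALSE)
  -expm1(n * log1p(-y))
}

#' Rate achieving a given cumulative conception probability
#'
#' Inverts the geometric CDF: the intrinsic conception rate `y` for which
#' the probability of conceiving within `n` cycles equals `P`, namely
#' `y = 1 - (1 - P)^(1/n)`.
#'
#' @param P Target cumulative probability in `[0, 1)`.
#' @param n Number of cycles (positive integer).
#' @return Rates in `[0, 1)`.
#' @examples
#' invert_cdf(0.5, 12)  # 0.0561
#' @export
invert_cdf <- function(P, n) {
  if (any(P < 0 | P >= 1))
    stop("'P' must lie in [0, 1): no finite rate makes conception certain",
         call. = FALSE)
  if (any(n < 1) || any(n != floor(n)))
    stop("'n' must be a positive integer", call. = FALSE)
  -expm1(log1p(-P) / n)
}

#' Survival function of non-conception
#'
#' Probability that a couple drawn from the prior has not conceived within
#' `n` cycles: the sterile atom plus the prior expectation of
#' `(1 - y)^n`. Equals 1 at `n = 0` for any prior.
#'
#' @param prior A [prior_spec()] or [build_prior()] result.
#' @param n Vector of non-negative integers.
#' @param grid_size Grid resolution used if `prior` is a specification.
#' @return Survival probabilities, one per element of `n`.
#' @examples
#' survival_prob(example_prior("example1"), c(0, 12))
#' @export
survival_prob <- function(prior, n, grid_size = 8193) {
  dist <- as_distribution(prior, grid_size)
  if (any(n < 0) || any(n != floor(n)))
    stop("'n' must be a non-negative integer", call. = FALSE)
  lg <- log1p(-dist$nodes)
  vapply(n, function(k) dist$atom_mass + sum(dist$mass * exp(k * lg)),
         numeric(1))
}

#' Posterior rate distribution after cycles of non-conception
#'
#' Applies Bayes' theorem: the prior density is tilted by the geometric
#' non-conception likelihood `(1 - y)^n` and renormalized by the survival
#' probability `s(n)`. The sterile atom is tilted by a factor of one, so
#' its posterior share grows as fertile couples conceive and leave the
#' cohort.
#'
#' @inheritParams survival_prob
#' @param n Number of elapsed non-conception cycles (single non-negative
#'   integer).
#' @return An object of class `posterior_state` with fields
#'   `cycles_elapsed`, `distribution` (a `discretized_distribution`) and
#'   `survival` (`s(n)`).
#' @examples
#' st <- posterior(example_prior("example1"), 12)
#' sterile_proportion(st)
#' @export
posterior <- function(prior, n, grid_size = 8193) {
  dist <- as_distribution(prior, grid_size)
  if (length(n) != 1L || n < 0 || n != floor(n))
    stop("'n' must be a single non-negative integer", call. = FALSE)
  g <- exp(n * log1p(-dist$nodes))
  s_n <- dist$atom_mass + sum(dist$mass * g)
  post <- new_distribution(dist$edges, dist$nodes,
                           dist$mass * g / s_n,
                           dist$density * g / s_n,
                           dist$atom_mass / s_n)
  structure(list(cycles_elapsed = as.integer(n), distribution = post,
                 survival = s_n),
            class = "posterior_state")
}

#' @export
print.posterior_state <- function(x, ...) {
  cat(sprintf(
    "Posterior after %d non-conception cycle(s): s(n) = %.4g, sterile %.4g\n",
    x$cycles_elapsed, x$survival, x$distribution$atom_mass))
  invisible(x)
}

#' Probability of conceiving in the next cycle
#'
#' The posterior mean of the intrinsic conception rate: what "probability
#' of conception" means once the rate itself is uncertain.
#'
#' @param state A `posterior_state` from [posterior()].
#' @return A probability in `[0, 1)`.
#' @export
p_next_cycle <- function(state) {
  d <- state$distribution
  sum(d$mass * d$nodes)
}

#' Probability of conceiving within the next k cycles
#'
#' One minus the posterior expectation of `(1 - y)^k`; equivalently
#' `1 - s(n + k) / s(n)` for a couple already `n` cycles in.
#'
#' @param state A `posterior_state` from [posterior()].
#' @param k Horizon in cycles (positive integer).
#' @return A probability in `[0, 1]`.
#' @export
p_within <- function(state, k) {
  if (length(k) != 1L || k < 1 || k != floor(k))
    stop("'k' must be a single positive integer", call. = FALSE)
  d <- state$distribution
  -expm1(log(d$atom_mass + sum(d$mass * exp(k * log1p(-d$nodes)))))
}

#' Percentile of the posterior rate distribution
#'
#' Quantile of the mixed discrete-continuous posterior, sterile atom
#' included: the smallest rate `y` whose cumulative posterior mass reaches
#' `q`. Returns exactly 0 whenever the sterile share alone reaches `q`.
#' Between grid nodes the cumulative mass is interpolated linearly.
#'
#' @param state A `posterior_state` from [posterior()], or a
#'   `discretized_distribution`.
#' @param q Probability level(s) in `(0, 1)`.
#' @return Rate value(s) in `[0, 1)`.
#' @export
rate_percentile <- function(state, q) {
  d <- if (inherits(state, "posterior_state")) state$distribution else state
  if (!inherits(d, "discretized_distribution"))
    stop("'state' must be a posterior_state or discretized_distribution",
         call. = FALSE)
  if (any(q <= 0 | q >= 1)) stop("'q' must lie in (0, 1)", call. = FALSE)
  cum <- d$atom_mass + cumsum(d$mass)
  vapply(q, function(p) {
    if (d$atom_mass >= p) return(0)
    i <- which(cum >= p)[1L]
    if (is.na(i)) return(d$edges[length(d$edges)])
    prev <- cum[i] - d$mass[i]
    d$edges[i] + (p - prev) / d$mass[i] * (d$edges[i + 1L] - d$edges[i])
  }, numeric(1))
}

#' Proportion of the remaining population who are sterile
#'
#' The sterile share among couples still unpregnant after `n` cycles:
#' prior sterile mass divided by `s(n)`.
#'
#' @param state A `posterior_state` from [posterior()].
#' @return A probability in `[0, 1]`.
#' @export
sterile_proportion <- function(state) {
  state$distribution$atom_mass
}

#' Per-cycle fertility metrics table
#'
#' For each elapsed-cycle count `n = 0, ..., n_max`, computes the standard
#' panel of subfertility metrics on the posterior: sterile proportion,
#' posterior median and 90th percentile of the rate, probability of
#' conceiving in the next cycle and within the next 12 and 24 cycles, and
#' the cumulative conception probability `1 - s(n)`.
#'
#' @inheritParams survival_prob
#' @param n_max Largest elapsed-cycle count (default 36).
#' @param horizons Forward horizons, in cycles, for the
#'   probability-of-conceiving-within columns.
#' @return A data.frame with one row per `n`, columns `cycles_elapsed`,
#'   `prop_sterile`, `median_rate`, `p90_rate`, `p_next_cycle`,
#'   `p_next_12`, `p_next_24` and `cumulative`.
#' @examples
#' head(metrics_table(example_prior("example1"), n_max = 6))
#' @export
metrics_table <- function(prior, n_max = 36, grid_size = 8193,
                          horizons = c(12, 24)) {
  if (length(n_max) != 1L || n_max < 1 || n_max != floor(n_max))
    stop("'n_max' must be a single positive integer", call. = FALSE)
  dist <- as_distribution(prior, grid_size)
  validate_distribution(dist)
  hmax <- if (length(horizons)) max(horizons) else 0L
  g <- exp(log1p(-dist$nodes))
  s <- numeric(n_max + hmax + 1L)
  mk <- dist$mass
  rows <- vector("list", n_max + 1L)
  for (n in 0:(n_max + hmax)) {
    s_n <- dist$atom_mass + sum(mk)
    s[n + 1L] <- s_n
    if (n <= n_max) {
      cond <- new_distribution(dist$edges, dist$nodes, mk / s_n,
                               dist$density, dist$atom_mass / s_n)
      rows[[n + 1L]] <- data.frame(
        cycles_elapsed = n,
        prop_sterile = cond$atom_mass,
        median_rate = rate_percentile(cond, 0.5),
        p90_rate = rate_percentile(cond, 0.9),
        p_next_cycle = sum(cond$mass * cond$nodes),
        cumulative = 1 - s_n)
    }
    mk <- mk * g
  }
  out <- do.call(rbind, rows)
  for (h in horizons)
    out[[sprintf("p_next_%d", h)]] <-
      1 - s[out$cycles_elapsed + 1L + h] / s[out$cycles_elapsed + 1L]
  ord <- c("cycles_elapsed", "prop_sterile", "median_rate", "p90_rate",
           "p_next_cycle", sprintf("p_next_%d", horizons), "cumulative")
  out[, ord]
}

#' Subfertility threshold policy
#'
#' Pairs a posterior metric with a threshold; a couple is flagged once the
#' metric falls strictly below the threshold.
#'
#' @param metric One of `"median_rate"`, `"p90_rate"`, `"p_next_cycle"`,
#'   `"p_next_12"`.
#' @param threshold Threshold value in `(0, 1)`.
#' @return An object of class `threshold_policy`.
#' @examples
#' threshold_policy("p_next_cycle", 0.1)
#' @export
threshold_policy <- function(metric, threshold) {
  metric <- as.character(metric)
  if (!metric %in% c("median_rate", "p90_rate", "p_next_cycle", "p_next_12"))
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("'threshold' must be a single number in (0, 1]", call. = FALSE)
  structure(list(metric = metric, threshold = threshold),
            class = "threshold_policy")
}

#' The five standard subfertility policies
#'
#' Median rate below 0.05; 90th percentile below 0.2; next-cycle conception
#' probability below 0.1 and below 0.05; 12-cycle conception probability
#' below 0.5.
#'
#' @return A named list of [threshold_policy()] objects.
#' @export
default_policies <- function() {
  list(median_lt_0.05 = threshold_policy("median_rate", 0.05),
       p90_lt_0.2 = threshold_policy("p90_rate", 0.2),
       p_next_lt_0.1 = threshold_policy("p_next_cycle", 0.1),
       p_next_lt_0.05 = threshold_policy("p_next_cycle", 0.05),
       p_next12_lt_0.5 = threshold_policy("p_next_12", 0.5))
}

#' Cycles of non-conception until a subfertility threshold is crossed
#'
#' Scans `n = 0, 1, 2, ...` and returns the smallest `n` at which the
#' policy's metric, evaluated on the posterior after `n` cycles, is
#' strictly below the policy threshold. `n = 0` means the prior population
#' already meets the criterion. Returns `NA` (the not-reached sentinel)
#' if the threshold is not crossed by `n_max`.
#'
#' @inheritParams survival_prob
#' @param policy A [threshold_policy()].
#' @param n_max Scan limit (default 60).
#' @return A single integer, or `NA_integer_` if not reached.
#' @examples
#' cycles_to_threshold(example_prior("example1"),
#'                     threshold_policy("p_next_cycle", 0.1))
#' @export
cycles_to_threshold <- function(prior, policy, n_max = 60, grid_size = 8193) {
  if (!inherits(policy, "threshold_policy"))
    stop("'policy' must be a threshold_policy", call. = FALSE)
  tab <- metrics_table(prior, n_max = n_max, grid_size = grid_size,
                       horizons = 12)
  hit <- which(tab[[policy$metric]] < policy$threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(tab$cycles_elapsed[hit[1L]])
}
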