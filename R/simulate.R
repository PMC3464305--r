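#' Draw couples' latent fertility parameters
#'
#' Samples from the prior: with probability `sterile_fraction` a couple is
#' sterile (rate zero); otherwise a mixture component is chosen by weight
#' and the rate drawn from it. For an [ageing_spec()], draws independent
#' (peak rate, sterility age) pairs instead, with the sterility age drawn
#' by inverting the piecewise-linear sterility-age CDF.
#'
#' Uses the current RNG state; call `set.seed()` (or use
#' [simulate_cohort()], which seeds for you) for reproducibility.
#'
#' @param spec A [prior_spec()] or [ageing_spec()].
#' @param n Number of couples.
#' @return A data.frame with column `rate` (static spec) or columns
#'   `peak` and `sterility_age` (ageing spec).
#' @examples
#' set.seed(1)
#' draw_couples(example_prior("example1"), 5)
#' @export
draw_couples <- function(spec, n) {
  if (n < 1 || n != floor(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (inherits(spec, "ageing_spec")) {
    peak <- rbeta(n, spec$peak_alpha, spec$peak_beta)
    u <- runif(n)
    anchors <- spec$anchors
    ## invert the piecewise-linear CDF; mass below the first anchor's
    ## fraction maps to the first anchor age (already sterile by then)
    sage <- approx(anchors$fraction, anchors$age, xout = u,
                   ties = "ordered", rule = 2)$y
    sage[u <= anchors$fraction[1L]] <- anchors$age[1L]
    return(data.frame(peak = peak, sterility_age = sage))
  }
  stopifnot(inherits(spec, "prior_spec"))
  rate <- numeric(n)
  u <- runif(n)
  w <- vapply(spec$components, `[[`, numeric(1), "weight")
  breaks <- cumsum(c(spec$sterile_fraction, w))
  idx <- findInterval(u, breaks, left.open = TRUE)  # 0 = sterile
  for (j in seq_along(spec$components)) {
    sel <- idx == j
    if (!any(sel)) next
    cp <- spec$components[[j]]
    rate[sel] <- if (cp$type == "beta") {
      cp$scale_max * rbeta(sum(sel), cp$alpha, cp$beta)
    } else {
      rtri(sum(sel), cp$lower, cp$mode, cp$upper)
    }
  }
  data.frame(rate = pmin(rate, 1 - .Machine$double.eps))
}

# inverse-CDF triangular sampler
rtri <- function(n, l, m, u) {
  p <- runif(n)
  split <- if (u > l) (m - l) / (u - l) else 0
  out <- numeric(n)
  lo <- p <= split
  out[lo] <- l + sqrt(p[lo] * (u - l) * (m - l))
  out[!lo] <- u - sqrt((1 - p[!lo]) * (u - l) * (u - m))
  out
}

#' Simulate a cohort of couples attempting conception
#'
#' Each couple undergoes independent per-cycle Bernoulli conception trials
#' at its intrinsic rate — constant for a static prior, age-varying (via
#' [intrinsic_rate_at_age()]) for an ageing population — until conception
#' or `max_cycles`. Fully reproducible given `seed`.
#'
#' @param spec A [prior_spec()] or [ageing_spec()].
#' @param n_couples Number of couples (positive integer).
#' @param max_cycles Observation window in cycles (positive integer).
#' @param seed Integer seed for the single RNG stream.
#' @param start_age Starting female age; required for an ageing spec.
#' @return A data.frame of couple records: latent parameters,
#'   `conception_cycle` (`NA` if censored), `cycles_observed` and
#'   `censored`.
#' @examples
#' sim <- simulate_cohort(example_prior("example3"), 500, 12, seed = 1)
#' mean(!sim$censored)
#' @export
simulate_cohort <- function(spec, n_couples, max_cycles = 36, seed = 1,
                            start_age = NULL) {
  if (n_couples < 1 || n_couples != floor(n_couples))
    stop("'n_couples' must be a positive integer", call. = FALSE)
  if (max_cycles < 1 || max_cycles != floor(max_cycles))
    stop("'max_cycles' must be a positive integer", call. = FALSE)
  ageing <- inherits(spec, "ageing_spec")
  if (ageing && is.null(start_age))
    stop("'start_age' is required for an ageing population", call. = FALSE)
  set.seed(seed)
  lat <- draw_couples(spec, n_couples)
  cyc <- rep(NA_integer_, n_couples)
  alive <- rep(TRUE, n_couples)
  for (k in seq_len(max_cycles)) {
    rate <- if (ageing) {
      age_k <- start_age + (k - 1) / spec$cycles_per_year
      intrinsic_rate_at_age(lat$peak, lat$sterility_age, age_k,
                            spec$decline_years)
    } else lat$rate
    u <- runif(n_couples)
    hit <- alive & (u < rate)
    cyc[hit] <- k
    alive <- alive & !hit
  }
  out <- lat
  out$conception_cycle <- cyc
  out$cycles_observed <- ifelse(is.na(cyc), max_cycles, cyc)
  out$censored <- is.na(cyc)
  out
}

#' Summarize a simulated cohort per cycle
#'
#' Empirical cumulative conception fraction and the conditional per-cycle
#' conception fraction among couples still at risk, with Wilson 95%
#' confidence intervals.
#'
#' @param records Output of [simulate_cohort()].
#' @return A data.frame keyed by `cycle` with columns `n_at_risk`,
#'   `conceived`, `empirical_p_next` (+ Wilson bounds) and
#'   `empirical_cumulative` (+ Wilson bounds).
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data.frame of couple records",
         call. = FALSE)
  n <- nrow(records)
  max_cycles <- max(records$cycles_observed)
  rows <- lapply(seq_len(max_cycles), function(k) {
    at_risk <- sum(is.na(records$conception_cycle) |
                     records$conception_cycle >= k)
    conceived_k <- sum(!is.na(records$conception_cycle) &
                         records$conception_cycle == k)
    cum_k <- sum(!is.na(records$conception_cycle) &
                   records$conception_cycle <= k)
    pn <- wilson(conceived_k, at_risk)
    pc <- wilson(cum_k, n)
    data.frame(cycle = k, n_at_risk = at_risk, conceived = conceived_k,
               empirical_p_next = pn[1], p_next_lo = pn[2], p_next_hi = pn[3],
               empirical_cumulative = pc[1], cumulative_lo = pc[2],
               cumulative_hi = pc[3])
  })
  do.call(rbind, rows)
}

# Wilson 95% interval for x successes out of n
wilson <- function(x, n, z = 1.959964) {
  if (n == 0L) return(c(NaN, NaN, NaN))
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(p, max(0, centre - half), min(1, centre + half))
}
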