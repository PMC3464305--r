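#' Default sterility-age schedule
#'
#' Cumulative fraction of couples that have become sterile by each female
#' age, following Leridon's demographic estimates of the age at onset of
#' permanent sterility: about 1% of couples are sterile by age 25, the
#' median sterility age falls between 44 and 45, and all couples are
#' sterile by 59. Only a handful of points on Leridon's curve are fixed by
#' published population summaries; the yearly values between them are a
#' monotone reconstruction, calibrated once against published age-specific
#' fertility metrics, and are synthetic in that sense. Pass your own
#' anchors to [ageing_spec()] to override.
#'
#' @return A two-column data.frame with `age` (years) and `fraction`
#'   (cumulative probability of being sterile by that age).
#' @export
sterility_age_anchors <- function() {
  data.frame(
    age = c(25:44, 44.5, 45:59),
    fraction = c(
      0.0100, 0.0110, 0.0128, 0.0156, 0.0177,
      0.0200, 0.0233, 0.0295, 0.0376, 0.0393,
      0.0510, 0.0613, 0.0836, 0.1093, 0.1121,
      0.1660, 0.1980, 0.2481, 0.3108, 0.3539,
      0.5000,
      0.5451, 0.5893, 0.7571, 0.8259, 0.8677,
      0.9408, 0.9780, 0.9840, 0.9898, 0.9933,
      0.9957, 0.9968, 0.9979, 0.9987, 1.0000))
}

#' Monotone CDF of the sterility age
#'
#' Builds a piecewise-linear monotone interpolant through `(age, fraction)`
#' anchor points, clamped to `[0, 1]` and held constant outside the anchor
#' range (couples sterile before the first anchor age are treated as an
#' atom at that age).
#'
#' @param anchors Data.frame or matrix with columns age and fraction,
#'   strictly increasing in both.
#' @return A function mapping age (years) to cumulative sterile fraction,
#'   with the anchor table attached as attribute `"anchors"`.
#' @examples
#' F <- build_sterility_age_cdf(data.frame(age = c(25, 44.5, 59),
#'                                         fraction = c(0.01, 0.5, 1)))
#' F(c(25, 44.5, 59))
#' @export
build_sterility_age_cdf <- function(anchors = sterility_age_anchors()) {
  anchors <- as.data.frame(anchors)
  names(anchors)[1:2] <- c("age", "fraction")
  if (nrow(anchors) < 2L)
    stop("need at least two anchor points", call. = FALSE)
  if (any(diff(anchors$age) <= 0) || any(diff(anchors$fraction) < 0))
    stop("anchors must be strictly increasing in age and non-decreasing in fraction",
         call. = FALSE)
  if (any(anchors$fraction < 0 | anchors$fraction > 1))
    stop("anchor fractions must lie in [0, 1]", call. = FALSE)
  f <- approxfun(anchors$age, anchors$fraction, rule = 2)
  out <- function(age) pmin(1, pmax(0, f(age)))
  attr(out, "anchors") <- anchors
  out
}

#' Reproductive-ageing population specification
#'
#' Describes a population in which each couple has a peak intrinsic
#' conception rate (beta-distributed) and a couple-specific female age at
#' which they become sterile (drawn from a sterility-age distribution).
#' Fertility is at its peak until `decline_years` before the sterility
#' age, then declines linearly to zero.
#'
#' @param peak_alpha,peak_beta Beta shape parameters of the peak rate
#'   (defaults 3 and 10, mean peak rate 0.23).
#' @param decline_years Length of the linear pre-sterility decline window
#'   in years (default 12.5).
#' @param anchors Sterility-age CDF anchors as in
#'   [build_sterility_age_cdf()].
#' @param cycles_per_year Menstrual cycles per year (default 12, one cycle
#'   per month).
#' @return An object of class `ageing_spec`.
#' @examples
#' ageing_spec()
#' @export
ageing_spec <- function(peak_alpha = 3, peak_beta = 10, decline_years = 12.5,
                        anchors = sterility_age_anchors(),
                        cycles_per_year = 12) {
  if (peak_alpha <= 0 || peak_beta <= 0)
    stop("peak shape parameters must be positive", call. = FALSE)
  if (decline_years <= 0)
    stop("'decline_years' must be positive", call. = FALSE)
  if (cycles_per_year < 1 || cycles_per_year != floor(cycles_per_year))
    stop("'cycles_per_year' must be a positive integer", call. = FALSE)
  cdf <- build_sterility_age_cdf(anchors)
  structure(list(peak_alpha = peak_alpha, peak_beta = peak_beta,
                 decline_years = decline_years,
                 sterility_age_cdf = cdf,
                 anchors = attr(cdf, "anchors"),
                 cycles_per_year = as.integer(cycles_per_year)),
            class = "ageing_spec")
}

#' @export
print.ageing_spec <- function(x, ...) {
  cat(sprintf(
    "Ageing population: peak ~ Beta(%g, %g), %g-year linear decline, %d cycles/year\n",
    x$peak_alpha, x$peak_beta, x$decline_years, x$cycles_per_year))
  cat(sprintf("  sterility-age anchors: %d points from age %g to %g\n",
              nrow(x$anchors), min(x$anchors$age), max(x$anchors$age)))
  invisible(x)
}

#' Intrinsic conception rate at a given age
#'
#' A couple's rate equals its peak until `decline_years` before its
#' sterility age, declines linearly to zero across that window, and is
#' zero from the sterility age onwards.
#'
#' @param peak Peak intrinsic conception rate(s) in `[0, 1)`.
#' @param sterility_age Female age (years) at which the couple becomes
#'   sterile.
#' @param age Current female age (years).
#' @param decline_years Length of the linear decline window (years).
#' @return Rate value(s) in `[0, 1)`.
#' @examples
#' intrinsic_rate_at_age(0.23, 45, 32.5)   # still at peak
#' intrinsic_rate_at_age(0.2, 45, 38.75)   # halfway down: 0.1
#' @export
intrinsic_rate_at_age <- function(peak, sterility_age, age,
                                  decline_years = 12.5) {
  if (any(peak < 0 | peak >= 1)) stop("'peak' must lie in [0, 1)", call. = FALSE)
  if (decline_years <= 0) stop("'decline_years' must be positive", call. = FALSE)
  peak * pmin(1, pmax(0, (sterility_age - age) / decline_years))
}

#' Initialize an aged cohort on a joint grid
#'
#' Discretizes the joint distribution of (peak rate, sterility age) for
#' couples starting to attempt conception at `start_age`. The peak axis
#' carries exact beta cell masses at cell conditional means; the
#' sterility-age axis carries CDF-increment masses at cell midpoints, one
#' cell per cycle. Couples already sterile at `start_age` (including any
#' sterile mass before the first anchor age) are merged into a single
#' atom, since their future behaviour is identical.
#'
#' @param spec An [ageing_spec()].
#' @param start_age Female age (years) at the start of the attempt.
#' @param grid_sizes Two integers: number of peak-rate cells and number of
#'   sterility-age cells per year (defaults 513 and `cycles_per_year`).
#' @return An object of class `aged_cohort_state` with fields
#'   `peak_nodes`, `sterility_age_nodes`, `weights` (matrix, peak by age),
#'   `sterile_mass`, `start_age`, `current_age`, `cycles_elapsed` and
#'   `survival`.
#' @examples
#' st <- initialize_cohort(ageing_spec(), 25, grid_sizes = c(65, 12))
#' st$sterile_mass
#' @export
initialize_cohort <- function(spec, start_age,
                              grid_sizes = c(513, spec$cycles_per_year)) {
  stopifnot(inherits(spec, "ageing_spec"))
  ages <- spec$anchors$age
  if (start_age < min(ages) || start_age >= max(ages))
    stop(sprintf("'start_age' must lie in [%g, %g)", min(ages), max(ages)),
         call. = FALSE)
  kp <- as.integer(grid_sizes[1L])
  steps <- as.integer(grid_sizes[2L])
  if (kp < 64L)
    stop("peak grid too coarse: need at least 64 cells", call. = FALSE)
  if (steps < 1L)
    stop("need at least one sterility-age cell per year", call. = FALSE)
  if ((max(ages) - min(ages)) * steps < 64)
    stop("sterility-age grid too coarse: need at least 64 cells", call. = FALSE)

  ## peak axis: exact beta masses, conditional-mean nodes
  pe <- seq(0, 1, length.out = kp + 1L)
  dF <- pbeta(pe[-1L], spec$peak_alpha, spec$peak_beta) -
        pbeta(pe[-(kp + 1L)], spec$peak_alpha, spec$peak_beta)
  mu <- spec$peak_alpha / (spec$peak_alpha + spec$peak_beta)
  dM <- mu * (pbeta(pe[-1L], spec$peak_alpha + 1, spec$peak_beta) -
              pbeta(pe[-(kp + 1L)], spec$peak_alpha + 1, spec$peak_beta))
  peak_nodes <- ifelse(dF > 0, dM / pmax(dF, .Machine$double.xmin),
                       (pe[-1L] + pe[-(kp + 1L)]) / 2)
  peak_nodes <- pmin(peak_nodes, 1 - .Machine$double.eps)

  ## sterility-age axis: CDF increments at cell midpoints
  te <- seq(min(ages), max(ages), by = 1 / steps)
  if (te[length(te)] < max(ages)) te <- c(te, max(ages))
  tmass <- spec$sterility_age_cdf(te[-1L]) -
           spec$sterility_age_cdf(te[-length(te)])
  tnodes <- (te[-1L] + te[-length(te)]) / 2

  ## already sterile: before-first-anchor atom plus cells at or below start
  keep <- tnodes > start_age
  sterile <- spec$sterility_age_cdf(min(ages)) + sum(tmass[!keep])
  W <- outer(dF, tmass[keep])

  structure(list(peak_nodes = peak_nodes,
                 sterility_age_nodes = tnodes[keep],
                 weights = W,
                 sterile_mass = sterile,
                 start_age = start_age,
                 current_age = start_age,
                 cycles_elapsed = 0L,
                 survival = 1),
            class = "aged_cohort_state")
}

#' @export
print.aged_cohort_state <- function(x, ...) {
  cat(sprintf(
    "Aged cohort at age %.3f (start %.1f): %d cycles elapsed, s = %.4g, sterile %.4g\n",
    x$current_age, x$start_age, x$cycles_elapsed, x$survival,
    x$sterile_mass + sum(x$weights[, decline_factor_zero(x)])))
  invisible(x)
}

# columns whose current rate is zero (for display only)
decline_factor_zero <- function(state) {
  state$sterility_age_nodes <= state$current_age
}

# per-column linear decline factor at a given evaluation age
decline_factors <- function(state, spec, frozen = FALSE) {
  age <- if (frozen) state$start_age else state$current_age
  pmin(1, pmax(0, (state$sterility_age_nodes - age) / spec$decline_years))
}

#' Advance an aged cohort by one cycle of non-conception
#'
#' Each (peak, sterility-age) cell conceives with probability equal to its
#' current intrinsic rate, evaluated at the age at the start of the cycle.
#' Conditional on non-conception the cell weights are tilted by one minus
#' that rate and renormalized, the cohort survival is multiplied by the
#' mean non-conception probability, and age advances by one cycle.
#'
#' @param state An `aged_cohort_state`.
#' @param spec The [ageing_spec()] the state was built from.
#' @param frozen If `TRUE`, rates are held at their `start_age` values
#'   (reproductive ageing switched off during the attempt).
#' @return The advanced `aged_cohort_state`.
#' @export
advance_cycle <- function(state, spec, frozen = FALSE) {
  stopifnot(inherits(state, "aged_cohort_state"), inherits(spec, "ageing_spec"))
  f <- decline_factors(state, spec, frozen)
  C <- outer(state$peak_nodes, f)
  m <- sum(state$weights * C)
  state$weights <- state$weights * (1 - C) / (1 - m)
  state$sterile_mass <- state$sterile_mass / (1 - m)
  state$survival <- state$survival * (1 - m)
  state$current_age <- state$current_age + 1 / spec$cycles_per_year
  state$cycles_elapsed <- state$cycles_elapsed + 1L
  state
}

# weighted quantile of the induced rate distribution (atom included)
aged_quantile <- function(y, w, atom, q) {
  if (atom >= q) return(0)
  o <- order(y)
  ys <- y[o]; ws <- w[o]
  pos <- ys > 0
  cum <- atom + cumsum(ws[pos])
  i <- which(cum >= q)[1L]
  if (is.na(i)) return(ys[length(ys)])
  ys[pos][i]
}

#' Fertility metrics under reproductive ageing
#'
#' The ageing counterpart of [metrics_table()]: per-cycle metrics for a
#' cohort starting at `start_age`, computed on the induced distribution of
#' the current intrinsic rate (mass at zero rate — couples already sterile
#' — forms the atom). Forward-looking columns account for continuing
#' decline during the forward horizon.
#'
#' @inheritParams initialize_cohort
#' @param n_max Largest elapsed-cycle count (default 36).
#' @param horizons Forward horizons in cycles for the conceiving-within
#'   columns.
#' @param frozen If `TRUE`, hold every couple's rate at its `start_age`
#'   value throughout (no ageing during the attempt).
#' @return A data.frame in the same layout as [metrics_table()].
#' @examples
#' aged_metrics_table(ageing_spec(), 35, n_max = 3,
#'                    grid_sizes = c(65, 4), horizons = 12)
#' @export
aged_metrics_table <- function(spec, start_age, n_max = 36,
                               grid_sizes = c(513, spec$cycles_per_year),
                               horizons = c(12, 24), frozen = FALSE) {
  if (length(n_max) != 1L || n_max < 1 || n_max != floor(n_max))
    stop("'n_max' must be a single positive integer", call. = FALSE)
  state <- initialize_cohort(spec, start_age, grid_sizes)
  hmax <- if (length(horizons)) max(horizons) else 0L
  s <- numeric(n_max + hmax + 1L)
  rows <- vector("list", n_max + 1L)
  for (n in 0:(n_max + hmax)) {
    s[n + 1L] <- state$survival
    if (n <= n_max) {
      f <- decline_factors(state, spec, frozen)
      C <- outer(state$peak_nodes, f)
      y <- as.vector(C)
      w <- as.vector(state$weights)
      atom <- state$sterile_mass + sum(w[y == 0])
      rows[[n + 1L]] <- data.frame(
        cycles_elapsed = n,
        prop_sterile = atom,
        median_rate = aged_quantile(y, w, atom, 0.5),
        p90_rate = aged_quantile(y, w, atom, 0.9),
        p_next_cycle = sum(w * y),
        cumulative = 1 - state$survival)
    }
    state <- advance_cycle(state, spec, frozen)
  }
  out <- do.call(rbind, rows)
  for (h in horizons)
    out[[sprintf("p_next_%d", h)]] <-
      1 - s[out$cycles_elapsed + 1L + h] / s[out$cycles_elapsed + 1L]
  ord <- c("cycles_elapsed", "prop_sterile", "median_rate", "p90_rate",
           "p_next_cycle", sprintf("p_next_%d", horizons), "cumulative")
  out[, ord]
}

#' Cycles to a subfertility threshold under ageing
#'
#' Smallest number of elapsed non-conception cycles at which the policy's
#' metric first falls strictly below its threshold, for a cohort ageing
#' from `start_age`. `NA` if not reached by `n_max`.
#'
#' @inheritParams aged_metrics_table
#' @param policy A [threshold_policy()].
#' @param n_max Scan limit (default 60).
#' @return A single integer, or `NA_integer_`.
#' @export
aged_cycles_to_threshold <- function(spec, start_age, policy, n_max = 60,
                                     grid_sizes = c(513, spec$cycles_per_year),
                                     frozen = FALSE) {
  if (!inherits(policy, "threshold_policy"))
    stop("'policy' must be a threshold_policy", call. = FALSE)
  tab <- aged_metrics_table(spec, start_age, n_max = n_max,
                            grid_sizes = grid_sizes, horizons = 12,
                            frozen = frozen)
  hit <- which(tab[[policy$metric]] < policy$threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(tab$cycles_elapsed[hit[1L]])
}

#' Effect of ignoring ageing during the attempt
#'
#' Difference in cycles-to-threshold between a model with reproductive
#' ageing switched off during the attempt (rates frozen at their
#' `start_age` values) and the full ageing model. Non-negative: ignoring
#' ongoing decline can only delay the flag.
#'
#' @inheritParams aged_cycles_to_threshold
#' @return Integer difference (frozen minus ageing), `NA` if either scan
#'   does not reach the threshold.
#' @export
frozen_ageing_delta <- function(spec, start_age, policy, n_max = 60,
                                grid_sizes = c(513, spec$cycles_per_year)) {
  aged_cycles_to_threshold(spec, start_age, policy, n_max, grid_sizes,
                           frozen = TRUE) -
    aged_cycles_to_threshold(spec, start_age, policy, n_max, grid_sizes,
                             frozen = FALSE)
}
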