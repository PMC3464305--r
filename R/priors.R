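#' Beta mixture component for the intrinsic conception rate
#'
#' A (possibly rescaled) beta density used as one continuous component of a
#' prior for the intrinsic conception rate. With `scale_max = c < 1` the
#' standard beta variate is compressed onto `[0, c]` by a linear change of
#' variable, so that the maximum attainable rate is `c` ("compressed beta").
#'
#' @param alpha,beta Positive shape parameters.
#' @param weight Mixture weight in `[0, 1]`.
#' @param scale_max Upper support bound in `(0, 1]`; `1` gives the standard
#'   beta distribution on `[0, 1]`.
#' @return An object of class `beta_component`.
#' @examples
#' beta_component(2.3, 3.7, weight = 0.95)
#' @export
beta_component <- function(alpha, beta, weight = 1, scale_max = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha <= 0 || beta <= 0)
    stop("beta component shape parameters must be positive", call. = FALSE)
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0 || weight > 1)
    stop("'weight' must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(scale_max) || length(scale_max) != 1L ||
      scale_max <= 0 || scale_max > 1)
    stop("'scale_max' must lie in (0, 1]", call. = FALSE)
  structure(list(type = "beta", alpha = alpha, beta = beta,
                 weight = weight, scale_max = scale_max),
            class = c("beta_component", "prior_component"))
}

#' Triangular mixture component for the intrinsic conception rate
#'
#' @param lower,mode,upper Support limits and mode, with
#'   `0 <= lower <= mode <= upper <= 1` and `lower < upper`.
#' @param weight Mixture weight in `[0, 1]`.
#' @return An object of class `triangular_component`.
#' @examples
#' triangular_component(0, 0.2, 0.6)
#' @export
triangular_component <- function(lower, mode, upper, weight = 1) {
  stopifnot(is.numeric(lower), is.numeric(mode), is.numeric(upper))
  if (!(lower <= mode && mode <= upper))
    stop("need lower <= mode <= upper", call. = FALSE)
  if (lower >= upper)
    stop("need lower < upper", call. = FALSE)
  if (lower < 0 || upper > 1)
    stop("triangular support must lie within [0, 1]", call. = FALSE)
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0 || weight > 1)
    stop("'weight' must be a single number in [0, 1]", call. = FALSE)
  structure(list(type = "triangular", lower = lower, mode = mode,
                 upper = upper, weight = weight),
            class = c("triangular_component", "prior_component"))
}

#' Prior specification for the intrinsic conception rate
#'
#' Combines a sterile point mass at `y = 0` with a weighted mixture of
#' continuous components on `[0, 1)`. The sterile fraction and the component
#' weights must sum to one.
#'
#' @param sterile_fraction Probability mass at `y = 0`, in `[0, 1]`.
#' @param components List of [beta_component()] / [triangular_component()]
#'   objects (may be empty when `sterile_fraction == 1`).
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec(0.05, list(beta_component(2.3, 3.7, weight = 0.95)))
#' @export
prior_spec <- function(sterile_fraction, components = list()) {
  if (!is.numeric(sterile_fraction) || length(sterile_fraction) != 1L ||
      sterile_fraction < 0 || sterile_fraction > 1)
    stop("'sterile_fraction' must be a single number in [0, 1]", call. = FALSE)
  if (inherits(components, "prior_component")) components <- list(components)
  ok <- vapply(components, inherits, logical(1), "prior_component")
  if (!all(ok))
    stop("'components' must be a list of prior components", call. = FALSE)
  w <- vapply(components, `[[`, numeric(1), "weight")
  total <- sterile_fraction + sum(w)
  if (abs(total - 1) > 1e-12)
    stop(sprintf(
      "sterile_fraction plus component weights must sum to 1 (got %.15g)",
      total), call. = FALSE)
  structure(list(sterile_fraction = sterile_fraction, components = components),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Prior for the intrinsic conception rate\n"))
  cat(sprintf("  sterile fraction: %g\n", x$sterile_fraction))
  for (cp in x$components) {
    if (cp$type == "beta") {
      cat(sprintf("  beta(alpha = %g, beta = %g)%s, weight %g\n",
                  cp$alpha, cp$beta,
                  if (cp$scale_max < 1)
                    sprintf(" compressed to [0, %g]", cp$scale_max) else "",
                  cp$weight))
    } else {
      cat(sprintf("  triangular(%g, %g, %g), weight %g\n",
                  cp$lower, cp$mode, cp$upper, cp$weight))
    }
  }
  invisible(x)
}

#' Bundled example prior populations
#'
#' Four preset populations used throughout the package's documentation and
#' tests: (1) 5% sterile plus Beta(2.3, 3.7) — a relatively fertile cohort;
#' (2) 5% sterile plus Beta(1.8, 4.2) — systematically less fertile;
#' (3) 1% sterile plus Beta(11, 22) — homogeneous and fertile;
#' (4) 5% sterile plus a two-beta mixture, 85% Beta(11, 22) and
#' 10% Beta(4, 76) — distinct fertile and subfertile subpopulations.
#'
#' @param name One of `"example1"`, `"example2"`, `"example3"`, `"example4"`.
#' @return A [prior_spec()].
#' @examples
#' example_prior("example1")
#' @export
example_prior <- function(name = c("example1", "example2",
                                   "example3", "example4")) {
  name <- match.arg(name)
  switch(name,
    example1 = prior_spec(0.05, list(beta_component(2.3, 3.7, weight = 0.95))),
    example2 = prior_spec(0.05, list(beta_component(1.8, 4.2, weight = 0.95))),
    example3 = prior_spec(0.01, list(beta_component(11, 22, weight = 0.99))),
    example4 = prior_spec(0.05, list(beta_component(11, 22, weight = 0.85),
                                     beta_component(4, 76, weight = 0.10))))
}

#' Density of a single prior component
#'
#' Normalized density of one mixture component at rate `y` (the component
#' weight is not applied). Zero outside the component's support.
#'
#' @param component A [beta_component()] or [triangular_component()].
#' @param y Vector of rates in `[0, 1)`.
#' @return Non-negative densities, same length as `y`.
#' @examples
#' component_pdf(beta_component(2, 2), 0.5)  # 1.5
#' @export
component_pdf <- function(component, y) {
  if (!inherits(component, "prior_component"))
    stop("'component' must be a prior component", call. = FALSE)
  if (any(y < 0 | y >= 1)) stop("'y' must lie in [0, 1)", call. = FALSE)
  if (component$type == "beta") {
    c0 <- component$scale_max
    out <- numeric(length(y))
    inside <- y < c0
    out[inside] <- dbeta(y[inside] / c0, component$alpha, component$beta) / c0
    out
  } else {
    tri_pdf(y, component$lower, component$mode, component$upper)
  }
}

## --- triangular closed forms (density, CDF, first moment) ----------------

tri_pdf <- function(y, l, m, u) {
  out <- numeric(length(y))
  if (m > l) {
    i <- y >= l & y <= m
    out[i] <- 2 * (y[i] - l) / ((u - l) * (m - l))
  }
  if (u > m) {
    i <- y > m & y <= u
    out[i] <- 2 * (u - y[i]) / ((u - l) * (u - m))
  }
  out
}

tri_cdf <- function(y, l, m, u) {
  y <- pmin(pmax(y, l), u)
  out <- numeric(length(y))
  if (m > l) {
    i <- y <= m
    out[i] <- (y[i] - l)^2 / ((u - l) * (m - l))
  } else out[y <= m] <- 0
  i <- y > m
  out[i] <- 1 - (u - y[i])^2 / ((u - l) * (u - m))
  out
}

# int_l^y t * pdf(t) dt, vectorized
tri_moment <- function(y, l, m, u) {
  y <- pmin(pmax(y, l), u)
  m1 <- function(t) { # within [l, m]
    if (m == l) return(numeric(length(t)))
    2 / ((u - l) * (m - l)) * (t^3 / 3 - l * t^2 / 2 - (l^3 / 3 - l^3 / 2))
  }
  m2 <- function(t) { # within [m, u], measured from m
    if (u == m) return(numeric(length(t)))
    2 / ((u - l) * (u - m)) * (u * (t^2 - m^2) / 2 - (t^3 - m^3) / 3)
  }
  atm <- if (m > l) m1(m) else 0
  out <- numeric(length(y))
  lo <- y <= m
  out[lo] <- m1(y[lo])
  out[!lo] <- atm + m2(y[!lo])
  out
}

## --- per-component cell mass and first moment on [a, b] ------------------

component_cell_mass <- function(component, a, b) {
  if (component$type == "beta") {
    c0 <- component$scale_max
    pbeta(pmin(b, c0) / c0, component$alpha, component$beta) -
      pbeta(pmin(a, c0) / c0, component$alpha, component$beta)
  } else {
    tri_cdf(b, component$lower, component$mode, component$upper) -
      tri_cdf(a, component$lower, component$mode, component$upper)
  }
}

component_cell_moment <- function(component, a, b) {
  if (component$type == "beta") {
    c0 <- component$scale_max
    al <- component$alpha; be <- component$beta
    mu <- c0 * al / (al + be)
    mu * (pbeta(pmin(b, c0) / c0, al + 1, be) -
          pbeta(pmin(a, c0) / c0, al + 1, be))
  } else {
    tri_moment(b, component$lower, component$mode, component$upper) -
      tri_moment(a, component$lower, component$mode, component$upper)
  }
}

#' Discretize a prior onto a computational grid
#'
#' Carries the continuous part of the prior as per-cell probability masses:
#' the grid divides `[0, 1)` into `grid_size` equal cells, each holding its
#' exact mixture mass (computed from the component CDFs) located at the
#' cell's conditional mean. The sterile point mass is kept as a separate
#' scalar atom, never smeared onto the grid. Total mass is therefore exactly
#' one, and the grid mean equals the analytic prior mean to floating-point
#' accuracy.
#'
#' @param spec A [prior_spec()].
#' @param grid_size Number of grid cells (at least 64; default 8193).
#' @return An object of class `discretized_distribution` with fields
#'   `edges` (cell boundaries, length `grid_size + 1`), `nodes` (cell
#'   representative points), `mass` (cell probabilities), `density`
#'   (mixture density at the nodes) and `atom_mass`.
#' @examples
#' d <- build_prior(example_prior("example1"))
#' d$atom_mass + sum(d$mass)  # 1
#' @export
build_prior <- function(spec, grid_size = 8193) {
  if (!inherits(spec, "prior_spec"))
    stop("'spec' must be a prior_spec", call. = FALSE)
  if (!is.numeric(grid_size) || length(grid_size) != 1L || grid_size < 64)
    stop("'grid_size' must be a single integer >= 64", call. = FALSE)
  grid_size <- as.integer(grid_size)
  edges <- seq(0, 1, length.out = grid_size + 1L)
  a <- edges[-(grid_size + 1L)]
  b <- edges[-1L]
  mass <- numeric(grid_size)
  mom <- numeric(grid_size)
  for (cp in spec$components) {
    mass <- mass + cp$weight * component_cell_mass(cp, a, b)
    mom <- mom + cp$weight * component_cell_moment(cp, a, b)
  }
  mass <- pmax(mass, 0)
  nodes <- ifelse(mass > 0, mom / pmax(mass, .Machine$double.xmin), (a + b) / 2)
  nodes <- pmin(pmax(nodes, a), pmin(b, 1 - .Machine$double.eps))
  dens <- numeric(grid_size)
  for (cp in spec$components)
    dens <- dens + cp$weight * component_pdf(cp, pmin(nodes, 1 - 1e-15))
  new_distribution(edges, nodes, mass, dens, spec$sterile_fraction)
}

new_distribution <- function(edges, nodes, mass, density, atom_mass) {
  structure(list(edges = edges, nodes = nodes, mass = mass,
                 density = density, atom_mass = atom_mass),
            class = "discretized_distribution")
}

validate_distribution <- function(dist, tol = 1e-9) {
  stopifnot(inherits(dist, "discretized_distribution"))
  total <- dist$atom_mass + sum(dist$mass)
  if (abs(total - 1) > tol)
    stop(sprintf("distribution mass %.12g differs from 1", total),
         call. = FALSE)
  invisible(dist)
}

#' @export
print.discretized_distribution <- function(x, ...) {
  cat(sprintf(
    "Discretized rate distribution: %d cells on [0, 1), atom %.4g, mean %.4g\n",
    length(x$mass), x$atom_mass, sum(x$mass * x$nodes)))
  invisible(x)
}

# coerce prior_spec -> discretized_distribution where either is accepted
as_distribution <- function(x, grid_size = 8193) {
  if (inherits(x, "discretized_distribution")) return(x)
  if (inherits(x, "prior_spec")) return(build_prior(x, grid_size))
  stop("expected a prior_spec or discretized_distribution", call. = FALSE)
}
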