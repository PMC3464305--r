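#' Read and write prior specifications as YAML
#'
#' A prior is stored as a flat mapping: `sterile_fraction`, then
#' `components`, a list of mappings each with `type` (`beta` or
#' `triangular`), its parameters and `weight`. Round-trips are lossless to
#' full double precision.
#'
#' @param spec A [prior_spec()].
#' @param path File path.
#' @return `write_prior_spec` returns `path` invisibly; `read_prior_spec`
#'   returns a [prior_spec()].
#' @examples
#' p <- file.path(tempdir(), "prior.yaml")
#' write_prior_spec(example_prior("example4"), p)
#' read_prior_spec(p)
#' @export
write_prior_spec <- function(spec, path) {
  stopifnot(inherits(spec, "prior_spec"))
  obj <- list(
    sterile_fraction = spec$sterile_fraction,
    components = lapply(spec$components, function(cp) {
      if (cp$type == "beta")
        list(type = "beta", alpha = cp$alpha, beta = cp$beta,
             weight = cp$weight, scale_max = cp$scale_max)
      else
        list(type = "triangular", lower = cp$lower, mode = cp$mode,
             upper = cp$upper, weight = cp$weight)
    }))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_prior_spec
#' @export
read_prior_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$sterile_fraction))
    stop(sprintf("'%s': missing sterile_fraction", path), call. = FALSE)
  comps <- lapply(obj$components, function(cp) {
    if (is.null(cp$type))
      stop(sprintf("'%s': component without a type", path), call. = FALSE)
    switch(cp$type,
      beta = beta_component(cp$alpha, cp$beta, cp$weight,
                            if (is.null(cp$scale_max)) 1 else cp$scale_max),
      triangular = triangular_component(cp$lower, cp$mode, cp$upper,
                                        cp$weight),
      stop(sprintf("'%s': unknown component type '%s'", path, cp$type),
           call. = FALSE))
  })
  prior_spec(obj$sterile_fraction, comps)
}

#' Read and write ageing specifications as YAML
#'
#' Same dialect as [write_prior_spec()]: scalar fields plus an explicit
#' `anchors` list of `(age, fraction)` pairs.
#'
#' @param spec An [ageing_spec()].
#' @param path File path.
#' @return `write_ageing_spec` returns `path` invisibly;
#'   `read_ageing_spec` returns an [ageing_spec()].
#' @export
write_ageing_spec <- function(spec, path) {
  stopifnot(inherits(spec, "ageing_spec"))
  obj <- list(peak_alpha = spec$peak_alpha, peak_beta = spec$peak_beta,
              decline_years = spec$decline_years,
              cycles_per_year = spec$cycles_per_year,
              anchors = lapply(seq_len(nrow(spec$anchors)), function(i)
                list(age = spec$anchors$age[i],
                     fraction = spec$anchors$fraction[i])))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_ageing_spec
#' @export
read_ageing_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  anchors <- data.frame(
    age = vapply(obj$anchors, `[[`, numeric(1), "age"),
    fraction = vapply(obj$anchors, `[[`, numeric(1), "fraction"))
  ageing_spec(peak_alpha = obj$peak_alpha, peak_beta = obj$peak_beta,
              decline_years = obj$decline_years, anchors = anchors,
              cycles_per_year = obj$cycles_per_year)
}
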