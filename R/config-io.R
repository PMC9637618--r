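#' Serialize a generator configuration to YAML (and read it back)
#'
#' Round-trips every field needed to reproduce a two-wave simulation:
#' sample sizes, per-sex true partial matrices, margin specifications,
#' missingness, attrition model, wave-2 shift, autocorrelation, frozen
#' traits and seed. The bundled scenario lives at
#' `system.file("extdata", "fixture_scenario.yaml", package = "rankggm")`.
#'
#' @param config a [generator_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the reconstructed `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  doc <- list(
    n_per_sex = as.list(config$n_per_sex),
    true_partials = lapply(config$true_partials, function(m)
      apply(unname(m), 1, as.list)),
    margins = lapply(config$margins, function(sp) unclass(sp)),
    missing_rate = as.list(config$missing_rate),
    attrition = config$attrition,
    wave2_shift = as.list(config$wave2_shift),
    autocorr = config$autocorr,
    frozen = as.list(config$frozen),
    seed = config$seed)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  doc <- yaml::read_yaml(path)
  partials <- lapply(doc$true_partials, function(rows)
    do.call(rbind, lapply(rows, unlist)))
  margins <- lapply(doc$margins, function(sp) {
    kind <- sp$kind
    sp$kind <- NULL
    sp$cutpoints <- if (!is.null(sp$cutpoints)) unlist(sp$cutpoints)
    do.call(margin_spec, c(list(kind = kind),
                           sp[!vapply(sp, is.null, NA)]))
  })
  generator_config(n_per_sex = unlist(doc$n_per_sex),
                   true_partials = partials, margins = margins,
                   missing_rate = unlist(doc$missing_rate),
                   attrition = doc$attrition,
                   wave2_shift = unlist(doc$wave2_shift),
                   autocorr = doc$autocorr, frozen = unlist(doc$frozen),
                   seed = doc$seed)
}
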