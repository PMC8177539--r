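#' Read and write synthetic configurations as YAML
#'
#' A [synth_config()] serializes losslessly to YAML: data.frames become
#' column maps, named numeric vectors become maps, and are reconstructed
#' on read.
#'
#' @param config a [synth_config()].
#' @param path YAML file path.
#' @return `write_synth_config()` returns `path` invisibly;
#'   `read_synth_config()` returns a validated [synth_config()].
#' @export
write_synth_config <- function(config, path) {
  x <- unclass(config)
  x$horses <- as.list(x$horses)
  x$codes <- as.list(x$codes)
  x$multipliers <- lapply(x$multipliers, as.list)
  x$ear_flicker$prob <- as.list(x$ear_flicker$prob)
  x$hr$baseline_mean <- as.list(x$hr$baseline_mean)
  x$hr$baseline_sd <- as.list(x$hr$baseline_sd)
  x$hr$shift <- lapply(x$hr$shift, as.list)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$horses <- data.frame(lapply(x$horses, unlist),
                         stringsAsFactors = FALSE)
  x$codes <- data.frame(lapply(x$codes, unlist), stringsAsFactors = FALSE)
  x$conditions <- lapply(x$conditions, unlist)
  x$multipliers <- lapply(x$multipliers, function(m) unlist(m))
  x$ear_flicker$prob <- unlist(x$ear_flicker$prob)
  x$hr$baseline_mean <- unlist(x$hr$baseline_mean)
  x$hr$baseline_sd <- unlist(x$hr$baseline_sd)
  x$hr$shift <- lapply(x$hr$shift, unlist)
  x$couplings <- lapply(x$couplings, function(cp) {
    cp$conditions <- unlist(cp$conditions)
    cp
  })
  cfg <- structure(x, class = "synth_config")
  validate_synth_config(cfg)
  cfg
}
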