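#' Read a YAML run configuration
#'
#' A run configuration bundles everything a pipeline invocation needs:
#' the marker map, the condition labels, a simulator block and a seed.
#' Recognised top-level fields:
#'
#' * `markers`: list of `{name, channel, position}` entries (required for
#'   stages that classify tetrads);
#' * `mode`: `"two-color"` or `"three-color"` (checked against the map);
#' * `sim`: any arguments of [sim_config()];
#' * `seed`: integer, overridable on the command line.
#'
#' The parsed configuration is validated before any stage runs.
#'
#' @param path path to a YAML file.
#' @return A list of class `run_config` with elements `map` (a
#'   [marker_map()] or `NULL`), `mode`, `sim` (a [sim_config()]), `seed`,
#'   and `raw` (the YAML contents, echoed verbatim into run logs).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  map <- NULL
  if (!is.null(raw$markers)) {
    mk <- raw$markers
    # YAML 1.1 reads bare Y/N as logicals; map those back to channel letters
    chan <- vapply(mk, function(m) {
      v <- m$channel
      if (is.logical(v)) v <- if (v) "Y" else "N"
      as.character(v)
    }, "")
    map <- marker_map(vapply(mk, function(m) as.character(m$name), ""),
                      chan,
                      vapply(mk, function(m) as.numeric(m$position), 0))
  }
  mode <- raw$mode
  if (!is.null(mode)) {
    if (!mode %in% c("two-color", "three-color"))
      stop("mode must be 'two-color' or 'three-color'")
    if (!is.null(map)) {
      want <- if (mode == "two-color") 2L else 3L
      if (nrow(map) != want)
        stop("mode '", mode, "' expects ", want, " markers, got ", nrow(map))
    }
  }
  sim_args <- if (is.null(raw$sim)) list() else raw$sim
  if (!is.null(raw$seed) && is.null(sim_args$seed)) sim_args$seed <- raw$seed
  sim <- do.call(sim_config, sim_args)
  out <- list(map = map, mode = mode, sim = sim,
              seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
              raw = raw)
  class(out) <- "run_config"
  out
}
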