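#' Define an FTL marker map
#'
#' A marker map describes an ordered set of pollen-expressed fluorescent
#' transgene insertions (FTL markers) on one chromosome: a name, a single
#' fluorescent channel letter, and a genetic position in centimorgans.  All
#' markers are assumed to be in coupling, i.e. carried on the same parental
#' homolog, which is the configuration under which the PD/T/NPD tetrad
#' classes have their textbook meaning.
#'
#' @param name character vector of marker names.
#' @param channel character vector of single-letter fluorescent channel
#'   labels (e.g. `"C"`, `"Y"`, `"R"`); must be unique.
#' @param position_cM numeric vector of genetic positions in cM; must be
#'   strictly increasing.
#' @return An object of class `marker_map`: a data frame with columns
#'   `name`, `channel`, `position_cM`.
#' @examples
#' marker_map(c("FTL1963", "FTL1143", "FTL2450"), c("C", "Y", "R"),
#'            c(0, 5, 13))
#' @export
marker_map <- function(name, channel, position_cM) {
  name <- as.character(name)
  channel <- as.character(channel)
  position_cM <- as.numeric(position_cM)
  if (length(name) < 2L)
    stop("a marker map needs at least two markers")
  if (length(channel) != length(name) || length(position_cM) != length(name))
    stop("name, channel and position_cM must have equal length")
  if (anyDuplicated(name))
    stop("marker names must be unique")
  if (anyDuplicated(channel))
    stop("channel labels must be unique")
  if (any(nchar(channel) != 1L))
    stop("channel labels must be single characters")
  if (any(diff(position_cM) <= 0))
    stop("positions must be strictly increasing")
  map <- data.frame(name = name, channel = channel, position_cM = position_cM,
                    stringsAsFactors = FALSE)
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Built-in synthetic FTL interval maps
#'
#' Returns a `marker_map` for one of the marker configurations used
#' throughout the package examples: the two-colour intervals `"I1a"` and
#' `"I3a"` and the three-colour `"I5cd"` configuration (markers FTL1963,
#' FTL1143 and FTL2450 carrying CFP, YFP and dsRED, read here as channels
#' C/Y/R).  The genetic sizes are synthetic defaults chosen to be
#' representative of small FTL intervals; they are not measured values.
#'
#' @param interval one of `"I1a"`, `"I3a"`, `"I5cd"`.
#' @return A [marker_map()].
#' @examples
#' ftl_preset("I5cd")
#' @export
ftl_preset <- function(interval = c("I3a", "I1a", "I5cd")) {
  interval <- match.arg(interval)
  switch(interval,
    I3a  = marker_map(c("I3a_L", "I3a_R"), c("Y", "R"), c(0, 6)),
    I1a  = marker_map(c("I1a_L", "I1a_R"), c("Y", "R"), c(0, 10)),
    I5cd = marker_map(c("FTL1963", "FTL1143", "FTL2450"), c("C", "Y", "R"),
                      c(0, 5, 13)))
}

#' @export
print.marker_map <- function(x, ...) {
  cat("FTL marker map (", nrow(x), " markers, coupling phase)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# resolve a marker pair given as names, channels or indices; returns indices
marker_pair_index <- function(map, pair) {
  if (length(pair) != 2L) stop("a marker pair must have exactly two elements")
  if (is.numeric(pair)) {
    idx <- as.integer(pair)
  } else {
    idx <- match(pair, map$name)
    if (anyNA(idx)) idx <- match(pair, map$channel)
  }
  if (anyNA(idx) || any(idx < 1L) || any(idx > nrow(map)))
    stop("unknown markers: ", paste(pair, collapse = ", "))
  if (idx[1] == idx[2]) stop("marker pair must name two distinct markers")
  sort(idx)
}
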