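#' Classify one tetrad for a marker pair
#'
#' Projects a four-grain tetrad onto a pair of coupling-phase markers and
#' assigns the classical tetrad class: parental ditype (`PD`, two grains
#' with both channels and two with neither), tetratype (`T`, one grain of
#' each phenotype), or non-parental ditype (`NPD`, two grains with only the
#' first channel and two with only the second).  Any pattern impossible for
#' a true tetrad from a coupling heterozygote — e.g. 3:1 segregation of a
#' channel, caused by transgene silencing or an aborted grain — is classed
#' `OTHER` and excluded from linkage statistics.
#'
#' @param grains character vector of 4 grain phenotype strings (channel
#'   letters in any order, `"-"` for a blank grain).
#' @param map a [marker_map()].
#' @param pair the two markers, given as names, channel letters or indices.
#' @return One of `"PD"`, `"T"`, `"NPD"`, `"OTHER"`.
#' @examples
#' map <- ftl_preset("I3a")
#' classify_interval(c("YR", "YR", "-", "-"), map, c("I3a_L", "I3a_R"))  # PD
#' classify_interval(c("YR", "Y", "R", "-"), map, c("Y", "R"))           # T
#' @export
classify_interval <- function(grains, map, pair) {
  stopifnot(inherits(map, "marker_map"))
  if (length(grains) != 4L) stop("a tetrad has exactly 4 grains")
  check_grain_channels(grains, map)
  idx <- marker_pair_index(map, pair)
  cls <- classify_vec(matrix(grains, nrow = 1L), map$channel[idx[1]],
                      map$channel[idx[2]])
  as.character(cls)
}

check_grain_channels <- function(grains, map) {
  letters_used <- unique(unlist(strsplit(gsub("-", "", grains), "")))
  bad <- setdiff(letters_used, map$channel)
  if (length(bad))
    stop("unknown channel label(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

# Vectorised classification: grains is an n x 4 character matrix.
classify_vec <- function(grains, chan_a, chan_b) {
  has_a <- matrix(grepl(chan_a, grains, fixed = TRUE), nrow = nrow(grains))
  has_b <- matrix(grepl(chan_b, grains, fixed = TRUE), nrow = nrow(grains))
  na <- rowSums(has_a); nb <- rowSums(has_b)
  nab <- rowSums(has_a & has_b); n0 <- rowSums(!has_a & !has_b)
  cls <- rep("OTHER", nrow(grains))
  ok <- na == 2L & nb == 2L            # 2:2 segregation of both channels
  cls[ok & nab == 2L & n0 == 2L] <- "PD"
  cls[ok & nab == 1L & n0 == 1L] <- "T"
  cls[ok & nab == 0L & n0 == 0L] <- "NPD"
  factor(cls, levels = c("PD", "T", "NPD", "OTHER"))
}

grain_matrix <- function(dataset) {
  cols <- paste0("grain", 1:4)
  if (!all(cols %in% names(dataset)))
    stop("dataset must have columns grain1..grain4")
  as.matrix(dataset[, cols])
}

dataset_map <- function(dataset, map) {
  if (is.null(map)) map <- attr(dataset, "marker_map")
  if (is.null(map)) stop("no marker map supplied and none attached to the dataset")
  stopifnot(inherits(map, "marker_map"))
  map
}

#' Tabulate tetrad classes for a marker pair
#'
#' Classifies every tetrad in a dataset for one marker pair and tallies
#' PD/T/NPD/OTHER counts, optionally split by condition columns.  `n` is
#' `PD + T + NPD`; `OTHER` tetrads are tallied but never enter linkage
#' statistics.
#'
#' @param dataset a `tetrad_data` data frame (see
#'   [simulate_tetrad_dataset()] or [read_tetrad_table()]).
#' @param pair the marker pair (names, channels or indices).
#' @param map a [marker_map()]; defaults to the map attached to `dataset`.
#' @param group_by character vector of grouping columns present in
#'   `dataset` (default `c("genotype", "temperature")`), or `NULL` for a
#'   single pooled row.
#' @return A data frame of class `class_counts` with the grouping columns
#'   and `PD`, `T`, `NPD`, `OTHER`, `n`, `interval`.
#' @examples
#' cfg <- sim_config(n_meioses = 300, seed = 2)
#' td <- simulate_tetrad_dataset(cfg, ftl_preset("I3a"))
#' tabulate_tetrads(td, c("Y", "R"))
#' @export
tabulate_tetrads <- function(dataset, pair, map = NULL,
                             group_by = c("genotype", "temperature")) {
  map <- dataset_map(dataset, map)
  idx <- marker_pair_index(map, pair)
  gm <- grain_matrix(dataset)
  check_grain_channels(as.vector(gm), map)
  cls <- classify_vec(gm, map$channel[idx[1]], map$channel[idx[2]])
  interval <- paste(map$name[idx], collapse = "-")
  group_by <- intersect(group_by, names(dataset))
  if (length(group_by)) {
    key <- interaction(dataset[group_by], drop = TRUE, sep = "\r")
  } else {
    key <- factor(rep("all", nrow(dataset)), levels = "all")
  }
  tab <- table(key, cls)
  out <- data.frame(PD = as.integer(tab[, "PD"]),
                    T = as.integer(tab[, "T"]),
                    NPD = as.integer(tab[, "NPD"]),
                    OTHER = as.integer(tab[, "OTHER"]))
  if (length(group_by)) {
    labs <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
    labs <- as.data.frame(labs, stringsAsFactors = FALSE)
    names(labs) <- group_by
    out <- cbind(labs, out)
  }
  out$n <- out$PD + out$T + out$NPD
  out$interval <- interval
  rownames(out) <- NULL
  class(out) <- c("class_counts", "data.frame")
  out
}

#' Construct a PD/T/NPD count record directly
#'
#' @param PD,T,NPD,OTHER non-negative integer tallies.
#' @param interval,condition optional labels.
#' @return A one-row `class_counts` data frame.
#' @examples
#' class_counts(PD = 70, T = 28, NPD = 2)
#' @export
class_counts <- function(PD, T, NPD, OTHER = 0L, interval = NA_character_,
                         condition = NA_character_) {
  v <- c(PD = PD, T = T, NPD = NPD, OTHER = OTHER)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  out <- data.frame(condition = condition, PD = as.integer(PD), T = as.integer(T),
                    NPD = as.integer(NPD), OTHER = as.integer(OTHER),
                    n = as.integer(PD + T + NPD), interval = interval,
                    stringsAsFactors = FALSE)
  class(out) <- c("class_counts", "data.frame")
  out
}

#' Partition tetrads by crossover status in an adjacent interval
#'
#' Implements the conditioning used for interference analysis with three
#' linked markers: tetrads are split by whether the conditioning interval
#' shows a crossover (class `T` or `NPD`; `NPD` tetrads contain two
#' crossovers, so they belong to the "with" partition) and the test
#' interval is tabulated within each part.  Tetrads whose conditioning
#' class is `OTHER` are dropped from both partitions.
#'
#' @param dataset a `tetrad_data` data frame.
#' @param test_pair,conditioning_pair two adjacent marker pairs sharing
#'   exactly one marker.
#' @param map a [marker_map()]; defaults to the attached map.
#' @return A list with elements `wo` (no adjacent crossover) and `wi`
#'   (adjacent crossover present), each a pooled one-row `class_counts`
#'   for the test interval, plus `n_dropped`.
#' @examples
#' cfg <- sim_config(n_meioses = 500, seed = 3)
#' td <- simulate_tetrad_dataset(cfg, ftl_preset("I5cd"))
#' partition_by_adjacent(td, c("C", "Y"), c("Y", "R"))
#' @export
partition_by_adjacent <- function(dataset, test_pair, conditioning_pair,
                                  map = NULL) {
  map <- dataset_map(dataset, map)
  ti <- marker_pair_index(map, test_pair)
  ci <- marker_pair_index(map, conditioning_pair)
  if (length(intersect(ti, ci)) != 1L)
    stop("test and conditioning pairs must be adjacent (share exactly one marker)")
  gm <- grain_matrix(dataset)
  check_grain_channels(as.vector(gm), map)
  ccls <- classify_vec(gm, map$channel[ci[1]], map$channel[ci[2]])
  keep <- ccls != "OTHER"
  wi <- ccls %in% c("T", "NPD")
  tcls <- classify_vec(gm, map$channel[ti[1]], map$channel[ti[2]])
  interval <- paste(map$name[ti], collapse = "-")
  mk <- function(sel, label) {
    tab <- table(tcls[sel])
    class_counts(PD = tab[["PD"]], T = tab[["T"]], NPD = tab[["NPD"]],
                 OTHER = tab[["OTHER"]], interval = interval, condition = label)
  }
  list(wo = mk(keep & !wi, "no adjacent CO"),
       wi = mk(keep & wi, "adjacent CO"),
       n_dropped = sum(!keep))
}
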