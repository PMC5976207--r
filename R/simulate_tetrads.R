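#' Resolve chiasmata into a pollen tetrad
#'
#' Applies the standard four-chromatid bivalent model: the two chromatids of
#' the transgene-bearing homolog start out carrying every fluorescent
#' channel and the two chromatids of the other homolog carry none.  Each
#' chiasma joins two non-sister strands — one of the two strands carrying
#' each parental origin at its position, chosen uniformly at random (no
#' chromatid interference) — and exchanges everything distal to it.
#' The four resulting chromatids are the four pollen grains; a grain shows a
#' channel iff its chromatid carries the transgene allele at that marker.
#'
#' @param chiasma_positions numeric vector of chiasma positions on the same
#'   cM axis as `map$position_cM` (need not be sorted).
#' @param map a [marker_map()].
#' @return Character vector of 4 grain phenotype strings, each the
#'   concatenation of the channel letters the grain displays (`"-"` for
#'   none).  With no chiasmata, two grains show all channels and two show
#'   none (a parental ditype for every marker pair).
#' @examples
#' map <- ftl_preset("I5cd")
#' resolve_tetrad(numeric(0), map)    # parental ditype
#' resolve_tetrad(2.5, map)           # tetratype for pairs spanning 2.5 cM
#' @export
resolve_tetrad <- function(chiasma_positions, map) {
  stopifnot(inherits(map, "marker_map"))
  if (length(chiasma_positions) && !is.numeric(chiasma_positions))
    stop("chiasma_positions must be numeric")
  pos <- sort(as.numeric(chiasma_positions))
  carries <- c(TRUE, TRUE, FALSE, FALSE)   # current transgene state, chromatids 1..4
  grains <- rep("", 4L)
  j <- 1L
  for (m in seq_len(nrow(map))) {
    while (j <= length(pos) && pos[j] <= map$position_cM[m]) {
      # a chiasma joins non-sister chromatids: one strand carrying each
      # parental origin at that position, chosen uniformly (no chromatid
      # interference); exactly two strands carry each origin at any point
      a <- which(carries)[sample.int(2L, 1L)]
      b <- which(!carries)[sample.int(2L, 1L)]
      carries[a] <- FALSE; carries[b] <- TRUE
      j <- j + 1L
    }
    grains <- paste0(grains, ifelse(carries, map$channel[m], ""))
  }
  grains[grains == ""] <- "-"
  grains
}

#' Simulate a tetrad dataset
#'
#' Draws `config$n_meioses` meioses: Type I chiasmata from the stationary
#' gamma-renewal process, Type II chiasmata from a Poisson process (see
#' [place_type1_events()]), superposed on the genetic span of `map`, then
#' resolved through the four-chromatid bivalent model of [resolve_tetrad()].
#'
#' @param config a [sim_config()]; `config$seed`, when set, makes the draw
#'   reproducible.
#' @param map a [marker_map()].
#' @return A data frame of class `tetrad_data` with columns `tetrad`,
#'   `genotype`, `temperature`, `grain1`..`grain4`; the marker map is kept
#'   in attribute `"marker_map"`.
#' @examples
#' cfg <- sim_config(n_meioses = 200, seed = 7)
#' td <- simulate_tetrad_dataset(cfg, ftl_preset("I3a"))
#' head(td)
#' @export
simulate_tetrad_dataset <- function(config, map) {
  stopifnot(inherits(config, "sim_config"), inherits(map, "marker_map"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_meioses
  span <- max(map$position_cM) - min(map$position_cM)
  rel_map <- map
  rel_map$position_cM <- map$position_cM - min(map$position_cM)
  ev <- meiosis_events(config, span, n)
  if (config$obligate_co) {
    # redraw meioses that received no chiasma on the simulated segment
    for (it in 1:1000) {
      missing <- setdiff(seq_len(n), unique(ev$id))
      if (!length(missing)) break
      re <- meiosis_events(config, span, length(missing))
      re$id <- missing[re$id]
      ev <- rbind(ev, re)
    }
    ev <- ev[order(ev$id, ev$pos), , drop = FALSE]
  }
  grains <- resolve_tetrads_bulk(n, ev, rel_map)
  out <- data.frame(tetrad = seq_len(n),
                    genotype = rep(config$genotype, n),
                    temperature = rep(config$temperature, n),
                    grain1 = grains[, 1L], grain2 = grains[, 2L],
                    grain3 = grains[, 3L], grain4 = grains[, 4L],
                    stringsAsFactors = FALSE)
  class(out) <- c("tetrad_data", "data.frame")
  attr(out, "marker_map") <- map
  out
}

# Vectorised tetrad resolution: meioses are grouped by chiasma count and the
# chromatid-exchange sweep is applied with matrix indexing within each group.
resolve_tetrads_bulk <- function(n, events, rel_map) {
  M <- nrow(rel_map)
  mpos <- rel_map$position_cM
  chan <- rel_map$channel
  # origin-at-marker array: n x 4 grains x M markers, TRUE = carries transgene
  orig <- array(rep(c(TRUE, TRUE, FALSE, FALSE), each = n), dim = c(n, 4L, M))
  counts <- tabulate(events$id, nbins = n)
  for (k in sort(unique(counts[counts > 0L]))) {
    rows <- which(counts == k)
    nk <- length(rows)
    sel <- events$id %in% rows
    P <- matrix(events$pos[sel], nrow = nk, ncol = k, byrow = TRUE)
    O <- matrix(rep(c(TRUE, TRUE, FALSE, FALSE), each = nk), nk, 4L)
    applied <- matrix(FALSE, nk, k)
    for (m in seq_len(M)) {
      for (j in seq_len(k)) {
        act <- which(!applied[, j] & P[, j] <= mpos[m])
        if (length(act)) {
          # pick one current transgene carrier and one non-carrier per row
          ot <- O[act, , drop = FALSE] + 0
          a <- ifelse(stats::runif(length(act)) < 0.5,
                      max.col(ot, ties.method = "first"),
                      max.col(ot, ties.method = "last"))
          b <- ifelse(stats::runif(length(act)) < 0.5,
                      max.col(1 - ot, ties.method = "first"),
                      max.col(1 - ot, ties.method = "last"))
          O[cbind(act, a)] <- FALSE
          O[cbind(act, b)] <- TRUE
          applied[act, j] <- TRUE
        }
      }
      orig[rows, , m] <- O
    }
  }
  grains <- matrix("", n, 4L)
  for (g in 1:4) {
    s <- rep("", n)
    for (m in seq_len(M)) s <- paste0(s, ifelse(orig[, g, m], chan[m], ""))
    s[s == ""] <- "-"
    grains[, g] <- s
  }
  grains
}
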