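#' Configure the meiosis simulator
#'
#' Collects the parameters of the two-pathway crossover model used by the
#' simulator.  Crossovers arise from a superposition of two point processes
#' on the genetic map: an interfering Type I (ZMM/MSH4-dependent) pathway
#' modelled as a stationary gamma-renewal process with shape `interference_shape`,
#' and a non-interfering Type II (MUS81-dependent) pathway modelled as a
#' homogeneous Poisson process.  At baseline the two pathways contribute
#' `type1_weight` and `type2_weight` of the total chiasma intensity, which is
#' calibrated so that the expected chiasma count on the bivalent over a
#' region of genetic length X cM equals X/50 — i.e. configured marker
#' distances are recovered by tetrad analysis for small intervals.
#'
#' Elevated temperature is modelled purely as a multiplier on the Type I
#' intensity (`type1_rate_factor`); mutants are switches: `type1_active = FALSE`
#' emulates *msh4*, `type2_active = FALSE` emulates *mus81*, `type2_scale > 1`
#' emulates the *fancm* Type II gain, and `spo11 = TRUE` scales the DSB mean
#' by `dsb_scale_spo11`.  DSB formation is homeostatic: `dsb_mean` does not
#' depend on `type1_rate_factor`.
#'
#' @param n_meioses number of meioses (tetrads) to simulate.
#' @param type1_rate_factor multiplier on Type I intensity (>= 0); the
#'   default 28 degree scenario uses 1.22, the ratio of observed MLH1 focus
#'   means between elevated and control temperature.
#' @param type1_active,type2_active logical pathway switches.
#' @param type2_scale multiplier on Type II intensity (>= 0).
#' @param interference_shape gamma shape nu >= 1 of the Type I inter-event
#'   distance distribution; nu = 1 is a Poisson (no-interference) process and
#'   larger nu means stronger interference.
#' @param type1_weight,type2_weight baseline share of total chiasma intensity
#'   carried by each pathway (defaults 0.85/0.15, the canonical Type I share
#'   in Arabidopsis).
#' @param dsb_mean expected meiotic DSBs per meiocyte (default 200).
#' @param dsb_scale_spo11 DSB multiplier applied when `spo11 = TRUE`
#'   (default 0.1, a hypomorphic allele retaining residual breaks).
#' @param spo11 logical; apply `dsb_scale_spo11` to the DSB mean.
#' @param rad51_efficiency fraction of DSB sites detected as RAD51 foci
#'   (default 0.9); gamma-H2AX detection is taken as 1.
#' @param mlh1_background mean of the Poisson background added to MLH1 focus
#'   counts (default 0.5), representing occasional off-pathway foci.
#' @param genome_length_cM total genetic map length used for genome-wide
#'   focus counts (default 540 cM across the five chromosomes).
#' @param obligate_co logical; if `TRUE`, meioses with no chiasma on the
#'   simulated segment are redrawn (off by default so closed-form count
#'   distributions hold).
#' @param genotype,temperature condition labels attached to simulated
#'   records; opaque strings, never computed on.
#' @param seed integer seed; identical configurations with the same seed
#'   yield identical datasets.
#' @return An object of class `sim_config` (a list of the above).
#' @examples
#' sim_config(n_meioses = 100, seed = 1)
#' @export
sim_config <- function(n_meioses = 1000L,
                       type1_rate_factor = 1,
                       type1_active = TRUE,
                       type2_active = TRUE,
                       type2_scale = 1,
                       interference_shape = 5,
                       type1_weight = 0.85,
                       type2_weight = 0.15,
                       dsb_mean = 200,
                       dsb_scale_spo11 = 0.1,
                       spo11 = FALSE,
                       rad51_efficiency = 0.9,
                       mlh1_background = 0.5,
                       genome_length_cM = 540,
                       obligate_co = FALSE,
                       genotype = "WT",
                       temperature = "20C",
                       seed = NULL) {
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("type1_rate_factor", "type2_scale", "type1_weight",
               "type2_weight", "dsb_mean", "dsb_scale_spo11",
               "rad51_efficiency", "mlh1_background", "genome_length_cM")) {
    v <- get(nm)
    if (!num_ok(v) || v < 0) stop(nm, " must be a single non-negative number")
  }
  if (!num_ok(interference_shape) || interference_shape < 1)
    stop("interference_shape must be >= 1 (1 = no interference)")
  n_meioses <- as.integer(n_meioses)
  if (is.na(n_meioses) || n_meioses < 0L)
    stop("n_meioses must be a non-negative integer")
  cfg <- list(n_meioses = n_meioses,
              type1_rate_factor = type1_rate_factor,
              type1_active = isTRUE(type1_active),
              type2_active = isTRUE(type2_active),
              type2_scale = type2_scale,
              interference_shape = interference_shape,
              type1_weight = type1_weight,
              type2_weight = type2_weight,
              dsb_mean = dsb_mean,
              dsb_scale_spo11 = dsb_scale_spo11,
              spo11 = isTRUE(spo11),
              rad51_efficiency = rad51_efficiency,
              mlh1_background = mlh1_background,
              genome_length_cM = genome_length_cM,
              obligate_co = isTRUE(obligate_co),
              genotype = as.character(genotype),
              temperature = as.character(temperature),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Meiosis simulator configuration\n")
  cat(sprintf("  condition: %s at %s, %d meioses (seed %s)\n",
              x$genotype, x$temperature, x$n_meioses,
              if (is.null(x$seed)) "unset" else x$seed))
  cat(sprintf("  Type I : %s, weight %.2f x factor %.3g, gamma shape %.3g\n",
              if (x$type1_active) "active" else "off",
              x$type1_weight, x$type1_rate_factor, x$interference_shape))
  cat(sprintf("  Type II: %s, weight %.2f x scale %.3g (Poisson)\n",
              if (x$type2_active) "active" else "off",
              x$type2_weight, x$type2_scale))
  cat(sprintf("  DSBs   : mean %.3g%s; RAD51 efficiency %.2f; MLH1 background %.2f\n",
              x$dsb_mean,
              if (x$spo11) sprintf(" x %.3g (spo11)", x$dsb_scale_spo11) else "",
              x$rad51_efficiency, x$mlh1_background))
  invisible(x)
}

# effective per-cM intensities (events per cM on the bivalent)
type1_lambda <- function(cfg) {
  if (!cfg$type1_active) return(0)
  cfg$type1_weight * cfg$type1_rate_factor / 50
}
type2_lambda <- function(cfg) {
  if (!cfg$type2_active) return(0)
  cfg$type2_weight * cfg$type2_scale / 50
}
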