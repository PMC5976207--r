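#' Simulate cytological focus counts
#'
#' Generates per-meiocyte immunostaining focus counts under the two-pathway
#' model of [sim_config()]:
#'
#' * `gH2AX` and `RAD51` mark DSB sites: counts are Poisson with mean
#'   `dsb_mean` (times `dsb_scale_spo11` in the spo11 scenario, and times
#'   `rad51_efficiency` for RAD51).  By homeostasis the mean never depends
#'   on `type1_rate_factor`.
#' * `MLH1` marks nascent Type I crossover sites: counts are the number of
#'   Type I events of the gamma-renewal process over the whole genetic map
#'   (`genome_length_cM`), plus a small Poisson background
#'   (`mlh1_background`) of off-pathway foci.  The MLH1 mean therefore
#'   scales with `type1_rate_factor` and collapses to background when
#'   `type1_active = FALSE`.
#'
#' @param config a [sim_config()].
#' @param n_cells number of meiocytes to score.
#' @param antibody one of `"MLH1"`, `"RAD51"`, `"gH2AX"`.
#' @return A data frame with columns `cell`, `genotype`, `temperature`,
#'   `antibody`, `count`.
#' @examples
#' cfg <- sim_config(seed = 11)
#' head(simulate_foci_dataset(cfg, 5, "MLH1"))
#' @export
simulate_foci_dataset <- function(config, n_cells, antibody = c("MLH1", "RAD51", "gH2AX")) {
  stopifnot(inherits(config, "sim_config"))
  antibody <- match.arg(antibody)
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 0L) stop("n_cells must be a non-negative integer")
  if (!is.null(config$seed)) set.seed(config$seed)
  dsb <- config$dsb_mean * if (config$spo11) config$dsb_scale_spo11 else 1
  count <- switch(antibody,
    gH2AX = stats::rpois(n_cells, dsb),
    RAD51 = stats::rpois(n_cells, dsb * config$rad51_efficiency),
    MLH1 = {
      ev <- renewal_events(n_cells, config$genome_length_cM,
                           config$interference_shape, type1_lambda(config))
      tabulate(ev$id, nbins = n_cells) + stats::rpois(n_cells, config$mlh1_background)
    })
  data.frame(cell = seq_len(n_cells),
             genotype = rep(config$genotype, n_cells),
             temperature = rep(config$temperature, n_cells),
             antibody = rep(antibody, n_cells),
             count = as.integer(count),
             stringsAsFactors = FALSE)
}

#' Simulate viable-pollen counts per anther
#'
#' Emulates an Alexander-stain viability table: viable pollen grains per
#' anther drawn from a negative binomial with the given mean and dispersion
#' (size), giving the anther-to-anther overdispersion seen in such counts
#' (size 50 corresponds to a coefficient of variation of roughly 15% at
#' several hundred grains).
#'
#' @param n_anthers number of anthers scored.
#' @param mean_viable expected viable grains per anther.
#' @param dispersion negative-binomial size parameter.
#' @param temperature condition label.
#' @param seed optional integer seed.
#' @return A data frame with columns `anther`, `temperature`, `count`.
#' @examples
#' simulate_pollen_counts(5, 660, seed = 4)
#' @export
simulate_pollen_counts <- function(n_anthers, mean_viable, dispersion = 50,
                                   temperature = "20C", seed = NULL) {
  check_nonneg(mean_viable, "mean_viable")
  check_nonneg(dispersion, "dispersion")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_anthers <- as.integer(n_anthers)
  data.frame(anther = seq_len(n_anthers),
             temperature = rep(as.character(temperature), n_anthers),
             count = stats::rnbinom(n_anthers, size = dispersion,
                                    mu = mean_viable),
             stringsAsFactors = FALSE)
}
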