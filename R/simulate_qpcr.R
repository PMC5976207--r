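#' Treatment effects for a simulated qPCR experiment
#'
#' A long-format table of log2 fold changes (relative to the reference
#' treatment) for each treatment x gene combination.  The default emulates
#' a salinity-stress marker experiment: two stress-inducible target genes
#' (`BHLH122`, `AKR4C9`) responding to NaCl dose, and a tubulin endogenous
#' control (`TUB4`) that does not respond.  The default effect sizes are
#' the fold changes 1.2 and 1.6 at 100 mM and 8.2 and 10.5 at 200 mM.
#'
#' @return A data frame with columns `treatment`, `gene`, `log2fc`.
#' @examples
#' nacl_qpcr_effects()
#' @export
nacl_qpcr_effects <- function() {
  data.frame(
    treatment = rep(c("0mM", "100mM", "200mM"), each = 3),
    gene = rep(c("BHLH122", "AKR4C9", "TUB4"), times = 3),
    log2fc = c(0, 0, 0,
               log2(1.2), log2(1.6), 0,
               log2(8.2), log2(10.5), 0),
    stringsAsFactors = FALSE)
}

#' Simulate a qPCR plate of CT values
#'
#' CT values follow the standard comparative-CT generative model:
#' `CT = baseline(gene) - log2fc(treatment, gene) + sample offset +
#' gene-level biological noise + technical noise`.  The sample offset
#' (template amount/quality) shifts every gene of a biological sample
#' equally and therefore cancels in delta-CT; the gene-level biological and
#' technical terms do not.  The endogenous control has `log2fc = 0` under
#' every treatment, so its expected delta-CT against itself is zero and
#' fold changes of an unresponsive target come out at 1.
#'
#' @param effects a data frame as from [nacl_qpcr_effects()] with columns
#'   `treatment`, `gene`, `log2fc`.
#' @param n_biological biological replicates per treatment (default 3).
#' @param n_technical technical replicates per sample x gene (default 3).
#' @param baselines named numeric vector of baseline CT per gene; genes
#'   missing from it default to 24 cycles.
#' @param sd_sample SD (cycles) of the per-sample offset (default 0.3).
#' @param sd_biological SD of gene-level biological noise (default 0.25).
#' @param sd_technical SD of technical noise (default 0.15).
#' @param seed optional integer seed.
#' @return A data frame with columns `sample`, `treatment`, `gene`, `rep`,
#'   `ct`.
#' @examples
#' plate <- simulate_qpcr_plate(nacl_qpcr_effects(), seed = 5)
#' head(plate)
#' @export
simulate_qpcr_plate <- function(effects, n_biological = 3, n_technical = 3,
                                baselines = c(TUB4 = 22, BHLH122 = 26, AKR4C9 = 25),
                                sd_sample = 0.3, sd_biological = 0.25,
                                sd_technical = 0.15, seed = NULL) {
  stopifnot(is.data.frame(effects),
            all(c("treatment", "gene", "log2fc") %in% names(effects)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  treatments <- unique(effects$treatment)
  genes <- unique(effects$gene)
  rows <- expand.grid(rep = seq_len(n_technical), gene = genes,
                      biorep = seq_len(n_biological), treatment = treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$sample <- paste0(rows$treatment, "_s", rows$biorep)
  key <- paste(rows$treatment, rows$gene)
  eff <- effects$log2fc[match(key, paste(effects$treatment, effects$gene))]
  if (anyNA(eff)) stop("effects table must cover every treatment x gene")
  base <- baselines[rows$gene]
  base[is.na(base)] <- 24
  samples <- unique(rows$sample)
  offs <- stats::rnorm(length(samples), 0, sd_sample)
  names(offs) <- samples
  biokey <- paste(rows$sample, rows$gene)
  biolevels <- unique(biokey)
  bio <- stats::rnorm(length(biolevels), 0, sd_biological)
  names(bio) <- biolevels
  ct <- as.numeric(base) - eff + offs[rows$sample] + bio[biokey] +
    stats::rnorm(nrow(rows), 0, sd_technical)
  out <- data.frame(sample = rows$sample, treatment = rows$treatment,
                    gene = rows$gene, rep = rows$rep, ct = round(ct, 3),
                    stringsAsFactors = FALSE)
  out <- out[order(out$treatment, out$sample, out$gene, out$rep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
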