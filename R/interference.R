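#' Crossover interference ratio from adjacent-interval conditioning
#'
#' Quantifies interference following the conditioned-distance approach of
#' classical tetrad analysis: the Perkins distance of a test interval is
#' estimated separately in tetrads *without* a crossover in the adjacent
#' conditioning interval (X_wo) and in tetrads *with* one (X_wi), and the
#' interference ratio is
#'
#' \deqn{R = X_{wo} / X_{wi}.}
#'
#' Positive interference suppresses crossovers next to an existing one, so
#' X_wi < X_wo and R > 1; R = 1 indicates no interference.  The ratio
#' variance uses the standard first-order (delta-method) propagation for a
#' quotient with the covariance term set to zero — the two partitions are
#' disjoint tetrad sets:
#'
#' \deqn{Var(R) = R^2 (Var(X_{wo})/X_{wo}^2 + Var(X_{wi})/X_{wi}^2),}
#'
#' where Var(X) is the squared delta-method SE from [perkins()].
#'
#' @param counts_wo,counts_wi PD/T/NPD counts for the test interval in the
#'   two partitions (see [partition_by_adjacent()]), or a list with
#'   elements `wo` and `wi` as that function returns.
#' @return An object of class `interference_fit`: `X_wo`, `X_wi`, `Var_wo`,
#'   `Var_wi` (cM^2), `R`, `Var_R`, `n_wo`, `n_wi`, and the two
#'   `perkins_fit` objects.
#' @examples
#' p <- list(wo = class_counts(900, 95, 5), wi = class_counts(95, 5, 0))
#' interference_ratio(p)
#' @export
interference_ratio <- function(counts_wo, counts_wi = NULL) {
  if (is.null(counts_wi)) {
    if (!is.list(counts_wo) || !all(c("wo", "wi") %in% names(counts_wo)))
      stop("supply counts_wo and counts_wi, or a list with elements wo and wi")
    counts_wi <- counts_wo$wi
    counts_wo <- counts_wo$wo
  }
  fit_wo <- perkins(counts_wo)
  fit_wi <- perkins(counts_wi)
  if (fit_wi$X <= 0)
    stop("interference ratio undefined: distance with adjacent CO is zero")
  R <- fit_wo$X / fit_wi$X
  # algebraically R^2*(V_wo/X_wo^2 + V_wi/X_wi^2); this form is safe at X_wo = 0
  Var_R <- (fit_wo$SE^2 + R^2 * fit_wi$SE^2) / fit_wi$X^2
  out <- list(X_wo = fit_wo$X, X_wi = fit_wi$X,
              Var_wo = fit_wo$SE^2, Var_wi = fit_wi$SE^2,
              R = R, Var_R = Var_R,
              n_wo = fit_wo$n, n_wi = fit_wi$n,
              fit_wo = fit_wo, fit_wi = fit_wi)
  class(out) <- "interference_fit"
  out
}

#' @export
print.interference_fit <- function(x, digits = 4, ...) {
  cat("Crossover interference (conditioned Perkins distances)\n")
  cat(sprintf("  X_wo = %.*g cM (n = %d), X_wi = %.*g cM (n = %d)\n",
              digits, x$X_wo, x$n_wo, digits, x$X_wi, x$n_wi))
  cat(sprintf("  R = X_wo/X_wi = %.*g  (Var_R = %.*g; R > 1 indicates interference)\n",
              digits, x$R, digits, x$Var_R))
  invisible(x)
}

#' @export
coef.interference_fit <- function(object, ...) c(R = object$R)

#' @export
vcov.interference_fit <- function(object, ...) {
  matrix(object$Var_R, 1, 1, dimnames = list("R", "R"))
}

#' Compare interference ratios between two conditions
#'
#' Tests whether the interference ratio differs between two conditions
#' (e.g. control and elevated temperature) with the Z statistic
#'
#' \deqn{Z = |R_1 - R_2| / \sqrt{Var(R_1) + Var(R_2)}}
#'
#' referred to the standard normal; the p-value is two-sided,
#' p = 2(1 - Phi(Z)).
#'
#' @param r1,r2 `interference_fit` objects.
#' @return An object of class `interference_comparison`: `Z` (>= 0), `p`,
#'   and the two fits.
#' @examples
#' a <- interference_ratio(class_counts(900, 95, 5), class_counts(95, 5, 0))
#' compare_interference(a, a)   # Z = 0, p = 1
#' @export
compare_interference <- function(r1, r2) {
  stopifnot(inherits(r1, "interference_fit"), inherits(r2, "interference_fit"))
  v <- r1$Var_R + r2$Var_R
  if (!is.finite(v)) stop("both ratio variances must be finite")
  Z <- if (v == 0) 0 else abs(r1$R - r2$R) / sqrt(v)
  p <- if (Z == 0) 1 else 2 * (1 - stats::pnorm(Z))
  out <- list(Z = Z, p = p, r1 = r1, r2 = r2)
  class(out) <- "interference_comparison"
  out
}

#' @export
print.interference_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Interference ratio comparison: R = %.*g vs %.*g\n",
              digits, x$r1$R, digits, x$r2$R))
  cat(sprintf("  Z = %.*g, two-sided p = %.*g\n", digits, x$Z, digits, x$p))
  invisible(x)
}
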