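#' Perkins tetrad map distance
#'
#' Fits the Perkins estimator of genetic distance from tetrad class counts,
#'
#' \deqn{X = 100 (T/2 + 3\,NPD) / n, \qquad n = PD + T + NPD,}
#'
#' which corrects the tetratype frequency for undetected double crossovers
#' using the NPD class.  The standard error is the multinomial delta-method
#' (equivalently, per-tetrad score) SE: writing the per-tetrad score
#' s = 0 for PD, 1/2 for T and 3 for NPD, X = 100 E[s] and
#' SE = 100 sqrt((E[s^2] - E[s]^2)/n) with expectations taken over the
#' observed class frequencies.  `OTHER` tetrads never enter the estimate.
#'
#' `perkins()` accepts a one-row `class_counts` record (or anything with
#' `PD`/`T`/`NPD` components) or a `tetrad_data` dataset together with a
#' marker pair, in which case the counts are tabulated first (pooled over
#' conditions).
#'
#' @param x counts or a tetrad dataset.
#' @param pair,map for the dataset method, passed to [tabulate_tetrads()].
#' @param ... unused.
#' @return An object of class `perkins_fit` with components `X` (cM), `SE`
#'   (cM), `n`, and `counts`; methods: `print`, `summary`, `coef`, `vcov`,
#'   `confint`.
#' @examples
#' fit <- perkins(class_counts(PD = 70, T = 28, NPD = 2))
#' fit
#' coef(fit)
#' confint(fit)
#' @export
perkins <- function(x, ...) UseMethod("perkins")

#' @rdname perkins
#' @export
perkins.default <- function(x, ...) {
  iv <- if (is.data.frame(x) && "interval" %in% names(x)) x$interval[1] else NULL
  cnt <- extract_counts(x)
  n <- cnt[["PD"]] + cnt[["T"]] + cnt[["NPD"]]
  if (n <= 0) stop("map distance undefined: no PD/T/NPD tetrads (n = 0)")
  p <- c(cnt[["PD"]], cnt[["T"]], cnt[["NPD"]]) / n
  s <- c(0, 0.5, 3)
  m1 <- sum(p * s)
  m2 <- sum(p * s^2)
  fit <- list(X = 100 * m1,
              SE = 100 * sqrt(max(m2 - m1^2, 0) / n),
              n = as.integer(n),
              counts = cnt,
              interval = iv)
  class(fit) <- "perkins_fit"
  fit
}

#' @rdname perkins
#' @export
perkins.tetrad_data <- function(x, pair, map = NULL, ...) {
  tab <- tabulate_tetrads(x, pair, map = map, group_by = NULL)
  fit <- perkins.default(tab)
  fit$interval <- tab$interval[1]
  fit
}

extract_counts <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L)
      stop("supply a single count record (one row); got ", nrow(x), " rows")
    x <- as.list(x)
  }
  need <- c("PD", "T", "NPD")
  if (!all(need %in% names(x)))
    stop("counts must contain PD, T and NPD")
  cnt <- c(PD = as.numeric(x[["PD"]]), T = as.numeric(x[["T"]]),
           NPD = as.numeric(x[["NPD"]]),
           OTHER = if ("OTHER" %in% names(x)) as.numeric(x[["OTHER"]]) else 0)
  if (any(!is.finite(cnt)) || any(cnt < 0))
    stop("counts must be finite and non-negative")
  cnt
}

#' Delta-method standard error of a Perkins distance
#'
#' Convenience wrapper returning only the SE component of [perkins()].
#'
#' @param counts PD/T/NPD counts as for [perkins()].
#' @return Standard error in cM.
#' @examples
#' perkins_se(class_counts(PD = 70, T = 28, NPD = 2))
#' @export
perkins_se <- function(counts) perkins(counts)$SE

#' @export
print.perkins_fit <- function(x, digits = 4, ...) {
  iv <- if (!is.null(x$interval) && !is.na(x$interval)) paste0(" [", x$interval, "]") else ""
  cat(sprintf("Perkins map distance%s: %.*g cM (SE %.*g, n = %d)\n",
              iv, digits, x$X, digits, x$SE, x$n))
  invisible(x)
}

#' @export
summary.perkins_fit <- function(object, ...) {
  structure(object, class = c("summary.perkins_fit", class(object)))
}

#' @export
print.summary.perkins_fit <- function(x, digits = 4, ...) {
  print.perkins_fit(x, digits = digits)
  cat(sprintf("  classes: PD %d, T %d, NPD %d (OTHER %d excluded)\n",
              x$counts[["PD"]], x$counts[["T"]], x$counts[["NPD"]],
              x$counts[["OTHER"]]))
  ci <- confint(x)
  cat(sprintf("  95%% CI: [%.*g, %.*g] cM\n", digits, ci[1], digits, ci[2]))
  invisible(x)
}

#' @export
coef.perkins_fit <- function(object, ...) c(distance_cM = object$X)

#' @export
vcov.perkins_fit <- function(object, ...) {
  matrix(object$SE^2, 1, 1, dimnames = list("distance_cM", "distance_cM"))
}

#' @export
confint.perkins_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- object$X + c(-1, 1) * z * object$SE
  m <- matrix(ci, 1, 2, dimnames = list("distance_cM",
              sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))))
  m
}

#' Compare two map distances
#'
#' Primary comparison: a normal Z statistic on the two Perkins estimates,
#' `Z = (X_A - X_B) / sqrt(SE_A^2 + SE_B^2)`, with a two-sided p-value.
#' As a cross-check under a different convention, a chi-square test of
#' homogeneity on the (PD, T, NPD) count table is also reported.
#'
#' @param a,b `perkins_fit` objects.
#' @return An object of class `distance_comparison`: `Z`, `p` (two-sided
#'   normal), `chisq` (statistic, df, p), and the two fits.
#' @examples
#' a <- perkins(class_counts(700, 280, 20))
#' b <- perkins(class_counts(650, 330, 20))
#' compare_distances(a, b)
#' @export
compare_distances <- function(a, b) {
  stopifnot(inherits(a, "perkins_fit"), inherits(b, "perkins_fit"))
  se <- sqrt(a$SE^2 + b$SE^2)
  if (se == 0) {
    Z <- 0
  } else {
    Z <- (a$X - b$X) / se
  }
  p <- if (Z == 0) 1 else 2 * stats::pnorm(-abs(Z))
  tab <- rbind(a$counts[c("PD", "T", "NPD")], b$counts[c("PD", "T", "NPD")])
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  chs <- if (ncol(tab) >= 2)
    suppressWarnings(stats::chisq.test(tab))
  else
    list(statistic = c(`X-squared` = 0), parameter = c(df = 0), p.value = 1)
  out <- list(Z = Z, p = p,
              chisq = list(statistic = unname(chs$statistic),
                           df = unname(chs$parameter),
                           p = chs$p.value),
              a = a, b = b)
  class(out) <- "distance_comparison"
  out
}

#' @export
print.distance_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Map distance comparison: %.*g vs %.*g cM\n",
              digits, x$a$X, digits, x$b$X))
  cat(sprintf("  normal Z = %.*g, two-sided p = %.*g\n", digits, x$Z, digits, x$p))
  cat(sprintf("  chi-square cross-check: X2 = %.*g (df %g), p = %.*g\n",
              digits, x$chisq$statistic, x$chisq$df, digits, x$chisq$p))
  invisible(x)
}
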