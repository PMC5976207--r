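#' @rdname place_type1_events
#' @export
place_type2_events <- function(interval_length_cM, rate_factor = 1) {
  check_nonneg(interval_length_cM, "interval_length_cM")
  check_nonneg(rate_factor, "rate_factor")
  lambda <- rate_factor / 50
  if (lambda == 0 || interval_length_cM == 0) return(numeric(0))
  k <- stats::rpois(1L, lambda * interval_length_cM)
  sort(stats::runif(k, 0, interval_length_cM))
}

#' Place crossover-pathway events on a genetic interval
#'
#' `place_type1_events()` draws chiasma positions from a stationary
#' gamma-renewal process on the genetic scale: inter-event distances are
#' Gamma(shape = nu, rate = nu * lambda) with intensity
#' `lambda = rate_factor / 50` events per cM, so the expected chiasma count
#' on a region of genetic length X cM is `rate_factor * X / 50` (two of the
#' four chromatids cross over at each chiasma, hence the factor 50 rather
#' than 100).  The first event is drawn from the equilibrium (length-biased)
#' forward-recurrence distribution, which makes the process stationary on
#' the interval: counts do not depend on where the interval sits on the
#' chromosome.  `nu = 1` reduces to a homogeneous Poisson process (no
#' interference); larger `nu` gives more regular spacing, i.e. positive
#' crossover interference.
#'
#' `place_type2_events()` is the non-interfering counterpart: a homogeneous
#' Poisson process with the same intensity calibration.
#'
#' @param interval_length_cM genetic length of the region (cM, >= 0).
#' @param nu gamma shape (>= 1).
#' @param rate_factor multiplier on the baseline intensity (>= 0).
#' @return Sorted numeric vector of event positions in
#'   `[0, interval_length_cM]` (possibly empty).
#' @examples
#' set.seed(1)
#' place_type1_events(50, nu = 5, rate_factor = 1)
#' place_type2_events(50, rate_factor = 1)
#' @export
place_type1_events <- function(interval_length_cM, nu = 1, rate_factor = 1) {
  check_nonneg(interval_length_cM, "interval_length_cM")
  check_nonneg(rate_factor, "rate_factor")
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu < 1)
    stop("nu must be a single number >= 1")
  ev <- renewal_events(1L, interval_length_cM, nu, rate_factor / 50)
  ev$pos
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(name, " must be a single non-negative number")
}

# Forward-recurrence (equilibrium) distribution of a gamma-renewal process
# with interarrival Gamma(shape, rate): density S(x; shape, rate) / mu with
# mu = shape / rate.  CDF in closed form:
#   F_e(x) = F(x; shape + 1, rate) + (rate * x / shape) * S(x; shape, rate)
# Sampled by monotone bisection of F_e; Gamma(shape + 1, rate) quantiles give
# a valid upper bracket because F_e(x) >= F(x; shape + 1, rate).
r_equilibrium_gamma <- function(n, shape, rate) {
  if (n == 0L) return(numeric(0))
  if (shape == 1) return(stats::rexp(n, rate))
  u <- stats::runif(n)
  lo <- numeric(n)
  hi <- stats::qgamma(u, shape + 1, rate)
  Fe <- function(x) stats::pgamma(x, shape + 1, rate) +
    (rate * x / shape) * stats::pgamma(x, shape, rate, lower.tail = FALSE)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    up <- Fe(mid) >= u
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
    if (max(hi - lo) <= 1e-12 * (1 + max(hi))) break
  }
  (lo + hi) / 2
}

# Vectorised stationary gamma-renewal draw for n independent meioses on
# [0, len]; returns data.frame(id, pos) sorted by (id, pos).
renewal_events <- function(n, len, shape, lambda) {
  if (n == 0L || lambda == 0 || len == 0)
    return(data.frame(id = integer(0), pos = numeric(0)))
  rate <- shape * lambda                 # gamma rate of interarrivals
  pos <- r_equilibrium_gamma(n, shape, rate)
  id <- seq_len(n)
  out_id <- vector("list", 8L); out_pos <- vector("list", 8L); k <- 0L
  repeat {
    keep <- pos <= len
    if (!any(keep)) break
    id <- id[keep]; pos <- pos[keep]
    k <- k + 1L
    if (k > length(out_id)) { length(out_id) <- 2L * k; length(out_pos) <- 2L * k }
    out_id[[k]] <- id; out_pos[[k]] <- pos
    pos <- pos + stats::rgamma(length(pos), shape = shape, rate = rate)
  }
  if (k == 0L) return(data.frame(id = integer(0), pos = numeric(0)))
  id <- unlist(out_id[seq_len(k)]); pos <- unlist(out_pos[seq_len(k)])
  o <- order(id, pos)
  data.frame(id = id[o], pos = pos[o])
}

# Vectorised homogeneous Poisson draw, same return shape.
poisson_events <- function(n, len, lambda) {
  if (n == 0L || lambda == 0 || len == 0)
    return(data.frame(id = integer(0), pos = numeric(0)))
  counts <- stats::rpois(n, lambda * len)
  tot <- sum(counts)
  if (tot == 0L) return(data.frame(id = integer(0), pos = numeric(0)))
  id <- rep.int(seq_len(n), counts)
  pos <- stats::runif(tot, 0, len)
  o <- order(id, pos)
  data.frame(id = id[o], pos = pos[o])
}

# Superposed Type I + Type II events for all meioses of a config on [0, len].
# Retains the pathway label per event so Type I events can be counted alone.
meiosis_events <- function(cfg, len, n = cfg$n_meioses) {
  e1 <- renewal_events(n, len, cfg$interference_shape, type1_lambda(cfg))
  e2 <- poisson_events(n, len, type2_lambda(cfg))
  ev <- rbind(cbind(e1, pathway = rep("I", nrow(e1))),
              cbind(e2, pathway = rep("II", nrow(e2))))
  ev <- ev[order(ev$id, ev$pos), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
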