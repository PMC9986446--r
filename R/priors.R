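#' Prior distribution specification
#'
#' One marginal prior.  Families and their parameters:
#' \describe{
#'   \item{normal}{\code{p1} = mean, \code{p2} = sd}
#'   \item{lognormal}{\code{p1} = meanlog, \code{p2} = sdlog}
#'   \item{halfnormal}{\code{p1} = scale sigma (the sd of the underlying
#'     normal, support \eqn{[0,\infty)}); \code{p2} unused}
#'   \item{uniform}{\code{p1} = lower, \code{p2} = upper}
#' }
#' Optional truncation bounds restrict the support; densities are
#' renormalised over the truncated interval.
#'
#' @param name Parameter name.
#' @param family One of \code{"normal"}, \code{"lognormal"},
#'   \code{"halfnormal"}, \code{"uniform"}.
#' @param p1,p2 Family parameters (see Details).
#' @param lower,upper Optional truncation bounds (default untruncated).
#' @return Object of class \code{priorSpec}.
#' @export
priorSpec <- function(name, family, p1, p2 = NA_real_,
                      lower = -Inf, upper = Inf) {
  family <- match.arg(family, c("normal", "lognormal", "halfnormal", "uniform"))
  if (!is.finite(p1)) stop("p1 must be finite for ", name)
  if (family %in% c("normal", "lognormal") && (!is.finite(p2) || p2 <= 0))
    stop("sd parameter p2 must be positive for ", name)
  if (family == "halfnormal" && p1 <= 0)
    stop("halfnormal scale must be positive for ", name)
  if (family == "uniform" && (!is.finite(p2) || p2 <= p1))
    stop("uniform bounds must be ordered for ", name)
  if (lower >= upper) stop("truncation bounds must be ordered for ", name)
  structure(list(name = name, family = family, p1 = p1, p2 = p2,
                 lower = lower, upper = upper),
            class = "priorSpec")
}

#' @export
print.priorSpec <- function(x, ...) {
  tr <- if (is.finite(x$lower) || is.finite(x$upper))
    sprintf(" truncated (%s, %s)", format(x$lower), format(x$upper)) else ""
  cat(sprintf("<priorSpec> %s ~ %s(%s%s)%s\n", x$name, x$family,
              format(x$p1),
              if (is.finite(x$p2)) paste0(", ", format(x$p2)) else "", tr))
  invisible(x)
}

## effective support after truncation
priorSupport <- function(spec) {
  lo <- spec$lower; hi <- spec$upper
  switch(spec$family,
         normal = c(lo, hi),
         lognormal = c(max(lo, 0), hi),
         halfnormal = c(max(lo, 0), hi),
         uniform = c(max(lo, spec$p1), min(hi, spec$p2)))
}

## cdf of the untruncated family
priorCdf <- function(spec, q) {
  switch(spec$family,
         normal = stats::pnorm(q, spec$p1, spec$p2),
         lognormal = stats::plnorm(q, spec$p1, spec$p2),
         halfnormal = pmax(0, 2 * stats::pnorm(q / spec$p1) - 1),
         uniform = stats::punif(q, spec$p1, spec$p2))
}

## quantile of the untruncated family
priorQf <- function(spec, p) {
  switch(spec$family,
         normal = stats::qnorm(p, spec$p1, spec$p2),
         lognormal = stats::qlnorm(p, spec$p1, spec$p2),
         halfnormal = spec$p1 * stats::qnorm((p + 1) / 2),
         uniform = stats::qunif(p, spec$p1, spec$p2))
}

#' Sample from a prior
#'
#' Inverse-CDF sampling so truncation is exact (no rejection).  Randomness
#' comes from R's global RNG stream unless \code{seed} is given.
#'
#' @param spec A \code{\link{priorSpec}}.
#' @param n Number of draws.
#' @param seed Optional integer seed applied locally.
#' @return Numeric vector of n draws within the (truncated) support.
#' @export
#' @examples
#' samplePrior(priorSpec("Pbab", "uniform", 1, 30), 5, seed = 1)
samplePrior <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "priorSpec"))
  if (!is.null(seed)) set.seed(seed)
  su <- priorSupport(spec)
  plo <- priorCdf(spec, su[1]); phi <- priorCdf(spec, su[2])
  u <- stats::runif(n, plo, phi)
  priorQf(spec, u)
}

#' Log prior density (with truncation renormalisation)
#'
#' Returns \code{-Inf} outside the (truncated) support.
#'
#' @param spec A \code{\link{priorSpec}}.
#' @param x Quantiles (vectorised).
#' @return Log densities.
#' @export
logPriorDensity <- function(spec, x) {
  su <- priorSupport(spec)
  ld <- switch(spec$family,
               normal = stats::dnorm(x, spec$p1, spec$p2, log = TRUE),
               lognormal = stats::dlnorm(x, spec$p1, spec$p2, log = TRUE),
               halfnormal = log(2) +
                 stats::dnorm(x, 0, spec$p1, log = TRUE),
               uniform = stats::dunif(x, spec$p1, spec$p2, log = TRUE))
  z <- priorCdf(spec, su[2]) - priorCdf(spec, su[1])
  ld <- ld - log(z)
  ld[x < su[1] | x > su[2]] <- -Inf
  ld
}

#' Empirical median and 95 percent interval of a sample
#'
#' @param samples Numeric vector (n >= 1000 recommended for stable tails).
#' @return Named vector \code{median}, \code{q2.5}, \code{q97.5}.
#' @export
summarisePrior <- function(samples) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  q <- stats::quantile(samples, c(0.5, 0.025, 0.975), names = FALSE,
                       type = 7)
  c(median = q[1], q2.5 = q[2], q97.5 = q[3])
}

#' Read a prior configuration file
#'
#' Tab-delimited, one record per parameter:
#' \code{name family p1 p2 lower upper} with \code{NA} for unused fields
#' (untruncated bounds may be left \code{NA}).
#'
#' @param path File path.
#' @return Named list of \code{\link{priorSpec}} objects, in file order.
#' @export
readPriorConfig <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "family", "p1", "p2", "lower", "upper")
  if (!all(need %in% names(x)))
    stop("prior config must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(x)), function(i) {
    priorSpec(x$name[i], x$family[i], x$p1[i],
              ifelse(is.na(x$p2[i]), NA_real_, x$p2[i]),
              lower = ifelse(is.na(x$lower[i]), -Inf, x$lower[i]),
              upper = ifelse(is.na(x$upper[i]), Inf, x$upper[i]))
  })
  names(out) <- x$name
  out
}

#' Default calibration priors
#'
#' \code{defaultGlobalPriors()} returns the 15 global kinetic priors plus
#' the three half-normal(1) error-SD priors; \code{defaultLocalPriors()}
#' the 19 volunteer-level priors (one copy is used per volunteer).
#' Families and parameters follow the published prior summaries; uniform
#' bounds for parameters specified only through a median and 95 percent
#' interval are back-solved from those summaries (see the methods
#' vignette).  Physiological locals are normals truncated at their
#' 5th/95th percentiles.
#'
#' @return Named list of \code{\link{priorSpec}} objects.
#' @export
defaultGlobalPriors <- function() {
  readPriorConfig(system.file("extdata", "priors_global.tsv",
                              package = "dehtpk", mustWork = TRUE))
}

#' @rdname defaultGlobalPriors
#' @export
defaultLocalPriors <- function() {
  readPriorConfig(system.file("extdata", "priors_local.tsv",
                              package = "dehtpk", mustWork = TRUE))
}
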