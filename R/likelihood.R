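## Calibrated parameter layout: 15 globals + 3 error SDs shared across
## volunteers, 19 locals per volunteer.

.globalNames <- c("FB_DEHTP", "FB_MEHTP", "DEHTP_GUT_half_life",
                  "DEHTP_half_life", "Pbab", "Pgub", "Plib", "PbaM",
                  "PliM", "PguM", "K1_2cx", "K1_MOH", "K1_5cx",
                  "escapeFracgu", "escapeFracli")
.sigmaNames <- c("sigma_OH", "sigma_2cx", "sigma_5cx")
.localNames <- c("FracMetabMOH", "FracMetab2cx", "FracMetab5cx",
                 "K1_DEHTP_Liver", "FracDOSEHep", "BELLYPERM", "GIPERM1",
                 "GIPERM2", "Gutlag", "FracDoseLymph", "Lymphlag",
                 "K1_Lymph", "MPY", "MPYgu", "VBldC", "VliC", "VguC",
                 "VkiC", "QguC")

#' Names of the calibrated parameters
#'
#' @return List with elements \code{globals} (15), \code{sigmas} (3) and
#'   \code{locals} (19, replicated per volunteer).
#' @export
calibratedParameterNames <- function() {
  list(globals = .globalNames, sigmas = .sigmaNames, locals = .localNames)
}

#' Assemble a calibration dataset
#'
#' Bundles void records with per-volunteer dose and body weight and
#' precomputes the deposition-rate observations the likelihood consumes.
#'
#' @param voids Void records for all volunteers (see
#'   \code{\link{readVoids}}).
#' @param info data.frame with columns \code{volunteer}, \code{dose_mg},
#'   \code{bodyWeight}.
#' @return Object of class \code{calibrationDataset}: list with
#'   \code{voids}, \code{info}, \code{volunteers} and per-volunteer
#'   observation tables.
#' @export
calibrationDataset <- function(voids, info) {
  voids <- validateVoids(voids)
  need <- c("volunteer", "dose_mg", "bodyWeight")
  if (!all(need %in% names(info)))
    stop("info needs columns: ", paste(need, collapse = ", "))
  vols <- sort(unique(voids$volunteer))
  if (!setequal(vols, info$volunteer))
    stop("volunteers in voids and info differ")
  if (any(info$dose_mg <= 0) || any(info$bodyWeight <= 0))
    stop("doses and body weights must be positive")
  info <- info[match(vols, info$volunteer), ]
  rates <- voidsToRates(voids)
  obs <- lapply(vols, function(v) {
    r <- rates[rates$volunteer == v, ]
    list(times = sort(unique(r$tEnd)),
         byMetab = split(r[, c("tStart", "tEnd", "midpoint", "rate")],
                         r$metabolite))
  })
  names(obs) <- as.character(vols)
  structure(list(voids = voids, info = info, volunteers = vols, obs = obs),
            class = "calibrationDataset")
}

#' @export
print.calibrationDataset <- function(x, ...) {
  cat(sprintf("<calibrationDataset> %d volunteers, %d voids\n",
              length(x$volunteers), nrow(x$voids)))
  invisible(x)
}

#' Zero-truncated normal log density
#'
#' Log density of \eqn{N(\mu, \sigma)} truncated to \eqn{[0, \infty)}:
#' the normal log density minus the log normalising constant
#' \eqn{\log(1 - \Phi(-\mu/\sigma)) = \log\Phi(\mu/\sigma)}.
#'
#' @param y Observations (non-negative; \code{-Inf} returned below 0).
#' @param mu Mean of the untruncated normal (may be any sign).
#' @param sigma Standard deviation, positive.
#' @return Log densities, vectorised over all arguments.
#' @export
#' @examples
#' truncNormLogDensity(0.5, 0, 1)  # dnorm(0.5, log = TRUE) + log(2)
truncNormLogDensity <- function(y, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  ld <- stats::dnorm(y, mu, sigma, log = TRUE) -
    stats::pnorm(mu / sigma, log.p = TRUE)
  ld[y < 0] <- -Inf
  ld
}

## split a flat named vector into the structured parameter list
pvFromFlat <- function(flat, J) {
  g <- flat[.globalNames]
  s <- flat[.sigmaNames]
  loc <- matrix(NA_real_, length(.localNames), J,
                dimnames = list(.localNames, seq_len(J)))
  for (j in seq_len(J))
    loc[, j] <- flat[paste0(.localNames, ".", j)]
  list(globals = g, sigmas = s, locals = loc)
}

flatFromPv <- function(pv) {
  J <- ncol(pv$locals)
  loc <- as.vector(pv$locals)
  names(loc) <- as.vector(outer(.localNames, seq_len(J),
                                function(a, b) paste0(a, ".", b)))
  c(pv$globals, pv$sigmas, loc)
}

## model context for volunteer j under parameter list pv
ctxForVolunteer <- function(pv, j, data, validate = FALSE) {
  glob <- defaultGlobals()
  glob[.globalNames] <- as.list(unname(pv$globals[.globalNames]))
  loc <- defaultLocals()
  loc[.localNames] <- as.list(unname(pv$locals[.localNames, j]))
  phys <- defaultPhysiology(data$info$bodyWeight[j])
  buildModel(phys, glob, loc, validate = validate)
}

## per-volunteer log likelihood from cached mu
llFromMu <- function(mu, obsTab, sigmas) {
  smap <- c("5OH" = "sigma_OH", "2cx" = "sigma_2cx", "5cx" = "sigma_5cx")
  tot <- 0
  for (m in names(obsTab)) {
    tot <- tot + sum(truncNormLogDensity(obsTab[[m]]$rate, mu[[m]],
                                         sigmas[[smap[[m]]]]))
  }
  tot
}

#' Log likelihood of the calibration error model
#'
#' Zero-truncated normal likelihood: each observed deposition rate is
#' compared with the model's interval-average deposition rate over the
#' same void interval, with one error SD per metabolite.  A solver
#' failure yields \code{-Inf} with a warning.
#'
#' @param pv Parameter list with elements \code{globals}, \code{sigmas},
#'   \code{locals} (see \code{\link{calibratedParameterNames}}), or a
#'   flat named vector.
#' @param data A \code{\link{calibrationDataset}}.
#' @param rtol,atol Solver tolerances for the embedded simulations.
#' @return Log likelihood (scalar), with per-volunteer contributions as
#'   attribute \code{"byVolunteer"}.
#' @export
logLikelihood <- function(pv, data, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(data, "calibrationDataset"))
  if (is.numeric(pv)) pv <- pvFromFlat(pv, length(data$volunteers))
  J <- length(data$volunteers)
  ll <- numeric(J)
  for (j in seq_len(J)) {
    mu <- tryCatch(computeMu(pv, j, data, rtol, atol), error = function(e) {
      warning("forward model failed for volunteer ", j, ": ",
              conditionMessage(e))
      NULL
    })
    ll[j] <- if (is.null(mu)) -Inf
    else llFromMu(mu, data$obs[[j]]$byMetab, pv$sigmas)
  }
  structure(sum(ll), byVolunteer = ll)
}

## solve the forward model for volunteer j and return interval means.
## Lean path: single oral bolus at t = 0, lymph arrival as one state jump,
## direct deSolve calls without the full SimOutput assembly.
computeMu <- function(pv, j, data, rtol = 1e-8, atol = 1e-10) {
  ctx <- ctxForVolunteer(pv, j, data)
  dose <- data$info$dose_mg[j]
  times <- c(0, data$obs[[j]]$times)   # void boundaries, increasing
  loc <- ctx$loc
  lym <- loc$Lymphlag
  nState <- length(.stateNames)
  y <- numeric(nState)
  y[1L] <- loc$FracDOSEHep * dose
  iALY <- 3L + .NG
  iCum <- nState - 3L + c(0L, 1L, 2L)  # UMOH, U2CX, U5CX

  solveSeg <- function(y, tseq)
    deSolve::ode(y = y, times = tseq, func = "dehtp_derivs",
                 parms = ctx$parms, dllname = "dehtpk",
                 initfunc = "dehtp_initmod", rtol = rtol, atol = atol)

  tmax <- times[length(times)]
  cum <- matrix(NA_real_, length(times), 3L)
  cum[1L, ] <- 0
  if (lym >= tmax) {
    out <- solveSeg(y, times)
    cum <- out[, 1L + iCum, drop = FALSE]
  } else {
    pre <- times[times <= lym]
    t1 <- unique(c(pre, lym))
    out1 <- solveSeg(y, t1)
    y <- out1[nrow(out1), -1L]
    y[iALY] <- y[iALY] + loc$FracDoseLymph * dose
    t2 <- c(lym, times[times > lym])
    out2 <- solveSeg(y, t2)
    cum <- rbind(out1[seq_along(pre), 1L + iCum, drop = FALSE],
                 out2[-1L, 1L + iCum, drop = FALSE])
  }
  if (any(!is.finite(cum))) stop("solver returned non-finite output")
  chems <- ctx$chems
  mwM <- chems$MEHTP$molecularWeight
  w <- c(chems$OH5$molecularWeight, chems$cx2$molecularWeight,
         chems$cx5$molecularWeight) / mwM
  dt <- diff(times)
  list("2cx" = diff(cum[, 2L]) * w[2L] / dt,
       "5OH" = diff(cum[, 1L]) * w[1L] / dt,
       "5cx" = diff(cum[, 3L]) * w[3L] / dt)
}

#' Log prior of the calibrated parameter vector
#'
#' Sum of the independent marginal log prior densities of the globals,
#' error SDs and each volunteer's locals, including truncation
#' renormalisation, plus the structural constraint
#' FracDOSEHep + FracDoseLymph <= 1 (the remainder passes to faeces).
#' Returns \code{-Inf} outside the support.
#'
#' @param pv Parameter list or flat named vector.
#' @param priors List with elements \code{global} and \code{local}: named
#'   lists of \code{\link{priorSpec}}s (defaults from the package
#'   configuration).
#' @param J Number of volunteers (needed only for a flat \code{pv}).
#' @return Log prior density (scalar).
#' @export
logPrior <- function(pv, priors = list(global = defaultGlobalPriors(),
                                       local = defaultLocalPriors()),
                     J = NULL) {
  if (is.numeric(pv)) {
    if (is.null(J)) stop("J is required for a flat parameter vector")
    pv <- pvFromFlat(pv, J)
  }
  lp <- 0
  for (nm in c(.globalNames, .sigmaNames)) {
    x <- if (nm %in% .globalNames) pv$globals[[nm]] else pv$sigmas[[nm]]
    lp <- lp + logPriorDensity(priors$global[[nm]], x)
    if (!is.finite(lp)) return(-Inf)
  }
  for (j in seq_len(ncol(pv$locals))) {
    for (nm in .localNames) {
      lp <- lp + logPriorDensity(priors$local[[nm]], pv$locals[nm, j])
      if (!is.finite(lp)) return(-Inf)
    }
    if (pv$locals["FracDOSEHep", j] + pv$locals["FracDoseLymph", j] > 1)
      return(-Inf)
  }
  lp
}
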