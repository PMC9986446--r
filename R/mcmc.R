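#' Adaptive block Metropolis calibration
#'
#' Random-walk Metropolis over the full calibrated vector (globals, error
#' SDs, one local block per volunteer), updated block-wise so each
#' iteration re-solves the forward model only where needed: a global
#' proposal re-simulates every volunteer, a local proposal only its own
#' volunteer, an error-SD proposal none (the cached model means are
#' reused).  Error SDs are proposed on the log scale.  Proposal scales
#' (and, late in burn-in, the marginal proposal SDs) adapt towards a
#' 20-35 percent acceptance rate during the burn-in and are frozen
#' afterwards.  The burn-in (first 25 percent of iterations by default)
#' is excluded from the retained sample.
#'
#' @param data A \code{\link{calibrationDataset}}, or \code{NULL} to
#'   sample the prior alone (a distribution-level check of the sampler
#'   against the closed-form prior quantiles).
#' @param priors Prior list as in \code{\link{logPrior}}.
#' @param iterations Total iterations (burn-in included).
#' @param thin Keep every \code{thin}-th post-burn-in iteration.
#' @param seed Integer seed; fixed seed gives an identical chain.
#' @param burnInFrac Fraction of iterations used as adaptive burn-in.
#' @param start Optional flat named start vector (default: prior medians).
#' @param rtol,atol Solver tolerances inside the likelihood.
#' @param nVolunteers Number of volunteers when \code{data} is NULL.
#' @param verbose Print progress every 1000 iterations.
#' @return Object of class \code{dehtpChain}: \code{samples} (matrix of
#'   retained draws), \code{logPost}, per-block acceptance rates and the
#'   run configuration.
#' @export
runMCMC <- function(data, priors = list(global = defaultGlobalPriors(),
                                        local = defaultLocalPriors()),
                    iterations = 20000, thin = 10, seed = 1,
                    burnInFrac = 0.25, start = NULL,
                    rtol = 1e-6, atol = 1e-9, nVolunteers = 3,
                    verbose = FALSE) {
  noData <- is.null(data)
  if (!noData) stopifnot(inherits(data, "calibrationDataset"))
  set.seed(seed)
  J <- if (noData) nVolunteers else length(data$volunteers)
  parNames <- c(.globalNames, .sigmaNames,
                as.vector(outer(.localNames, seq_len(J),
                                function(a, b) paste0(a, ".", b))))
  npar <- length(parNames)

  priorOf <- function(nm) {
    base <- sub("\\.[0-9]+$", "", nm)
    if (base %in% names(priors$global)) priors$global[[base]]
    else priors$local[[base]]
  }
  specs <- lapply(parNames, priorOf)
  names(specs) <- parNames

  ## start at prior medians (guaranteed inside the support)
  flat <- if (is.null(start)) {
    vapply(specs, function(s) {
      su <- priorSupport(s)
      priorQf(s, (priorCdf(s, su[1]) + priorCdf(s, su[2])) / 2)
    }, numeric(1))
  } else start[parNames]
  names(flat) <- parNames

  ## initial proposal SDs from the prior spread
  priorSd <- vapply(specs, function(s) {
    q <- priorQf(s, c(0.25, 0.75))
    if (s$family == "uniform") (s$p2 - s$p1) / sqrt(12)
    else (q[2] - q[1]) / 1.349
  }, numeric(1))
  isSigma <- parNames %in% .sigmaNames
  propSd <- priorSd / 10
  propSd[isSigma] <- 0.4   # log-scale steps for the error SDs

  blocks <- c(list(gA = .globalNames[1:7], gB = .globalNames[8:15],
                   s = .sigmaNames),
              stats::setNames(
                lapply(seq_len(J),
                       function(j) paste0(.localNames, ".", j)),
                paste0("loc", seq_len(J))))
  blockIdx <- lapply(blocks, function(b) match(b, parNames))
  volOfBlock <- c(gA = 0L, gB = 0L, s = -1L,
                  stats::setNames(seq_len(J), paste0("loc", seq_len(J))))
  nb <- length(blocks)

  pv <- pvFromFlat(flat, J)
  lp <- logPrior(pv, priors)
  if (!is.finite(lp)) stop("starting point has zero prior density")
  muList <- vector("list", J)
  llVol <- numeric(J)
  if (!noData) {
    for (j in seq_len(J)) {
      muList[[j]] <- computeMu(pv, j, data, rtol, atol)
      llVol[j] <- llFromMu(muList[[j]], data$obs[[j]]$byMetab, pv$sigmas)
    }
  }

  burnIn <- floor(burnInFrac * iterations)
  nKeep <- floor((iterations - burnIn) / thin)
  samples <- matrix(NA_real_, nKeep, npar, dimnames = list(NULL, parNames))
  logPost <- numeric(nKeep)
  accept <- tries <- stats::setNames(numeric(nb), names(blocks))
  accWin <- triesWin <- stats::setNames(numeric(nb), names(blocks))
  lambda <- stats::setNames(rep(1, nb), names(blocks))
  history <- matrix(NA_real_, 500, npar)
  histAt <- 0L
  kept <- 0L

  for (it in seq_len(iterations)) {
    for (b in seq_len(nb)) {
      idx <- blockIdx[[b]]
      prop <- flat
      step <- stats::rnorm(length(idx), 0, propSd[idx] * lambda[b])
      jac <- 0
      if (names(blocks)[b] == "s") {
        prop[idx] <- flat[idx] * exp(step)
        jac <- sum(log(prop[idx]) - log(flat[idx]))
      } else prop[idx] <- flat[idx] + step
      tries[b] <- tries[b] + 1; triesWin[b] <- triesWin[b] + 1

      pvProp <- pvFromFlat(prop, J)
      lpProp <- logPrior(pvProp, priors)
      if (is.finite(lpProp)) {
        v <- volOfBlock[b]
        if (noData) {             # prior-only target
          llPropVol <- llVol
          muProp <- muList
        } else if (v == -1L) {    # error SDs: reuse cached model means
          llPropVol <- vapply(seq_len(J), function(j)
            llFromMu(muList[[j]], data$obs[[j]]$byMetab, pvProp$sigmas),
            numeric(1))
          muProp <- muList
        } else if (v == 0L) {     # globals: re-simulate every volunteer
          muProp <- tryCatch(
            lapply(seq_len(J), function(j)
              computeMu(pvProp, j, data, rtol, atol)),
            error = function(e) NULL)
          llPropVol <- if (is.null(muProp)) rep(-Inf, J)
          else vapply(seq_len(J), function(j)
            llFromMu(muProp[[j]], data$obs[[j]]$byMetab, pvProp$sigmas),
            numeric(1))
        } else {                  # one volunteer's locals
          muV <- tryCatch(computeMu(pvProp, v, data, rtol, atol),
                          error = function(e) NULL)
          muProp <- muList
          llPropVol <- llVol
          if (is.null(muV)) llPropVol[v] <- -Inf
          else {
            muProp[[v]] <- muV
            llPropVol[v] <- llFromMu(muV, data$obs[[v]]$byMetab,
                                     pvProp$sigmas)
          }
        }
        logAcc <- (lpProp + sum(llPropVol)) - (lp + sum(llVol)) + jac
        if (is.finite(logAcc) && log(stats::runif(1)) < logAcc) {
          flat <- prop; pv <- pvProp; lp <- lpProp
          muList <- muProp; llVol <- llPropVol
          accept[b] <- accept[b] + 1; accWin[b] <- accWin[b] + 1
        }
      }
    }

    if (it <= burnIn) {
      if (it %% 50L == 0L) {      # scale adaptation towards 20-35% acc
        rate <- accWin / pmax(triesWin, 1)
        lambda[rate < 0.20] <- lambda[rate < 0.20] * 0.8
        lambda[rate > 0.35] <- lambda[rate > 0.35] * 1.25
        accWin[] <- 0; triesWin[] <- 0
      }
      histAt <- histAt %% 500L + 1L
      history[histAt, ] <- flat
      if (it %% 500L == 0L && it >= 1000L) {
        # marginal-SD adaptation from the trailing window
        emp <- apply(history, 2, stats::sd)
        emp[isSigma] <- apply(log(history[, isSigma, drop = FALSE]), 2,
                              stats::sd)
        ok <- is.finite(emp) & emp > 0
        propSd[ok] <- pmax(emp[ok] * 2.38 / sqrt(19), priorSd[ok] / 2000,
                           1e-12)
        propSd[isSigma & ok] <- pmax(emp[isSigma & ok], 0.05)
      }
    } else if ((it - burnIn) %% thin == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- flat
      logPost[kept] <- lp + sum(llVol)
    }
    if (verbose && it %% 1000L == 0L)
      message(sprintf("iteration %d / %d, logPost %.2f", it, iterations,
                      lp + sum(llVol)))
  }

  rate <- accept / pmax(tries, 1)
  if (any(rate == 0))
    warning("no accepted proposals in block(s): ",
            paste(names(rate)[rate == 0], collapse = ", "))

  structure(list(samples = samples[seq_len(kept), , drop = FALSE],
                 logPost = logPost[seq_len(kept)],
                 acceptance = rate, lambda = lambda,
                 config = list(iterations = iterations, thin = thin,
                               seed = seed, burnIn = burnIn, J = J),
                 priors = priors),
            class = "dehtpChain")
}

#' @export
print.dehtpChain <- function(x, ...) {
  cat(sprintf(paste0("<dehtpChain> %d retained samples (%d iterations, ",
                     "thin %d, burn-in %d)\n  acceptance: %s\n"),
              nrow(x$samples), x$config$iterations, x$config$thin,
              x$config$burnIn,
              paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
                    collapse = ", ")))
  invisible(x)
}

#' Posterior summary of a chain
#'
#' Empirical medians and 95 percent credible intervals per parameter, the
#' posterior-mode parameter set (the retained sample with the highest log
#' posterior) and, per volunteer, the derived absorbed fraction
#' (FracDOSEHep + FracDoseLymph).
#'
#' @param chain A \code{\link{runMCMC}} result.
#' @return List with \code{table} (data.frame: parameter, median, q2.5,
#'   q97.5, mode) and \code{mode} (named vector).
#' @export
posteriorSummary <- function(chain) {
  stopifnot(inherits(chain, "dehtpChain"))
  s <- chain$samples
  J <- chain$config$J
  for (j in seq_len(J)) {
    af <- s[, paste0("FracDOSEHep.", j)] + s[, paste0("FracDoseLymph.", j)]
    s <- cbind(s, af)
    colnames(s)[ncol(s)] <- paste0("absorbedFraction.", j)
  }
  q <- t(apply(s, 2, stats::quantile, c(0.5, 0.025, 0.975), names = FALSE))
  modeRow <- which.max(chain$logPost)
  mode <- s[modeRow, ]
  tab <- data.frame(parameter = colnames(s), median = q[, 1],
                    q2.5 = q[, 2], q97.5 = q[, 3], mode = mode,
                    row.names = NULL)
  list(table = tab, mode = mode)
}

#' Pointwise posterior predictive band for a deposition-rate curve
#'
#' Runs retained posterior draws through the forward model and returns
#' pointwise 2.5th/97.5th percentile curves together with the
#' posterior-mode trace.  The mode trace is a single best-fitting curve
#' and may step outside the pointwise band.
#'
#' @param chain A \code{\link{runMCMC}} result.
#' @param data The \code{\link{calibrationDataset}} used for calibration.
#' @param volunteer Volunteer index (1-based).
#' @param metabolite One of \code{"5OH"}, \code{"2cx"}, \code{"5cx"}.
#' @param grid Output time grid (h).
#' @param draws Number of retained draws to use (subsampled evenly;
#'   \code{Inf} for all).
#' @return data.frame with columns \code{time}, \code{lower},
#'   \code{upper}, \code{mode} (mg/h).
#' @export
predictiveBand <- function(chain, data, volunteer = 1,
                           metabolite = c("5OH", "2cx", "5cx"),
                           grid = seq(0, 48, by = 0.25), draws = 200) {
  metabolite <- match.arg(metabolite)
  stopifnot(inherits(chain, "dehtpChain"))
  n <- nrow(chain$samples)
  take <- if (is.finite(draws) && draws < n)
    unique(round(seq(1, n, length.out = draws))) else seq_len(n)
  col <- switch(metabolite, "5OH" = "r5OH", "2cx" = "r2cx", "5cx" = "r5cx")
  J <- chain$config$J
  simRate <- function(flat) {
    pv <- pvFromFlat(flat, J)
    ctx <- ctxForVolunteer(pv, volunteer, data)
    sim <- simulatePBPK(ctx, doses = data.frame(
      time = 0, amount = data$info$dose_mg[volunteer]), times = grid,
      rtol = 1e-6, atol = 1e-9)
    sim$output[[col]]
  }
  curves <- vapply(take, function(i) simRate(chain$samples[i, ]),
                   numeric(length(grid)))
  qs <- apply(curves, 1, stats::quantile, c(0.025, 0.975), names = FALSE)
  modeCurve <- simRate(chain$samples[which.max(chain$logPost), ])
  data.frame(time = grid, lower = qs[1, ], upper = qs[2, ],
             mode = modeCurve)
}

#' Measured versus predicted 48-h excretions
#'
#' Simulates each volunteer under a given parameter set (typically the
#' posterior mode) and compares the predicted cumulative urinary
#' excretion of each metabolite at 48 h with the measured cumulative
#' excretion from the void records.
#'
#' @param params Flat named parameter vector (e.g.
#'   \code{posteriorSummary(chain)$mode}) or structured list.
#' @param data A \code{\link{calibrationDataset}}.
#' @param window Comparison window in hours (default 48).
#' @return data.frame with columns \code{volunteer}, \code{metabolite},
#'   \code{measured}, \code{predicted} (mg).
#' @export
compare48h <- function(params, data, window = 48) {
  stopifnot(inherits(data, "calibrationDataset"))
  J <- length(data$volunteers)
  if (is.numeric(params)) params <- pvFromFlat(params, J)
  meas <- cumulativeExcretion(data$voids, window)
  out <- do.call(rbind, lapply(seq_len(J), function(j) {
    ctx <- ctxForVolunteer(params, j, data)
    sim <- simulatePBPK(ctx, doses = data.frame(
      time = 0, amount = data$info$dose_mg[j]),
      times = c(seq(0, window - 1), window))
    n <- length(sim$time)
    mrow <- meas[meas$volunteer == data$volunteers[j], ]
    data.frame(volunteer = data$volunteers[j],
               metabolite = c("5OH", "2cx", "5cx"),
               measured = c(mrow$m5OH, mrow$m2cx, mrow$m5cx),
               predicted = c(sim$output$u5OH[n], sim$output$u2cx[n],
                             sim$output$u5cx[n]))
  }))
  rownames(out) <- NULL
  out
}

#' Persist or reload a chain as delimited text
#'
#' One row per retained sample with a header of parameter names plus a
#' \code{logPost} column; run metadata is written to a \code{.meta.tsv}
#' sidecar.
#'
#' @param chain A \code{\link{runMCMC}} result.
#' @param path Output path for the samples table.
#' @return \code{readChain} returns a \code{dehtpChain}-like object
#'   (samples, logPost, config).
#' @export
writeChain <- function(chain, path) {
  stopifnot(inherits(chain, "dehtpChain"))
  tab <- cbind(as.data.frame(chain$samples), logPost = chain$logPost)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- data.frame(key = names(chain$config),
                     value = unlist(chain$config))
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeChain
#' @export
readChain <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  meta <- utils::read.delim(paste0(path, ".meta.tsv"))
  config <- as.list(stats::setNames(meta$value, meta$key))
  config[] <- lapply(config, function(v)
    if (!is.na(suppressWarnings(as.numeric(v)))) as.numeric(v) else v)
  lp <- tab$logPost
  samples <- as.matrix(tab[, setdiff(names(tab), "logPost"), drop = FALSE])
  structure(list(samples = samples, logPost = lp,
                 acceptance = NULL, config = config),
            class = "dehtpChain")
}
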