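#' Fit an in vitro substrate-depletion half-life
#'
#' Estimates the first-order depletion rate constant k by ordinary least
#' squares of log concentration on time (slope = -k) and returns the
#' half-life T1/2 = ln 2 / k.  Replicate incubations are fitted
#' independently (sampling schedules differ between incubations), so the
#' input is a single replicate's series.
#'
#' @param time Sampling times in minutes, strictly increasing, length >= 3.
#' @param concentration Relative substrate amounts, all positive.
#' @return Half-life in minutes, with the fitted \code{k} (per minute) as
#'   attribute \code{"k"}.
#' @export
#' @examples
#' t <- c(0, 15, 30, 45)
#' fitDepletionHalfLife(t, exp(-0.022697 * t))  # 30.54 min
fitDepletionHalfLife <- function(time, concentration) {
  if (length(time) < 3L) stop("need at least 3 time points")
  if (length(time) != length(concentration))
    stop("time and concentration lengths differ")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(concentration <= 0)) stop("concentrations must be positive")
  fit <- stats::lm.fit(cbind(1, time), log(concentration))
  k <- -fit$coefficients[[2L]]
  if (!is.finite(k) || k <= 0)
    stop("fitted depletion rate is not positive: no measurable depletion")
  structure(log(2) / k, k = k)
}

#' Read substrate-depletion series from delimited text
#'
#' Expects a header with columns \code{replicate}, \code{time_min},
#' \code{concentration}.
#'
#' @param path File path.
#' @return data.frame with those three columns, checked for validity.
#' @export
readDepletionSeries <- function(path) {
  x <- utils::read.delim(path, sep = "", header = TRUE)
  need <- c("replicate", "time_min", "concentration")
  if (!all(need %in% names(x)))
    stop("depletion file must have columns: ", paste(need, collapse = ", "))
  x <- x[order(x$replicate, x$time_min), need]
  if (any(x$concentration <= 0)) stop("concentrations must be positive")
  bad <- tapply(x$time_min, x$replicate, function(t) any(diff(t) <= 0))
  if (any(unlist(bad))) stop("times must be strictly increasing within replicate")
  x
}

#' In vitro intrinsic clearance from a depletion half-life
#'
#' \deqn{CL_{in\,vitro} = \frac{\ln 2}{T_{1/2}} \times
#'       \frac{ml\ incubation}{mg\ microsomes}}
#'
#' @param tHalf In vitro half-life in minutes, positive.
#' @param incubationVolume Incubation volume in ml (default 1 ml).
#' @param microsomalProtein Microsomal protein in the incubation in mg
#'   (default 0.5 mg: 0.5 mg/ml protein in a 1 ml incubation).
#' @return Intrinsic clearance in ml min^-1 mg^-1 microsomal protein.
#' @export
intrinsicClearanceInVitro <- function(tHalf, incubationVolume = 1,
                                      microsomalProtein = 0.5) {
  if (any(c(tHalf, incubationVolume, microsomalProtein) <= 0))
    stop("tHalf, incubationVolume and microsomalProtein must be positive")
  (log(2) / tHalf) * (incubationVolume / microsomalProtein)
}

#' Scale in vitro intrinsic clearance to a whole organ
#'
#' \deqn{CL_{int} = CL_{in\,vitro} \times MPY \times V_{organ} \times 60 / 1000}
#' where MPY is the microsomal protein yield (mg per g organ) and the
#' organ mass is in grams.  The printed scale-up yields ml/h; the division
#' by 1000 reports L/h for dimensional consistency with the well-stirred
#' clearance formula.
#'
#' @param clInVitro Intrinsic clearance, ml min^-1 mg^-1 protein.
#' @param mpy Microsomal protein yield, mg per g organ.
#' @param organMass Organ mass in g.
#' @return Organ intrinsic clearance in L/h.
#' @export
#' @examples
#' cl <- intrinsicClearanceInVitro(30.54)     # 0.0454 ml/min/mg
#' scaleClearanceToOrgan(cl, 34, 2750)        # ~255 L/h, liver
#' scaleClearanceToOrgan(cl, 3.34, 1335)      # ~12 L/h, gut
scaleClearanceToOrgan <- function(clInVitro, mpy, organMass) {
  if (any(c(clInVitro, mpy, organMass) < 0))
    stop("inputs must be non-negative")
  clInVitro * mpy * organMass * 60 / 1000
}

#' Well-stirred hepatic plasma clearance
#'
#' \deqn{CL_H = \frac{Q_H \, fu \, CL_{int,H}}
#'                   {Q_H + fu \, CL_{int,H} / (C_{RBC}/C_P)}}
#' Clearance is bounded above by hepatic blood flow \eqn{Q_H}
#' (flow-limited regime) and tends to \eqn{fu \, CL_{int,H}} when
#' intrinsic clearance is small (unbound-limited regime).
#'
#' @param qh Hepatic blood flow, L/h.
#' @param fu Plasma fraction unbound, in (0, 1].
#' @param clInt Organ intrinsic clearance, L/h.
#' @param rbcPlasmaRatio Red-cell to plasma concentration ratio
#'   \eqn{C_{RBC}/C_P} (default 1).
#' @return Whole-organ plasma clearance in L/h.
#' @export
hepaticPlasmaClearance <- function(qh, fu, clInt, rbcPlasmaRatio = 1) {
  if (qh <= 0 || clInt < 0 || rbcPlasmaRatio <= 0)
    stop("qh and rbcPlasmaRatio must be positive, clInt non-negative")
  if (fu < 0 || fu > 1) stop("fu must lie in [0, 1]")
  qh * fu * clInt / (qh + fu * clInt / rbcPlasmaRatio)
}
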