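#' Default physiology
#'
#' Reference anatomical and physiological parameter set for an adult male:
#' body weight, organ volume fractions (fraction of body weight, tissue
#' density 1 kg/L), cardiac output coefficient (L/h per kg body weight)
#' and regional blood-flow fractions (fraction of cardiac output).  Flow
#' fractions are renormalised to sum to one when the model context is
#' built.
#'
#' @param bodyWeight Body weight in kg (default 89).
#' @return Object of class \code{dehtpPhysiology} (named list).
#' @export
defaultPhysiology <- function(bodyWeight = 89) {
  phys <- list(
    BW = bodyWeight,
    QCC = 14,           # cardiac output, L/h per kg
    # organ volume fractions (of BW)
    VLiC = 0.0309, VKiC = 0.0058, VFaC = 0.195, VGuC = 0.015,
    VStC = 0.0022, VSpdC = 0.607, VRpdC = 0.0371, VBldC = 0.05,
    # blood-flow fractions (of cardiac output); QHepartC is hepatic artery
    QHepartC = 0.060, QKiC = 0.200, QFaC = 0.050, QGuC = 0.149,
    QStC = 0.011, QSpdC = 0.270, QRpdC = 0.220,
    haematocrit = 0.45,
    arterialFraction = 0.25  # arterial share of blood volume
  )
  class(phys) <- "dehtpPhysiology"
  validatePhysiology(phys)
  phys
}

validatePhysiology <- function(phys) {
  num <- unlist(phys[setdiff(names(phys), character())])
  bad <- names(num)[!is.finite(num) | num <= 0]
  if (length(bad))
    stop("physiology parameters must be positive and finite: ",
         paste(bad, collapse = ", "))
  vsum <- with(phys, VLiC + VKiC + VFaC + VGuC + VStC + VSpdC + VRpdC + VBldC)
  if (vsum > 0.953)  # vascularised-tissue budget
    stop(sprintf("organ volume fractions sum to %.3f > 0.95", vsum))
  if (phys$haematocrit >= 1 || phys$arterialFraction >= 1)
    stop("haematocrit and arterialFraction must be fractions below 1")
  invisible(phys)
}

#' @export
print.dehtpPhysiology <- function(x, ...) {
  cat(sprintf("<dehtpPhysiology> BW %.1f kg, cardiac output %.0f L/h\n",
              x$BW, x$QCC * x$BW))
  invisible(x)
}

#' Default global kinetic parameters
#'
#' Baseline values for the parameters shared across volunteers: arterial
#' bound fractions, in vivo DEHTP half-lives (liver, gut; minutes), in
#' vitro MEHTP depletion half-life (minutes; drives hepatic intrinsic
#' clearance), partition coefficients of both chemicals and the
#' first-order urinary elimination rates of the three second-order
#' metabolites.  Defaults are the baseline column of the parameter table;
#' parameters specified only by priors take their prior medians.
#'
#' @return Object of class \code{dehtpGlobals} (named list).
#' @export
defaultGlobals <- function() {
  glob <- list(
    FB_DEHTP = 0.9, FB_MEHTP = 0.9,
    DEHTP_half_life = 3,          # min, liver
    DEHTP_GUT_half_life = 60,     # min
    T_half_MEHTP = 30.54,         # min, in vitro
    # DEHTP tissue:blood PCs
    Pbab = 15.5, Pfab = 47.2, Plib = 5.89, Pkib = 3.7, Prbcb = 3.0,
    Pgub = 7.4, Pstb = 3.7, Prpdb = 3.7, Pspdb = 3.3,
    # MEHTP tissue:blood PCs
    PbaM = 25.23, PfaM = 20.3, PliM = 5.9, PkiM = 12.2, PrbcM = 6.67,
    PguM = 7.4, PstM = 7.4, PrpdM = 3.7, PspdM = 3.3,
    # urinary elimination of second-order metabolites, 1/h
    K1_MOH = 2.49, K1_2cx = 2.49, K1_5cx = 2.49,
    escapeFracgu = 0.49, escapeFracli = 0.49,
    K1_MEHTP_kidney = 0.1,        # renal elimination of MEHTP itself, 1/h
    incubationVolume = 1,         # ml, in vitro assay
    microsomalProtein = 0.5       # mg per incubation
  )
  class(glob) <- "dehtpGlobals"
  glob
}

#' Default volunteer-level (local) parameters
#'
#' Baseline values for the parameters that vary between volunteers: the
#' fractions of MEHTP routed to each measured metabolite, enterohepatic
#' bile uptake, dose-fraction split, lumen-to-blood uptake rates, transit
#' delays, lymph release, microsomal protein yields and the calibrated
#' physiological fractions.  Defaults are prior medians.
#'
#' @return Object of class \code{dehtpLocals} (named list).
#' @export
defaultLocals <- function() {
  loc <- list(
    FracMetabMOH = 0.065, FracMetab2cx = 0.010, FracMetab5cx = 0.425,
    K1_DEHTP_Liver = 1,     # 1/h, liver -> bile (baseline value)
    FracDOSEHep = 0.354, FracDoseLymph = 0.152,
    BELLYPERM = 3.72, GIPERM1 = 4.98, GIPERM2 = 15.17,  # 1/h
    Gutlag = 1.98, Lymphlag = 3.0,                      # h
    K1_Lymph = 1.53,                                    # 1/h
    MPY = 34, MPYgu = 3.34,                             # mg/g
    VBldC = 0.05, VliC = 0.0309, VguC = 0.015, VkiC = 0.0058,
    QguC = 0.149,
    bileLag = 2,            # h, liver-to-gut bile transit (fixed)
    gastricEmptying = 2     # 1/h, stomach-lumen to gut-1 (fixed)
  )
  class(loc) <- "dehtpLocals"
  loc
}

#' Absorbed fraction of an oral DEHTP dose
#'
#' The sum of the hepatic and lymphatic dose fractions; the remainder of
#' the dose passes straight through the gut to faeces.
#'
#' @param loc A \code{\link{defaultLocals}}-style list (or any list with
#'   \code{FracDOSEHep} and \code{FracDoseLymph}).
#' @return Dimensionless absorbed fraction.
#' @export
#' @examples
#' absorbedFraction(list(FracDOSEHep = 0.031, FracDoseLymph = 0.263)) # 0.294
absorbedFraction <- function(loc) {
  f <- loc$FracDOSEHep + loc$FracDoseLymph
  if (any(f < 0 | f > 1)) stop("dose fractions must lie in [0, 1]")
  f
}
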