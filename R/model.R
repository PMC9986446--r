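## Internal layout shared by the R reference derivatives and the compiled
## C derivatives.  Order matters: the C code indexes both vectors by
## position.  NG/NB are the Erlang transit-chain lengths for the gut-1
## residence (Gutlag) and the liver-to-gut bile transit.

.NG <- 5L
.NB <- 5L

.parmNames <- c(
  "mwRatio", "fbD", "fbM", "kMetLiD", "kMetGuD", "clIntM",
  "k1MOH", "k12cx", "k15cx", "fracMOH", "frac2cx", "frac5cx",
  "escGu", "escLi", "k1Bile", "kBileT", "kGutT", "k1Lymph",
  "bellyperm", "giperm1", "giperm2", "kGE", "k1MKid",
  "qc", "qHa", "qKi", "qFa", "qGu", "qSt", "qSpd", "qRpd",
  "vArt", "vVen", "vLi", "vKi", "vFa", "vGu", "vSt", "vSpd", "vRpd",
  "pLiD", "pKiD", "pFaD", "pGuD", "pStD", "pSpdD", "pRpdD",
  "pLiM", "pKiM", "pFaM", "pGuM", "pStM", "pSpdM", "pRpdM")

.stateNames <- c(
  "AST", paste0("AG1_", seq_len(.NG)), "AG2", "ALY",
  paste0("ABI_", seq_len(.NB)),
  "AART", "AVEN", "ALI", "AKI", "AFA", "AGU", "ASTT", "ASPD", "ARPD",
  "AFAEC",
  "MART", "MVEN", "MLI", "MKI", "MFA", "MGU", "MSTT", "MSPD", "MRPD",
  "MURN", "PMOH", "P2CX", "P5CX", "UMOH", "U2CX", "U5CX", "TPA")

#' Build a PBPK model context
#'
#' Derives organ volumes (L, tissue density 1), regional blood flows
#' (L/h, renormalised to sum to cardiac output), first-order metabolism
#' rates from the in vivo half-lives (k = 60 ln2 / T1/2 in 1/h), the
#' MEHTP hepatic intrinsic clearance from the in vitro depletion
#' half-life scaled through microsomal protein yield and liver mass, and
#' packs everything into the parameter vector the ODE right-hand side
#' consumes.
#'
#' @param phys A \code{\link{defaultPhysiology}}-style list.
#' @param glob A \code{\link{defaultGlobals}}-style list.
#' @param loc A \code{\link{defaultLocals}}-style list; its VBldC, VliC,
#'   VguC, VkiC and QguC override the physiology fractions.
#' @param chems Chemical set, \code{\link{defaultChemicals}}.
#' @param validate Run invariant checks (disable only in tight loops that
#'   have already validated their inputs).
#' @return Object of class \code{dehtpModel}: a list with the packed
#'   \code{parms} vector, the derived quantities (\code{volumes},
#'   \code{flows}, \code{clIntM}, \code{clIntGut}) and the inputs.
#' @export
#' @examples
#' ctx <- buildModel()
#' ctx$volumes[["liver"]]  # 2.75 L at 89 kg
buildModel <- function(phys = defaultPhysiology(), glob = defaultGlobals(),
                       loc = defaultLocals(), chems = defaultChemicals(),
                       validate = TRUE) {
  if (validate) {
    validatePhysiology(phys)
    fr <- c(FracDOSEHep = loc$FracDOSEHep, FracDoseLymph = loc$FracDoseLymph,
            FracMetabMOH = loc$FracMetabMOH, FracMetab2cx = loc$FracMetab2cx,
            FracMetab5cx = loc$FracMetab5cx,
            FB_DEHTP = glob$FB_DEHTP, FB_MEHTP = glob$FB_MEHTP,
            escapeFracgu = glob$escapeFracgu, escapeFracli = glob$escapeFracli)
    bad <- names(fr)[fr < 0 | fr > 1]
    if (length(bad))
      stop("fractions outside [0, 1]: ", paste(bad, collapse = ", "))
    if (loc$FracDOSEHep + loc$FracDoseLymph > 1)
      stop("FracDOSEHep + FracDoseLymph exceeds 1")
    if (loc$FracMetabMOH + loc$FracMetab2cx + loc$FracMetab5cx > 0.7)
      stop("metabolised fractions exceed 0.7 (TPA remainder below 0.3)")
    pos <- c(DEHTP_half_life = glob$DEHTP_half_life,
             DEHTP_GUT_half_life = glob$DEHTP_GUT_half_life,
             T_half_MEHTP = glob$T_half_MEHTP, Gutlag = loc$Gutlag,
             Lymphlag = loc$Lymphlag, bileLag = loc$bileLag,
             MPY = loc$MPY, MPYgu = loc$MPYgu)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad))
      stop("parameters must be positive: ", paste(bad, collapse = ", "))
  }

  bw <- phys$BW
  # volumes in L; calibrated local fractions override the physiology
  vBld <- loc$VBldC * bw
  volumes <- c(liver = loc$VliC * bw, kidney = loc$VkiC * bw,
               adipose = phys$VFaC * bw, gut = loc$VguC * bw,
               stomach = phys$VStC * bw, slowly = phys$VSpdC * bw,
               rapidly = phys$VRpdC * bw, blood = vBld,
               arterial = phys$arterialFraction * vBld,
               venous = (1 - phys$arterialFraction) * vBld)

  qc <- phys$QCC * bw
  fracs <- c(hepart = phys$QHepartC, kidney = phys$QKiC, adipose = phys$QFaC,
             gut = loc$QguC, stomach = phys$QStC, slowly = phys$QSpdC,
             rapidly = phys$QRpdC)
  fracs <- fracs / sum(fracs)     # renormalise to cardiac output
  flows <- c(qc * fracs, total = qc)

  # metabolism: first-order rates from half-lives (min -> 1/h)
  kMetLiD <- 60 * log(2) / glob$DEHTP_half_life
  kMetGuD <- 60 * log(2) / glob$DEHTP_GUT_half_life

  clVitro <- intrinsicClearanceInVitro(glob$T_half_MEHTP,
                                       glob$incubationVolume,
                                       glob$microsomalProtein)
  clIntM <- scaleClearanceToOrgan(clVitro, loc$MPY,
                                  volumes[["liver"]] * 1000)
  # gut-wall intrinsic clearance: derived and reported, but metabolism of
  # MEHTP is ascribed to the liver alone, so it does not enter the ODEs
  clIntGut <- scaleClearanceToOrgan(clVitro, loc$MPYgu,
                                    volumes[["gut"]] * 1000)

  mwRatio <- chems$MEHTP$molecularWeight / chems$DEHTP$molecularWeight

  parms <- c(
    mwRatio, glob$FB_DEHTP, glob$FB_MEHTP, kMetLiD, kMetGuD, clIntM,
    glob$K1_MOH, glob$K1_2cx, glob$K1_5cx,
    loc$FracMetabMOH, loc$FracMetab2cx, loc$FracMetab5cx,
    glob$escapeFracgu, glob$escapeFracli,
    loc$K1_DEHTP_Liver, .NB / loc$bileLag, .NG / loc$Gutlag, loc$K1_Lymph,
    loc$BELLYPERM, loc$GIPERM1, loc$GIPERM2, loc$gastricEmptying,
    glob$K1_MEHTP_kidney,
    qc, flows[["hepart"]], flows[["kidney"]], flows[["adipose"]],
    flows[["gut"]], flows[["stomach"]], flows[["slowly"]],
    flows[["rapidly"]],
    volumes[["arterial"]], volumes[["venous"]], volumes[["liver"]],
    volumes[["kidney"]], volumes[["adipose"]], volumes[["gut"]],
    volumes[["stomach"]], volumes[["slowly"]], volumes[["rapidly"]],
    glob$Plib, glob$Pkib, glob$Pfab, glob$Pgub, glob$Pstb, glob$Pspdb,
    glob$Prpdb,
    glob$PliM, glob$PkiM, glob$PfaM, glob$PguM, glob$PstM, glob$PspdM,
    glob$PrpdM)
  names(parms) <- .parmNames

  structure(list(parms = parms, volumes = volumes, flows = flows,
                 clIntM = clIntM, clIntGut = clIntGut,
                 phys = phys, glob = glob, loc = loc, chems = chems),
            class = "dehtpModel")
}

#' @export
print.dehtpModel <- function(x, ...) {
  cat(sprintf(paste0("<dehtpModel> BW %.1f kg, QC %.0f L/h, liver %.2f L\n",
                     "  CLint MEHTP (liver) %.1f L/h, dose split hep %.3f",
                     " / lymph %.3f / faecal %.3f\n"),
              x$phys$BW, x$flows[["total"]], x$volumes[["liver"]],
              x$clIntM, x$loc$FracDOSEHep, x$loc$FracDoseLymph,
              1 - x$loc$FracDOSEHep - x$loc$FracDoseLymph))
  invisible(x)
}

#' PBPK derivatives (R reference implementation)
#'
#' Pure-R implementation of the model right-hand side, index-compatible
#' with the compiled C derivatives used by \code{\link{simulatePBPK}}.
#' Usable directly as a \code{deSolve} \code{func}; kept primarily as an
#' executable specification that the compiled code is cross-checked
#' against.
#'
#' All amounts are mg (second-order metabolites in MEHTP-equivalent mass
#' until the urine output), volumes L, flows L/h, time h.
#'
#' @param t Time (unused: the system is autonomous between dose events).
#' @param state Named state vector (see \code{stateNames()}).
#' @param parms Packed parameter vector from \code{\link{buildModel}}
#'   (\code{ctx$parms}), or a \code{dehtpModel}.
#' @return \code{list(dstate)} as deSolve expects.
#' @export
pbpkRhs <- function(t, state, parms) {
  if (inherits(parms, "dehtpModel")) parms <- parms$parms
  p <- as.list(parms)
  s <- unname(state)
  ng <- .NG; nb <- .NB
  iG1 <- 1L + seq_len(ng)          # AG1 block
  iBI <- (2L + ng + 1L) + seq_len(nb)  # ABI block after AST,AG1,AG2,ALY
  AST <- s[1L]; AG1 <- s[iG1]; AG2 <- s[2L + ng]; ALY <- s[3L + ng]
  ABI <- s[iBI]
  o <- 3L + ng + nb                # offset of circulation block
  AART <- s[o + 1L]; AVEN <- s[o + 2L]; ALI <- s[o + 3L]; AKI <- s[o + 4L]
  AFA <- s[o + 5L]; AGU <- s[o + 6L]; ASTT <- s[o + 7L]; ASPD <- s[o + 8L]
  ARPD <- s[o + 9L]
  m <- o + 10L                     # AFAEC at m; MEHTP block after
  MART <- s[m + 1L]; MVEN <- s[m + 2L]; MLI <- s[m + 3L]; MKI <- s[m + 4L]
  MFA <- s[m + 5L]; MGU <- s[m + 6L]; MSTT <- s[m + 7L]; MSPD <- s[m + 8L]
  MRPD <- s[m + 9L]; MKIcum <- s[m + 10L]
  PMOH <- s[m + 11L]; P2CX <- s[m + 12L]; P5CX <- s[m + 13L]

  with(p, {
    qLiTot <- qHa + qGu + qSt

    ## DEHTP lumen and delay chains
    dAST <- -(kGE + bellyperm) * AST
    dAG1 <- numeric(ng)
    dAG1[1] <- kGE * AST - (kGutT + giperm1 + kMetGuD) * AG1[1]
    if (ng > 1L)
      dAG1[2:ng] <- kGutT * AG1[1:(ng - 1L)] -
        (kGutT + giperm1 + kMetGuD) * AG1[2:ng]
    dAG2 <- kGutT * AG1[ng] + kBileT * ABI[nb] - giperm2 * AG2
    dALY <- -k1Lymph * ALY
    dABI <- numeric(nb)
    dABI[1] <- k1Bile * ALI - kBileT * ABI[1]
    if (nb > 1L)
      dABI[2:nb] <- kBileT * (ABI[1:(nb - 1L)] - ABI[2:nb])

    uptake <- bellyperm * AST + giperm1 * sum(AG1) + giperm2 * AG2
    gutMetD <- kMetGuD * sum(AG1)
    livMetD <- kMetLiD * ALI

    ## DEHTP circulation (flow-limited; only unbound arterial chemical
    ## distributes, the bound stream bypasses to venous blood)
    CartD <- AART / vArt; CvenD <- AVEN / vVen
    CfD <- (1 - fbD) * CartD
    CvLiD <- ALI / (vLi * pLiD); CvKiD <- AKI / (vKi * pKiD)
    CvFaD <- AFA / (vFa * pFaD); CvGuD <- AGU / (vGu * pGuD)
    CvStD <- ASTT / (vSt * pStD); CvSpdD <- ASPD / (vSpd * pSpdD)
    CvRpdD <- ARPD / (vRpd * pRpdD)

    dAART <- qc * (CvenD - CartD)
    dAVEN <- qKi * CvKiD + qFa * CvFaD + qSpd * CvSpdD + qRpd * CvRpdD +
      qLiTot * CvLiD + qc * fbD * CartD - qc * CvenD + uptake +
      k1Lymph * ALY
    dALI <- qHa * CfD + qGu * CvGuD + qSt * CvStD - qLiTot * CvLiD -
      livMetD - k1Bile * ALI
    dAKI <- qKi * (CfD - CvKiD)
    dAFA <- qFa * (CfD - CvFaD)
    dAGU <- qGu * (CfD - CvGuD)
    dASTT <- qSt * (CfD - CvStD)
    dASPD <- qSpd * (CfD - CvSpdD)
    dARPD <- qRpd * (CfD - CvRpdD)
    dAFAEC <- 0

    ## MEHTP formation (molar-mass scaling at the conversion)
    G <- gutMetD * mwRatio
    toVenM <- escGu * G
    toLivM <- (1 - escGu) * escLi * G
    firstPass <- (1 - escGu) * (1 - escLi) * G
    livFormM <- livMetD * mwRatio

    ## MEHTP circulation; hepatic metabolism by intrinsic clearance on
    ## the venous-equivalent liver concentration
    CartM <- MART / vArt; CvenM <- MVEN / vVen
    CfM <- (1 - fbM) * CartM
    CvLiM <- MLI / (vLi * pLiM); CvKiM <- MKI / (vKi * pKiM)
    CvFaM <- MFA / (vFa * pFaM); CvGuM <- MGU / (vGu * pGuM)
    CvStM <- MSTT / (vSt * pStM); CvSpdM <- MSPD / (vSpd * pSpdM)
    CvRpdM <- MRPD / (vRpd * pRpdM)
    metM <- clIntM * CvLiM

    dMART <- qc * (CvenM - CartM)
    dMVEN <- qKi * CvKiM + qFa * CvFaM + qSpd * CvSpdM + qRpd * CvRpdM +
      qLiTot * CvLiM + qc * fbM * CartM - qc * CvenM + toVenM
    dMLI <- qHa * CfM + qGu * CvGuM + qSt * CvStM - qLiTot * CvLiM -
      metM + toLivM + livFormM
    dMKI <- qKi * (CfM - CvKiM) - k1MKid * MKI
    dMFA <- qFa * (CfM - CvFaM)
    dMGU <- qGu * (CfM - CvGuM)
    dMSTT <- qSt * (CfM - CvStM)
    dMSPD <- qSpd * (CfM - CvSpdM)
    dMRPD <- qRpd * (CfM - CvRpdM)
    dMURN <- k1MKid * MKI

    ## second-order metabolite pools (MEHTP-equivalent mass) and urine
    totMet <- metM + firstPass
    dPMOH <- fracMOH * totMet - k1MOH * PMOH
    dP2CX <- frac2cx * totMet - k12cx * P2CX
    dP5CX <- frac5cx * totMet - k15cx * P5CX
    dUMOH <- k1MOH * PMOH
    dU2CX <- k12cx * P2CX
    dU5CX <- k15cx * P5CX
    dTPA <- (1 - fracMOH - frac2cx - frac5cx) * totMet

    list(c(dAST, dAG1, dAG2, dALY, dABI,
           dAART, dAVEN, dALI, dAKI, dAFA, dAGU, dASTT, dASPD, dARPD,
           dAFAEC,
           dMART, dMVEN, dMLI, dMKI, dMFA, dMGU, dMSTT, dMSPD, dMRPD,
           dMURN, dPMOH, dP2CX, dP5CX, dUMOH, dU2CX, dU5CX, dTPA))
  })
}

#' State names of the model
#'
#' @return Character vector naming the 40 model states in order.
#' @export
stateNames <- function() .stateNames
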