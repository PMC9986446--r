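#' Chemical specification
#'
#' A light container for the identity and physico-chemical properties of a
#' chemical in the DEHTP metabolic tree.
#'
#' @param name Chemical name (e.g. \code{"DEHTP"}).
#' @param molecularWeight Molecular weight in g/mol; must be positive.
#' @param logPow Log10 octanol:water partition coefficient.
#' @param fractionUnbound Plasma fraction unbound, strictly in (0, 1).
#'   Defaults to the value predicted from \code{logPow} by
#'   \code{\link{fractionUnbound}}.
#' @param role One of \code{"parent"}, \code{"monoester"},
#'   \code{"secondary"}.
#'
#' @return An object of class \code{chemicalSpec} (a named list).
#' @export
#' @examples
#' chemicalSpec("DEHTP", 390.56, 9.54, role = "parent")
chemicalSpec <- function(name, molecularWeight, logPow = NA_real_,
                         fractionUnbound = NULL,
                         role = c("parent", "monoester", "secondary")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(molecularWeight) || molecularWeight <= 0)
    stop("molecularWeight must be positive for ", name)
  if (is.null(fractionUnbound)) {
    fractionUnbound <- if (is.finite(logPow)) fractionUnbound(logPow) else NA_real_
  }
  if (is.finite(fractionUnbound) &&
      (fractionUnbound <= 0 || fractionUnbound >= 1))
    stop("fractionUnbound must lie strictly in (0, 1) for ", name)
  structure(list(name = name, molecularWeight = molecularWeight,
                 logPow = logPow, fractionUnbound = fractionUnbound,
                 role = role),
            class = "chemicalSpec")
}

#' @export
print.chemicalSpec <- function(x, ...) {
  cat(sprintf("<chemicalSpec> %s (%s)\n  MW %.2f g/mol, logPow %s, fu %s\n",
              x$name, x$role, x$molecularWeight,
              format(x$logPow), format(x$fractionUnbound)))
  invisible(x)
}

#' Default chemical set for the DEHTP model
#'
#' DEHTP (C24H38O4), its monoester MEHTP (C16H22O4) and the three measured
#' side-chain-oxidised metabolites.  Second-order metabolites are tracked
#' in MEHTP-equivalent mass inside the model and converted to their own
#' molecular weight only at the urine output, so only their molecular
#' weights matter.
#'
#' @return Named list of \code{\link{chemicalSpec}} objects with elements
#'   \code{DEHTP}, \code{MEHTP}, \code{OH5} (5OH-MEHTP), \code{cx2}
#'   (2cx-MMHTP) and \code{cx5} (5cx-MEPTP).
#' @export
defaultChemicals <- function() {
  list(
    DEHTP = chemicalSpec("DEHTP", 390.56, 9.54, role = "parent"),
    MEHTP = chemicalSpec("MEHTP", 278.35, 5.84, role = "monoester"),
    # C16H22O5, C16H20O6, C16H20O6 from the side-chain oxidation products
    OH5 = chemicalSpec("5OH-MEHTP", 294.35, role = "secondary"),
    cx2 = chemicalSpec("2cx-MMHTP", 308.33, role = "secondary"),
    cx5 = chemicalSpec("5cx-MEPTP", 308.33, role = "secondary")
  )
}

#' Plasma fraction unbound from log Pow
#'
#' Empirical regression for chemicals predominantly uncharged at pH 7.4:
#' \deqn{fu = 1 / (10^x + 1), \quad x = 0.4485\,\log P_{ow} - 0.4782.}
#' The function is strictly decreasing in log Pow and maps onto (0, 1).
#'
#' @param logPow Log10 octanol:water partition coefficient (vectorised).
#' @return Predicted plasma fraction unbound.
#' @export
#' @examples
#' fractionUnbound(9.54)   # DEHTP, 1.58e-4
#' fractionUnbound(5.84)   # MEHTP, 7.18e-3
fractionUnbound <- function(logPow) {
  if (any(!is.finite(logPow))) stop("logPow must be finite")
  x <- 0.4485 * logPow - 0.4782
  1 / (10^x + 1)
}

#' Fractions of MEHTP metabolised to the measured second-order metabolites
#'
#' Given molar amounts of the five measured urinary species, returns the
#' molar fraction of each of 5OH-MEHTP, 2cx-MMHTP and 5cx-MEPTP relative
#' to the five-species total.  5oxo-MEHTP contributes to the denominator
#' only (it is a downstream product of 5OH-MEHTP and is not simulated), so
#' the three returned fractions sum to less than one.
#'
#' @param molarAmounts Named numeric vector with (at least) entries
#'   \code{MEHTP}, \code{"5OH"}, \code{"2cx"}, \code{"5cx"}, \code{"5oxo"}
#'   in moles; all non-negative, total positive.
#' @return Named numeric vector with fractions \code{"5OH"}, \code{"2cx"},
#'   \code{"5cx"}.
#' @export
fractionsMetabolised <- function(molarAmounts) {
  need <- c("MEHTP", "5OH", "2cx", "5cx", "5oxo")
  if (!all(need %in% names(molarAmounts)))
    stop("molarAmounts must contain: ", paste(need, collapse = ", "))
  a <- molarAmounts[need]
  if (any(a < 0)) stop("molar amounts must be non-negative")
  tot <- sum(a)
  if (tot <= 0) stop("total molar amount must be positive")
  c("5OH" = unname(a[["5OH"]] / tot),
    "2cx" = unname(a[["2cx"]] / tot),
    "5cx" = unname(a[["5cx"]] / tot))
}
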