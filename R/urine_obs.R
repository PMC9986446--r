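#' Read and write urine-void records
#'
#' Void records are exchanged as tab- or comma-delimited text with header
#' \code{volunteer, time_h, volume_L, conc_5OH, conc_2cx, conc_5cx}:
#' time since dose in hours, void volume in litres and the concentration
#' of each measured metabolite in mg/L.  Missing concentrations are
#' rejected, not imputed.
#'
#' @param path File path.
#' @param voids data.frame in the dialect above.
#' @return \code{readVoids}: validated data.frame ordered by volunteer
#'   and time.
#' @export
readVoids <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  x <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  validateVoids(x)
}

#' @rdname readVoids
#' @export
writeVoids <- function(voids, path) {
  validateVoids(voids)
  utils::write.table(voids, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

voidColumns <- c("volunteer", "time_h", "volume_L",
                 "conc_5OH", "conc_2cx", "conc_5cx")

validateVoids <- function(x) {
  if (!all(voidColumns %in% names(x)))
    stop("void records need columns: ", paste(voidColumns, collapse = ", "))
  x <- x[, voidColumns]
  num <- x[, c("time_h", "volume_L", "conc_5OH", "conc_2cx", "conc_5cx")]
  if (any(!is.finite(as.matrix(num))))
    stop("missing or non-finite values in void records")
  if (any(x$volume_L <= 0)) stop("void volumes must be positive")
  if (any(num[c("conc_5OH", "conc_2cx", "conc_5cx")] < 0))
    stop("concentrations must be non-negative")
  # record order within each volunteer must already be chronological:
  # sorting would silently repair (and so hide) corrupted records
  bad <- tapply(x$time_h, x$volunteer, function(t) any(diff(t) <= 0))
  if (any(unlist(bad)))
    stop("void times must be strictly increasing per volunteer")
  if (any(x$time_h <= 0)) stop("void times must be after the dose (t = 0)")
  x <- x[order(x$volunteer), ]   # stable: keeps within-volunteer order
  rownames(x) <- NULL
  x
}

#' Bladder deposition rates from urine voids
#'
#' For each void the deposited mass (concentration x volume) is divided
#' by the time since the previous void, giving an average deposition rate
#' associated with the interval midpoint.  The first interval starts at
#' the dose time (t = 0), assuming the bladder was emptied at dosing.
#'
#' @param voids Void records (see \code{\link{readVoids}}).
#' @return data.frame with one row per void and metabolite: columns
#'   \code{volunteer}, \code{metabolite} (\code{"5OH"}, \code{"2cx"},
#'   \code{"5cx"}), \code{tStart}, \code{tEnd}, \code{midpoint} (h) and
#'   \code{rate} (mg/h).
#' @export
#' @examples
#' v <- data.frame(volunteer = 1, time_h = 2, volume_L = 0.25,
#'                 conc_5OH = 2, conc_2cx = 0, conc_5cx = 0)
#' voidsToRates(v)  # 0.25 mg/h for 5OH at midpoint 1 h
voidsToRates <- function(voids) {
  voids <- validateVoids(voids)
  out <- lapply(split(voids, voids$volunteer), function(v) {
    t0 <- c(0, v$time_h[-nrow(v)])
    dt <- v$time_h - t0
    do.call(rbind, lapply(c("5OH", "2cx", "5cx"), function(metab) {
      conc <- v[[paste0("conc_", metab)]]
      data.frame(volunteer = v$volunteer, metabolite = metab,
                 tStart = t0, tEnd = v$time_h, midpoint = (t0 + v$time_h) / 2,
                 rate = conc * v$volume_L / dt)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$volunteer, out$metabolite, out$tEnd), ]
}

#' Cumulative urinary excretion within a window
#'
#' Sums concentration x volume over all voids up to and including
#' \code{window} hours after dosing, per metabolite and volunteer.
#'
#' @param voids Void records.
#' @param window Window length in hours (default 48), positive.
#' @return data.frame with columns \code{volunteer}, \code{m5OH},
#'   \code{m2cx}, \code{m5cx} (mg).
#' @export
cumulativeExcretion <- function(voids, window = 48) {
  if (window <= 0) stop("window must be positive")
  if (nrow(voids) == 0L)
    return(data.frame(volunteer = character(0), m5OH = numeric(0),
                      m2cx = numeric(0), m5cx = numeric(0)))
  voids <- validateVoids(voids)
  v <- voids[voids$time_h <= window, , drop = FALSE]
  agg <- function(col) {
    if (nrow(v) == 0L) return(stats::setNames(numeric(0), character(0)))
    tapply(v[[col]] * v$volume_L, v$volunteer, sum)
  }
  vols <- sort(unique(voids$volunteer))
  m1 <- agg("conc_5OH"); m2 <- agg("conc_2cx"); m3 <- agg("conc_5cx")
  pick <- function(m) ifelse(as.character(vols) %in% names(m),
                             m[as.character(vols)], 0)
  data.frame(volunteer = vols, m5OH = unname(pick(m1)),
             m2cx = unname(pick(m2)), m5cx = unname(pick(m3)))
}
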