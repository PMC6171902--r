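#' @import methods
NULL

#' DoseSeries: quantal dose groups on a log10 grid
#'
#' An ordered set of dose groups from a quantal (all-or-none) tumorigenicity
#' assay: at each cell dose, `nAnimals` animals were inoculated and `nTumor`
#' developed a tumor. Doses must be positive and lie on an equally spaced
#' log10 grid (e.g. 10-fold dilution steps), the design the Spearman-Karber
#' estimator assumes. Dose-0 control groups are excluded before construction
#' (the log grid is undefined at 0); use [doseSeries()], which drops them
#' with a message.
#'
#' @slot dose Numeric, strictly increasing positive doses (cells/animal).
#' @slot nAnimals Integer, animals inoculated per group.
#' @slot nTumor Integer, tumor-bearing animals per group.
#' @slot extendedLow,extendedHigh Logical flags marking dummy groups added by
#'   [extendSeries()] below/above the tested range.
#'
#' @seealso [doseSeries()], [extendSeries()], [spearmanKarber()]
#' @export
setClass("DoseSeries",
  representation(
    dose = "numeric",
    nAnimals = "integer",
    nTumor = "integer",
    extendedLow = "logical",
    extendedHigh = "logical"
  ),
  prototype(extendedLow = FALSE, extendedHigh = FALSE)
)

setValidity("DoseSeries", function(object) {
  msg <- character()
  k <- length(object@dose)
  if (k == 0L) msg <- c(msg, "series must contain at least one dose group")
  if (length(object@nAnimals) != k || length(object@nTumor) != k) {
    msg <- c(msg, "dose, nAnimals and nTumor must have equal length")
  } else {
    if (any(object@dose <= 0)) msg <- c(msg, "all doses must be > 0")
    if (is.unsorted(object@dose, strictly = TRUE)) {
      msg <- c(msg, "doses must be strictly increasing")
    }
    if (any(object@nAnimals < 1L)) msg <- c(msg, "each group needs >= 1 animal")
    if (any(object@nTumor < 0L) || any(object@nTumor > object@nAnimals)) {
      msg <- c(msg, "nTumor must satisfy 0 <= nTumor <= nAnimals")
    }
    if (k >= 2L) {
      d <- diff(log10(object@dose))
      if (max(d) - min(d) > .GRID_TOL) {
        msg <- c(msg, "log10 doses must be equally spaced (10-fold style grid)")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' PotencyEstimate: Spearman-Karber TPD50 estimate
#'
#' Result of [spearmanKarber()]: the log10 50% tumor-producing dose `m`, its
#' variance, and a normal-theory confidence interval, all on the log10 scale,
#' together with back-transformed doses. `extendedLow`/`extendedHigh` record
#' whether dummy dose groups were added to make the incidence span 0 to 1.
#'
#' @slot m Numeric, log10 TPD50.
#' @slot tpd50 Numeric, `10^m` (cells/animal), unrounded.
#' @slot varM Numeric, variance of `m`.
#' @slot z Numeric, normal quantile used for the interval (default 1.96).
#' @slot ciLog Numeric length 2, `m -/+ z*sqrt(varM)`.
#' @slot ciDose Numeric length 2, `10^ciLog`, unrounded.
#' @slot extendedLow,extendedHigh Logical extension flags carried through.
#'
#' @seealso [spearmanKarber()], [estimateTPD50()], [tpd50Ratio()]
#' @export
setClass("PotencyEstimate",
  representation(
    m = "numeric",
    tpd50 = "numeric",
    varM = "numeric",
    z = "numeric",
    ciLog = "numeric",
    ciDose = "numeric",
    extendedLow = "logical",
    extendedHigh = "logical"
  )
)

setValidity("PotencyEstimate", function(object) {
  msg <- character()
  if (object@varM < 0) msg <- c(msg, "varM must be >= 0")
  if (length(object@ciLog) != 2L || length(object@ciDose) != 2L) {
    msg <- c(msg, "ciLog and ciDose must have length 2")
  } else if (object@ciDose[1] > object@tpd50 || object@ciDose[2] < object@tpd50) {
    msg <- c(msg, "confidence interval must bracket the point estimate")
  }
  if (length(msg)) msg else TRUE
})
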