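# Spearman-Karber estimation of the 50% tumor-producing dose (TPD50).
#
# The estimator works on quantal incidence proportions p_i = k_i/n_i observed
# at doses equally spaced on the log10 scale (spacing d). With x_k the log10
# of the highest dose and the series spanning p_1 = 0 to p_k = 1,
#
#   m      = x_k + d/2 - d * sum_i p_i          (log10 TPD50)
#   Var(m) = d^2 * sum_i p_i (1 - p_i) / n_i
#
# and the 95% CI is m -/+ 1.96 sqrt(Var(m)), back-transformed with 10^.
# A series whose incidence does not reach 0 at the bottom or 1 at the top is
# first extended by one dummy dilution step on the deficient side
# (extendSeries), the convention used for endpoint-dilution titers.

#' Build a quantal dose series
#'
#' Constructs a [DoseSeries-class] from parallel vectors, sorting by dose and
#' dropping dose-0 control groups (a log-dose grid is undefined at dose 0;
#' untreated controls carry no information for the median-dose estimate).
#'
#' @param dose Numeric doses in cells/animal; must be positive after control
#'   removal and lie on an equally spaced log10 grid.
#' @param nAnimals Integer number of animals inoculated per group.
#' @param nTumor Integer number of tumor-bearing animals per group.
#' @return A [DoseSeries-class] object.
#' @examples
#' doseSeries(c(1e2, 1e3, 1e4), nAnimals = c(6, 6, 6), nTumor = c(2, 2, 6))
#' @export
doseSeries <- function(dose, nAnimals, nTumor) {
  if (length(dose) != length(nAnimals) || length(dose) != length(nTumor)) {
    stop("dose, nAnimals and nTumor must have equal length", call. = FALSE)
  }
  keep <- dose > 0
  if (!any(keep)) {
    stop("no positive-dose groups: series contains only dose-0 controls",
         call. = FALSE)
  }
  if (any(!keep)) {
    .logInfo("dropping ", sum(!keep), " dose-0 control group(s) before estimation")
  }
  ord <- order(dose[keep])
  new("DoseSeries",
      dose = as.numeric(dose[keep][ord]),
      nAnimals = as.integer(nAnimals[keep][ord]),
      nTumor = as.integer(nTumor[keep][ord]))
}

#' @describeIn doseSeries Observed incidence proportions k_i/n_i.
#' @param object,x A `DoseSeries`.
#' @export
setGeneric("incidenceProportions", function(object) {
  standardGeneric("incidenceProportions")
})

#' @export
setMethod("incidenceProportions", "DoseSeries", function(object) {
  object@nTumor / object@nAnimals
})

#' Log10 spacing of a dose series
#'
#' @param object A [DoseSeries-class].
#' @return The common log10 step `d` between consecutive doses (for a
#'   single-group series, 1 by convention of the 10-fold design).
#' @export
setGeneric("logSpacing", function(object) standardGeneric("logSpacing"))

#' @export
setMethod("logSpacing", "DoseSeries", function(object) {
  if (length(object@dose) < 2L) return(1)
  mean(diff(log10(object@dose)))
})

#' @export
setMethod("length", "DoseSeries", function(x) length(x@dose))

#' @export
setMethod("as.data.frame", "DoseSeries",
  function(x, row.names = NULL, optional = FALSE, ...) {
    dummy <- rep(FALSE, length(x@dose))
    if (x@extendedLow) dummy[1] <- TRUE
    if (x@extendedHigh) dummy[length(dummy)] <- TRUE
    data.frame(
      dose = x@dose,
      n_animals = x@nAnimals,
      n_tumor = x@nTumor,
      p = incidenceProportions(x),
      dummy = dummy,
      row.names = row.names
    )
  })

setMethod("show", "DoseSeries", function(object) {
  cat("DoseSeries with", length(object@dose), "dose group(s)\n")
  print(as.data.frame(object), row.names = FALSE)
})

#' Extend a dose series with dummy dilution steps
#'
#' The Spearman-Karber estimator requires the incidence to span 0% at the
#' bottom of the dose range and 100% at the top. When the tested range falls
#' short, a dummy group is assumed one dilution step (10-fold for the usual
#' grid) below the lowest tested dose with 0% incidence, and/or one step above
#' the highest dose with 100% incidence. Dummy groups inherit the group size
#' of the adjacent tested group; since their p is 0 or 1 they contribute
#' nothing to the variance. At most one step is added per side; a series still
#' not spanning 0 to 1 afterwards is rejected by [spearmanKarber()].
#'
#' @param series A [DoseSeries-class].
#' @return The series, possibly with dummy groups prepended/appended and the
#'   `extendedLow`/`extendedHigh` flags set.
#' @examples
#' s <- doseSeries(c(1e2, 1e3, 1e4), c(6, 6, 6), c(2, 2, 6))
#' extendSeries(s) # gains a 0/6 dummy group at dose 10
#' @export
setGeneric("extendSeries", function(series) standardGeneric("extendSeries"))

#' @export
setMethod("extendSeries", "DoseSeries", function(series) {
  p <- incidenceProportions(series)
  k <- length(series)
  step <- 10^logSpacing(series)
  dose <- series@dose; nA <- series@nAnimals; nT <- series@nTumor
  lo <- hi <- FALSE
  if (p[1] > 0) {
    dose <- c(dose[1] / step, dose)
    nA <- c(nA[1], nA)
    nT <- c(0L, nT)
    lo <- TRUE
  }
  if (p[k] < 1) {
    dose <- c(dose, dose[length(dose)] * step)
    nA <- c(nA, nA[length(nA)])
    nT <- c(nT, nA[length(nA)])
    hi <- TRUE
  }
  new("DoseSeries", dose = dose, nAnimals = nA, nTumor = nT,
      extendedLow = lo || series@extendedLow,
      extendedHigh = hi || series@extendedHigh)
})

#' Spearman-Karber TPD50 estimate
#'
#' Computes the log10 50% tumor-producing dose from an extended quantal dose
#' series via the Spearman-Karber closed form
#' `m = x_k + d/2 - d * sum(p_i)`, with variance
#' `Var(m) = d^2 * sum(p_i (1 - p_i) / n_i)` and normal-theory interval
#' `m -/+ z sqrt(Var(m))`, everything on the log10 scale. The series must
#' already span incidence 0 to 1 (apply [extendSeries()] first, or use the
#' convenience wrapper [estimateTPD50()]).
#'
#' @param series A [DoseSeries-class] with `p[1] == 0` and `p[k] == 1`.
#' @param z Normal quantile for the confidence interval; 1.96 gives a 95% CI.
#' @return A [PotencyEstimate-class].
#' @examples
#' s <- extendSeries(doseSeries(c(1e2, 1e3, 1e4), c(6, 6, 6), c(2, 2, 6)))
#' spearmanKarber(s)
#' @export
setGeneric("spearmanKarber", function(series, z = 1.96) {
  standardGeneric("spearmanKarber")
})

#' @export
setMethod("spearmanKarber", "DoseSeries", function(series, z = 1.96) {
  .assertScalarNumber(z, "z", positive = TRUE)
  k <- length(series)
  if (k < 2L) {
    stop("degenerate design: at least two dose groups are required",
         call. = FALSE)
  }
  p <- incidenceProportions(series)
  if (p[1] != 0 || p[k] != 1) {
    stop("series does not span incidence 0 to 1; apply extendSeries() first ",
         "(one dummy step per side at most)", call. = FALSE)
  }
  d <- logSpacing(series)
  xk <- log10(series@dose[k])
  m <- xk + d / 2 - d * sum(p)
  varM <- d^2 * sum(p * (1 - p) / series@nAnimals)
  half <- z * sqrt(varM)
  ciLog <- c(m - half, m + half)
  new("PotencyEstimate",
      m = m, tpd50 = 10^m, varM = varM, z = z,
      ciLog = ciLog, ciDose = 10^ciLog,
      extendedLow = series@extendedLow, extendedHigh = series@extendedHigh)
})

#' One-call TPD50 estimation
#'
#' Convenience wrapper: extends the series where needed, then applies
#' [spearmanKarber()].
#'
#' @param series A [DoseSeries-class] (raw, unextended is fine).
#' @param z Normal quantile for the confidence interval.
#' @param extend Apply the dummy-dose extension first (default `TRUE`).
#' @return A [PotencyEstimate-class].
#' @export
estimateTPD50 <- function(series, z = 1.96, extend = TRUE) {
  if (extend) series <- extendSeries(series)
  spearmanKarber(series, z = z)
}

#' @describeIn estimateTPD50 Point estimate on the dose scale (cells/animal).
#' @param object A `PotencyEstimate`.
#' @export
setGeneric("tpd50", function(object) standardGeneric("tpd50"))

#' @export
setMethod("tpd50", "PotencyEstimate", function(object) object@tpd50)

#' Confidence interval of a potency estimate
#'
#' @param object A [PotencyEstimate-class].
#' @param scale `"dose"` for cells/animal or `"log10"` for the log scale.
#' @return Numeric length-2 vector `(lower, upper)`.
#' @export
setGeneric("potencyCI", function(object, scale = c("dose", "log10")) {
  standardGeneric("potencyCI")
})

#' @export
setMethod("potencyCI", "PotencyEstimate", function(object,
                                                   scale = c("dose", "log10")) {
  scale <- match.arg(scale)
  ci <- if (scale == "dose") object@ciDose else object@ciLog
  stats::setNames(ci, c("lower", "upper"))
})

setMethod("show", "PotencyEstimate", function(object) {
  ci <- roundHalfUp(object@ciDose)
  cat("Spearman-Karber potency estimate\n")
  cat(sprintf("  TPD50: %d cells (log10 m = %.4f)\n",
              as.integer(roundHalfUp(object@tpd50)), object@m))
  cat(sprintf("  %.0f%% CI: (%d, %d)   Var(m) = %.5f\n",
              100 * (2 * stats::pnorm(object@z) - 1),
              as.integer(ci[1]), as.integer(ci[2]), object@varM))
  if (object@extendedLow)  cat("  low-dose dummy group assumed (0% incidence)\n")
  if (object@extendedHigh) cat("  high-dose dummy group assumed (100% incidence)\n")
})

#' @export
setMethod("as.data.frame", "PotencyEstimate",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(
      m = x@m,
      tpd50 = x@tpd50,
      tpd50_rounded = roundHalfUp(x@tpd50),
      var_m = x@varM,
      ci_lower = x@ciDose[1],
      ci_upper = x@ciDose[2],
      ci_lower_rounded = roundHalfUp(x@ciDose[1]),
      ci_upper_rounded = roundHalfUp(x@ciDose[2]),
      extended_low = x@extendedLow,
      extended_high = x@extendedHigh,
      row.names = row.names
    )
  })

#' Fold-change between two potency estimates
#'
#' Ratio of the TPD50 point estimates, reported to one decimal. A higher
#' TPD50 means more cells are needed to reach 50% tumor incidence, i.e. the
#' condition is less tumorigenic per cell.
#'
#' @param a,b [PotencyEstimate-class] objects (numerator, denominator).
#' @return `a`'s TPD50 over `b`'s, rounded to one decimal.
#' @export
tpd50Ratio <- function(a, b) {
  stopifnot(is(a, "PotencyEstimate"), is(b, "PotencyEstimate"))
  round(a@tpd50 / b@tpd50, 1)
}

#' Read dose-incidence series from CSV
#'
#' Expects columns `group_label`, `dose`, `n_animals`, `n_tumor`; one
#' [DoseSeries-class] is built per `group_label` (dose-0 controls dropped).
#'
#' @param path CSV file path.
#' @return Named list of [DoseSeries-class], one per group label, in file
#'   order of first appearance.
#' @export
readDoseIncidence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_label", "dose", "n_animals", "n_tumor")
  if (!all(need %in% names(df))) {
    stop("dose-incidence file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  labels <- unique(df$group_label)
  out <- lapply(labels, function(lab) {
    sub <- df[df$group_label == lab, , drop = FALSE]
    doseSeries(sub$dose, sub$n_animals, sub$n_tumor)
  })
  names(out) <- labels
  out
}
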