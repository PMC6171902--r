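# Shared fixtures built in code. Dose-incidence rows, specimen grades and
# per-line variables mirror the printed study tables shipped under
# inst/extdata; per-animal outcomes are reconstructed to be consistent with
# the per-line incidence and latency values.

options(teratopd.quiet = TRUE)

extdata <- function(name) {
  system.file("extdata", name, package = "teratopd", mustWork = TRUE)
}

table1Series <- function() {
  readDoseIncidence(extdata("table1_dose_incidence.csv"))
}

lineVariables <- function() {
  readVariables(extdata("line_variables.csv"))
}

# Per-animal outcomes consistent with the per-line summaries: n animals per
# line, nTumor chosen to give the target incidence percent, the earliest
# palpable week equal to the target latency and later weeks spread upward.
buildOutcomes <- function(vars = lineVariables(), nAnimals = 6L) {
  rows <- lapply(seq_len(nrow(vars)), function(i) {
    nT <- round(vars$incidence_pct[i] / 100 * nAnimals)
    weeks <- rep(NA_integer_, nAnimals)
    if (nT > 0) {
      weeks[seq_len(nT)] <- pmin(vars$latency_weeks[i] + seq_len(nT) - 1L, 16L)
      weeks[1] <- vars$latency_weeks[i]
    }
    data.frame(
      animal_id = sprintf("%s_m%d", vars$line_id[i], seq_len(nAnimals)),
      line_id = vars$line_id[i],
      dose = 3e4,
      tumor_formed = !is.na(weeks),
      first_palpable_week = weeks
    )
  })
  do.call(rbind, rows)
}

# Independent trapezoid-rule oracle for the Spearman-Karber log-median:
# integrates x dP over the piecewise-linear incidence curve.
trapezoidSK <- function(logDose, p) {
  sum((logDose[-length(logDose)] + logDose[-1]) / 2 * diff(p))
}

# Random extended equal-spacing series for property tests.
randomExtendedSeries <- function() {
  k <- sample(3:6, 1)
  d <- sample(c(0.5, 1), 1)
  x0 <- runif(1, 0, 3)
  n <- sample(3:12, k, replace = TRUE)
  nT <- vapply(n, function(ni) sample(0:ni, 1), 0L)
  nT[1] <- 0L
  nT[k] <- n[k]
  doseSeries(10^(x0 + d * (0:(k - 1))), n, nT)
}
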