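# Seeded generators emulating the three data layers of the assay, each with
# ground truth exposed so downstream recovery can be scored:
#   * quantal dose-response cohorts under a one-hit tumor-initiation model,
#   * replicate expression matrices with probes planted on a latent
#     tumorigenicity score built from the per-line latency/incidence ranks,
#   * annotated variant tables constructed arm-by-arm around the triage
#     thresholds.
# Every generator is a pure function of its parameters and the seed.

#' Simulate a quantal dose-response cohort (one-hit model)
#'
#' Under the one-hit model each inoculated cell independently initiates a
#' tumor with a small probability, giving
#' `P(tumor | dose D) = 1 - exp(-ln(2) * D / TPD50)`; the probability is
#' exactly 0.5 at the true TPD50. Each animal's outcome is a Bernoulli draw
#' at its dose; tumor-bearing animals get a first palpable week drawn
#' uniformly from `latencyRange`.
#'
#' @param trueTPD50 True 50% tumor-producing dose (cells/animal).
#' @param doses Dose design (default the 10-fold grid `10^(1:4)`).
#' @param nPerDose Animals per dose group (default 10, recycled).
#' @param seed Integer seed (required: the generator is deterministic).
#' @param latencyRange Integer range of first palpable weeks for
#'   tumor-bearing animals (default 4:9, the span seen across lines).
#' @param lineId Line label stamped on the outcomes.
#' @return A list with `series` (a [DoseSeries-class]), `outcomes` (per-animal
#'   data frame), and `truth` (the generating parameters).
#' @export
simulateDoseResponse <- function(trueTPD50, doses = 10^(1:4), nPerDose = 10L,
                                 seed, latencyRange = 4:9,
                                 lineId = "simulated") {
  .assertScalarNumber(trueTPD50, "trueTPD50", positive = TRUE)
  if (any(doses <= 0) || any(nPerDose < 1)) {
    stop("doses must be positive and nPerDose >= 1", call. = FALSE)
  }
  nPerDose <- rep_len(as.integer(nPerDose), length(doses))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pTumor <- oneHitProbability(doses, trueTPD50)
  nTumor <- stats::rbinom(length(doses), nPerDose, pTumor)
  formed <- unlist(mapply(function(k, n) {
    sample(c(rep(TRUE, k), rep(FALSE, n - k)))
  }, nTumor, nPerDose, SIMPLIFY = FALSE))
  weeks <- rep(NA_integer_, length(formed))
  weeks[formed] <- sample(latencyRange, sum(formed), replace = TRUE)
  outcomes <- data.frame(
    animal_id = sprintf("%s_a%03d", lineId, seq_along(formed)),
    line_id = lineId,
    dose = rep(doses, nPerDose),
    tumor_formed = formed,
    first_palpable_week = weeks
  )
  list(
    series = doseSeries(doses, nPerDose, nTumor),
    outcomes = outcomes,
    truth = list(trueTPD50 = trueTPD50, model = "one_hit", doses = doses,
                 nPerDose = nPerDose, seed = seed)
  )
}

#' One-hit tumor-initiation probability
#'
#' @param dose Cell dose(s).
#' @param tpd50 Dose at which the tumor probability is 0.5.
#' @return `1 - exp(-ln(2) * dose / tpd50)`.
#' @export
oneHitProbability <- function(dose, tpd50) {
  1 - exp(-log(2) * dose / tpd50)
}

#' Latent tumorigenicity score from per-line variables
#'
#' Rank-standardized average of the negated latency midranks and the
#' incidence midranks: a line that forms tumors early and often scores high.
#' Planted probes tied to this score correlate with BOTH screening variables,
#' the structure the dual Spearman selection targets.
#'
#' @param variables Data frame with `line_id`, `latency_weeks`,
#'   `incidence_pct` (see [readVariables()]).
#' @return Named numeric score, standardized to mean 0 / SD 1 across lines.
#' @export
tumorigenicityScore <- function(variables) {
  z <- function(v) as.vector(scale(rank(v, ties.method = "average")))
  s <- (z(-variables$latency_weeks) + z(variables$incidence_pct)) / 2
  s <- as.vector(scale(s))
  stats::setNames(s, variables$line_id)
}

#' Simulate a replicate expression matrix with planted probes
#'
#' Null probes share one baseline mean; planted probes shift each line's mean
#' by `effectSize * sigma * score(line)`, where the score is the latent
#' tumorigenicity score of the supplied variables. Noise is i.i.d. normal
#' with SD `sigma`; detection calls are present independently with
#' probability `presentRate`. Intensities are floored at 0 to stay on the
#' non-negative normalized scale.
#'
#' @param variables Per-line tumorigenicity variables (defines the lines).
#' @param nProbes Total probe count (default 2000).
#' @param nPlanted Number of planted probes (default 100).
#' @param effectSize Mean shift per unit score, in within-line SD units
#'   (default 3).
#' @param sigma Within-line SD on the intensity scale (default 50).
#' @param baseline Baseline mean intensity (default 500, the usual scaling
#'   target of the normalized arrays).
#' @param presentRate Probability a call is `"P"` (default 1).
#' @param nReplicates Replicates per line (default 3).
#' @param seed Integer seed (required).
#' @return A list with `se` (the expression experiment), and `truth`
#'   (`planted` and `null` probe ids, the per-line `score`, and parameters).
#' @export
simulateExpression <- function(variables, nProbes = 2000L, nPlanted = 100L,
                               effectSize = 3, sigma = 50, baseline = 500,
                               presentRate = 1, nReplicates = 3L, seed) {
  if (nPlanted > nProbes) stop("nPlanted must be <= nProbes", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  score <- tumorigenicityScore(variables)
  lines <- rep(variables$line_id, each = nReplicates)
  nSamples <- length(lines)
  probeIds <- sprintf("probe_%05d", seq_len(nProbes))
  planted <- probeIds[seq_len(nPlanted)]
  mu <- matrix(baseline, nProbes, nSamples)
  if (nPlanted > 0L) {
    shift <- effectSize * sigma * score[lines] # per-sample shift for planted
    mu[seq_len(nPlanted), ] <- baseline +
      matrix(shift, nPlanted, nSamples, byrow = TRUE)
  }
  y <- mu + matrix(stats::rnorm(nProbes * nSamples, sd = sigma),
                   nProbes, nSamples)
  y <- pmax(y, 0)
  calls <- matrix(ifelse(stats::runif(nProbes * nSamples) < presentRate,
                         "P", "A"),
                  nProbes, nSamples)
  sampleIds <- sprintf("%s_r%d", lines, sequence(rep(nReplicates,
                                                     nrow(variables))))
  dimnames(y) <- dimnames(calls) <- list(probeIds, sampleIds)
  se <- expressionExperiment(y, calls, lines)
  list(
    se = se,
    truth = list(planted = planted, null = setdiff(probeIds, planted),
                 score = score, effectSize = effectSize, sigma = sigma,
                 presentRate = presentRate, seed = seed)
  )
}

#' Synthetic cancer-gene list
#'
#' A reproducible stand-in for a curated cancer-gene census list: `extra`
#' symbols of the form `CGC0001..` appended to any `include` symbols
#' supplied, up to `nGenes` unique upper-case symbols (default 613, the size
#' of the census-derived list the triage consumes).
#'
#' @param nGenes Total number of symbols (default 613).
#' @param include Character vector of symbols that must be on the list.
#' @return Character vector of unique upper-case symbols.
#' @export
syntheticCancerGeneList <- function(nGenes = 613L, include = character()) {
  include <- unique(toupper(include))
  extra <- sprintf("CGC%04d", seq_len(max(0L, nGenes - length(include))))
  c(include, extra)
}

#' Simulate an annotated variant table around the triage thresholds
#'
#' Builds records arm-by-arm with known truth: `nPass` records per line
#' satisfy every filter criterion, and each `failArms` entry adds records
#' violating exactly one criterion (`vaf`, `depth`, `impact`, `gene`,
#' `cosmic`) while satisfying the rest. VAFs are Beta(2, 5) draws rescaled to
#' the required side of the VAF threshold; depths are Poisson(150) draws
#' truncated to the required side of the depth threshold.
#'
#' @param lineIds Character vector of line labels.
#' @param genes Cancer-gene list the passing records draw symbols from.
#' @param nPass Integer survivors per line (recycled; default sampled
#'   uniformly from 61..77 per line).
#' @param failArms Named integer vector: records per line failing each arm
#'   (default 10 each of `vaf`, `depth`, `impact`, `gene`, `cosmic`).
#' @param vafMin,depthMin Thresholds the construction straddles (defaults
#'   0.09 and 40, matching [filterVariants()]).
#' @param seed Integer seed (required).
#' @return A list with `records` (variant table), and `truth` (per-line
#'   expected survivor counts and the construction parameters).
#' @export
simulateVariants <- function(lineIds, genes, nPass = NULL,
                             failArms = c(vaf = 10L, depth = 10L,
                                          impact = 10L, gene = 10L,
                                          cosmic = 10L),
                             vafMin = 0.09, depthMin = 40L, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(nPass)) {
    nPass <- sample(61:77, length(lineIds), replace = TRUE)
  }
  nPass <- rep_len(as.integer(nPass), length(lineIds))
  arms <- c("pass", names(failArms))

  passVaf <- function(n) vafMin + (1 - vafMin) * stats::rbeta(n, 2, 5) *
    0.99 + 1e-6
  failVaf <- function(n) vafMin * stats::rbeta(n, 2, 5)
  passDepth <- function(n) {
    d <- stats::rpois(n, 150)
    pmax(d, depthMin)
  }
  failDepth <- function(n) {
    d <- stats::rpois(n, 150)
    pmin(d, depthMin - 1L)
  }
  offGenes <- sprintf("NONCGC%04d", 1:50)

  buildArm <- function(line, arm, n) {
    if (n == 0L) return(NULL)
    data.frame(
      line_id = line,
      chrom = sample(c(1:22, "X"), n, replace = TRUE),
      pos = sample.int(1e8, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      gene = if (arm == "gene") sample(offGenes, n, replace = TRUE)
             else sample(genes, n, replace = TRUE),
      vaf = if (arm == "vaf") failVaf(n) else passVaf(n),
      depth = if (arm == "depth") failDepth(n) else passDepth(n),
      impact = if (arm == "impact") {
        sample(c("LOW", "MODIFIER"), n, replace = TRUE)
      } else {
        sample(c("HIGH", "MODERATE"), n, replace = TRUE)
      },
      cosmic_ids = if (arm == "cosmic") "" else
        sprintf("COSM%07d", sample.int(9999999, n)),
      stringsAsFactors = FALSE
    )
  }

  pieces <- list()
  for (i in seq_along(lineIds)) {
    counts <- c(pass = nPass[i], failArms)
    for (arm in arms) {
      pieces[[length(pieces) + 1L]] <-
        buildArm(lineIds[i], arm, as.integer(counts[[arm]]))
    }
  }
  records <- do.call(rbind, pieces)
  if (is.null(records)) {
    records <- data.frame(line_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), gene = character(),
                          vaf = numeric(), depth = integer(),
                          impact = character(), cosmic_ids = character(),
                          stringsAsFactors = FALSE)
  }
  list(
    records = records,
    truth = list(nPass = stats::setNames(nPass, lineIds),
                 failArms = failArms, vafMin = vafMin, depthMin = depthMin,
                 seed = seed)
  )
}
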