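# Probe-selection pipeline over replicate microarray intensities:
#   1. detection-call filter   - keep probes called present in every sample
#   2. per-line ANOVA filter   - keep probes differing among lines (p < 0.05)
#   3. dual rank-correlation   - keep probes whose per-line mean expression
#      Spearman-correlates (p < 0.01, either sign) with BOTH tumor-formation
#      latency and tumor incidence.
# The container is a SummarizedExperiment with two assays ("intensities" on
# the normalized scale, "calls" in {P, A, M}) and a line factor in colData.

#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

#' Build an expression experiment
#'
#' Wraps probe x sample intensities, matching detection calls and the
#' sample-to-line map into a [SummarizedExperiment::SummarizedExperiment].
#' The reference design is 10 lines x 3 replicates = 30 samples, but any
#' balanced replicate structure is accepted.
#'
#' @param intensities Numeric probe x sample matrix (non-negative, normalized
#'   scale), with probe ids as rownames and sample ids as colnames.
#' @param calls Character matrix of identical shape with detection calls in
#'   `{"P", "A", "M"}` (present / absent / marginal).
#' @param lines Character or factor of length `ncol(intensities)` mapping each
#'   sample to its cell line.
#' @return A `SummarizedExperiment` with assays `intensities` and `calls` and
#'   `colData(x)$line`.
#' @export
expressionExperiment <- function(intensities, calls, lines) {
  if (!identical(dim(intensities), dim(calls))) {
    stop("intensities and calls must share dimensions", call. = FALSE)
  }
  if (length(lines) != ncol(intensities)) {
    stop("one line assignment is required per sample", call. = FALSE)
  }
  if (!all(calls %in% c("P", "A", "M"))) {
    stop("detection calls must be 'P', 'A' or 'M'", call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  lines <- factor(lines)
  if (length(unique(table(lines))) > 1L) {
    stop("every line must have the same replicate count", call. = FALSE)
  }
  SummarizedExperiment(
    assays = list(intensities = intensities, calls = calls),
    colData = S4Vectors::DataFrame(line = lines,
                                   row.names = colnames(intensities))
  )
}

#' Read an expression experiment from TSV files
#'
#' @param exprPath Intensities TSV: first column `probe_id`, then one column
#'   per sample.
#' @param callsPath Detection-call TSV with the identical layout, values in
#'   `{P, A, M}`.
#' @param samplesPath Sample sheet CSV with columns `sample_id`, `line_id`.
#' @return A `SummarizedExperiment` (see [expressionExperiment()]).
#' @export
readExpressionSet <- function(exprPath, callsPath, samplesPath) {
  ex <- utils::read.delim(exprPath, check.names = FALSE)
  ca <- utils::read.delim(callsPath, check.names = FALSE)
  sh <- utils::read.csv(samplesPath, stringsAsFactors = FALSE)
  if (names(ex)[1] != "probe_id" || names(ca)[1] != "probe_id") {
    stop("first column of expression/calls TSV must be 'probe_id'",
         call. = FALSE)
  }
  if (!identical(ex$probe_id, ca$probe_id) ||
      !identical(names(ex), names(ca))) {
    stop("expression and calls tables must have identical probe and sample ",
         "layout", call. = FALSE)
  }
  m <- as.matrix(ex[, -1, drop = FALSE])
  rownames(m) <- ex$probe_id
  cm <- as.matrix(ca[, -1, drop = FALSE])
  rownames(cm) <- ca$probe_id
  idx <- match(colnames(m), sh$sample_id)
  if (anyNA(idx)) {
    stop("sample sheet is missing samples: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  expressionExperiment(m, cm, sh$line_id[idx])
}

#' Detection-call filter
#'
#' A probe survives only when called present (`"P"`) in every sample;
#' marginal calls count as absent.
#'
#' @param se Expression experiment from [expressionExperiment()].
#' @return Character vector of retained probe ids.
#' @export
presentFilter <- function(se) {
  calls <- assay(se, "calls")
  if (is.null(calls)) stop("detection calls are missing", call. = FALSE)
  rownames(se)[rowSums(calls == "P") == ncol(se)]
}

#' Per-line ANOVA filter
#'
#' One-way fixed-effects ANOVA of intensity on cell line, per probe, on the
#' normalized intensity scale; probes without a significant line effect
#' (p >= alpha) are eliminated. Probes constant across all samples carry no
#' signal and are eliminated with a logged note.
#'
#' @param se Expression experiment.
#' @param alpha Retention threshold on the ANOVA p-value (default 0.05).
#' @param probes Optional probe ids to restrict to (e.g. the
#'   [presentFilter()] survivors); defaults to all probes.
#' @param log2 Apply a log2(x + 1) transform before testing (off by default:
#'   the filter operates on the scale the intensities are provided on).
#' @return Character vector of retained probe ids.
#' @export
anovaFilter <- function(se, alpha = 0.05, probes = rownames(se), log2 = FALSE) {
  g <- colData(se)$line
  if (nlevels(g) < 2L || min(table(g)) < 2L) {
    stop("ANOVA filter needs >= 2 lines with >= 2 replicates each",
         call. = FALSE)
  }
  y <- assay(se, "intensities")[probes, , drop = FALSE]
  if (log2) y <- log2(y + 1)
  f <- rowAnovaF(y, g)
  constant <- is.na(f$p)
  if (any(constant)) {
    .logInfo(sum(constant), " constant probe(s) eliminated by the ANOVA filter")
  }
  probes[!constant & f$p < alpha]
}

#' Row-wise one-way ANOVA F statistics
#'
#' Vectorized fixed-effects one-way ANOVA across the rows of a matrix: the
#' decomposition of each row's total sum of squares into between-group and
#' within-group parts, with the upper-tail F p-value. Rows with zero total
#' variance get `NA` statistics.
#'
#' @param y Numeric matrix (features x samples).
#' @param g Factor of group labels, one per column.
#' @return A list with numeric vectors `F` and `p` (length `nrow(y)`).
#' @export
rowAnovaF <- function(y, g) {
  g <- factor(g)
  N <- ncol(y)
  k <- nlevels(g)
  n <- as.vector(table(g))
  ind <- stats::model.matrix(~ 0 + g) # samples x groups indicator
  gm <- (y %*% ind) / rep(n, each = nrow(y)) # row x group means
  grand <- rowMeans(y)
  ssb <- rowSums(sweep(gm, 1, grand)^2 * rep(n, each = nrow(y)))
  sst <- rowSums(sweep(y, 1, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  zero <- sst <= .Machine$double.eps * N * pmax(grand^2, 1)
  Fstat[zero] <- NA_real_
  p[zero] <- NA_real_
  list(F = Fstat, p = p)
}

#' Per-line mean expression
#'
#' Arithmetic mean of the replicate intensities for each line, the summary
#' correlated against the per-line tumorigenicity variables.
#'
#' @param se Expression experiment.
#' @param probes Optional probe ids to restrict to.
#' @return Numeric probe x line matrix.
#' @export
perLineSummary <- function(se, probes = rownames(se)) {
  g <- colData(se)$line
  y <- assay(se, "intensities")[probes, , drop = FALSE]
  n <- as.vector(table(g))
  ind <- stats::model.matrix(~ 0 + g)
  out <- (y %*% ind) / rep(n, each = nrow(y))
  colnames(out) <- levels(g)
  rownames(out) <- probes
  out
}

# Spearman rho (midranks) of each row of m against v, with the two-sided
# t-approximation p-value on n - 2 degrees of freedom.
.rowSpearman <- function(m, v) {
  n <- length(v)
  rv <- rank(v)
  rm_ <- t(apply(m, 1, rank))
  if (nrow(m) == 1L) rm_ <- matrix(rank(m[1, ]), nrow = 1)
  rv_c <- rv - mean(rv)
  rm_c <- rm_ - rowMeans(rm_)
  denom <- sqrt(rowSums(rm_c^2) * sum(rv_c^2))
  rho <- as.vector(rm_c %*% rv_c) / denom
  rho[denom == 0] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[is.finite(rho) & abs(rho) >= 1 - 1e-12] <- 0
  list(rho = rho, p = p)
}

# Monte-Carlo permutation p-value for row-wise Spearman rho: permutes the
# line labels of v, two-sided by |rho|.
.rowSpearmanPerm <- function(m, v, nPerm, seed) {
  obs <- .rowSpearman(m, v)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  hits <- rep(1, nrow(m)) # add-one correction
  for (i in seq_len(nPerm)) {
    r <- .rowSpearman(m, sample(v))
    hits <- hits + (abs(r$rho) >= abs(obs$rho) - 1e-12)
  }
  list(rho = obs$rho, p = hits / (nPerm + 1))
}

#' Read per-line tumorigenicity variables
#'
#' CSV with columns `line_id`, `latency_weeks`, `incidence_pct`.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
readVariables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "latency_weeks", "incidence_pct")
  if (!all(need %in% names(df))) {
    stop("variables file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$line_id)) {
    stop("duplicate line_id in variables file", call. = FALSE)
  }
  df
}

#' Spearman association of probes with tumorigenicity variables
#'
#' For each probe, the Spearman rank correlation (midranks for ties) of its
#' per-line mean expression with the line's tumor-formation latency and with
#' its tumor incidence, plus two-sided p-values from the t-approximation with
#' n - 2 degrees of freedom (n = number of lines), or optionally from a
#' seeded Monte-Carlo permutation of line labels.
#'
#' @param summary Probe x line matrix from [perLineSummary()].
#' @param variables Data frame from [readVariables()]; must cover every line
#'   column of `summary`.
#' @param nPerm If > 0, use that many label permutations for the p-values
#'   instead of the t-approximation.
#' @param seed Integer seed for the permutation draw.
#' @return Data frame with one row per probe: `probe_id`, `rho_latency`,
#'   `p_latency`, `rho_incidence`, `p_incidence`, `reason` (`NA` or why the
#'   correlation is undefined). Probes with constant summaries get `NA` rho
#'   and p = 1 with `reason = "constant probe summary"`.
#' @export
spearmanAssoc <- function(summary, variables, nPerm = 0L, seed = NULL) {
  if (ncol(summary) < 4L) {
    stop("at least 4 lines are required for the rank correlation",
         call. = FALSE)
  }
  idx <- match(colnames(summary), variables$line_id)
  if (anyNA(idx)) {
    stop("variables are missing lines: ",
         paste(colnames(summary)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lat <- variables$latency_weeks[idx]
  inc <- variables$incidence_pct[idx]
  for (v in list(latency = lat, incidence = inc)) {
    if (length(unique(v)) == 1L) {
      stop("a tumorigenicity variable is constant across lines; ",
           "rank correlation is undefined", call. = FALSE)
    }
  }
  run <- function(v) {
    if (nPerm > 0L) .rowSpearmanPerm(summary, v, nPerm, seed)
    else .rowSpearman(summary, v)
  }
  a <- run(lat)
  b <- run(inc)
  reason <- ifelse(is.na(a$rho) | is.na(b$rho), "constant probe summary",
                   NA_character_)
  data.frame(
    probe_id = rownames(summary),
    rho_latency = a$rho,
    p_latency = ifelse(is.na(a$rho), 1, a$p),
    rho_incidence = b$rho,
    p_incidence = ifelse(is.na(b$rho), 1, b$p),
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Select probes correlated with both tumorigenicity variables
#'
#' A probe is selected iff its latency correlation AND its incidence
#' correlation are both significant at `alpha` (default 0.01); either sign of
#' rho qualifies. Probes flagged with an undefined correlation are never
#' selected.
#'
#' @param assocs Data frame from [spearmanAssoc()].
#' @param alpha Dual significance threshold (default 0.01).
#' @return `assocs` with a logical `selected` column added.
#' @export
selectCorrelated <- function(assocs, alpha = 0.01) {
  assocs$selected <- !is.na(assocs$rho_latency) & !is.na(assocs$rho_incidence) &
    assocs$p_latency < alpha & assocs$p_incidence < alpha
  assocs
}

#' Run the full probe-selection cascade
#'
#' Detection-call filter, then per-line ANOVA filter, then the dual Spearman
#' screen; each stage operates on the survivors of the previous one.
#'
#' @param se Expression experiment.
#' @param variables Per-line tumorigenicity variables (see [readVariables()]).
#' @param alphaAnova ANOVA retention threshold (default 0.05).
#' @param alphaCorr Dual correlation threshold (default 0.01).
#' @param nPerm,seed Permutation settings passed to [spearmanAssoc()].
#' @param log2 Passed to [anovaFilter()].
#' @return A list with `present` (probe ids), `anova` (probe ids), `assoc`
#'   (association table for the ANOVA survivors, with `selected`), and
#'   `selected` (probe ids).
#' @export
probeSelection <- function(se, variables, alphaAnova = 0.05,
                           alphaCorr = 0.01, nPerm = 0L, seed = NULL,
                           log2 = FALSE) {
  present <- presentFilter(se)
  anova <- anovaFilter(se, alpha = alphaAnova, probes = present, log2 = log2)
  if (length(anova) == 0L) {
    return(list(present = present, anova = anova,
                assoc = NULL, selected = character()))
  }
  sm <- perLineSummary(se, probes = anova)
  assoc <- selectCorrelated(
    spearmanAssoc(sm, variables, nPerm = nPerm, seed = seed),
    alpha = alphaCorr)
  list(present = present, anova = anova, assoc = assoc,
       selected = assoc$probe_id[assoc$selected])
}

#' Collapse selected probes to genes
#'
#' Maps probe ids to gene symbols via a probe-to-gene table and deduplicates:
#' a gene hit by several selected probes is counted once.
#'
#' @param probeIds Character vector of probe ids.
#' @param map Data frame with columns `probe_id`, `gene_symbol`.
#' @return Sorted unique gene symbols; probes missing from the map are
#'   dropped with a logged note.
#' @export
collapseGenes <- function(probeIds, map) {
  idx <- match(probeIds, map$probe_id)
  if (anyNA(idx)) {
    .logInfo(sum(is.na(idx)), " probe(s) missing from the probe-gene map")
  }
  sort(unique(map$gene_symbol[idx[!is.na(idx)]]))
}
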