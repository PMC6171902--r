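# Small deterministic experiment used across tests: 10 lines x 3 replicates.
makeTestSE <- function(nProbes = 50, seed = 123, presentRate = 1,
                       effectSize = 0, nPlanted = 0) {
  simulateExpression(lineVariables(), nProbes = nProbes, nPlanted = nPlanted,
                     effectSize = effectSize, presentRate = presentRate,
                     seed = seed)
}

test_that("the detection-call filter demands present in every sample", {
  sim <- makeTestSE(nProbes = 200, presentRate = 0.97)
  se <- sim$se
  kept <- presentFilter(se)
  calls <- SummarizedExperiment::assay(se, "calls")
  # brute-force scan per probe
  expect_setequal(kept, rownames(se)[apply(calls == "P", 1, all)])
  # flipping one call to marginal removes the probe
  if (length(kept)) {
    calls[kept[1], 5] <- "M"
    se2 <- expressionExperiment(
      SummarizedExperiment::assay(se, "intensities"), calls,
      SummarizedExperiment::colData(se)$line)
    expect_false(kept[1] %in% presentFilter(se2))
  }
  all_present <- makeTestSE(nProbes = 30, presentRate = 1)$se
  expect_length(presentFilter(all_present), 30)
})

test_that("row-wise ANOVA F matches lm and flags constant probes", {
  sim <- makeTestSE(nProbes = 20, nPlanted = 5, effectSize = 2)
  y <- SummarizedExperiment::assay(sim$se, "intensities")
  g <- SummarizedExperiment::colData(sim$se)$line
  f <- rowAnovaF(y, g)
  for (i in c(1, 7, 20)) {
    fit <- anova(lm(y[i, ] ~ g))
    expect_equal(unname(f$F[i]), fit$`F value`[1])
    expect_equal(unname(f$p[i]), fit$`Pr(>F)`[1])
  }
  y[3, ] <- 500 # constant probe
  f2 <- rowAnovaF(y, g)
  expect_true(is.na(f2$p[3]))
})

test_that("the ANOVA filter keeps planted shifts and drops constants", {
  sim <- makeTestSE(nProbes = 100, nPlanted = 10, effectSize = 3)
  se <- sim$se
  kept <- anovaFilter(se)
  expect_true(all(sim$truth$planted %in% kept))
  y <- SummarizedExperiment::assay(se, "intensities")
  y[15, ] <- 500
  se2 <- expressionExperiment(y, SummarizedExperiment::assay(se, "calls"),
                              SummarizedExperiment::colData(se)$line)
  expect_false(rownames(se)[15] %in% anovaFilter(se2))
})

test_that("null probes pass the ANOVA filter at about the nominal rate", {
  sim <- makeTestSE(nProbes = 2000, nPlanted = 0, seed = 77)
  kept <- anovaFilter(sim$se, alpha = 0.05)
  # binomial 99% band around alpha = 0.05 for 2000 null probes
  band <- qbinom(c(0.005, 0.995), 2000, 0.05)
  expect_gte(length(kept), band[1])
  expect_lte(length(kept), band[2])
})

test_that("per-line summary equals brute-force replicate means", {
  sim <- makeTestSE(nProbes = 10)
  se <- sim$se
  sm <- perLineSummary(se)
  y <- SummarizedExperiment::assay(se, "intensities")
  g <- SummarizedExperiment::colData(se)$line
  for (l in levels(g)) {
    expect_equal(unname(sm[, l]), unname(rowMeans(y[, g == l])))
  }
  expect_equal(dim(sm), c(10L, 10L))
})

test_that("spearman association matches cor.test and midrank Pearson", {
  sim <- makeTestSE(nProbes = 40, nPlanted = 10, effectSize = 2, seed = 9)
  vars <- lineVariables()
  sm <- perLineSummary(sim$se)
  assoc <- spearmanAssoc(sm, vars)
  lat <- vars$latency_weeks[match(colnames(sm), vars$line_id)]
  inc <- vars$incidence_pct[match(colnames(sm), vars$line_id)]
  for (i in c(1, 3, 25, 40)) {
    ct <- suppressWarnings(cor.test(sm[i, ], lat, method = "spearman",
                                    exact = FALSE))
    expect_equal(assoc$rho_latency[i], unname(ct$estimate))
    expect_equal(assoc$p_latency[i], ct$p.value, tolerance = 1e-10)
    # independent midrank Pearson oracle
    expect_equal(assoc$rho_incidence[i],
                 cor(rank(sm[i, ]), rank(inc)))
  }
})

test_that("perfectly monotone probes reach |rho| = 1 with untied latencies", {
  vars <- data.frame(line_id = paste0("L", 1:6),
                     latency_weeks = c(3, 5, 7, 9, 11, 13),
                     incidence_pct = c(100, 90, 80, 60, 40, 20))
  sm <- matrix(1:6, nrow = 1, dimnames = list("p1", vars$line_id))
  assoc <- spearmanAssoc(sm, vars)
  expect_equal(assoc$rho_latency, 1)
  expect_equal(assoc$p_latency, 0)
  # sign symmetry: negating the summary negates both correlations
  neg <- spearmanAssoc(-sm + 100, vars)
  expect_equal(neg$rho_latency, -assoc$rho_latency)
  expect_equal(neg$rho_incidence, -assoc$rho_incidence)
})

test_that("constant probe summaries are flagged, never selected", {
  vars <- lineVariables()
  sm <- rbind(p1 = rep(500, 10), p2 = rnorm(10, 500, 50))
  colnames(sm) <- vars$line_id
  assoc <- selectCorrelated(spearmanAssoc(sm, vars))
  expect_true(is.na(assoc$rho_latency[1]))
  expect_identical(assoc$reason[1], "constant probe summary")
  expect_false(assoc$selected[1])
})

test_that("selection requires both variables below the threshold", {
  assoc <- data.frame(probe_id = c("a", "b", "c"),
                      rho_latency = c(0.9, 0.9, 0.9),
                      p_latency = c(0.005, 0.005, 0.02),
                      rho_incidence = c(-0.9, 0.9, 0.9),
                      p_incidence = c(0.005, 0.02, 0.005),
                      reason = NA_character_)
  out <- selectCorrelated(assoc, alpha = 0.01)
  expect_identical(out$selected, c(TRUE, FALSE, FALSE))
})

test_that("the pipeline is a strict cascade of probe subsets", {
  sim <- makeTestSE(nProbes = 300, nPlanted = 20, effectSize = 3,
                    presentRate = 0.995, seed = 21)
  sel <- probeSelection(sim$se, lineVariables())
  expect_true(all(sel$selected %in% sel$anova))
  expect_true(all(sel$anova %in% sel$present))
  expect_true(length(sel$present) <= nrow(sim$se))
})

test_that("permutation p-values share rho and are reported for comparison", {
  sim <- makeTestSE(nProbes = 60, nPlanted = 15, effectSize = 3, seed = 5)
  vars <- lineVariables()
  sm <- perLineSummary(sim$se, probes = rownames(sim$se)[1:30])
  tApprox <- selectCorrelated(spearmanAssoc(sm, vars))
  perm <- selectCorrelated(spearmanAssoc(sm, vars, nPerm = 4000L, seed = 8))
  # the permutation route changes only the p-values, never the correlations
  expect_equal(perm$rho_latency, tApprox$rho_latency)
  expect_equal(perm$rho_incidence, tApprox$rho_incidence)
  expect_true(all(perm$p_latency > 0 & perm$p_latency <= 1))
  # decision agreement is informative, not guaranteed: with the heavy ties
  # of the incidence variable the t-approximation is anti-conservative near
  # the threshold, so borderline probes can flip under permutation
  agree <- mean(perm$selected == tApprox$selected)
  message(sprintf("permutation vs t-approximation decision agreement: %.2f",
                  agree))
  expect_gte(agree, 0.5)
})

test_that("gene collapsing deduplicates multi-probe genes", {
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    gene_symbol = c("TP53", "TP53", "APC", "MEN1"))
  expect_equal(collapseGenes(c("p1", "p2", "p3"), map), c("APC", "TP53"))
  expect_equal(collapseGenes(c("p1", "px"), map), "TP53") # unknown dropped
})

test_that("expression TSV round-trip preserves the experiment", {
  sim <- makeTestSE(nProbes = 8)
  se <- sim$se
  y <- SummarizedExperiment::assay(se, "intensities")
  ca <- SummarizedExperiment::assay(se, "calls")
  d <- withr::local_tempdir()
  write.table(data.frame(probe_id = rownames(y), y, check.names = FALSE),
              file.path(d, "expr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(probe_id = rownames(ca), ca, check.names = FALSE),
              file.path(d, "calls.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(data.frame(sample_id = colnames(y),
                       line_id = SummarizedExperiment::colData(se)$line),
            file.path(d, "samples.csv"), row.names = FALSE)
  rt <- readExpressionSet(file.path(d, "expr.tsv"), file.path(d, "calls.tsv"),
                          file.path(d, "samples.csv"))
  expect_equal(SummarizedExperiment::assay(rt, "intensities"), y,
               tolerance = 1e-12)
  expect_identical(as.character(SummarizedExperiment::colData(rt)$line),
                   as.character(SummarizedExperiment::colData(se)$line))
})
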