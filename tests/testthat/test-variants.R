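geneList <- syntheticCancerGeneList(50, include = c("TP53", "APC", "MEN1"))

makeRecord <- function(vaf, depth, impact, gene, cosmic,
                       line = "L1") {
  data.frame(line_id = line, chrom = "1", pos = 1000L, ref = "A", alt = "T",
             gene = gene, vaf = vaf, depth = depth, impact = impact,
             cosmic_ids = cosmic, stringsAsFactors = FALSE)
}

test_that("VAF bound is strict and depth bound inclusive", {
  boundary <- makeRecord(0.09, 100L, "HIGH", "TP53", "COSM1")
  expect_equal(nrow(filterVariants(boundary, geneList)$surviving), 0L)
  atDepth <- makeRecord(0.40, 40L, "MODERATE", "TP53", "COSM1")
  expect_equal(nrow(filterVariants(atDepth, geneList)$surviving), 1L)
  justAbove <- makeRecord(0.0901, 40L, "HIGH", "TP53", "COSM1")
  expect_equal(nrow(filterVariants(justAbove, geneList)$surviving), 1L)
  shallow <- makeRecord(0.40, 39L, "HIGH", "TP53", "COSM1")
  expect_equal(nrow(filterVariants(shallow, geneList)$surviving), 0L)
})

test_that("each filter arm excludes exactly its violation", {
  recs <- rbind(
    makeRecord(0.40, 100L, "HIGH", "TP53", "COSM1"),      # passes all
    makeRecord(0.05, 100L, "HIGH", "TP53", "COSM2"),      # fails VAF
    makeRecord(0.40, 20L, "HIGH", "TP53", "COSM3"),       # fails depth
    makeRecord(0.40, 100L, "LOW", "TP53", "COSM4"),       # fails impact
    makeRecord(0.40, 100L, "HIGH", "NOTLISTED1", "COSM5"),# fails gene list
    makeRecord(0.40, 100L, "HIGH", "TP53", "")            # fails COSMIC
  )
  res <- filterVariants(recs, geneList)
  expect_equal(res$surviving$cosmic_ids, "COSM1")
  # relaxing arms individually restores the corresponding records
  noCosmic <- filterVariants(recs, geneList, requireCosmic = FALSE)
  expect_equal(nrow(noCosmic$surviving), 2L)
  allImpacts <- filterVariants(recs, geneList,
                               impacts = c("HIGH", "MODERATE", "LOW",
                                           "MODIFIER"))
  expect_equal(nrow(allImpacts$surviving), 2L)
})

test_that("triage equals a brute-force re-evaluation on 500 records", {
  sim <- simulateVariants(paste0("L", 1:5), geneList,
                          nPass = c(20, 20, 20, 20, 20), seed = 303)
  recs <- sim$records
  expect_equal(nrow(recs), 5 * (20 + 50))
  res <- filterVariants(recs, geneList)
  # independent per-record oracle
  oracle <- vapply(seq_len(nrow(recs)), function(i) {
    r <- recs[i, ]
    r$vaf > 0.09 && r$depth >= 40 &&
      r$impact %in% c("HIGH", "MODERATE") &&
      toupper(r$gene) %in% geneList && nzchar(r$cosmic_ids)
  }, TRUE)
  expect_equal(nrow(res$surviving), sum(oracle))
  expect_equal(sort(rownames(res$surviving)), sort(rownames(recs)[oracle]))
  expect_equal(unname(res$counts), rep(20L, 5))
})

test_that("the filter is monotone in every threshold", {
  set.seed(44)
  sim <- simulateVariants(paste0("L", 1:2), geneList, nPass = c(15, 15),
                          seed = 77)
  base <- nrow(filterVariants(sim$records, geneList)$surviving)
  looserVaf <- nrow(filterVariants(sim$records, geneList,
                                   vafMin = 0.01)$surviving)
  looserDepth <- nrow(filterVariants(sim$records, geneList,
                                     depthMin = 10L)$surviving)
  moreImpacts <- nrow(filterVariants(sim$records, geneList,
                                     impacts = c("HIGH", "MODERATE",
                                                 "LOW"))$surviving)
  expect_gte(looserVaf, base)
  expect_gte(looserDepth, base)
  expect_gte(moreImpacts, base)
  # order-independence
  shuf <- sim$records[sample(nrow(sim$records)), ]
  res2 <- filterVariants(shuf, geneList)
  expect_equal(nrow(res2$surviving), base)
})

test_that("unknown impact labels and missing genes are handled as specified", {
  bad <- makeRecord(0.4, 100L, "HUGE", "TP53", "COSM1")
  expect_error(filterVariants(bad, geneList), "unknown impact label 'HUGE'")
  noGene <- rbind(makeRecord(0.4, 100L, "HIGH", "TP53", "COSM1"),
                  makeRecord(0.4, 100L, "HIGH", "", "COSM2"))
  res <- filterVariants(noGene, geneList)
  expect_equal(nrow(res$surviving), 1L)
})

test_that("per-line gene summaries are deduplicated and sorted", {
  recs <- rbind(
    makeRecord(0.4, 100L, "HIGH", "TP53", "COSM1"),
    makeRecord(0.5, 90L, "MODERATE", "TP53", "COSM2"), # same gene again
    makeRecord(0.4, 100L, "HIGH", "APC", "COSM3"),
    makeRecord(0.4, 100L, "HIGH", "MEN1", "COSM4", line = "L2")
  )
  summ <- perLineGeneSummary(filterVariants(recs, geneList))
  expect_equal(summ$L1, c("APC", "TP53"))
  expect_equal(summ$L2, "MEN1")
  empty <- filterVariants(makeRecord(0.01, 100L, "HIGH", "TP53", "COSM1"),
                          geneList)
  expect_equal(perLineGeneSummary(empty)$L1, character(0))
})

test_that("Jaccard overlap matches direct set arithmetic", {
  expect_equal(lineOverlap(list(a = c("X", "Y"), b = c("X", "Y")))["a", "b"], 1)
  expect_equal(lineOverlap(list(a = "X", b = "Y"))["a", "b"], 0)
  expect_equal(lineOverlap(list(a = character(0), b = character(0)))["a", "b"],
               1)
  # printed per-line COSMIC gene sets of the two sibling lines
  sets <- read.delim(extdata("cosmic_gene_sets.tsv"))
  a <- sets$gene[sets$line_id == "201B7"]
  b <- sets$gene[sets$line_id == "253G1"]
  J <- lineOverlap(list(`201B7` = a, `253G1` = b))
  expect_equal(J["201B7", "253G1"],
               length(intersect(a, b)) / length(union(a, b)))
  expect_equal(J["201B7", "253G1"], 39 / 43)
  expect_true(isSymmetric(J))
})

test_that("variant TSV round-trip preserves records", {
  sim <- simulateVariants("L1", geneList, nPass = 5, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(sim$records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- readVariants(path)
  expect_equal(nrow(rt), nrow(sim$records))
  expect_equal(rt$vaf, sim$records$vaf, tolerance = 1e-12)
  expect_identical(rt$cosmic_ids[rt$cosmic_ids == ""],
                   sim$records$cosmic_ids[sim$records$cosmic_ids == ""])
})

test_that("single-sample VCF ingest derives VAF, depth, gene and impact", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: Allele|Annotation|Annotation_Impact|Gene_Name\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    paste0("1\t100\tCOSM111\tA\tT\t.\t.\t",
           "ANN=T|missense_variant|MODERATE|TP53\tDP:AD\t100:60,40"),
    paste0("1\t200\t.\tG\tC\t.\t.\t",
           "ANN=C|stop_gained|HIGH|APC,C|synonymous_variant|LOW|APC\t",
           "DP:AD\t50:45,5")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  recs <- readVariantVcf(path, lineId = "L1")
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$vaf, c(0.4, 0.1))
  expect_equal(recs$depth, c(100L, 50L))
  expect_equal(recs$gene, c("TP53", "APC"))
  expect_equal(recs$impact, c("MODERATE", "HIGH")) # highest-impact transcript
  expect_equal(recs$cosmic_ids, c("COSM111", ""))
})
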