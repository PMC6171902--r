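# Cancer-gene variant triage over annotated exome variants. A variant
# survives when ALL of these hold:
#   * variant allele fraction (VAF)  >  vafMin   (strict; default 0.09)
#   * read depth                     >= depthMin (inclusive; default 40)
#   * predicted impact in {HIGH, MODERATE}
#   * gene symbol on the supplied cancer-gene list
#   * at least one COSMIC id attached to the variant (when required)
# Survivors are summarized to per-line gene sets and compared across lines
# with the Jaccard index.

.IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Read a flat variant table (TSV)
#'
#' Canonical columns: `line_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `gene`, `vaf`, `depth`, `impact` (HIGH/MODERATE/LOW/MODIFIER),
#' `cosmic_ids` (semicolon-joined, may be empty). Records without a gene
#' symbol are dropped with a logged warning; an unknown impact label is an
#' error naming the record.
#'
#' @param path TSV file path.
#' @return Validated data frame of variant records.
#' @export
readVariants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "chrom", "pos", "ref", "alt", "gene", "vaf", "depth",
            "impact", "cosmic_ids")
  if (!all(need %in% names(df))) {
    stop("variant file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$cosmic_ids <- as.character(df$cosmic_ids)
  df$cosmic_ids[is.na(df$cosmic_ids)] <- ""
  validateVariants(df)
}

#' Validate a variant record table
#'
#' @param df Data frame in the layout of [readVariants()].
#' @return The validated table (gene-less records dropped, logged).
#' @export
validateVariants <- function(df) {
  bad <- which(!df$impact %in% .IMPACT_LEVELS)
  if (length(bad)) {
    stop("unknown impact label '", df$impact[bad[1]], "' in record ",
         df$line_id[bad[1]], ":", df$chrom[bad[1]], ":", df$pos[bad[1]],
         call. = FALSE)
  }
  if (any(df$vaf < 0 | df$vaf > 1)) {
    stop("vaf must lie in [0, 1]", call. = FALSE)
  }
  if (any(df$depth < 0)) stop("depth must be >= 0", call. = FALSE)
  if (any(df$pos < 1)) stop("pos must be >= 1 (1-based)", call. = FALSE)
  noGene <- is.na(df$gene) | !nzchar(df$gene)
  if (any(noGene)) {
    .logInfo("dropping ", sum(noGene), " record(s) without a gene symbol")
    df <- df[!noGene, , drop = FALSE]
  }
  df
}

#' Read a cancer-gene list (TSV, one symbol per line)
#'
#' Symbols are case-normalized to upper case and deduplicated; hyphenated
#' symbols (e.g. HLA-A) are preserved verbatim apart from case.
#'
#' @param path File path.
#' @return Character vector of unique upper-case gene symbols.
#' @export
readGeneList <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  unique(toupper(trimws(x[nzchar(trimws(x))])))
}

#' Read variants from a single-sample VCF
#'
#' Minimal ingest for annotated VCFs: VAF from FORMAT `AF` (or derived as
#' alt/total from FORMAT `AD`), depth from FORMAT `DP`, gene and impact from
#' the first matching SnpEff-style `ANN` INFO entry (taking the
#' highest-impact annotation when several transcripts are annotated), COSMIC
#' ids from the ID column (entries starting with `COS`) or from `cosmicKey`
#' in INFO. Multi-allelic records are expanded to one row per alt allele.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param lineId Cell-line identifier to stamp on every record.
#' @param cosmicKey Optional INFO key carrying COSMIC ids.
#' @return Data frame in the layout of [readVariants()].
#' @export
readVariantVcf <- function(path, lineId, cosmicKey = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("readVariantVcf() requires the VariantAnnotation package",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) != 1L) {
    stop("expected a single-sample VCF, found ", ncol(vcf), " samples",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  n <- length(rr)

  depth <- if ("DP" %in% names(geno)) as.integer(geno$DP[, 1]) else
    rep(NA_integer_, n)
  # per-variant (ref, alt) allele depths regardless of the container shape
  adPair <- function(ad, i) {
    if (is.list(ad)) ad[[i, 1]] else if (length(dim(ad)) == 3) ad[i, 1, ]
    else ad[i, ]
  }
  vaf <- if ("AF" %in% names(geno)) {
    af <- geno$AF
    if (is.list(af)) vapply(af[, 1], function(a) as.numeric(a)[1], 0)
    else as.numeric(af[, 1])
  } else if ("AD" %in% names(geno)) {
    vapply(seq_len(n), function(i) {
      a <- adPair(geno$AD, i)
      if (sum(a) == 0) return(0)
      a[2] / sum(a)
    }, 0)
  } else {
    stop("VCF carries neither FORMAT AF nor AD; cannot derive VAF",
         call. = FALSE)
  }

  info <- VariantAnnotation::info(vcf)
  gene <- rep(NA_character_, n)
  impact <- rep(NA_character_, n)
  if ("ANN" %in% names(info)) {
    ann <- info$ANN
    pick <- function(entries) {
      if (length(entries) == 0L) return(c(NA_character_, NA_character_))
      fields <- strsplit(entries, "|", fixed = TRUE)
      imps <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA, "")
      genes <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA, "")
      best <- order(match(imps, .IMPACT_LEVELS))[1]
      c(genes[best], imps[best])
    }
    gi <- vapply(seq_len(n), function(i) pick(ann[[i]]), c("", ""))
    gene <- gi[1, ]
    impact <- gi[2, ]
  }

  ids <- names(rr)
  cosmic <- vapply(strsplit(ifelse(is.na(ids), "", ids), ";"), function(v) {
    paste(v[startsWith(v, "COS")], collapse = ";")
  }, "")
  if (!is.null(cosmicKey) && cosmicKey %in% names(info)) {
    extra <- vapply(info[[cosmicKey]], paste, "", collapse = ";")
    cosmic <- ifelse(nzchar(cosmic), cosmic, extra)
  }

  validateVariants(data.frame(
    line_id = lineId,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    gene = gene,
    vaf = vaf,
    depth = depth,
    impact = impact,
    cosmic_ids = cosmic,
    stringsAsFactors = FALSE
  ))
}

#' Variant triage cascade
#'
#' Applies the full filter (VAF strict, depth inclusive, impact class,
#' cancer-gene-list membership, variant-level COSMIC membership) and returns
#' the survivors with per-line counts.
#'
#' @param records Variant table from [readVariants()] / [validateVariants()].
#' @param genes Character vector of cancer-gene symbols (upper case; see
#'   [readGeneList()]).
#' @param vafMin Strict lower bound on VAF (record kept iff `vaf > vafMin`;
#'   default 0.09).
#' @param depthMin Inclusive lower bound on read depth (default 40).
#' @param impacts Retained impact classes (default HIGH and MODERATE).
#' @param requireCosmic Require a non-empty `cosmic_ids` field
#'   (default `TRUE`).
#' @return A list with `surviving` (the filtered table), `counts` (named
#'   per-line survivor counts) and the thresholds used.
#' @export
filterVariants <- function(records, genes, vafMin = 0.09, depthMin = 40L,
                           impacts = c("HIGH", "MODERATE"),
                           requireCosmic = TRUE) {
  records <- validateVariants(records)
  if (!all(impacts %in% .IMPACT_LEVELS)) {
    stop("impacts must be a subset of: ",
         paste(.IMPACT_LEVELS, collapse = ", "), call. = FALSE)
  }
  keep <- records$vaf > vafMin &
    records$depth >= depthMin &
    records$impact %in% impacts &
    toupper(records$gene) %in% toupper(genes)
  if (requireCosmic) keep <- keep & nzchar(records$cosmic_ids)
  surviving <- records[keep, , drop = FALSE]
  counts <- table(factor(surviving$line_id, levels = unique(records$line_id)))
  list(
    surviving = surviving,
    counts = stats::setNames(as.integer(counts), names(counts)),
    thresholds = list(vafMin = vafMin, depthMin = depthMin,
                      impacts = impacts, requireCosmic = requireCosmic)
  )
}

#' Per-line gene summary of triage survivors
#'
#' @param result Output of [filterVariants()].
#' @return Named list: sorted unique gene symbols per line (a gene with
#'   several surviving variants appears once).
#' @export
perLineGeneSummary <- function(result) {
  lines <- names(result$counts)
  out <- lapply(lines, function(l) {
    sort(unique(result$surviving$gene[result$surviving$line_id == l]))
  })
  names(out) <- lines
  out
}

#' Pairwise Jaccard overlap of per-line gene sets
#'
#' `J(A, B) = |intersection| / |union|`; 1 on the diagonal. Two empty sets
#' are defined to overlap completely (J = 1, logged).
#'
#' @param summaries Named list of gene-symbol vectors per line.
#' @return Symmetric numeric matrix of Jaccard indices.
#' @export
lineOverlap <- function(summaries) {
  if (length(summaries) < 2L) {
    stop("at least two lines are required for an overlap matrix",
         call. = FALSE)
  }
  n <- length(summaries)
  J <- matrix(1, n, n, dimnames = list(names(summaries), names(summaries)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- unique(summaries[[i]])
      b <- unique(summaries[[j]])
      u <- length(union(a, b))
      if (u == 0L) {
        .logInfo("both gene sets empty for ", names(summaries)[i], " and ",
                 names(summaries)[j], "; Jaccard defined as 1")
        val <- 1
      } else {
        val <- length(intersect(a, b)) / u
      }
      J[i, j] <- J[j, i] <- val
    }
  }
  J
}
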