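# Teratoma histology: specimen records with ordinal immaturity grades
# (0 = fully mature, 1-3 = increasing amounts of immature neuroepithelium)
# and the Kruskal-Wallis comparison of grades across cell lines.

.GERM_LAYERS <- c("two_layers", "three_layers")

#' Read teratoma specimen records CSV
#'
#' Columns: `line_id`, `specimen_no`, `volume_mm3`, `week`, `germ_layers`
#' (`two_layers` or `three_layers`), `grade` (integer 0-3).
#'
#' @param path CSV file path.
#' @return Validated data frame of specimens.
#' @export
readSpecimens <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "specimen_no", "volume_mm3", "week", "germ_layers", "grade")
  if (!all(need %in% names(df))) {
    stop("specimens file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$germ_layers %in% .GERM_LAYERS)) {
    stop("germ_layers must be one of: ", paste(.GERM_LAYERS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$grade %in% 0:3)) {
    stop("grade must be an integer in 0..3", call. = FALSE)
  }
  if (any(df$volume_mm3 <= 0)) stop("volume_mm3 must be > 0", call. = FALSE)
  df$grade <- as.integer(df$grade)
  df
}

#' Classify teratoma maturity from its grade
#'
#' Grade 0 (no immature neuroepithelium) is a mature teratoma; grades 1-3 are
#' immature.
#'
#' @param grade Integer vector of grades in 0..3.
#' @return Character vector, `"mature"` or `"immature"`.
#' @examples
#' classifyMaturity(c(0, 1, 3))
#' @export
classifyMaturity <- function(grade) {
  if (any(!grade %in% 0:3)) {
    stop("grade must be an integer in 0..3", call. = FALSE)
  }
  ifelse(grade == 0L, "mature", "immature")
}

#' Compare teratoma grades across lines (Kruskal-Wallis)
#'
#' Tie-corrected Kruskal-Wallis rank-sum test of the ordinal grades grouped
#' by cell line, with the chi-square approximation (df = groups - 1) by
#' default, or a seeded Monte-Carlo permutation p-value. Groups with no
#' specimens are dropped with a logged note; single-specimen groups are
#' retained (the statistic is defined for n_j = 1).
#'
#' @param grades Named list: one integer vector of grades per line.
#' @param exact If `TRUE`, compute the p-value by Monte-Carlo permutation of
#'   group labels instead of the chi-square tail.
#' @param nPerm Number of permutations when `exact = TRUE`.
#' @param seed Optional integer seed for the permutation draw.
#' @return A list with `H` (tie-corrected statistic), `df`, `p_value`, and
#'   `method`.
#' @export
gradeComparison <- function(grades, exact = FALSE, nPerm = 10000L,
                            seed = NULL) {
  sizes <- lengths(grades)
  if (any(sizes == 0L)) {
    .logInfo("dropping ", sum(sizes == 0L), " empty group(s): ",
             paste(names(grades)[sizes == 0L], collapse = ", "))
    grades <- grades[sizes > 0L]
  }
  if (length(grades) < 2L) {
    stop("design error: at least two non-empty groups are required",
         call. = FALSE)
  }
  x <- unlist(grades, use.names = FALSE)
  g <- factor(rep(seq_along(grades), lengths(grades)))
  if (length(unique(x)) == 1L) {
    # every observation identical: no evidence of any group difference
    return(list(H = 0, df = length(grades) - 1L, p_value = 1,
                method = "degenerate (all observations tied)"))
  }
  kw <- stats::kruskal.test(x, g)
  H <- unname(kw$statistic)
  df <- unname(kw$parameter)
  p <- kw$p.value
  method <- "chi-square approximation"
  if (exact) {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    # permutation reference distribution of the tie-corrected statistic
    perm <- replicate(nPerm, .kwStatistic(sample(x), g))
    p <- (1 + sum(perm >= H - 1e-12)) / (nPerm + 1)
    method <- sprintf("Monte-Carlo permutation (%d draws)", nPerm)
  }
  list(H = H, df = df, p_value = p, method = method)
}

# Tie-corrected Kruskal-Wallis statistic from pooled values and group labels.
# Kept internal: the user-facing test delegates to stats::kruskal.test; this
# form feeds the permutation option.
.kwStatistic <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  Rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(n * Rbar^2) - 3 * (N + 1)
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C == 0) return(0) # all observations identical
  H / C
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Split specimen grades by line
#'
#' @param specimens Data frame from [readSpecimens()].
#' @return Named list of integer grade vectors, one per line.
#' @export
gradesByLine <- function(specimens) {
  split(specimens$grade, factor(specimens$line_id,
                                levels = unique(specimens$line_id)))
}
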