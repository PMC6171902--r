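# Descriptive layer of the in vivo assay: tumor volume from caliper
# measurements, per-line incidence and latency, and tied rank ordering of
# cell lines for the downstream rank-correlation screen.

#' Tumor volume from caliper measurements
#'
#' The modified-ellipsoid formula used for subcutaneous xenografts:
#' `volume (mm^3) = 1/2 * length (mm) * width (mm)^2`.
#'
#' @param length_mm,width_mm Positive tumor dimensions in mm (vectorized;
#'   recorded as measured, width may exceed length).
#' @return Volume(s) in mm^3.
#' @examples
#' tumorVolume(10, 10)       # 500
#' tumorVolume(16.2, 13.0)   # 1368.9
#' @export
tumorVolume <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(length_mm <= 0) || any(width_mm <= 0)) {
    stop("invalid measurement: tumor dimensions must be positive finite mm",
         call. = FALSE)
  }
  0.5 * length_mm * width_mm^2
}

#' Tumor incidence as an integer percentage
#'
#' `100 * nTumor / nAnimals`, rounded half away from zero to a whole percent
#' (so 5/6 -> 83, 4/6 -> 67, 1/6 -> 17).
#'
#' @param nTumor Number of tumor-bearing animals (vectorized).
#' @param nAnimals Number of animals inoculated; must be >= 1.
#' @return Integer percent.
#' @export
incidencePercent <- function(nTumor, nAnimals) {
  if (any(nAnimals < 1)) {
    stop("undefined incidence: nAnimals must be >= 1", call. = FALSE)
  }
  if (any(nTumor < 0) || any(nTumor > nAnimals)) {
    stop("nTumor must satisfy 0 <= nTumor <= nAnimals", call. = FALSE)
  }
  as.integer(roundHalfUp(100 * nTumor / nAnimals))
}

#' Group latency of tumor formation
#'
#' The latency reported for a cell line is the earliest week at which any
#' animal in the group had a palpable tumor. Returns `NA` when no animal in
#' the group formed a tumor.
#'
#' @param outcomes Data frame of per-animal outcomes with columns
#'   `tumor_formed` (logical or 0/1) and `first_palpable_week` (integer,
#'   `NA` for tumor-free animals). All rows must belong to one line.
#' @return Integer week, or `NA_integer_` if no tumor formed.
#' @export
groupLatency <- function(outcomes) {
  if (nrow(outcomes) == 0L) {
    stop("empty group: no animal outcomes supplied", call. = FALSE)
  }
  formed <- as.logical(outcomes$tumor_formed)
  if (any(formed & is.na(outcomes$first_palpable_week))) {
    stop("tumor-bearing animal without a first_palpable_week", call. = FALSE)
  }
  if (!any(formed)) return(NA_integer_)
  as.integer(min(outcomes$first_palpable_week[formed]))
}

#' Summarize per-animal outcomes by cell line
#'
#' Collapses an outcomes table (one row per animal) to one row per line with
#' animal counts, tumor counts, integer incidence percent and group latency.
#' Animals still tumor-free at the end of the observation window count as
#' non-tumor for incidence.
#'
#' @param outcomes Data frame with columns `animal_id`, `line_id`,
#'   `tumor_formed`, `first_palpable_week`.
#' @return Data frame with columns `line_id`, `n_animals`, `n_tumor`,
#'   `incidence_pct`, `latency_weeks` (one row per line, in order of first
#'   appearance).
#' @export
summarizeLines <- function(outcomes) {
  need <- c("line_id", "tumor_formed", "first_palpable_week")
  if (!all(need %in% names(outcomes))) {
    stop("outcomes must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lines <- unique(outcomes$line_id)
  rows <- lapply(lines, function(l) {
    sub <- outcomes[outcomes$line_id == l, , drop = FALSE]
    nT <- sum(as.logical(sub$tumor_formed))
    data.frame(
      line_id = l,
      n_animals = nrow(sub),
      n_tumor = nT,
      incidence_pct = incidencePercent(nT, nrow(sub)),
      latency_weeks = groupLatency(sub)
    )
  })
  do.call(rbind, rows)
}

#' Tied rank ordering of cell lines
#'
#' Groups lines into tie classes ordered by a per-line value (e.g. latency in
#' weeks or incidence percent) and assigns midranks, the form consumed by
#' Spearman rank correlation. Ties share a class and a midrank.
#'
#' @param values Named numeric vector, one finite value per line.
#' @param direction `"ascending"` (default; smallest value first) or
#'   `"descending"`.
#' @return A list with `classes` (list of character vectors of line ids, in
#'   rank order; ids within a class sorted alphabetically) and `midranks`
#'   (named numeric, midranks in the *ascending* ordering regardless of
#'   display direction, as used for correlation).
#' @examples
#' rankLines(c(A = 4, B = 4, C = 7))$classes
#' @export
rankLines <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (length(values) == 0L) stop("empty input: no line values", call. = FALSE)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named by line id", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("all values must be finite", call. = FALSE)
  uniq <- sort(unique(values), decreasing = (direction == "descending"))
  classes <- lapply(uniq, function(v) sort(names(values)[values == v]))
  midranks <- rank(values, ties.method = "average")
  list(classes = classes, midranks = midranks)
}

#' Render tie classes as a rank-order string
#'
#' @param classes The `classes` element of a [rankLines()] result.
#' @return A string like `"A = B < C"`.
#' @export
formatRankOrder <- function(classes) {
  paste(vapply(classes, paste, "", collapse = " = "), collapse = " < ")
}

#' Read per-animal outcomes CSV
#'
#' Columns: `animal_id`, `line_id`, `dose`, `tumor_formed` (0/1),
#' `first_palpable_week` (blank for tumor-free animals).
#'
#' @param path CSV file path.
#' @param horizon Observation horizon in weeks (default 16); palpable weeks
#'   beyond it are rejected.
#' @return Data frame of validated outcomes.
#' @export
readOutcomes <- function(path, horizon = 16L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "line_id", "dose", "tumor_formed", "first_palpable_week")
  if (!all(need %in% names(df))) {
    stop("outcomes file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$tumor_formed <- as.logical(as.integer(df$tumor_formed))
  df$first_palpable_week <- suppressWarnings(as.integer(df$first_palpable_week))
  bad <- which(df$tumor_formed != !is.na(df$first_palpable_week))
  if (length(bad)) {
    stop("rows ", paste(bad, collapse = ", "),
         ": first_palpable_week must be present iff tumor_formed",
         call. = FALSE)
  }
  wk <- df$first_palpable_week
  bad <- which(!is.na(wk) & (wk < 0L | wk > horizon))
  if (length(bad)) {
    stop("rows ", paste(bad, collapse = ", "),
         ": first_palpable_week outside 0..", horizon, call. = FALSE)
  }
  df
}

#' Read weekly caliper measurements CSV
#'
#' Columns: `animal_id`, `line_id`, `week`, `length_mm`, `width_mm`. Adds a
#' `volume_mm3` column via [tumorVolume()].
#'
#' @param path CSV file path.
#' @return Data frame with computed `volume_mm3`.
#' @export
readMeasurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "line_id", "week", "length_mm", "width_mm")
  if (!all(need %in% names(df))) {
    stop("measurements file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$week < 0)) stop("week must be >= 0", call. = FALSE)
  df$volume_mm3 <- tumorVolume(df$length_mm, df$width_mm)
  df
}
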