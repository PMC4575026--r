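#' Assemble a cohort report
#'
#' Merges per-animal measurement tables (from the mapping, classification,
#' volumetry and relaxometry stages) with a cohort table, computes group
#' mean +/- SD summaries for every measurement and [anova_tukey()]
#' comparisons for every measurement observed in at least two groups with
#' two or more animals each, and records provenance. Row ordering is
#' deterministic (sorted by animal then measurement) so reruns on the same
#' inputs serialize byte-identically.
#'
#' @param measurements One long-format data frame, or a list of them, with
#'   columns `animal`, `group`, `measurement`, `value` (and optionally
#'   `units`).
#' @param cohort Optional cohort table in the same layout; its animal id
#'   set must match the measurement tables (a mismatch is a reconciliation
#'   error listing the orphan ids).
#' @param alpha Significance level passed to [anova_tukey()].
#' @param provenance Named list recorded verbatim (e.g. config, seed).
#' @return List of class `muscle_report`: `per_animal`, `group_summary`,
#'   `comparisons` (named list of `comparison_result`), `provenance`.
#' @export
build_report <- function(measurements, cohort = NULL, alpha = 0.05,
                         provenance = list()) {
  if (is.data.frame(measurements)) measurements <- list(measurements)
  if (length(measurements) == 0L ||
      all(vapply(measurements, nrow, 1L) == 0L))
    stop("empty cohort: no measurements supplied")
  long <- do.call(rbind, lapply(measurements, function(m) {
    need <- c("animal", "group", "measurement", "value")
    if (!all(need %in% names(m)))
      stop("measurement tables need columns ",
           paste(need, collapse = ", "))
    if (!"units" %in% names(m)) m$units <- NA_character_
    m[, c(need, "units")]
  }))

  if (!is.null(cohort)) {
    orph_m <- setdiff(unique(long$animal), unique(cohort$animal))
    orph_c <- setdiff(unique(cohort$animal), unique(long$animal))
    if (length(orph_m) || length(orph_c))
      stop("reconciliation error: orphan animal ids — ",
           "measurements only: [", paste(orph_m, collapse = ", "),
           "]; cohort only: [", paste(orph_c, collapse = ", "), "]")
    long <- rbind(long, cohort[, names(long)])
  }
  dup <- duplicated(long[, c("animal", "measurement")])
  if (any(dup))
    stop("duplicate (animal, measurement) pairs: ",
         paste(unique(paste(long$animal[dup], long$measurement[dup])),
               collapse = ", "))
  long <- long[order(long$animal, long$measurement), ]
  rownames(long) <- NULL

  meas <- sort(unique(long$measurement))
  group_summary <- do.call(rbind, lapply(meas, function(m) {
    d <- long[long$measurement == m, ]
    do.call(rbind, lapply(sort(unique(d$group)), function(g) {
      v <- d$value[d$group == g]
      data.frame(measurement = m, group = g, n = length(v),
                 mean = mean(v), sd = sd(v))
    }))
  }))
  rownames(group_summary) <- NULL

  comparisons <- list()
  for (m in meas) {
    d <- long[long$measurement == m, ]
    cnt <- tapply(d$value, d$group, length)
    if (sum(cnt >= 2, na.rm = TRUE) >= 2) {
      d <- d[d$group %in% names(cnt)[!is.na(cnt) & cnt >= 2], ]
      comparisons[[m]] <- anova_tukey(d, m, alpha = alpha)
    }
  }

  structure(
    list(per_animal = long, group_summary = group_summary,
         comparisons = comparisons,
         provenance = c(provenance,
                        list(package = "myorelax",
                             version = as.character(
                               utils::packageVersion("myorelax"))))),
    class = "muscle_report")
}

#' @export
print.muscle_report <- function(x, ...) {
  cat(sprintf("<muscle_report> %d animals, %d measurements, %d comparisons\n",
              length(unique(x$per_animal$animal)),
              length(unique(x$per_animal$measurement)),
              length(x$comparisons)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Serializes a [build_report()] bundle as `per_animal.csv`,
#' `group_summary.csv`, `comparisons.csv` and `report.json` in `dir`.
#' Millisecond quantities are rounded to 2 decimals at serialization only
#' (full precision is retained in the R object); output is deterministic
#' for identical inputs.
#'
#' @param report A `muscle_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "muscle_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  round2 <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, 4)
    df
  }
  p1 <- file.path(dir, "per_animal.csv")
  p2 <- file.path(dir, "group_summary.csv")
  p3 <- file.path(dir, "comparisons.csv")
  p4 <- file.path(dir, "report.json")
  write.csv(round2(report$per_animal), p1, row.names = FALSE)
  write.csv(round2(report$group_summary), p2, row.names = FALSE)
  cmp <- do.call(rbind, lapply(report$comparisons, function(cr) {
    cbind(data.frame(measurement = cr$measurement, F = cr$F,
                     p_anova = cr$p_anova), cr$pairwise)
  }))
  if (is.null(cmp)) cmp <- data.frame()
  write.csv(round2(cmp), p3, row.names = FALSE)
  jsonlite::write_json(
    list(provenance = report$provenance,
         group_summary = report$group_summary,
         comparisons = lapply(report$comparisons, function(cr)
           list(measurement = cr$measurement, F = cr$F,
                p_anova = cr$p_anova, pairwise = cr$pairwise))),
    p4, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3, p4))
}
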