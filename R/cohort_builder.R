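# Cohort construction: sex-specific percentile hypertrophy flags, the
# eight-cell hypertrophy partition, prevalent-case removal, and phenotype
# correlation summaries.

#' Sex-specific percentile flag
#'
#' Within each sex, flags subjects whose mass lies strictly above that sex's
#' empirical percentile (type-7 linear-interpolation quantile). Thresholds
#' are attached as an attribute.
#'
#' @param table cohort data frame with a `sex` column.
#' @param mass_column column name to threshold.
#' @param percentile percentile in `[0, 100)` (default 90).
#' @return Integer 0/1 vector with attribute `thresholds` (named by sex).
#' @export
sex_specific_percentile_flag <- function(table, mass_column, percentile = 90) {
  x <- table[[mass_column]]
  if (is.null(x) || all(is.na(x)))
    stop(sprintf("column '%s' is missing or all NA", mass_column), call. = FALSE)
  sexes <- unique(table$sex)
  flag <- integer(nrow(table))
  thresholds <- stats::setNames(numeric(length(sexes)), sexes)
  for (sx in sexes) {
    idx <- which(table$sex == sx)
    if (sum(!is.na(x[idx])) < 2L)
      stop(sprintf("fewer than 2 non-missing values for sex '%s'", sx), call. = FALSE)
    q <- stats::quantile(x[idx], percentile / 100, na.rm = TRUE, names = FALSE, type = 7)
    thresholds[sx] <- q
    flag[idx] <- as.integer(!is.na(x[idx]) & x[idx] > q)
  }
  structure(flag, thresholds = thresholds)
}

#' Add hypertrophy flags to a cohort
#'
#' Global, apical, and septal hypertrophy: mass strictly above the
#' sex-specific percentile of total, apical, and septal mass respectively.
#'
#' @param table cohort data frame with `sex`, `total_mass_g`,
#'   `apical_mass_g`, `septal_mass_g`.
#' @param percentile percentile (default 90).
#' @return `table` with integer columns `global_htx`, `apical_htx`,
#'   `septal_htx` and attribute `htx_thresholds`.
#' @export
add_hypertrophy_flags <- function(table, percentile = 90) {
  g <- sex_specific_percentile_flag(table, "total_mass_g", percentile)
  a <- sex_specific_percentile_flag(table, "apical_mass_g", percentile)
  s <- sex_specific_percentile_flag(table, "septal_mass_g", percentile)
  table$global_htx <- as.integer(g)
  table$apical_htx <- as.integer(a)
  table$septal_htx <- as.integer(s)
  attr(table, "htx_thresholds") <- list(global = attr(g, "thresholds"),
                                        apical = attr(a, "thresholds"),
                                        septal = attr(s, "thresholds"))
  table
}

.category_levels <- c("none", "global_only", "isolated_apical", "isolated_septal",
                      "apical_and_septal", "global_plus_apical",
                      "global_plus_septal", "global_plus_both")
.group_levels <- c("control", "global", "isolated_apical", "isolated_septal",
                   "combined")

#' Assign hypertrophy categories
#'
#' Maps each subject to exactly one of the eight flag combinations
#' (`category`) and to the coarser five-level analysis grouping
#' (`hypertrophy_group`): control (no flags), global (global flag set,
#' regardless of regional flags), isolated apical / isolated septal
#' (one regional flag without global), combined (both regional flags
#' without global).
#'
#' @param table cohort with `global_htx`, `apical_htx`, `septal_htx`
#'   columns (see [add_hypertrophy_flags()]).
#' @return `table` with factor columns `category` and `hypertrophy_group`.
#' @export
assign_categories <- function(table) {
  need <- c("global_htx", "apical_htx", "septal_htx")
  if (!all(need %in% names(table)))
    stop("hypertrophy flags missing; call add_hypertrophy_flags() first", call. = FALSE)
  g <- table$global_htx == 1L; a <- table$apical_htx == 1L; s <- table$septal_htx == 1L
  cat8 <- ifelse(g & a & s, "global_plus_both",
          ifelse(g & a,     "global_plus_apical",
          ifelse(g & s,     "global_plus_septal",
          ifelse(g,         "global_only",
          ifelse(a & s,     "apical_and_septal",
          ifelse(a,         "isolated_apical",
          ifelse(s,         "isolated_septal", "none")))))))
  grp <- ifelse(g, "global",
         ifelse(a & s, "combined",
         ifelse(a, "isolated_apical",
         ifelse(s, "isolated_septal", "control"))))
  table$category <- factor(cat8, levels = .category_levels)
  table$hypertrophy_group <- factor(grp, levels = .group_levels)
  table
}

#' Remove prevalent cases for one outcome
#'
#' Subjects whose first event predates baseline are excluded for that
#' outcome; the remainder get recomputed incident fields: `<outcome>_event`
#' (1 when the first event falls in `(baseline, follow-up end]`) and
#' `<outcome>_years` (days / 365.25 from baseline to the event or to the end
#' of follow-up). Idempotent.
#'
#' @param table cohort with `baseline_date`, `<outcome>_first_event_date`,
#'   `<outcome>_follow_up_end_date` columns (Date or ISO strings).
#' @param outcome outcome name.
#' @return A list: `incident` (the filtered table) and `prevalent_ids`.
#' @export
remove_prevalent <- function(table, outcome) {
  evc <- paste0(outcome, "_first_event_date")
  fuc <- paste0(outcome, "_follow_up_end_date")
  need <- c("baseline_date", evc, fuc)
  if (!all(need %in% names(table)))
    stop(sprintf("missing date column(s): %s",
                 paste(setdiff(need, names(table)), collapse = ", ")), call. = FALSE)
  base <- as.Date(table$baseline_date)
  ev <- as.Date(table[[evc]])
  fu <- as.Date(table[[fuc]])
  orphan <- which(!is.na(ev) & is.na(base))
  if (length(orphan))
    stop(sprintf("event date without baseline date for subject(s): %s",
                 paste(table$id[orphan], collapse = ", ")), call. = FALSE)
  prevalent <- !is.na(ev) & ev < base
  keep <- which(!prevalent)
  out <- table[keep, , drop = FALSE]
  ev <- ev[keep]; base <- base[keep]; fu <- fu[keep]
  end <- ifelse(!is.na(ev) & ev <= fu, ev, fu)
  out[[paste0(outcome, "_event")]] <- as.integer(!is.na(ev) & ev <= fu)
  out[[paste0(outcome, "_years")]] <- as.numeric(end - as.numeric(base)) / 365.25
  list(incident = out, prevalent_ids = table$id[prevalent])
}

#' Pairwise squared correlations among phenotype columns
#'
#' Pairwise-complete squared Pearson correlations (r^2). Zero-variance
#' columns yield `NA` rows/columns (undefined, not zero).
#'
#' @param table cohort data frame.
#' @param columns columns to correlate; defaults to the three mass columns
#'   plus any of `lvedv`, `lvesv`, `lvef` that are present.
#' @return Symmetric r^2 matrix with unit diagonal.
#' @export
phenotype_correlations <- function(table,
                                   columns = intersect(c("apical_mass_g", "septal_mass_g",
                                                         "total_mass_g", "lvedv", "lvesv", "lvef"),
                                                       names(table))) {
  if (length(columns) < 2L) stop("need at least two columns", call. = FALSE)
  x <- as.matrix(table[, columns, drop = FALSE])
  if (sum(stats::complete.cases(x)) < 3L)
    stop("need at least 3 complete rows", call. = FALSE)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  r2 <- r^2
  degenerate <- apply(x, 2, function(col) stats::var(col, na.rm = TRUE) == 0)
  r2[degenerate, ] <- NA_real_
  r2[, degenerate] <- NA_real_
  diag(r2) <- ifelse(degenerate, NA_real_, 1)
  r2
}
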