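# Cox proportional-hazards model families for incident disease:
# categorical hypertrophy vs control, per-SD continuous masses, and joint
# total + regional mass models. Fitting delegates to survival::coxph with
# Efron tie handling; this module owns the model contracts and reporting.

#' Standardise a column to unit standard deviation
#'
#' Divides by the sample SD (computed over non-missing values) and records
#' the SD so hazard ratios can be reported per 1 SD in original units.
#'
#' @param table data frame.
#' @param column column name.
#' @return A list: `values` (the scaled column) and `sd` (the SD used).
#' @export
standardize_per_sd <- function(table, column) {
  x <- table[[column]]
  if (is.null(x)) stop(sprintf("no column '%s'", column), call. = FALSE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0 || length(unique(stats::na.omit(x))) < 2L)
    stop(sprintf("column '%s' has zero variance", column), call. = FALSE)
  list(values = x / s, sd = s)
}

.default_covariates <- c("sex", "age", "pulse_rate", "hypertension")

.new_hazard_table <- function(rows) {
  out <- do.call(rbind, rows)
  class(out) <- c("hazard_table", "data.frame")
  out
}

.hazard_row <- function(term, hr = NA_real_, lo = NA_real_, hi = NA_real_,
                        p = NA_real_, n_events = NA_integer_,
                        n_subjects = NA_integer_, sd_used = NA_real_) {
  data.frame(term = term, hazard_ratio = hr, ci_low = lo, ci_high = hi,
             p_value = p, n_events = n_events, n_subjects = n_subjects,
             sd_used = sd_used, stringsAsFactors = FALSE)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood with Efron tie handling (Newton
#' iteration to a 1e-9 convergence tolerance, at most 100 iterations) and
#' reports Wald 95% confidence intervals and p-values, with hazard ratios as
#' exponentiated coefficients. Complete-case analysis within the fit.
#'
#' @param table data frame with `<outcome>_years` and `<outcome>_event`
#'   columns (prevalent cases must already be removed).
#' @param outcome outcome name.
#' @param predictors character vector of predictor columns (continuous or
#'   factor).
#' @param covariates adjustment columns (default sex, age, pulse rate,
#'   hypertension).
#' @param standardize subset of continuous predictors to report per 1 SD.
#' @param ties tie-handling approximation; Efron is the default, Breslow is
#'   available (it makes integer case weights exactly equivalent to row
#'   replication).
#' @param weights_col optional column of case weights.
#' @return A `hazard_table` data frame: one row per model term with
#'   `term, hazard_ratio, ci_low, ci_high, p_value, n_events, n_subjects,
#'   sd_used`.
#' @export
fit_cox <- function(table, outcome, predictors,
                    covariates = .default_covariates,
                    standardize = character(0),
                    ties = c("efron", "breslow"), weights_col = NULL) {
  ties <- match.arg(ties)
  tcol <- paste0(outcome, "_years"); ecol <- paste0(outcome, "_event")
  need <- c(tcol, ecol, predictors, covariates, weights_col)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  if (length(intersect(predictors, covariates)))
    stop("predictors and covariates must be disjoint", call. = FALSE)
  dat <- table[, need, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (sum(dat[[ecol]]) < 1L)
    stop(sprintf("no events for outcome '%s'", outcome), call. = FALSE)
  sds <- stats::setNames(rep(NA_real_, length(predictors)), predictors)
  for (pcol in intersect(standardize, predictors)) {
    z <- standardize_per_sd(dat, pcol)
    dat[[pcol]] <- z$values
    sds[pcol] <- z$sd
  }
  rhs <- paste(c(predictors, covariates), collapse = " + ")
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s", tcol, ecol, rhs))
  w <- if (is.null(weights_col)) NULL else dat[[weights_col]]
  fit <- survival::coxph(fml, data = dat, ties = ties, weights = w,
                         control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  co <- stats::coef(fit)
  if (any(is.na(co)) || any(abs(co) > 15))
    stop(sprintf("Cox fit unstable (possible separation) for term(s): %s",
                 paste(names(co)[is.na(co) | abs(co) > 15], collapse = ", ")),
         call. = FALSE)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(se > 100))
    stop(sprintf("Cox fit unstable: huge standard error for term(s): %s",
                 paste(names(se)[se > 100], collapse = ", ")), call. = FALSE)
  z95 <- stats::qnorm(0.975)
  rows <- lapply(seq_along(co), function(i) {
    term <- names(co)[i]
    base <- sub("^`|`$", "", term)
    .hazard_row(term, exp(co[i]), exp(co[i] - z95 * se[i]), exp(co[i] + z95 * se[i]),
                p = 2 * stats::pnorm(-abs(co[i] / se[i])),
                n_events = sum(dat[[ecol]]), n_subjects = nrow(dat),
                sd_used = if (base %in% names(sds)) sds[[base]] else NA_real_)
  })
  out <- .new_hazard_table(rows)
  attr(out, "fit") <- fit
  out
}

#' Hazard table for the hypertrophy categories
#'
#' One categorical Cox fit of the outcome on `hypertrophy_group` with
#' control as the reference level, adjusted for the standard covariates.
#' Empty categories are reported with `n = 0` and no estimate rather than
#' silently dropped; a category whose subjects experienced no events (its
#' hazard ratio is not estimable) is likewise reported without an estimate,
#' with its subjects excluded from that fit.
#'
#' @inheritParams fit_cox
#' @param table cohort with `hypertrophy_group` assigned (see
#'   [assign_categories()]) and prevalent cases removed.
#' @return A `hazard_table` with one row per non-control category.
#' @export
hypertrophy_hazard_table <- function(table, outcome,
                                     covariates = .default_covariates) {
  if (!"hypertrophy_group" %in% names(table))
    stop("hypertrophy_group missing; call assign_categories() first", call. = FALSE)
  grp <- factor(table$hypertrophy_group, levels = .group_levels)
  counts <- table(grp)
  ecol <- paste0(outcome, "_event")
  events_by <- tapply(table[[ecol]], grp, sum, default = 0L)
  estimable <- names(counts)[counts > 0 &
                               (names(counts) == "control" | events_by > 0)]
  if (identical(estimable, "control") || !"control" %in% estimable)
    return(.new_hazard_table(list()))
  tab <- table[as.character(grp) %in% estimable, , drop = FALSE]
  tab$hypertrophy_group <- droplevels(
    stats::relevel(factor(tab$hypertrophy_group, levels = .group_levels),
                   ref = "control"))
  ht <- fit_cox(tab, outcome, predictors = "hypertrophy_group",
                covariates = covariates)
  rows <- list()
  for (lev in setdiff(.group_levels, "control")) {
    term <- paste0("hypertrophy_group", lev)
    hit <- ht[ht$term == term, , drop = FALSE]
    if (nrow(hit) == 1L) {
      hit$term <- lev
      hit$n_subjects <- unname(counts[lev])
      hit$n_events <- unname(as.integer(events_by[lev]))
      rows[[lev]] <- hit
    } else {
      rows[[lev]] <- .hazard_row(lev, n_events = unname(as.integer(events_by[lev])),
                                 n_subjects = unname(as.integer(counts[lev])))
    }
  }
  .new_hazard_table(rows)
}

#' Joint total + regional mass models
#'
#' Two Cox fits with the standard covariates: total LV mass together with
#' apical mass, and total LV mass together with septal mass, both reported
#' per 1 SD. This is the contrast under which a regional effect that merely
#' proxies total mass attenuates to the null.
#'
#' @inheritParams fit_cox
#' @return A list with `hazard_table` elements `m_apical` and `m_septal`.
#' @export
joint_mass_models <- function(table, outcome,
                              covariates = .default_covariates) {
  for (pair in list(c("total_mass_g", "apical_mass_g"),
                    c("total_mass_g", "septal_mass_g"))) {
    x <- stats::na.omit(as.matrix(table[, pair]))
    x <- scale(x)
    k <- kappa(crossprod(x) / nrow(x), exact = TRUE)
    if (!is.finite(k) || k > 1e8)
      stop(sprintf("collinearity between %s and %s (condition number %.3g)",
                   pair[1], pair[2], k), call. = FALSE)
  }
  list(m_apical = fit_cox(table, outcome,
                          predictors = c("total_mass_g", "apical_mass_g"),
                          covariates = covariates,
                          standardize = c("total_mass_g", "apical_mass_g")),
       m_septal = fit_cox(table, outcome,
                          predictors = c("total_mass_g", "septal_mass_g"),
                          covariates = covariates,
                          standardize = c("total_mass_g", "septal_mass_g")))
}

#' Write a hazard table as TSV
#' @param ht a `hazard_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hazard_table <- function(ht, path) {
  utils::write.table(as.data.frame(ht), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
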