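# Desk-scale genetic pipeline: variant filtering, covariate-adjusted
# per-variant linear association scan (ordinary least squares stand-in for a
# mixed-model scan; synthetic panels carry no relatedness, so the scan is
# calibrated under the null by construction), greedy LD clumping of
# significant variants, additive polygenic scoring, and polygenic-score
# outcome association.

#' Filter variants on MAF and imputation quality
#'
#' Retains variants with minor allele frequency >= `maf_min` and INFO score
#' >= `info_min` (both inclusive).
#'
#' @param panel a `genotype_panel`.
#' @param maf_min MAF threshold (default 0.01).
#' @param info_min INFO threshold (default 0.3).
#' @return The filtered panel, with attribute `n_removed`.
#' @export
filter_variants <- function(panel, maf_min = 0.01, info_min = 0.3) {
  keep <- panel$variants$maf >= maf_min & panel$variants$info >= info_min
  out <- panel
  out$dosages <- panel$dosages[, keep, drop = FALSE]
  out$variants <- panel$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  old_idx <- which(keep)
  tr <- panel$truth
  if (length(tr$causal_indices)) {
    still <- tr$causal_indices %in% old_idx
    out$truth$causal_indices <- match(tr$causal_indices[still], old_idx)
    out$truth$causal_betas <- tr$causal_betas[still]
  }
  structure(out, n_removed = sum(!keep))
}

#' Per-variant linear association scan
#'
#' Regresses the phenotype on each variant's dosage plus covariates
#' (ordinary least squares; covariates are projected out of both phenotype
#' and dosages, then per-variant slopes, standard errors and two-sided
#' t-test p-values are computed). Variants with (residually) constant dosage
#' are reported with `NA` statistics, not dropped.
#'
#' @param panel a `genotype_panel`.
#' @param phenotype numeric vector, one value per subject.
#' @param covariates optional data frame / matrix of adjustment columns.
#' @return A data frame of class `summary_stats`:
#'   `variant_id, chr, pos, ref, alt, beta, se, p, n`.
#' @export
linear_scan <- function(panel, phenotype, covariates = NULL) {
  y <- as.numeric(phenotype)
  n <- nrow(panel$dosages)
  if (length(y) != n) stop("phenotype length must match panel subjects", call. = FALSE)
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(lapply(as.data.frame(covariates), function(col) {
      if (is.character(col) || is.factor(col)) as.numeric(factor(col)) else as.numeric(col)
    })))
    X <- cbind(X, cv)
  }
  ok <- stats::complete.cases(cbind(y, X))
  if (!all(ok)) {
    y <- y[ok]; X <- X[ok, , drop = FALSE]
  }
  G <- panel$dosages[ok, , drop = FALSE]
  qx <- qr(X)
  yr <- stats::resid(stats::lm.fit(X, y))
  Gr <- qr.resid(qx, G)
  gg <- colSums(Gr^2)
  gy <- as.numeric(crossprod(Gr, yr))
  df <- length(y) - ncol(X) - 1L
  beta <- ifelse(gg > 1e-10, gy / gg, NA_real_)
  rss <- sum(yr^2) - ifelse(is.na(beta), 0, beta^2 * gg)
  sigma2 <- rss / df
  se <- ifelse(gg > 1e-10, sqrt(sigma2 / gg), NA_real_)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(variant_id = panel$variants$id,
                    chr = panel$variants$chr, pos = panel$variants$pos,
                    ref = panel$variants$ref, alt = panel$variants$alt,
                    beta = beta, se = se, p = p, n = length(y),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Genomic-control inflation factor
#'
#' Median chi-squared statistic of the scan divided by its null expectation;
#' approximately 1 for a calibrated scan.
#'
#' @param p vector of p-values (or a `summary_stats` data frame).
#' @return Lambda.
#' @export
genomic_lambda <- function(p) {
  if (is.data.frame(p)) p <- p$p
  p <- p[is.finite(p)]
  stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}

#' Pairwise LD (r^2) lookup from a panel
#'
#' Squared Pearson correlations between dosage columns for all variant pairs
#' on the same chromosome within `window_kb`.
#'
#' @param panel a `genotype_panel`.
#' @param window_kb window in kilobases (default 500).
#' @return A data frame `id1, id2, r2` of class `ld_table`.
#' @export
panel_ld <- function(panel, window_kb = 500) {
  v <- panel$variants
  rows <- list()
  for (ch in unique(v$chr)) {
    idx <- which(v$chr == ch)
    idx <- idx[order(v$pos[idx])]
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      jj <- ii + 1L
      while (jj <= length(idx) && v$pos[idx[jj]] - v$pos[i] <= window_kb * 1000) {
        j <- idx[jj]
        r <- suppressWarnings(stats::cor(panel$dosages[, i], panel$dosages[, j]))
        rows[[length(rows) + 1L]] <- data.frame(id1 = v$id[i], id2 = v$id[j],
                                                r2 = if (is.na(r)) 0 else r^2,
                                                stringsAsFactors = FALSE)
        jj <- jj + 1L
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(id1 = character(0), id2 = character(0), r2 = numeric(0))
  class(out) <- c("ld_table", "data.frame")
  out
}

.ld_lookup <- function(ld) {
  env <- new.env(parent = emptyenv(), size = max(2L * nrow(ld), 16L))
  for (i in seq_len(nrow(ld))) {
    assign(paste(ld$id1[i], ld$id2[i], sep = "\r"), ld$r2[i], envir = env)
    assign(paste(ld$id2[i], ld$id1[i], sep = "\r"), ld$r2[i], envir = env)
  }
  env
}

#' Greedy LD clumping of significant variants
#'
#' Variants with `p < p_thresh` are visited in ascending p-value order
#' (ties broken by chromosome then position); a variant becomes a lead
#' unless it lies within `window_kb` of an already-accepted lead on the same
#' chromosome *and* has `r^2 > r2_thresh` with it. The result is the set of
#' independent lead variants.
#'
#' @param stats a `summary_stats` data frame.
#' @param ld an `ld_table` (see [panel_ld()]); every same-chromosome pair of
#'   significant variants within the window must be present.
#' @param p_thresh significance threshold (default genome-wide 5e-8).
#' @param r2_thresh LD threshold (default 0.6).
#' @param window_kb distance window in kb (default 500).
#' @return The lead-variant rows of `stats`, in ascending p-value order.
#' @export
clump <- function(stats, ld, p_thresh = 5e-8, r2_thresh = 0.6, window_kb = 500) {
  sig <- stats[!is.na(stats$p) & stats$p < p_thresh, , drop = FALSE]
  if (nrow(sig) == 0L) return(sig)
  sig <- sig[order(sig$p, sig$chr, sig$pos), , drop = FALSE]
  lut <- .ld_lookup(ld)
  leads <- integer(0)
  for (i in seq_len(nrow(sig))) {
    absorbed <- FALSE
    for (j in leads) {
      if (sig$chr[i] == sig$chr[j] &&
          abs(sig$pos[i] - sig$pos[j]) <= window_kb * 1000) {
        key <- paste(sig$variant_id[i], sig$variant_id[j], sep = "\r")
        r2 <- get0(key, envir = lut, ifnotfound = NA_real_)
        if (is.na(r2))
          stop(sprintf("no LD entry for pair %s / %s within the clumping window",
                       sig$variant_id[i], sig$variant_id[j]), call. = FALSE)
        if (r2 > r2_thresh) { absorbed <- TRUE; break }
      }
    }
    if (!absorbed) leads <- c(leads, i)
  }
  out <- sig[leads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Additive polygenic score
#'
#' `score_i = sum_v w_v * dosage_iv` over weight variants matched to the
#' panel by id, after allele alignment: a weight whose effect allele is the
#' panel's alt allele enters as is; one whose effect allele is the panel's
#' ref allele enters with its sign flipped. Weight variants absent from the
#' panel are skipped (and counted); an effect allele matching neither panel
#' allele is an error.
#'
#' @param panel a `genotype_panel`.
#' @param weights data frame `variant_id, effect_allele, weight` with no
#'   duplicate ids.
#' @return Numeric score per subject (named when the panel has subject ids),
#'   with attribute `n_unmatched`.
#' @export
prs_score <- function(panel, weights) {
  if (anyDuplicated(weights$variant_id))
    stop("duplicate variant ids in weights", call. = FALSE)
  v <- panel$variants
  hit <- match(weights$variant_id, v$id)
  unmatched <- sum(is.na(hit))
  use <- which(!is.na(hit))
  w <- numeric(length(use))
  for (k in seq_along(use)) {
    i <- use[k]; j <- hit[i]
    ea <- weights$effect_allele[i]
    if (ea == v$alt[j]) w[k] <- weights$weight[i]
    else if (ea == v$ref[j]) w[k] <- -weights$weight[i]
    else stop(sprintf("allele mismatch for %s: effect allele %s is neither ref (%s) nor alt (%s)",
                      weights$variant_id[i], ea, v$ref[j], v$alt[j]), call. = FALSE)
  }
  scores <- as.numeric(panel$dosages[, hit[use], drop = FALSE] %*% w)
  names(scores) <- panel$subjects
  structure(scores, n_unmatched = unmatched)
}

#' Polygenic-score outcome association
#'
#' Three Cox fits of the outcome on the polygenic score: per 1 SD of the
#' score, and binary indicators for the top decile and top 5% (strict
#' percentile convention as in the hypertrophy flags). Adjusted for sex,
#' age, BMI, pulse rate, and hypertension.
#'
#' @param scores numeric per-subject score, named by subject id (matched to
#'   `cohort$id`) or in row order.
#' @param cohort cohort data frame with outcome time/event columns (prevalent
#'   cases removed).
#' @param outcome outcome name.
#' @param quantiles percentile cut-points for the indicator fits.
#' @param covariates adjustment columns.
#' @return A `hazard_table` with rows `PRS (per 1 std)` and
#'   `PRS (<q>th percentile)` per quantile.
#' @export
prs_outcome_association <- function(scores, cohort, outcome,
                                    quantiles = c(90, 95),
                                    covariates = c("sex", "age", "bmi",
                                                   "pulse_rate", "hypertension")) {
  tab <- cohort
  if (!is.null(names(scores))) {
    m <- match(tab$id, names(scores))
    if (anyNA(m)) stop("some cohort subjects have no score", call. = FALSE)
    tab$prs <- as.numeric(scores)[m]
  } else {
    if (length(scores) != nrow(tab))
      stop("unnamed scores must match the cohort row for row", call. = FALSE)
    tab$prs <- as.numeric(scores)
  }
  rows <- list()
  ht <- fit_cox(tab, outcome, predictors = "prs", covariates = covariates,
                standardize = "prs")
  r <- ht[ht$term == "prs", , drop = FALSE]
  r$term <- "PRS (per 1 std)"
  rows[[1]] <- r
  for (q in quantiles) {
    cut <- stats::quantile(tab$prs, q / 100, na.rm = TRUE, names = FALSE, type = 7)
    col <- sprintf("prs_top_%g", q)
    tab[[col]] <- as.integer(tab$prs > cut)
    ht <- fit_cox(tab, outcome, predictors = col, covariates = covariates)
    r <- ht[ht$term == col, , drop = FALSE]
    r$term <- sprintf("PRS (%gth percentile)", q)
    rows[[length(rows) + 1L]] <- r
  }
  .new_hazard_table(rows)
}

#' Write summary statistics as TSV
#' @param stats a `summary_stats` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
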