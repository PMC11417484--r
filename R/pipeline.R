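# End-to-end orchestration: simulate -> quantify -> cohort -> cox -> scan ->
# clump -> prs, driven by one validated config with per-stage seeds derived
# from a global seed, writing TSV artifacts and a JSON run manifest.

.config_schema <- list(
  seed = NULL,
  out_dir = NULL,
  phantoms = list(n = NULL, pixel_spacing = NULL, n_slices = NULL,
                  inner_radius_range = NULL, wall_thickness_range = NULL,
                  septal_arc = NULL, apical_taper = NULL),
  qc = list(min_myocardial_slices = NULL, apex_cap_fraction = NULL),
  quantify = list(n_apical = NULL, slice_coverage = NULL, septum_fallback = NULL),
  cohort = list(n_subjects = NULL, percentile = NULL, outcomes = NULL,
                baseline_hazard = NULL, heritability = NULL),
  association = list(covariates = NULL),
  genetics = list(n_variants = NULL, maf_range = NULL, n_causal = NULL,
                  causal_beta_sd = NULL, p_thresh = NULL, r2_thresh = NULL,
                  window_kb = NULL, prs_quantiles = NULL)
)

.check_keys <- function(config, schema, path = "") {
  for (key in names(config)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(schema))
      stop(sprintf("unknown config key: %s", full), call. = FALSE)
    if (is.list(schema[[key]]) && !is.null(config[[key]])) {
      if (!is.list(config[[key]]))
        stop(sprintf("config key %s must be a mapping", full), call. = FALSE)
      .check_keys(config[[key]], schema[[key]], full)
    }
  }
  invisible(TRUE)
}

#' Default pipeline configuration
#'
#' Demo-scale settings: 200 phantoms, a 5 000-subject cohort, 500 variants.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @return A nested list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, out_dir = "cardiomass_run") {
  list(seed = seed, out_dir = out_dir,
       phantoms = list(n = 200L, pixel_spacing = 1, n_slices = 10L,
                       inner_radius_range = c(16, 24),
                       wall_thickness_range = c(6, 12),
                       septal_arc = c(60, 150), apical_taper = 0.06),
       qc = list(min_myocardial_slices = 6, apex_cap_fraction = 0.5),
       quantify = list(n_apical = 4L, slice_coverage = "thickness_plus_gap",
                       septum_fallback = "zero"),
       cohort = list(n_subjects = 5000L, percentile = 90,
                     outcomes = "cardiomyopathy", baseline_hazard = 0.002,
                     heritability = 0.2),
       association = list(covariates = c("sex", "age", "pulse_rate", "hypertension")),
       genetics = list(n_variants = 500L, maf_range = c(0.05, 0.5),
                       n_causal = 10L, causal_beta_sd = 2,
                       p_thresh = 5e-8, r2_thresh = 0.6, window_kb = 500,
                       prs_quantiles = c(90, 95)))
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys anywhere in the nesting and fills omitted sections
#' with defaults.
#'
#' @param config nested list (e.g. from [yaml::read_yaml()]).
#' @return The completed config.
#' @export
validate_run_config <- function(config) {
  .check_keys(config, .config_schema)
  def <- default_run_config()
  merged <- utils::modifyList(def, config)
  if (is.null(merged$seed)) stop("config must set a seed", call. = FALSE)
  merged
}

# Deterministic per-stage seed below 2^31, derived from the global seed.
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 48271 + stage_index * 16807) %% 2147483647)
}

#' Run the full pipeline
#'
#' Executes, in order: phantom simulation + quantification (validating the
#' mass measurement against analytic truth), cohort simulation with a
#' genetic mass component, hypertrophy classification, Cox model families,
#' variant filtering + association scan + LD clumping, polygenic scoring of
#' the clumped leads, and polygenic-score outcome association. All stage
#' outputs are TSV files under `config$out_dir`; a JSON manifest records
#' versions, hashes, counts, and thresholds. Identical config + seed
#' reproduce identical outputs.
#'
#' @param config nested list, see [default_run_config()]; validated before
#'   any stage runs.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "cardiomass",
                   version = as.character(utils::packageVersion("cardiomass")),
                   seed = config$seed,
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_json))

  # -- stage 1: phantoms + quantification --------------------------------
  pc <- config$phantoms
  set.seed(stage_seed(config$seed, 1L))
  inner <- stats::runif(pc$n, pc$inner_radius_range[1], pc$inner_radius_range[2])
  wall <- stats::runif(pc$n, pc$wall_thickness_range[1], pc$wall_thickness_range[2])
  crit <- qc_criteria(min_myocardial_slices = config$qc$min_myocardial_slices,
                      apex_cap_fraction = config$qc$apex_cap_fraction)
  recs <- vector("list", pc$n)
  rel_err <- numeric(pc$n)
  for (i in seq_len(pc$n)) {
    reach <- inner[i] + wall[i] + 8
    side <- 2L * ceiling(reach / pc$pixel_spacing) + 9L
    spec <- phantom_spec(grid_shape = c(side, side),
                         pixel_spacing = pc$pixel_spacing,
                         n_slices = pc$n_slices,
                         inner_radius = inner[i],
                         outer_radius = inner[i] + wall[i],
                         septal_arc = pc$septal_arc,
                         apical_taper = pc$apical_taper)
    ph <- generate_phantom_stack(spec, subject_id = sprintf("P%04d", i))
    rec <- quantify_subject(ph$stack, criteria = crit,
                            n_apical = config$quantify$n_apical,
                            no_contact = config$quantify$septum_fallback,
                            slice_coverage = config$quantify$slice_coverage)
    rel_err[i] <- abs(rec$total_mass_g - ph$truth$total_mass_g) / ph$truth$total_mass_g
    recs[[i]] <- rec
  }
  masses <- quantify_batch_records(recs)
  mass_path <- file.path(out_dir, "phantom_masses.tsv")
  write_mass_table(masses, mass_path)
  manifest$stages$phantoms <- list(n = pc$n, qc_passed = sum(masses$qc_passed),
                                   max_total_rel_error = max(rel_err, na.rm = TRUE),
                                   file = basename(mass_path))

  # -- stage 2: genotypes ------------------------------------------------
  gc <- config$genetics
  n_sub <- config$cohort$n_subjects
  set.seed(stage_seed(config$seed, 2L))
  causal <- sort(sample.int(gc$n_variants, gc$n_causal))
  betas <- stats::rnorm(gc$n_causal, 0, gc$causal_beta_sd)
  gspec <- geno_sim_spec(n_subjects = n_sub, n_variants = gc$n_variants,
                         maf_range = gc$maf_range,
                         causal_indices = causal, causal_betas = betas,
                         seed = stage_seed(config$seed, 3L))
  panel <- generate_genotypes(gspec)
  geno_path <- file.path(out_dir, "genotypes.tsv")
  write_genotypes(panel, geno_path)
  manifest$stages$genotypes <- list(n_subjects = n_sub,
                                    n_variants = gc$n_variants,
                                    n_causal = gc$n_causal,
                                    file = basename(geno_path))

  # -- stage 3: cohort with a genetic mass component ---------------------
  cc <- config$cohort
  g_raw <- as.numeric(panel$dosages[, causal, drop = FALSE] %*% betas)
  g_raw <- g_raw - mean(g_raw)
  # scale the genetic component to the configured share of total-mass variance
  target_sd <- sqrt(cc$heritability) * 20
  if (stats::sd(g_raw) > 0) g_raw <- g_raw * target_sd / stats::sd(g_raw)
  coefs <- stats::setNames(
    lapply(cc$outcomes, function(o) c(total_mass_g = log(2.27) / 22.29)),
    cc$outcomes)
  cspec <- sim_cohort_spec(n_subjects = n_sub,
                           log_hazard_coefficients = coefs,
                           baseline_hazard = cc$baseline_hazard,
                           seed = stage_seed(config$seed, 4L))
  cohort <- generate_cohort(cspec, mass_offsets = list(total = g_raw))
  cohort <- add_hypertrophy_flags(cohort, percentile = cc$percentile)
  cohort <- assign_categories(cohort)
  cohort_path <- file.path(out_dir, "cohort.tsv")
  write_cohort(cohort, cohort_path)
  manifest$stages$cohort <- list(n = nrow(cohort),
                                 percentile = cc$percentile,
                                 category_counts = as.list(table(cohort$hypertrophy_group)),
                                 file = basename(cohort_path))

  # -- stage 4: Cox models ----------------------------------------------
  covars <- config$association$covariates
  for (oc in cc$outcomes) {
    inc <- remove_prevalent(cohort, oc)$incident
    per_sd <- fit_cox(inc, oc, predictors = "total_mass_g",
                      covariates = covars, standardize = "total_mass_g")
    categ <- hypertrophy_hazard_table(inc, oc, covariates = covars)
    joint <- joint_mass_models(inc, oc, covariates = covars)
    hr <- rbind(cbind(model = "per_sd", as.data.frame(per_sd)),
                cbind(model = "categorical", as.data.frame(categ)),
                cbind(model = "joint_apical", as.data.frame(joint$m_apical)),
                cbind(model = "joint_septal", as.data.frame(joint$m_septal)))
    hr_path <- file.path(out_dir, sprintf("hr_%s.tsv", oc))
    utils::write.table(hr, hr_path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages[[paste0("cox_", oc)]] <-
      list(n = nrow(inc), n_events = sum(inc[[paste0(oc, "_event")]]),
           file = basename(hr_path))
  }

  # -- stage 5: scan + clump --------------------------------------------
  panel_f <- filter_variants(panel)
  pheno <- cohort$total_mass_g
  scan <- linear_scan(panel_f, pheno,
                      covariates = cohort[, c("sex", "age")])
  scan_path <- file.path(out_dir, "summary_stats.tsv")
  write_summary_stats(scan, scan_path)
  ld <- panel_ld(panel_f, window_kb = gc$window_kb)
  leads <- clump(scan, ld, p_thresh = gc$p_thresh,
                 r2_thresh = gc$r2_thresh, window_kb = gc$window_kb)
  leads_path <- file.path(out_dir, "clumped_leads.tsv")
  write_summary_stats(leads, leads_path)
  manifest$stages$scan <- list(n_variants = nrow(scan),
                               n_filtered_out = attr(panel_f, "n_removed"),
                               lambda = genomic_lambda(scan),
                               n_significant = sum(scan$p < gc$p_thresh, na.rm = TRUE),
                               n_leads = nrow(leads),
                               p_thresh = gc$p_thresh, r2_thresh = gc$r2_thresh,
                               window_kb = gc$window_kb,
                               files = c(basename(scan_path), basename(leads_path)))

  # -- stage 6: PRS ------------------------------------------------------
  if (nrow(leads) > 0L) {
    weights <- data.frame(variant_id = leads$variant_id,
                          effect_allele = leads$alt,
                          weight = leads$beta, stringsAsFactors = FALSE)
    scores <- prs_score(panel_f, weights)
    sc_path <- file.path(out_dir, "prs_scores.tsv")
    utils::write.table(data.frame(id = names(scores), score = as.numeric(scores)),
                       sc_path, sep = "\t", quote = FALSE, row.names = FALSE)
    oc <- cc$outcomes[1]
    inc <- remove_prevalent(cohort, oc)$incident
    prs_ht <- prs_outcome_association(scores, inc, oc,
                                      quantiles = gc$prs_quantiles)
    prs_path <- file.path(out_dir, sprintf("prs_%s.tsv", oc))
    write_hazard_table(prs_ht, prs_path)
    manifest$stages$prs <- list(n_weights = nrow(weights),
                                quantiles = gc$prs_quantiles,
                                files = c(basename(sc_path), basename(prs_path)))
  } else {
    manifest$stages$prs <- list(n_weights = 0L, skipped = "no clumped leads")
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# rbind regional_mass_record objects into the standard mass table.
quantify_batch_records <- function(recs) {
  do.call(rbind, lapply(recs, function(r)
    data.frame(subject_id = r$subject_id,
               total_mass_g = r$total_mass_g,
               apical_mass_g = r$apical_mass_g,
               septal_mass_g = r$septal_mass_g,
               n_slices_used = r$n_slices_used,
               n_septal_slices = r$n_septal_slices,
               qc_passed = r$qc_passed,
               qc_reasons = paste(r$qc_reasons, collapse = ";"),
               stringsAsFactors = FALSE)))
}
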