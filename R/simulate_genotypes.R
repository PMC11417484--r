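# Synthetic genotype panels: dosages in [0, 2] with configurable minor
# allele frequencies, block LD via a calibrated Gaussian-copula threshold
# model, and known causal effects for ground-truth phenotypes.

#' Specification of a simulated genotype panel
#'
#' @param n_subjects number of subjects.
#' @param n_variants number of variants.
#' @param maf_range minor-allele-frequency range (uniform draw per variant;
#'   within `[0.01, 0.5]`, respecting the standard MAF inclusion filter).
#' @param n_chromosomes variants are spread evenly over this many
#'   chromosomes.
#' @param pos_step_bp base-pair spacing between consecutive variants on a
#'   chromosome.
#' @param causal_indices,causal_betas variant indices with true per-allele
#'   effects (phenotype units per alt allele).
#' @param ld_blocks list of `list(start, size, r)` — 1-based first variant,
#'   block length, and target pairwise dosage correlation in `[0, 1)`.
#'   Blocks share one MAF so the pairwise target is well defined.
#' @param info_range imputation-quality scores drawn uniformly from this
#'   range.
#' @param seed integer seed.
#' @return A list of class `geno_sim_spec`.
#' @export
geno_sim_spec <- function(n_subjects = 1000L, n_variants = 500L,
                          maf_range = c(0.05, 0.5), n_chromosomes = 22L,
                          pos_step_bp = 100000L,
                          causal_indices = integer(0), causal_betas = numeric(0),
                          ld_blocks = list(), info_range = c(0.7, 1),
                          seed = 1L) {
  if (any(maf_range < 0.01 - 1e-12) || any(maf_range > 0.5))
    stop("maf_range must lie within [0.01, 0.5]", call. = FALSE)
  if (length(causal_indices) != length(causal_betas))
    stop("causal_indices and causal_betas must have equal length", call. = FALSE)
  if (length(causal_indices) && (min(causal_indices) < 1 || max(causal_indices) > n_variants))
    stop("causal_indices out of range", call. = FALSE)
  for (b in ld_blocks) {
    if (b$r >= 1 || b$r < 0)
      stop("LD r target must lie in [0, 1)", call. = FALSE)
    if (b$start < 1 || b$start + b$size - 1 > n_variants)
      stop("LD block exceeds n_variants", call. = FALSE)
  }
  structure(as.list(environment()), class = "geno_sim_spec")
}

# P(Z1 < t, Z2 < t) for standard bivariate normal with correlation rho.
.bvn_orthant <- function(t, rho) {
  if (rho <= 0) return(stats::pnorm(t)^2)
  stats::integrate(function(z)
    stats::pnorm((t - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z),
    lower = -Inf, upper = t, rel.tol = 1e-10)$value
}

# Latent Gaussian correlation whose thresholded-allele (phi) correlation at
# the given MAF equals the requested dosage correlation r.
.calibrate_latent_rho <- function(r, maf) {
  if (r <= 0) return(0)
  t <- stats::qnorm(maf)
  phi_of <- function(rho) (.bvn_orthant(t, rho) - maf^2) / (maf * (1 - maf))
  if (phi_of(0.99999) < r) return(0.99999)
  stats::uniroot(function(rho) phi_of(rho) - r, c(1e-6, 0.99999),
                 tol = 1e-9)$root
}

#' Generate a genotype panel
#'
#' Dosages are sums of two haplotype alleles obtained by thresholding latent
#' Gaussians; within each declared LD block the latent correlation is
#' calibrated so the *dosage* correlation matches the block's r target.
#'
#' @param spec a [geno_sim_spec].
#' @return A list of class `genotype_panel`: `dosages` (subjects x variants
#'   matrix), `variants` (data frame `id, chr, pos, ref, alt, maf, info`),
#'   `subjects`, and `truth` (`causal_indices`, `causal_betas`).
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "geno_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects; m <- spec$n_variants
  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  in_block <- integer(m)  # 0 = singleton
  for (i in seq_along(spec$ld_blocks)) {
    b <- spec$ld_blocks[[i]]
    idx <- seq.int(b$start, b$start + b$size - 1L)
    in_block[idx] <- i
    maf[idx] <- maf[b$start]
  }
  dos <- matrix(0L, n, m)
  draw_block <- function(cols, rho_lat, p) {
    thr <- stats::qnorm(p)
    for (hap in 1:2) {
      common <- stats::rnorm(n)
      z <- sqrt(rho_lat) * common +
        sqrt(1 - rho_lat) * matrix(stats::rnorm(n * length(cols)), n)
      dos[, cols] <<- dos[, cols] + (z < thr)
    }
  }
  for (i in seq_along(spec$ld_blocks)) {
    b <- spec$ld_blocks[[i]]
    cols <- seq.int(b$start, b$start + b$size - 1L)
    rho_lat <- .calibrate_latent_rho(b$r, maf[b$start])
    draw_block(cols, rho_lat, maf[b$start])
  }
  singles <- which(in_block == 0L)
  if (length(singles))
    dos[, singles] <- matrix(stats::rbinom(n * length(singles), 2L, rep(maf[singles], each = n)),
                             n, length(singles))
  chr <- rep(seq_len(spec$n_chromosomes), length.out = m)
  chr <- sort(chr)
  pos <- unlist(lapply(split(seq_len(m), chr), function(ix)
    seq_along(ix) * spec$pos_step_bp), use.names = FALSE)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
  variants <- data.frame(id = sprintf("var%05d", seq_len(m)),
                         chr = chr, pos = pos, ref = ref, alt = alt,
                         maf = maf,
                         info = stats::runif(m, spec$info_range[1], spec$info_range[2]),
                         stringsAsFactors = FALSE)
  structure(list(dosages = dos,
                 variants = variants,
                 subjects = sprintf("S%06d", seq_len(n)),
                 truth = list(causal_indices = spec$causal_indices,
                              causal_betas = spec$causal_betas)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d subjects x %d variants (%d causal)\n",
              nrow(x$dosages), ncol(x$dosages), length(x$truth$causal_indices)))
  invisible(x)
}

#' Quantitative phenotype from a panel's causal truth
#'
#' `y = X[, causal] %*% beta + N(0, noise_sd)`; pure noise when the panel
#' has no causal variants.
#'
#' @param panel a `genotype_panel`.
#' @param noise_sd residual standard deviation.
#' @param seed optional seed.
#' @return Numeric vector, one value per subject.
#' @export
genetic_phenotype <- function(panel, noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(panel$dosages)
  y <- stats::rnorm(n, 0, noise_sd)
  tr <- panel$truth
  if (length(tr$causal_indices))
    y <- y + as.numeric(panel$dosages[, tr$causal_indices, drop = FALSE] %*% tr$causal_betas)
  y
}

#' Write a genotype panel as TSV
#'
#' One row per variant: `variant_id, chr, pos, ref, alt`, then one dosage
#' column per subject.
#'
#' @param panel a `genotype_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  meta <- panel$variants[, c("id", "chr", "pos", "ref", "alt")]
  names(meta)[1] <- "variant_id"
  dos <- t(panel$dosages)
  colnames(dos) <- panel$subjects
  utils::write.table(cbind(meta, as.data.frame(dos)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype panel from TSV
#'
#' Inverse of [write_genotypes()]; `maf` is recomputed from the dosages and
#' `info` defaults to 1 (unknown).
#'
#' @param path TSV file.
#' @return A `genotype_panel`.
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("variant_id", "chr", "pos", "ref", "alt")
  dos <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  af <- colMeans(dos) / 2
  variants <- data.frame(id = tab$variant_id, chr = tab$chr, pos = tab$pos,
                         ref = tab$ref, alt = tab$alt,
                         maf = pmin(af, 1 - af), info = 1,
                         stringsAsFactors = FALSE)
  structure(list(dosages = unname(dos), variants = variants,
                 subjects = rownames(dos),
                 truth = list(causal_indices = integer(0), causal_betas = numeric(0))),
            class = "genotype_panel")
}
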