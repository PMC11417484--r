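# Variant filtering, the linear association scan, LD clumping, and
# polygenic scoring.

test_that("MAF and INFO filters are inclusive at their thresholds", {
  g <- geno_sim_spec(n_subjects = 50, n_variants = 10, seed = 51)
  pan <- generate_genotypes(g)
  pan$variants$maf <- c(0.005, 0.01, rep(0.2, 8))
  pan$variants$info <- c(1, 1, 0.3, 0.29, rep(1, 6))
  out <- filter_variants(pan)
  expect_identical(attr(out, "n_removed"), 2L)          # maf 0.005 and info 0.29
  expect_true("var00002" %in% out$variants$id)          # maf exactly 0.01 kept
  expect_true("var00003" %in% out$variants$id)          # info exactly 0.3 kept
  expect_false("var00001" %in% out$variants$id)
  expect_false("var00004" %in% out$variants$id)
})

test_that("filtering a panel of 100 with 7 failing keeps 93", {
  g <- geno_sim_spec(n_subjects = 50, n_variants = 100, seed = 52)
  pan <- generate_genotypes(g)
  pan$variants$maf[c(3, 10, 20)] <- 0.002
  pan$variants$info[c(30, 40, 50, 60)] <- 0.1
  out <- filter_variants(pan)
  expect_identical(ncol(out$dosages), 93L)
  expect_identical(nrow(out$variants), 93L)
})

test_that("filtering remaps causal truth indices", {
  g <- geno_sim_spec(n_subjects = 50, n_variants = 20,
                     causal_indices = c(5, 10), causal_betas = c(0.3, -0.2),
                     seed = 53)
  pan <- generate_genotypes(g)
  pan$variants$maf[c(1, 5)] <- 0.001
  out <- filter_variants(pan)
  expect_identical(out$truth$causal_indices, match(10, setdiff(1:20, c(1, 5))))
  expect_identical(out$truth$causal_betas, -0.2)
})

test_that("the scan recovers an injected effect within 3 standard errors", {
  g <- geno_sim_spec(n_subjects = 5000, n_variants = 50,
                     maf_range = c(0.2, 0.2),
                     causal_indices = 25, causal_betas = 0.3, seed = 54)
  pan <- generate_genotypes(g)
  y <- genetic_phenotype(pan, noise_sd = 1, seed = 55)
  ss <- linear_scan(pan, y)
  expect_lt(abs(ss$beta[25] - 0.3), 3 * ss$se[25])
  expect_lt(ss$p[25], 1e-10)
})

test_that("scan betas match the closed-form slope without covariates", {
  g <- geno_sim_spec(n_subjects = 10000, n_variants = 5, seed = 56)
  pan <- generate_genotypes(g)
  y <- rnorm(10000)
  ss <- linear_scan(pan, y)
  for (j in 1:5) {
    gj <- pan$dosages[, j]
    expect_equal(ss$beta[j], cov(gj, y) / var(gj) * (1), tolerance = 1e-6)
  }
})

test_that("constant dosages yield undefined stats, not dropped rows", {
  g <- geno_sim_spec(n_subjects = 100, n_variants = 5, seed = 57)
  pan <- generate_genotypes(g)
  pan$dosages[, 3] <- 1L
  ss <- linear_scan(pan, rnorm(100))
  expect_identical(nrow(ss), 5L)
  expect_true(is.na(ss$beta[3]) && is.na(ss$p[3]))
})

test_that("a covariate that explains the phenotype nulls the scan", {
  g <- geno_sim_spec(n_subjects = 2000, n_variants = 100, seed = 58)
  pan <- generate_genotypes(g)
  conf <- rnorm(2000)
  y <- 3 * conf + rnorm(2000, 0, 0.01)
  ss <- linear_scan(pan, y, covariates = data.frame(conf = conf))
  expect_lt(max(abs(ss$beta), na.rm = TRUE), 0.01)
  expect_gt(min(ss$p, na.rm = TRUE), 1e-4)
})

test_that("clumping follows the greedy hand traces", {
  mk <- function(p, pos, chr = 1L) {
    data.frame(variant_id = sprintf("v%d", seq_along(p)), chr = chr, pos = pos,
               ref = "A", alt = "C", beta = 1, se = 1, p = p, n = 100,
               stringsAsFactors = FALSE)
  }
  # two variants 100 kb apart in strong LD: smaller p leads
  ld <- data.frame(id1 = "v1", id2 = "v2", r2 = 0.9)
  got <- clump(mk(c(1e-10, 1e-9), c(1e6, 1.1e6)), ld)
  expect_identical(got$variant_id, "v1")
  # 600 kb apart: both lead regardless of LD
  got2 <- clump(mk(c(1e-10, 1e-9), c(1e6, 1.6e6)), ld)
  expect_identical(sort(got2$variant_id), c("v1", "v2"))
  # nothing significant: empty result
  expect_identical(nrow(clump(mk(c(1e-4, 1e-5), c(1e6, 1.1e6)), ld)), 0L)
  # within window but r2 below threshold: both lead
  ld3 <- data.frame(id1 = "v1", id2 = "v2", r2 = 0.5)
  expect_identical(nrow(clump(mk(c(1e-10, 1e-9), c(1e6, 1.1e6)), ld3)), 2L)
  # missing LD entry inside the window is a configuration error
  expect_error(clump(mk(c(1e-10, 1e-9), c(1e6, 1.1e6)),
                     data.frame(id1 = character(0), id2 = character(0),
                                r2 = numeric(0))),
               "no LD entry")
})

test_that("clump output is order-invariant and verifies by brute force", {
  set.seed(59)
  for (rep in 1:3) {
    m <- 60
    stats <- data.frame(variant_id = sprintf("s%02d", 1:m),
                        chr = sample(1:2, m, TRUE),
                        pos = sample.int(3e6, m),
                        ref = "A", alt = "G", beta = 1, se = 1,
                        p = 10^runif(m, -12, -2), n = 500,
                        stringsAsFactors = FALSE)
    pairs <- t(combn(m, 2))
    ld <- data.frame(id1 = stats$variant_id[pairs[, 1]],
                     id2 = stats$variant_id[pairs[, 2]],
                     r2 = runif(nrow(pairs)), stringsAsFactors = FALSE)
    leads <- clump(stats, ld)
    expect_true(verify_clump(stats, leads, ld, 5e-8, 0.6, 500))
    shuffled <- stats[sample.int(m), ]
    leads2 <- clump(shuffled, ld)
    expect_identical(leads2$variant_id, leads$variant_id)
  }
})

test_that("polygenic scores equal the double-loop oracle", {
  g <- geno_sim_spec(n_subjects = 50, n_variants = 20, seed = 60)
  pan <- generate_genotypes(g)
  set.seed(61)
  w <- data.frame(variant_id = pan$variants$id,
                  effect_allele = ifelse(runif(20) < 0.5, pan$variants$alt,
                                         pan$variants$ref),
                  weight = rnorm(20), stringsAsFactors = FALSE)
  scores <- prs_score(pan, w)
  oracle <- numeric(50)
  for (i in 1:50) for (v in 1:20) {
    sign <- if (w$effect_allele[v] == pan$variants$alt[v]) 1 else -1
    oracle[i] <- oracle[i] + sign * w$weight[v] * pan$dosages[i, v]
  }
  expect_lt(max(abs(as.numeric(scores) - oracle)), 1e-12)
})

test_that("scoring is linear and exactly allele-flip invariant", {
  g <- geno_sim_spec(n_subjects = 40, n_variants = 10, seed = 62)
  pan <- generate_genotypes(g)
  set.seed(63)
  w1 <- data.frame(variant_id = pan$variants$id, effect_allele = pan$variants$alt,
                   weight = rnorm(10), stringsAsFactors = FALSE)
  w2 <- w1; w2$weight <- rnorm(10)
  wsum <- w1; wsum$weight <- w1$weight + w2$weight
  expect_equal(as.numeric(prs_score(pan, wsum)),
               as.numeric(prs_score(pan, w1)) + as.numeric(prs_score(pan, w2)),
               tolerance = 1e-14)
  flipped <- w1
  flipped$effect_allele <- pan$variants$ref
  flipped$weight <- -w1$weight
  expect_identical(as.numeric(prs_score(pan, flipped)),
                   as.numeric(prs_score(pan, w1)))
})

test_that("scoring handles trivial and invalid weights per contract", {
  g <- geno_sim_spec(n_subjects = 10, n_variants = 4, seed = 64)
  pan <- generate_genotypes(g)
  w0 <- data.frame(variant_id = pan$variants$id, effect_allele = pan$variants$alt,
                   weight = 0)
  expect_identical(unname(as.numeric(prs_score(pan, w0))), rep(0, 10))
  one <- data.frame(variant_id = pan$variants$id[1],
                    effect_allele = pan$variants$alt[1], weight = 0.5)
  pan$dosages[, 1] <- 2L
  expect_identical(unname(as.numeric(prs_score(pan, one))), rep(1, 10))
  bad <- one; bad$effect_allele <- "Z"
  expect_error(prs_score(pan, bad), "allele mismatch")
  dup <- rbind(one, one)
  expect_error(prs_score(pan, dup), "duplicate")
  # unmatched ids are skipped and counted
  extra <- rbind(one, data.frame(variant_id = "nope", effect_allele = "A",
                                 weight = 1))
  expect_identical(attr(prs_score(pan, extra), "n_unmatched"), 1L)
})

test_that("top-decile indicators flag exactly 10% of distinct scores", {
  set.seed(65)
  spec <- sim_cohort_spec(n_subjects = 2000, seed = 65,
                          log_hazard_coefficients = list(cm = c(total_mass_g = 0.02)),
                          baseline_hazard = 0.02)
  coh <- generate_cohort(spec)
  scores <- stats::setNames(rnorm(2000), coh$id)
  ht <- prs_outcome_association(scores, coh, "cm")
  expect_identical(ht$term, c("PRS (per 1 std)", "PRS (90th percentile)",
                              "PRS (95th percentile)"))
  cut <- quantile(scores, 0.9, names = FALSE)
  expect_identical(sum(scores > cut), 200L)
})
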