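# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Uniform (untapered) annulus phantom, convenient for geometry tests.
uniform_phantom <- function(pixel_spacing = 0.5, inner = 20, outer = 28,
                            n_slices = 1L, arc = c(60, 150), grid = NULL,
                            taper = 0, rv_extent = 8) {
  reach <- (outer + rv_extent) / pixel_spacing
  if (is.null(grid)) grid <- rep(2L * ceiling(reach) + 9L, 2L)
  generate_phantom_stack(phantom_spec(
    grid_shape = grid, pixel_spacing = pixel_spacing, n_slices = n_slices,
    inner_radius = inner, outer_radius = outer, septal_arc = arc,
    apical_taper = taper, rv_extent_mm = rv_extent))
}

# Brute-force minimal circular interval containing a set of angles (deg):
# try every angle as a candidate start and take the smallest forward span.
oracle_min_interval <- function(ang) {
  best <- NULL
  for (start in ang) {
    span <- max((ang - start) %% 360)
    if (is.null(best) || span < best$span) best <- list(start = start, span = span)
  }
  c(best$start, (best$start + best$span) %% 360)
}

# Brute-force contact-pixel angles for a slice: myocardium pixels with any
# 8-neighbour in the RV, angles about the centroid of labels 1 and 2.
oracle_contact_angles <- function(slc) {
  lv <- which(slc == 1L | slc == 2L, arr.ind = TRUE)
  ctr <- colMeans(lv)
  myo <- which(slc == 2L, arr.ind = TRUE)
  ang <- c()
  for (k in seq_len(nrow(myo))) {
    r <- myo[k, 1]; c <- myo[k, 2]
    nb <- expand.grid(r + (-1:1), c + (-1:1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(slc) & nb[, 2] >= 1 & nb[, 2] <= ncol(slc), ]
    if (any(slc[as.matrix(nb)] == 3L))
      ang <- c(ang, (atan2(r - ctr[1], c - ctr[2]) * 180 / pi) %% 360)
  }
  ang
}

# Score-equation solver for a one-covariate Cox model without ties or
# censoring: enumerates risk sets by hand and solves the partial-likelihood
# score U(beta) = 0 with uniroot.
oracle_cox_coef <- function(time, x) {
  ord <- order(time)
  x <- x[ord]
  n <- length(x)
  score <- function(beta) {
    u <- 0
    for (i in seq_len(n)) {
      risk <- i:n
      w <- exp(beta * x[risk])
      u <- u + x[i] - sum(w * x[risk]) / sum(w)
    }
    u
  }
  stats::uniroot(score, c(-20, 20), tol = 1e-12)$root
}

# Post-hoc verifier of the clumping contract: every significant non-lead
# must sit within the window of, and in LD above threshold with, at least
# one lead; no lead may be absorbable by an earlier (smaller-p) lead.
verify_clump <- function(stats, leads, ld, p_thresh, r2_thresh, window_kb) {
  look <- function(a, b) {
    hit <- ld$r2[(ld$id1 == a & ld$id2 == b) | (ld$id1 == b & ld$id2 == a)]
    if (length(hit)) hit[1] else NA_real_
  }
  sig <- stats[!is.na(stats$p) & stats$p < p_thresh, , drop = FALSE]
  lead_ids <- leads$variant_id
  for (i in seq_len(nrow(sig))) {
    id <- sig$variant_id[i]
    absorbers <- vapply(seq_len(nrow(leads)), function(j) {
      leads$p[j] <= sig$p[i] &&
        leads$variant_id[j] != id &&
        leads$chr[j] == sig$chr[i] &&
        abs(leads$pos[j] - sig$pos[i]) <= window_kb * 1000 &&
        isTRUE(look(id, leads$variant_id[j]) > r2_thresh)
    }, logical(1))
    if (id %in% lead_ids) {
      if (any(absorbers)) return(FALSE)   # lead should have been absorbed
    } else {
      if (!any(absorbers)) return(FALSE)  # non-lead has no absorbing lead
    }
  }
  TRUE
}

# Small deterministic cohort for categorical / date logic tests.
tiny_cohort <- function() {
  data.frame(
    id = sprintf("T%02d", 1:6),
    sex = rep(c("male", "female"), 3),
    baseline_date = as.Date("2015-01-01"),
    cm_first_event_date = as.Date(c("2013-01-01", "2016-06-01", NA,
                                    "2015-01-02", NA, "2012-05-05")),
    cm_follow_up_end_date = as.Date(c("2019-01-01", "2016-06-01", "2019-01-01",
                                      "2018-01-01", "2017-01-01", "2019-01-01")),
    stringsAsFactors = FALSE)
}
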