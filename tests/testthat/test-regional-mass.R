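# The core measurement: pixel counts to grams, apical slice selection,
# insertion angles, septal delineation, and whole-subject quantification.

test_that("pixel counts convert to grams per the density formula", {
  st <- mask_stack(array(2L, c(1, 2, 2)), pixel_spacing = 1,
                   slice_thickness = 8, slice_gap = 2)
  expect_equal(slice_region_mass(1000, st), 10.55)         # 10 cm^3
  expect_equal(slice_region_mass(0, st), 0)
  expect_equal(slice_region_mass(100, st), 1.055)          # the density constant
  expect_error(slice_region_mass(-1, st), "non-negative")
  # thickness-only convention drops the gap from the coverage
  expect_equal(slice_region_mass(1000, st, slice_coverage = "thickness_only"),
               8 * 1.055)
})

test_that("total mass matches analytic truth within 2% at 0.5 mm", {
  ph <- uniform_phantom(pixel_spacing = 0.5, n_slices = 10)
  expect_equal(total_lv_mass(ph$stack), ph$truth$total_mass_g,
               tolerance = 0.02)
})

test_that("mass scales with the pixel-area law", {
  ph <- uniform_phantom(pixel_spacing = 1, n_slices = 2)
  st2 <- ph$stack
  st2$pixel_spacing <- st2$pixel_spacing * 2  # same counts, 4x area
  expect_equal(total_lv_mass(st2), 4 * total_lv_mass(ph$stack))
})

test_that("apical selection takes the myocardium-containing tail", {
  ph <- generate_phantom_stack(phantom_spec(n_slices = 10))
  expect_identical(select_apical_slices(ph$stack), 7:10)

  # blank the two most apex-ward slices: selection must skip them
  st <- ph$stack
  st$labels[9:10, , ] <- 0L
  expect_identical(select_apical_slices(st), 5:8)

  st4 <- ph$stack
  st4$labels <- st4$labels[1:4, , , drop = FALSE]
  expect_identical(select_apical_slices(st4), 1:4)
  expect_equal(apical_mass(st4), total_lv_mass(st4))

  st3 <- ph$stack
  st3$labels <- st3$labels[1:3, , , drop = FALSE]
  expect_error(select_apical_slices(st3), "insufficient coverage")
})

test_that("apical mass matches the analytic last-four-slice truth", {
  ph <- uniform_phantom(pixel_spacing = 0.5, n_slices = 10)
  expect_equal(apical_mass(ph$stack), ph$truth$apical_mass_g, tolerance = 0.02)
  # uniform slices: apical is 4/10 of total (up to pixelation)
  expect_equal(apical_mass(ph$stack) / total_lv_mass(ph$stack), 0.4,
               tolerance = 1e-6)
  # taper shrinks the apex below the uniform share
  tp <- generate_phantom_stack(phantom_spec(pixel_spacing = 0.5,
                                            grid_shape = c(160, 160),
                                            apical_taper = 0.08))
  expect_lt(apical_mass(tp$stack) / total_lv_mass(tp$stack), 0.4)
})

test_that("insertion angles recover the constructed arc", {
  for (arc in list(c(60, 150), c(300, 20), c(330, 30))) {
    ph <- uniform_phantom(pixel_spacing = 0.5, arc = arc, n_slices = 1)
    slc <- ph$stack$labels[1, , ]
    got <- rv_insertion_angles(slc)
    res_deg <- atan(0.5 / 28) * 180 / pi  # one pixel at the epicardial radius
    expect_lt(abs(((got[1] - arc[1]) + 180) %% 360 - 180), 2 * res_deg)
    expect_lt(abs(((got[2] - arc[2]) + 180) %% 360 - 180), 2 * res_deg)
    # endpoints agree with the brute-force minimal circular interval
    oracle <- oracle_min_interval(oracle_contact_angles(slc))
    expect_equal(unname(got), oracle, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("slices without RV return no angles; huge arcs are degenerate", {
  ph <- uniform_phantom(n_slices = 1)
  slc <- ph$stack$labels[1, , ]
  slc[slc == 3L] <- 0L
  expect_null(rv_insertion_angles(slc))
  # paint RV around 270 degrees of the epicardium: degenerate contact
  big <- uniform_phantom(n_slices = 1)$stack$labels[1, , ]
  lv <- which(big == 1L | big == 2L, arr.ind = TRUE)
  ctr <- colMeans(lv)
  idx <- which(big == 0L, arr.ind = TRUE)
  ang <- (atan2(idx[, 1] - ctr[1], idx[, 2] - ctr[2]) * 180 / pi) %% 360
  rad <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2) * 0.5
  sel <- ang < 270 & rad >= 28 & rad < 34
  big[idx[sel, , drop = FALSE]] <- 3L
  expect_error(rv_insertion_angles(big), "degenerate")
  expect_warning(expect_null(rv_insertion_angles(big, on_degenerate = "drop")),
                 "degenerate")
})

test_that("a 90-degree septum holds a quarter of the slice myocardium", {
  ph <- uniform_phantom(pixel_spacing = 0.5, arc = c(45, 135), n_slices = 1)
  slc <- ph$stack$labels[1, , ]
  px <- septal_pixels(slc, rv_insertion_angles(slc))
  frac <- length(px) / sum(slc == 2L)
  expect_lt(abs(frac - 0.25), 0.02)
  expect_true(all(slc[px] == 2L))  # subset of myocardium by construction
})

test_that("septal plus non-septal pixel counts conserve the myocardium", {
  ph <- generate_phantom_stack(phantom_spec(pixel_spacing = 0.5,
                                            grid_shape = c(170, 170)))
  for (k in seq_len(10)) {
    slc <- ph$stack$labels[k, , ]
    px <- septal_pixels(slc, rv_insertion_angles(slc))
    n_myo <- sum(slc == 2L)
    n_non <- n_myo - length(px)
    expect_identical(length(px) + n_non, n_myo)
  }
})

test_that("septal mass matches the arc-fraction oracle", {
  ph <- uniform_phantom(pixel_spacing = 0.5, arc = c(45, 135), n_slices = 10)
  sm <- septal_mass(ph$stack)
  expect_equal(as.numeric(sm) / total_lv_mass(ph$stack), 0.25, tolerance = 0.02)
  expect_identical(attr(sm, "n_septal_slices"), 10L)
})

test_that("slices without RV contact follow the configured fallback", {
  ph <- uniform_phantom(pixel_spacing = 1, arc = c(45, 135), n_slices = 10)
  st <- ph$stack
  for (k in 7:10) {
    slc <- st$labels[k, , ]; slc[slc == 3L] <- 0L; st$labels[k, , ] <- slc
  }
  sm <- septal_mass(st)
  expect_identical(attr(sm, "n_septal_slices"), 6L)
  # per-slice decomposition oracle: 6 contributing uniform slices
  one <- uniform_phantom(pixel_spacing = 1, arc = c(45, 135), n_slices = 1)
  expect_equal(as.numeric(sm), 6 * as.numeric(septal_mass(one$stack)),
               tolerance = 1e-9)
  # nearest-slice fallback extends the angles to all 10 slices
  sm_near <- septal_mass(st, no_contact = "nearest")
  expect_identical(attr(sm_near, "n_septal_slices"), 10L)
  expect_equal(as.numeric(sm_near), 10 * as.numeric(septal_mass(one$stack)),
               tolerance = 1e-9)
  # no contact anywhere: septum undefined
  norv <- st
  norv$labels[norv$labels == 3L] <- 0L
  expect_error(septal_mass(norv), "no slice with RV contact")
})

test_that("rotating the anatomy rotates angles and preserves masses", {
  ph <- uniform_phantom(pixel_spacing = 0.5, arc = c(60, 150), n_slices = 1)
  slc <- ph$stack$labels[1, , ]
  rot <- t(slc[nrow(slc):1, ])  # 90-degree in-plane rotation
  st_rot <- ph$stack
  st_rot$labels <- array(rot, c(1, dim(rot)))
  a0 <- rv_insertion_angles(slc)
  a1 <- rv_insertion_angles(st_rot$labels[1, , ])
  d1 <- (a1[1] - a0[1]) %% 360
  d2 <- (a1[2] - a0[2]) %% 360
  expect_equal(unname(d1), 90, tolerance = 1e-6)
  expect_equal(unname(d2), 90, tolerance = 1e-6)
  expect_equal(total_lv_mass(st_rot), total_lv_mass(ph$stack))
  expect_equal(as.numeric(septal_mass(st_rot)), as.numeric(septal_mass(ph$stack)),
               tolerance = 0.005)
})

test_that("whole-pixel translation changes no output", {
  a <- generate_phantom_stack(phantom_spec(grid_shape = c(120, 120),
                                           lv_center = c(55, 55)))
  b <- generate_phantom_stack(phantom_spec(grid_shape = c(120, 120),
                                           lv_center = c(60, 50)))
  expect_equal(total_lv_mass(a$stack), total_lv_mass(b$stack))
  expect_equal(apical_mass(a$stack), apical_mass(b$stack))
  expect_equal(as.numeric(septal_mass(a$stack)), as.numeric(septal_mass(b$stack)))
})

test_that("mass errors shrink monotonically with grid refinement", {
  radii <- list(c(15, 23), c(18, 26), c(22, 31), c(25, 35))
  err <- sapply(c(2, 1, 0.5), function(sp) {
    rowMeans(vapply(radii, function(rr) {
      ph <- uniform_phantom(pixel_spacing = sp, inner = rr[1], outer = rr[2],
                            n_slices = 6, arc = c(45, 135))
      c(abs(total_lv_mass(ph$stack) - ph$truth$total_mass_g) / ph$truth$total_mass_g,
        abs(apical_mass(ph$stack) - ph$truth$apical_mass_g) / ph$truth$apical_mass_g,
        abs(as.numeric(septal_mass(ph$stack)) - ph$truth$septal_mass_g) / ph$truth$septal_mass_g)
    }, numeric(3)))
  })
  for (row in 1:3) expect_true(all(diff(err[row, ]) < 0))
})

test_that("quantify_subject produces complete records and honours QC", {
  ph <- generate_phantom_stack(phantom_spec(pixel_spacing = 0.5,
                                            grid_shape = c(170, 170)),
                               subject_id = "ok1")
  rec <- quantify_subject(ph$stack)
  expect_true(rec$qc_passed)
  expect_equal(rec$total_mass_g, ph$truth$total_mass_g, tolerance = 0.02)
  expect_equal(rec$apical_mass_g, ph$truth$apical_mass_g, tolerance = 0.02)
  expect_equal(rec$septal_mass_g, ph$truth$septal_mass_g, tolerance = 0.03)
  expect_identical(rec$n_slices_used, 10L)

  broken <- inject_defects(ph$stack, break_annulus_slice = 5)
  rec2 <- quantify_subject(broken)
  expect_false(rec2$qc_passed)
  expect_true(is.na(rec2$total_mass_g))
  expect_true("broken_annulus" %in% rec2$qc_reasons)
})

test_that("batch quantification is order-preserving", {
  specs <- list(phantom_spec(inner_radius = 18, outer_radius = 26),
                phantom_spec(inner_radius = 20, outer_radius = 28),
                phantom_spec(inner_radius = 22, outer_radius = 30))
  stacks <- lapply(seq_along(specs), function(i)
    generate_phantom_stack(specs[[i]], subject_id = sprintf("B%d", i))$stack)
  tab <- quantify_batch(stacks)
  expect_equal(tab$subject_id, c("B1", "B2", "B3"))
  expect_true(all(diff(tab$total_mass_g) > 0))
  expect_true(all(tab$qc_passed))
})
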