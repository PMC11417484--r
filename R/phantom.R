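# Myocardial density, g per mm^3 (1.055 g/cm^3).
MYOCARDIAL_DENSITY_G_PER_MM3 <- 1.055e-3

#' Specification of an annular myocardium phantom
#'
#' Defines a stack of concentric-annulus slices: LV cavity inside
#' `inner_radius`, LV myocardium between the radii, and an RV half-annulus
#' segment of radial extent `rv_extent_mm` touching the epicardium exactly
#' over `septal_arc`, so insertion-angle ground truth is known by
#' construction. Radii shrink by `apical_taper` per slice toward the apex.
#'
#' Angles are measured in the (row, col) plane: 0 degrees along +col,
#' increasing toward +row, in `[0, 360)`. `septal_arc` is the half-open
#' interval `[start, end)` going forward (mod 360); its span must be below
#' 180 degrees.
#'
#' @param grid_shape `(rows, cols)` in pixels.
#' @param pixel_spacing isotropic in-plane mm per pixel.
#' @param n_slices number of slices (base to apex).
#' @param slice_thickness,slice_gap slice geometry in mm.
#' @param lv_center `(row, col)` continuous pixel coordinates of the LV
#'   centre; defaults to the grid centre.
#' @param inner_radius,outer_radius endo- and epicardial radii in mm at the
#'   base.
#' @param septal_arc `(start_deg, end_deg)` RV-contact arc.
#' @param apical_taper fraction by which both radii shrink per slice toward
#'   the apex (radius at slice k is `radius * (1 - apical_taper)^k`).
#' @param rv_extent_mm radial extent of the RV segment beyond the epicardium.
#' @param seed integer seed (recorded; generation itself is deterministic).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(160L, 160L), pixel_spacing = 1,
                         n_slices = 10L, slice_thickness = 8, slice_gap = 2,
                         lv_center = NULL, inner_radius = 20, outer_radius = 28,
                         septal_arc = c(60, 150), apical_taper = 0.06,
                         rv_extent_mm = 8, seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 2L))
  if (is.null(lv_center)) lv_center <- (grid_shape + 1) / 2
  if (!(outer_radius > inner_radius && inner_radius > 0))
    stop("phantom geometry error: need outer_radius > inner_radius > 0", call. = FALSE)
  span <- (septal_arc[2] - septal_arc[1]) %% 360
  if (span >= 180)
    stop("unsupported geometry: septal arc span must be below 180 degrees", call. = FALSE)
  if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive", call. = FALSE)
  if (apical_taper < 0 || apical_taper >= 1)
    stop("apical_taper must be in [0, 1)", call. = FALSE)
  # the outermost structure (epicardium + RV segment) must fit on the grid
  reach_px <- (outer_radius + rv_extent_mm) / pixel_spacing
  if (lv_center[1] - reach_px < 1 || lv_center[1] + reach_px > grid_shape[1] ||
      lv_center[2] - reach_px < 1 || lv_center[2] + reach_px > grid_shape[2])
    stop("phantom geometry error: annulus plus RV segment exceeds the grid", call. = FALSE)
  structure(list(grid_shape = grid_shape, pixel_spacing = pixel_spacing,
                 n_slices = as.integer(n_slices),
                 slice_thickness = slice_thickness, slice_gap = slice_gap,
                 lv_center = as.numeric(lv_center),
                 inner_radius = inner_radius, outer_radius = outer_radius,
                 septal_arc = as.numeric(septal_arc),
                 apical_taper = apical_taper, rv_extent_mm = rv_extent_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Pixel-centre polar coordinates about a continuous centre, in mm / degrees.
.polar_grid <- function(grid_shape, pixel_spacing, center) {
  rows <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  cols <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2], byrow = TRUE)
  dr <- (rows - center[1]) * pixel_spacing
  dc <- (cols - center[2]) * pixel_spacing
  list(r = sqrt(dr^2 + dc^2),
       theta = (atan2(dr, dc) * 180 / pi) %% 360)
}

.in_arc <- function(theta, start, end) {
  span <- (end - start) %% 360
  ((theta - start) %% 360) < span
}

#' Generate an annular phantom stack with analytic ground truth
#'
#' @param spec a [phantom_spec].
#' @param subject_id subject id for the resulting stack.
#' @return A list with elements `stack` (a [mask_stack]) and `truth` (class
#'   `phantom_truth`: `total_mass_g`, `apical_mass_g`, `septal_mass_g`,
#'   `per_slice_areas_mm2`, `per_slice_mass_g`, `insertion_angles`).
#' @export
generate_phantom_stack <- function(spec, subject_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  pol <- .polar_grid(gs, spec$pixel_spacing, spec$lv_center)
  labels <- array(0L, c(spec$n_slices, gs[1], gs[2]))
  scale <- (1 - spec$apical_taper)^(seq_len(spec$n_slices) - 1)
  areas <- numeric(spec$n_slices)
  for (k in seq_len(spec$n_slices)) {
    rin <- spec$inner_radius * scale[k]
    rout <- spec$outer_radius * scale[k]
    slc <- matrix(0L, gs[1], gs[2])
    slc[pol$r < rin] <- LABEL_LV_CAVITY
    slc[pol$r >= rin & pol$r < rout] <- LABEL_LV_MYOCARDIUM
    rv <- pol$r >= rout & pol$r < rout + spec$rv_extent_mm &
      .in_arc(pol$theta, spec$septal_arc[1], spec$septal_arc[2])
    slc[rv] <- LABEL_RV_CAVITY
    labels[k, , ] <- slc
    areas[k] <- pi * (rout^2 - rin^2)
  }
  coverage <- spec$slice_thickness + spec$slice_gap
  slice_mass <- areas * coverage * MYOCARDIAL_DENSITY_G_PER_MM3
  arc_fraction <- ((spec$septal_arc[2] - spec$septal_arc[1]) %% 360) / 360
  n_ap <- min(4L, spec$n_slices)
  truth <- structure(list(
    total_mass_g = sum(slice_mass),
    apical_mass_g = sum(utils::tail(slice_mass, n_ap)),
    septal_mass_g = arc_fraction * sum(slice_mass),
    per_slice_areas_mm2 = areas,
    per_slice_mass_g = slice_mass,
    insertion_angles = spec$septal_arc), class = "phantom_truth")
  stack <- mask_stack(labels, pixel_spacing = spec$pixel_spacing,
                      slice_thickness = spec$slice_thickness,
                      slice_gap = spec$slice_gap, subject_id = subject_id)
  list(stack = stack, truth = truth)
}

#' Inject structural defects into a phantom stack
#'
#' Used to exercise quality control: drop the most apical slices (apex not
#' visualised) and/or cut the myocardial ring open in one slice.
#'
#' @param stack a [mask_stack].
#' @param drop_apex_slices number of apex-most slices to blank out.
#' @param break_annulus_slice slice index (base-to-apex) whose ring is cut,
#'   or `NULL`.
#' @param break_at_deg angular position of the cut.
#' @param break_width_px approximate width of the cut in pixels.
#' @return The modified [mask_stack].
#' @export
inject_defects <- function(stack, drop_apex_slices = 0L,
                           break_annulus_slice = NULL, break_at_deg = 0,
                           break_width_px = 2) {
  stopifnot(inherits(stack, "mask_stack"))
  ns <- n_slices(stack)
  if (drop_apex_slices > 0L) {
    keep_from <- ns - min(drop_apex_slices, ns) + 1L
    for (k in seq.int(keep_from, ns)) stack$labels[k, , ] <- 0L
  }
  if (!is.null(break_annulus_slice)) {
    k <- break_annulus_slice
    slc <- stack$labels[k, , ]
    myo <- which(slc == LABEL_LV_MYOCARDIUM, arr.ind = TRUE)
    if (nrow(myo)) {
      lv <- which(slc == LABEL_LV_CAVITY | slc == LABEL_LV_MYOCARDIUM, arr.ind = TRUE)
      ctr <- colMeans(lv)
      dr <- myo[, 1] - ctr[1]; dc <- myo[, 2] - ctr[2]
      theta <- (atan2(dr, dc) * 180 / pi) %% 360
      rad <- sqrt(dr^2 + dc^2)
      # angular half-width that spans break_width_px at the innermost radius
      half <- (break_width_px / max(min(rad), 1)) * 180 / pi / 2 + 1e-9
      cut <- abs(((theta - break_at_deg + 180) %% 360) - 180) <= half
      slc[myo[cut, , drop = FALSE]] <- 0L
      stack$labels[k, , ] <- slc
    }
  }
  stack
}
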