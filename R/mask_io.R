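# Label conventions for short-axis segmentation stacks.
# 0 = background, 1 = LV cavity, 2 = LV myocardium, 3 = RV cavity.
LABEL_BACKGROUND <- 0L
LABEL_LV_CAVITY <- 1L
LABEL_LV_MYOCARDIUM <- 2L
LABEL_RV_CAVITY <- 3L

.default_label_map <- function() {
  c(background = 0L, lv_cavity = 1L, lv_myocardium = 2L, rv_cavity = 3L)
}

#' Labelled short-axis segmentation stack
#'
#' Container for a 3-D integer label volume with its acquisition geometry.
#' Arrays are indexed `(slice, row, col)`, 0-based slice counting from the
#' base; slices are always stored base-to-apex internally.
#'
#' @param labels 3-D integer array `(slice, row, col)` with values in
#'   `{0, 1, 2, 3}` (background, LV cavity, LV myocardium, RV cavity).
#' @param pixel_spacing length-2 numeric, in-plane mm per pixel `(row, col)`.
#' @param slice_thickness slice thickness in mm.
#' @param slice_gap inter-slice gap in mm (>= 0).
#' @param slice_order `"base_to_apex"` (stored) or `"apex_to_base"`
#'   (reversed on construction so the stored order is always base-to-apex).
#' @param subject_id opaque subject identifier.
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(labels, pixel_spacing, slice_thickness = 8,
                       slice_gap = 2, slice_order = c("base_to_apex", "apex_to_base"),
                       subject_id = "subject") {
  slice_order <- match.arg(slice_order)
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array (slice, row, col)", call. = FALSE)
  if (dim(labels)[1] < 1L)
    stop("stack must contain at least one slice", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad))
    stop(sprintf("unknown label value(s): %s (expected 0-3)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be positive", call. = FALSE)
  if (slice_thickness <= 0) stop("slice thickness must be positive", call. = FALSE)
  if (slice_gap < 0) stop("slice gap must be non-negative", call. = FALSE)
  if (slice_order == "apex_to_base")
    labels <- labels[dim(labels)[1]:1, , , drop = FALSE]
  structure(list(labels = labels,
                 pixel_spacing = pixel_spacing,
                 slice_thickness = as.numeric(slice_thickness),
                 slice_gap = as.numeric(slice_gap),
                 slice_order = "base_to_apex",
                 subject_id = as.character(subject_id)),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("mask_stack '%s': %d slices x %d x %d px, spacing %.3g x %.3g mm, thickness %g mm, gap %g mm\n",
              x$subject_id, d[1], d[2], d[3],
              x$pixel_spacing[1], x$pixel_spacing[2],
              x$slice_thickness, x$slice_gap))
  invisible(x)
}

n_slices <- function(stack) dim(stack$labels)[1]

slice_labels <- function(stack, i) stack$labels[i, , ]

#' Write a segmentation stack as NIfTI
#'
#' The header encodes in-plane pixel spacing and slice spacing
#' (thickness + gap); the slice gap itself is recovered at read time from the
#' configured or default slice thickness.
#'
#' @param stack a [mask_stack].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(stack, path) {
  stopifnot(inherits(stack, "mask_stack"))
  if (prod(dim(stack$labels)) == 0L)
    stop("refusing to write an empty stack", call. = FALSE)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("cannot write to '%s': no such directory", dir), call. = FALSE)
  # NIfTI axis order (x = col, y = row, z = slice)
  arr <- aperm(stack$labels, c(3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(stack$pixel_spacing[2], stack$pixel_spacing[1],
                           stack$slice_thickness + stack$slice_gap)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a segmentation stack from NIfTI
#'
#' Geometry comes from the NIfTI header: in-plane spacing from pixdim 1-2,
#' slice spacing from pixdim 3, with `slice_gap = slice spacing -
#' slice_thickness`. When the header slice spacing is absent or non-positive
#' the common short-axis protocol defaults (thickness 8 mm, gap 2 mm) are
#' assumed with a warning. `label_map` maps file label values to the
#' canonical encoding; any file value not covered is an error.
#'
#' @param path NIfTI file.
#' @param label_map named integer vector mapping canonical names
#'   (`background`, `lv_cavity`, `lv_myocardium`, `rv_cavity`) to the values
#'   used in the file.
#' @param slice_order order of slices in the file; stacks are normalised to
#'   base-to-apex internally.
#' @param slice_thickness thickness in mm; `NULL` uses the 8 mm default.
#' @param slice_gap explicit gap override in mm; `NULL` derives it from the
#'   header slice spacing.
#' @param subject_id subject id; defaults to the file stem.
#' @return A [mask_stack].
#' @export
read_mask_stack <- function(path, label_map = .default_label_map(),
                            slice_order = c("base_to_apex", "apex_to_base"),
                            slice_thickness = NULL, slice_gap = NULL,
                            subject_id = NULL) {
  slice_order <- match.arg(slice_order)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- round(as.array(img))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  storage.mode(arr) <- "integer"
  needed <- c("background", "lv_cavity", "lv_myocardium", "rv_cavity")
  if (!all(needed %in% names(label_map)))
    stop("label_map must name background, lv_cavity, lv_myocardium, rv_cavity",
         call. = FALSE)
  present <- unique(as.vector(arr))
  unknown <- setdiff(present, label_map[needed])
  if (length(unknown))
    stop(sprintf("unknown label value(s) in %s: %s", basename(path),
                 paste(sort(unknown), collapse = ", ")), call. = FALSE)
  remapped <- array(0L, dim(arr))
  for (i in seq_along(needed))
    remapped[arr == label_map[[needed[i]]]] <- i - 1L

  pd <- RNifti::pixdim(img)
  if (length(pd) < 2L || any(pd[1:2] <= 0))
    stop(sprintf("non-positive in-plane pixel spacing in %s header", basename(path)),
         call. = FALSE)
  spacing <- c(pd[2], pd[1])  # header order is (x=col, y=row)
  slice_spacing <- if (length(pd) >= 3L) pd[3] else NA_real_
  if (is.null(slice_thickness)) slice_thickness <- 8
  if (is.null(slice_gap)) {
    if (is.na(slice_spacing) || slice_spacing <= 0) {
      warning(sprintf("%s: no usable slice spacing in header; assuming thickness 8 mm + gap 2 mm",
                      basename(path)), call. = FALSE)
      slice_gap <- 2
    } else {
      slice_gap <- slice_spacing - slice_thickness
      if (slice_gap < 0)
        stop(sprintf("%s: header slice spacing %.3g mm smaller than slice thickness %.3g mm",
                     basename(path), slice_spacing, slice_thickness), call. = FALSE)
    }
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  mask_stack(aperm(remapped, c(3L, 2L, 1L)), pixel_spacing = spacing,
             slice_thickness = slice_thickness, slice_gap = slice_gap,
             slice_order = slice_order, subject_id = subject_id)
}

# ---- connected components ----------------------------------------------

# Label connected components of a logical matrix via an igraph pixel graph.
# connectivity 8 links diagonal neighbours, 4 does not. Returns an integer
# matrix of component ids (0 outside the mask) with attribute "n".
.label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  n <- sum(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0L) return(structure(out, n = 0L))
  idx <- matrix(0L, nrow(mask), ncol(mask))
  idx[mask] <- seq_len(n)
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  nr <- nrow(mask); nc <- ncol(mask)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- idx[r1, c1, drop = FALSE]
    b <- idx[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    from <- c(from, a[keep]); to <- c(to, b[keep])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)
  out[mask] <- comp$membership
  structure(out, n = as.integer(comp$no))
}

# TRUE when the myocardium of a 2-D slice forms a closed ring:
# one 8-connected myocardial component whose enclosed cavity is not
# 4-connected to the image border background.
.annulus_intact <- function(slc) {
  myo <- slc == LABEL_LV_MYOCARDIUM
  if (!any(myo)) return(FALSE)
  comp <- .label_components(myo, connectivity = 8)
  if (attr(comp, "n") != 1L) return(FALSE)
  bg <- .label_components(!myo, connectivity = 4)
  cav <- which(slc == LABEL_LV_CAVITY, arr.ind = TRUE)
  if (nrow(cav) == 0L) return(FALSE)
  inside_id <- bg[cav[1, 1], cav[1, 2]]
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  !(inside_id %in% setdiff(border_ids, 0L))
}

# ---- quality control ----------------------------------------------------

#' Quality-control criteria for segmentation stacks
#'
#' @param min_myocardial_slices minimum number of slices containing LV
#'   myocardium.
#' @param apex_cap_fraction the most apical myocardial slice must have an LV
#'   cavity area below this fraction of the maximum mid-third cavity area for
#'   the apex to count as visualised.
#' @param checks which checks to run.
#' @return A list of class `qc_criteria`.
#' @export
qc_criteria <- function(min_myocardial_slices = 6, apex_cap_fraction = 0.5,
                        checks = c("too_few_slices", "no_rv_contact",
                                   "broken_annulus", "apex_not_capped")) {
  structure(list(min_myocardial_slices = min_myocardial_slices,
                 apex_cap_fraction = apex_cap_fraction,
                 checks = checks),
            class = "qc_criteria")
}

.mid_third <- function(n) {
  lo <- floor(n / 3) + 1L
  hi <- ceiling(2 * n / 3)
  seq.int(lo, max(lo, hi))
}

#' Quality-control a segmentation stack
#'
#' Applies configurable structural checks emulating the exclusion of poorly
#' visualised ventricles and apices: enough myocardium-bearing slices, RV
#' visible in the mid third of the stack, a closed myocardial ring in each
#' mid-third slice, and a capped (shrinking-cavity) apex. Failures are
#' reported, never raised.
#'
#' @param stack a [mask_stack].
#' @param criteria a [qc_criteria] object.
#' @return A list of class `qc_result` with `passed`, `reasons`,
#'   `n_myocardial_slices`.
#' @export
qc_stack <- function(stack, criteria = qc_criteria()) {
  stopifnot(inherits(stack, "mask_stack"), inherits(criteria, "qc_criteria"))
  reasons <- character(0)
  ns <- n_slices(stack)
  myo_per_slice <- vapply(seq_len(ns), function(i)
    sum(slice_labels(stack, i) == LABEL_LV_MYOCARDIUM), integer(1))
  myo_slices <- which(myo_per_slice > 0L)
  n_myo <- length(myo_slices)
  mid <- intersect(.mid_third(ns), seq_len(ns))

  if ("too_few_slices" %in% criteria$checks &&
      n_myo < criteria$min_myocardial_slices)
    reasons <- c(reasons, "too_few_slices")

  if ("no_rv_contact" %in% criteria$checks) {
    has_rv <- any(vapply(mid, function(i)
      any(slice_labels(stack, i) == LABEL_RV_CAVITY), logical(1)))
    if (!has_rv) reasons <- c(reasons, "no_rv_contact")
  }

  if ("broken_annulus" %in% criteria$checks) {
    intact <- vapply(mid, function(i) .annulus_intact(slice_labels(stack, i)),
                     logical(1))
    if (!all(intact)) reasons <- c(reasons, "broken_annulus")
  }

  if ("apex_not_capped" %in% criteria$checks && n_myo > 0L) {
    cav_area <- vapply(seq_len(ns), function(i)
      sum(slice_labels(stack, i) == LABEL_LV_CAVITY), integer(1))
    apex_slice <- max(myo_slices)
    ref <- max(cav_area[mid], 1L)
    if (cav_area[apex_slice] >= criteria$apex_cap_fraction * ref)
      reasons <- c(reasons, "apex_not_capped")
  }

  structure(list(passed = length(reasons) == 0L,
                 reasons = reasons,
                 n_myocardial_slices = n_myo),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  if (x$passed) cat("QC passed,", x$n_myocardial_slices, "myocardial slices\n")
  else cat("QC failed:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Append QC outcomes to a TSV audit log
#'
#' @param stack a [mask_stack].
#' @param result a `qc_result`.
#' @param path log file; created with a header when absent.
#' @return `path`, invisibly.
#' @export
append_qc_log <- function(stack, result, path) {
  row <- data.frame(subject_id = stack$subject_id,
                    passed = result$passed,
                    reasons = paste(result$reasons, collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.table(row, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !file.exists(path),
                     append = file.exists(path))
  invisible(path)
}
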