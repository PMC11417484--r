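# Regional left-ventricular mass from labelled short-axis stacks.
#
# Per-slice myocardial pixel counts are converted to grams as
#   count * pixel_area_mm2 * (slice_thickness + slice_gap) * 1.055e-3 g/mm3,
# the septum on each slice is the myocardial segment bounded by the two RV
# insertion points about the LV centroid, and the apical region is the four
# most apex-ward myocardium-containing slices.

#' Convert a per-slice pixel count to mass in grams
#'
#' Pixel area times per-slice coverage (slice thickness plus inter-slice gap,
#' or thickness alone under `slice_coverage = "thickness_only"`) times
#' myocardial density 1.055 g/cm^3.
#'
#' @param pixel_count non-negative number of pixels in the region.
#' @param stack a [mask_stack] supplying the geometry.
#' @param slice_coverage `"thickness_plus_gap"` (contiguous-coverage
#'   convention, default) or `"thickness_only"`.
#' @return Mass in grams.
#' @export
slice_region_mass <- function(pixel_count, stack,
                              slice_coverage = c("thickness_plus_gap", "thickness_only")) {
  slice_coverage <- match.arg(slice_coverage)
  if (any(pixel_count < 0)) stop("pixel_count must be non-negative", call. = FALSE)
  coverage <- if (slice_coverage == "thickness_plus_gap")
    stack$slice_thickness + stack$slice_gap else stack$slice_thickness
  pixel_count * prod(stack$pixel_spacing) * coverage * MYOCARDIAL_DENSITY_G_PER_MM3
}

.myocardial_slices <- function(stack) {
  ns <- n_slices(stack)
  which(vapply(seq_len(ns), function(i)
    any(slice_labels(stack, i) == LABEL_LV_MYOCARDIUM), logical(1)))
}

#' Total left-ventricular mass
#'
#' Sum of [slice_region_mass()] over the LV myocardium pixels of every slice.
#'
#' @inheritParams slice_region_mass
#' @return Total LV mass in grams.
#' @export
total_lv_mass <- function(stack, slice_coverage = "thickness_plus_gap") {
  count <- sum(stack$labels == LABEL_LV_MYOCARDIUM)
  if (count == 0L) stop("no myocardial pixels in stack", call. = FALSE)
  slice_region_mass(count, stack, slice_coverage)
}

#' Select the apical slices
#'
#' The `n_apical` most apex-ward slices *containing LV myocardium* (trailing
#' myocardium-free slices are skipped), in base-to-apex order.
#'
#' @param stack a [mask_stack] (stored base-to-apex).
#' @param n_apical number of apical slices (default 4).
#' @return Integer slice indices.
#' @export
select_apical_slices <- function(stack, n_apical = 4L) {
  stopifnot(n_apical >= 1L)
  myo <- .myocardial_slices(stack)
  if (length(myo) < n_apical)
    stop(sprintf("insufficient coverage: %d myocardial slice(s), need %d",
                 length(myo), n_apical), call. = FALSE)
  utils::tail(myo, n_apical)
}

#' Apical left-ventricular mass
#'
#' Myocardial mass restricted to the slices chosen by
#' [select_apical_slices()].
#'
#' @inheritParams slice_region_mass
#' @param n_apical number of apical slices (default 4).
#' @return Apical mass in grams.
#' @export
apical_mass <- function(stack, n_apical = 4L,
                        slice_coverage = "thickness_plus_gap") {
  idx <- select_apical_slices(stack, n_apical)
  count <- sum(vapply(idx, function(i)
    sum(slice_labels(stack, i) == LABEL_LV_MYOCARDIUM), integer(1)))
  slice_region_mass(count, stack, slice_coverage)
}

# Pixel-centre angles (degrees in [0, 360)) of the TRUE entries of a mask
# about a continuous centre (row, col).
.pixel_angles <- function(mask_idx, center) {
  dr <- mask_idx[, 1] - center[1]
  dc <- mask_idx[, 2] - center[2]
  (atan2(dr, dc) * 180 / pi) %% 360
}

# 8-connected dilation of a logical matrix by one pixel.
.dilate8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  shift <- function(m, dr, dc) {
    res <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    res[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    res
  }
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out | shift(mask, dr, dc)
  out
}

#' Right-ventricular insertion angles of one slice
#'
#' Finds the myocardial pixels 8-adjacent to the RV cavity and returns the
#' endpoints of the smallest circular angular interval (about the LV
#' centroid, cavity plus myocardium) containing all of them. Angles follow
#' the (row, col)-plane convention of [phantom_spec()]. `NULL` when the
#' slice has no RV contact.
#'
#' @param slc 2-D integer label matrix.
#' @param on_degenerate behaviour when the contact interval spans at least
#'   180 degrees: raise an error (default) or return `NULL` with a warning.
#' @return `c(theta1, theta2)` in degrees with attribute `span_deg`, or
#'   `NULL`.
#' @export
rv_insertion_angles <- function(slc, on_degenerate = c("error", "drop")) {
  on_degenerate <- match.arg(on_degenerate)
  lv <- which(slc == LABEL_LV_CAVITY | slc == LABEL_LV_MYOCARDIUM, arr.ind = TRUE)
  if (nrow(lv) == 0L) return(NULL)
  rv <- slc == LABEL_RV_CAVITY
  if (!any(rv)) return(NULL)
  contact <- slc == LABEL_LV_MYOCARDIUM & .dilate8(rv)
  if (!any(contact)) return(NULL)
  center <- colMeans(lv)
  ang <- sort(.pixel_angles(which(contact, arr.ind = TRUE), center))
  m <- length(ang)
  if (m == 1L) {
    return(structure(c(ang, ang), span_deg = 0))
  }
  gaps <- c(diff(ang), ang[1] + 360 - ang[m])
  g <- which.max(gaps)
  span <- 360 - gaps[g]
  theta1 <- if (g == m) ang[1] else ang[g + 1L]
  theta2 <- ang[g]
  if (span >= 180) {
    msg <- sprintf("degenerate RV contact: interval spans %.1f degrees", span)
    if (on_degenerate == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    return(NULL)
  }
  structure(c(theta1, theta2), span_deg = span)
}

#' Septal pixels of one slice
#'
#' LV myocardium pixels whose centre angle about the LV centroid lies in the
#' closed circular interval `[theta1, theta2]` (going forward from `theta1`,
#' i.e. the RV side by construction of [rv_insertion_angles()]).
#'
#' @param slc 2-D integer label matrix.
#' @param angles `c(theta1, theta2)` from [rv_insertion_angles()].
#' @return Linear indices (into `slc`) of the septal pixels.
#' @export
septal_pixels <- function(slc, angles) {
  stopifnot(length(angles) == 2L)
  lv <- which(slc == LABEL_LV_CAVITY | slc == LABEL_LV_MYOCARDIUM, arr.ind = TRUE)
  myo_lin <- which(slc == LABEL_LV_MYOCARDIUM)
  if (length(myo_lin) == 0L) return(integer(0))
  center <- colMeans(lv)
  myo_idx <- which(slc == LABEL_LV_MYOCARDIUM, arr.ind = TRUE)
  theta <- .pixel_angles(myo_idx, center)
  span <- (angles[2] - angles[1]) %% 360
  eps <- 1e-9
  inside <- ((theta - angles[1]) %% 360) <= span + eps
  myo_lin[inside]
}

#' Septal left-ventricular mass
#'
#' Per slice, the insertion angles delimit the septum and its pixels are
#' converted to grams; slices with no RV contact contribute per
#' `no_contact`: nothing (default) or with the nearest contact-bearing
#' slice's angles. Slices with degenerate (>= 180 degree) contact are
#' excluded and counted.
#'
#' @inheritParams slice_region_mass
#' @param no_contact fallback for slices without RV contact.
#' @return Septal mass in grams, with attributes `n_septal_slices` (slices
#'   that contributed) and `n_degenerate` (slices dropped for degenerate
#'   contact).
#' @export
septal_mass <- function(stack, no_contact = c("zero", "nearest"),
                        slice_coverage = "thickness_plus_gap") {
  no_contact <- match.arg(no_contact)
  myo <- .myocardial_slices(stack)
  if (length(myo) == 0L) stop("no myocardial pixels in stack", call. = FALSE)
  angles <- vector("list", length(myo))
  degenerate <- logical(length(myo))
  for (j in seq_along(myo)) {
    a <- tryCatch(rv_insertion_angles(slice_labels(stack, myo[j])),
                  error = function(e) structure(list(), degenerate = TRUE))
    if (is.list(a) && isTRUE(attr(a, "degenerate"))) {
      degenerate[j] <- TRUE
    } else angles[j] <- list(a)
  }
  has <- which(!vapply(angles, is.null, logical(1)))
  if (length(has) == 0L)
    stop("no slice with RV contact: septum undefined", call. = FALSE)
  if (no_contact == "nearest") {
    for (j in seq_along(angles)) {
      if (is.null(angles[[j]]) && !degenerate[j]) {
        nearest <- has[which.min(abs(has - j))]
        angles[[j]] <- angles[[nearest]]
      }
    }
  }
  count <- 0L
  used <- 0L
  for (j in seq_along(myo)) {
    if (is.null(angles[[j]])) next
    px <- septal_pixels(slice_labels(stack, myo[j]), angles[[j]])
    count <- count + length(px)
    used <- used + 1L
  }
  structure(slice_region_mass(count, stack, slice_coverage),
            n_septal_slices = used, n_degenerate = sum(degenerate))
}

#' Quantify one subject
#'
#' Runs quality control, then total, apical, and septal mass. When QC fails
#' the record carries the failure reasons and `NA` masses; computation
#' errors on pathological anatomy are likewise captured, not raised.
#'
#' @param stack a [mask_stack].
#' @param criteria a [qc_criteria] object.
#' @param n_apical number of apical slices.
#' @param no_contact septal fallback, see [septal_mass()].
#' @param slice_coverage see [slice_region_mass()].
#' @return A list of class `regional_mass_record`.
#' @export
quantify_subject <- function(stack, criteria = qc_criteria(), n_apical = 4L,
                             no_contact = "zero",
                             slice_coverage = "thickness_plus_gap") {
  qc <- qc_stack(stack, criteria)
  rec <- list(subject_id = stack$subject_id,
              total_mass_g = NA_real_, apical_mass_g = NA_real_,
              septal_mass_g = NA_real_,
              n_slices_used = length(.myocardial_slices(stack)),
              n_septal_slices = NA_integer_,
              insertion_angles = NULL,
              qc_passed = qc$passed,
              qc_reasons = qc$reasons)
  if (qc$passed) {
    res <- tryCatch({
      tot <- total_lv_mass(stack, slice_coverage)
      ap <- apical_mass(stack, n_apical, slice_coverage)
      sep <- septal_mass(stack, no_contact, slice_coverage)
      myo <- .myocardial_slices(stack)
      ang <- lapply(myo, function(i)
        tryCatch(rv_insertion_angles(slice_labels(stack, i)),
                 error = function(e) NULL))
      list(tot = tot, ap = ap, sep = sep, ang = ang)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rec$qc_passed <- FALSE
      rec$qc_reasons <- conditionMessage(res)
    } else {
      rec$total_mass_g <- res$tot
      rec$apical_mass_g <- res$ap
      rec$septal_mass_g <- as.numeric(res$sep)
      rec$n_septal_slices <- attr(res$sep, "n_septal_slices")
      rec$insertion_angles <- res$ang
    }
  }
  structure(rec, class = "regional_mass_record")
}

#' @export
print.regional_mass_record <- function(x, ...) {
  cat(sprintf("%s: total %.2f g, apical %.2f g, septal %.2f g (QC %s)\n",
              x$subject_id, x$total_mass_g, x$apical_mass_g, x$septal_mass_g,
              if (x$qc_passed) "passed" else paste("failed:", paste(x$qc_reasons, collapse = ";"))))
  invisible(x)
}

#' Quantify a batch of stacks
#'
#' @param stacks list of [mask_stack] objects.
#' @param ... passed to [quantify_subject()].
#' @return A data frame, one row per stack in input order, with columns
#'   `subject_id`, `total_mass_g`, `apical_mass_g`, `septal_mass_g`,
#'   `n_slices_used`, `n_septal_slices`, `qc_passed`, `qc_reasons`.
#' @export
quantify_batch <- function(stacks, ...) {
  recs <- lapply(stacks, quantify_subject, ...)
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

#' Write a mass table as TSV
#' @param masses data frame from [quantify_batch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mass_table <- function(masses, path) {
  utils::write.table(masses, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
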