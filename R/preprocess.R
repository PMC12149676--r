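# Label cleanup and geometric standardization: shape-based interpolation of
# missing axial slices, connected-component filtering, rigid alignment of
# the pre- onto the mid-treatment grid, then resampling and cropping.

# signed distance of a 2D slice, voxel units; positive inside foreground
slice_sdf <- function(sl) {
  d <- c(dim(sl), 1L)
  din <- sqrt(pmin(edt_sq_cpp(as.logical(sl), d, c(1, 1, 1)), 1e12))
  dout <- sqrt(pmin(edt_sq_cpp(as.logical(!sl), d, c(1, 1, 1)), 1e12))
  matrix(dout - din, dim(sl)[1], dim(sl)[2])
}

#' Interpolate missing axial slices of a binary mask
#'
#' Interior gaps of at most `max_gap` consecutive empty axial (z) slices
#' flanked by non-empty slices are filled by shape-based interpolation:
#' the signed distance fields of the flanking slices are blended linearly
#' and thresholded at zero.  Slices outside the structure's axial extent are
#' untouched, and no existing foreground is ever removed.
#'
#' @param mask binary 3D array.
#' @param max_gap largest gap (slice count) that is filled; larger gaps are
#'   left as-is.
#' @return The filled mask with attribute `slices_filled`.
#' @export
interpolate_missing_slices <- function(mask, max_gap = 5L) {
  mask <- as.array(mask) >= 0.5
  nz <- dim(mask)[3]
  occ <- apply(mask, 3, any)
  filled <- 0L
  if (any(occ)) {
    zs <- which(occ)
    for (i in seq_len(length(zs) - 1)) {
      z1 <- zs[i]; z2 <- zs[i + 1]
      gap <- z2 - z1 - 1L
      if (gap < 1L || gap > max_gap) next
      s1 <- slice_sdf(mask[, , z1])
      s2 <- slice_sdf(mask[, , z2])
      for (z in (z1 + 1):(z2 - 1)) {
        a <- (z - z1) / (z2 - z1)
        mask[, , z] <- ((1 - a) * s1 + a * s2) > 0
        filled <- filled + 1L
      }
    }
  }
  attr(mask, "slices_filled") <- filled
  mask
}

#' Keep only the largest connected component of a mask
#'
#' 26-connectivity by default; ties are broken in favour of the component
#' containing the lowest-index voxel.
#'
#' @param mask binary 3D array.
#' @param connectivity 6, 18 or 26.
#' @return The filtered mask with attribute `voxels_removed`.
#' @export
remove_disconnected <- function(mask, connectivity = 26L) {
  mask <- as.array(mask) >= 0.5
  d <- dim(mask)
  lab <- label_components_cpp(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  n <- attr(lab, "n")
  if (n <= 1L) {
    attr(mask, "voxels_removed") <- 0L
    return(mask)
  }
  sizes <- tabulate(lab, nbins = n)
  keep <- which.max(sizes)  # first maximum = lowest-index component on ties
  out <- array(lab == keep, d)
  attr(out, "voxels_removed") <- as.integer(sum(mask) - sizes[keep])
  out
}

clean_structures <- function(ss, max_gap, connectivity) {
  rep_rows <- list()
  for (i in seq_along(ss$names)) {
    s <- ss$names[i]
    if (!ss$present[i]) {
      rep_rows[[s]] <- c(filled = 0L, removed = 0L)
      next
    }
    m <- interpolate_missing_slices(ss$masks[[s]], max_gap)
    f <- attr(m, "slices_filled")
    m <- remove_disconnected(m, connectivity)
    r <- attr(m, "voxels_removed")
    ss$masks[[s]] <- array(as.logical(m), dim(m))
    rep_rows[[s]] <- c(filled = f, removed = r)
  }
  list(ss = ss, report = rep_rows)
}

#' Standardize a patient case
#'
#' Applies the preprocessing chain in order: label cleanup (slice
#' interpolation then component filtering), rigid alignment of the
#' pre-treatment data onto the mid-treatment grid, resampling of both
#' timepoints to a common spacing, and cropping to a fixed physical extent.
#' Near-identity registrations (under 0.05 mm / 0.05 deg) are snapped to the
#' identity so the operation is idempotent on already-standard cases.
#'
#' @param case a [patient_case()].
#' @param spacing target voxel spacing, mm.
#' @param crop_extent physical extent of the output grid, mm; defaults to
#'   the mid-treatment extent.
#' @param crop_center world centre of the crop, mm; defaults to the
#'   mid-treatment grid centre.
#' @param align if `TRUE` (default), register pre to mid and warp the
#'   pre-treatment data onto the mid grid before resampling.
#' @param max_gap,connectivity label-cleanup parameters.
#' @param settings registration settings for the alignment step.
#' @return `list(case =, report =)`; the report records per-structure
#'   cleanup counts and the geometry applied.  The returned case carries the
#'   pre-to-mid transform as attribute `pre_to_mid`.
#' @export
standardize_case <- function(case, spacing = NULL, crop_extent = NULL,
                             crop_center = NULL, align = TRUE, max_gap = 5L,
                             connectivity = 26L,
                             settings = registration_settings()) {
  pre_cl <- clean_structures(case$pre$structures, max_gap, connectivity)
  mid_cl <- clean_structures(case$mid$structures, max_gap, connectivity)
  pre <- list(image = case$pre$image, structures = pre_cl$ss)
  mid <- list(image = case$mid$image, structures = mid_cl$ss)

  t_pm <- rigid_transform()
  if (align) {
    t_pm <- register_rigid(mid$image, pre$image, settings)
    if (max(abs(t_pm$translation)) < 0.05 && max(abs(t_pm$rotation)) < 0.05)
      t_pm <- rigid_transform(center = t_pm$center)  # snap to identity
    id <- all(t_pm$translation == 0) && all(t_pm$rotation == 0) &&
      same_grid(pre$image, mid$image)
    if (!id) {
      pre$image <- warp(pre$image, t_pm, mid$image)
      pre$structures <- warp(pre$structures, t_pm, mid$image)
    }
  }

  if (is.null(spacing)) spacing <- mid$image$spacing
  if (is.null(crop_extent)) crop_extent <- grid_dim(mid$image) * mid$image$spacing
  if (is.null(crop_center)) crop_center <- grid_center(mid$image)
  for (tp in c("pre", "mid")) {
    x <- get(tp)
    if (any(abs(x$image$spacing - spacing) > 1e-9)) {
      x$image <- resample(x$image, spacing)
      x$structures <- resample(x$structures, spacing)
    }
    x$image <- crop_to_region(x$image, crop_center, crop_extent)
    x$structures <- crop_to_region(x$structures, crop_center, crop_extent)
    assign(tp, x)
  }
  out <- patient_case(case$patient_id, pre, mid, case$interval_days)
  attr(out, "pre_to_mid") <- t_pm
  report <- data.frame(
    structure = rep(names(pre_cl$report), 2),
    timepoint = rep(c("pre", "mid"), each = length(pre_cl$report)),
    slices_filled = c(vapply(pre_cl$report, `[[`, 0L, "filled"),
                      vapply(mid_cl$report, `[[`, 0L, "filled")),
    voxels_removed = c(vapply(pre_cl$report, `[[`, 0L, "removed"),
                       vapply(mid_cl$report, `[[`, 0L, "removed")))
  attr(report, "spacing") <- spacing
  attr(report, "crop_extent") <- crop_extent
  attr(report, "crop_center") <- crop_center
  list(case = out, report = report)
}

#' Standardize every case of a cohort
#'
#' @param cohort named list of [patient_case()] objects.
#' @param ... passed to [standardize_case()].
#' @return `list(cases =, reports =)`.
#' @export
standardize_cohort <- function(cohort, ...) {
  if (!is.null(cohort$cases)) cohort <- cohort$cases
  out <- lapply(cohort, standardize_case, ...)
  list(cases = lapply(out, `[[`, "case"),
       reports = lapply(out, `[[`, "report"))
}
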