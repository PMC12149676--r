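# Core spatial types and geometry: volumes with physical spacing/origin,
# resampling, cropping and NIfTI I/O.  World coordinates are voxel-centre
# based: x_world = origin + spacing * index (0-based), axes fixed to the
# canonical right-handed (RAS) convention.

#' Create an image volume
#'
#' A 3D scalar grid with physical geometry.  Intensities are in
#' Hounsfield-like arbitrary units for CT-analog images.
#'
#' @param voxels 3D numeric array.
#' @param spacing length-3 numeric, mm per voxel along each axis; all > 0.
#' @param origin length-3 numeric, world position (mm) of voxel (0,0,0).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    stop("`voxels` must be a 3D array with positive dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  if (any(!is.finite(voxels)))
    stop("all intensities must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Create a structure set
#'
#' Named binary masks sharing one grid, with explicit per-structure presence
#' flags.  A structure with `present = FALSE` carries an all-zero mask and is
#' excluded from losses and metrics downstream.
#'
#' @param masks named list of 3D logical/numeric arrays on a shared grid.
#' @param spacing,origin grid geometry, as for [image_volume()].
#' @param present named logical; defaults to `TRUE` for every mask.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing, origin = c(0, 0, 0), present = NULL) {
  if (length(masks) == 0 || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a non-empty named list")
  masks <- lapply(masks, function(m) {
    m <- as.array(m)
    if (is.numeric(m)) {
      if (any(!is.finite(m))) stop("mask values must be finite")
      m <- array(m >= 0.5, dim = dim(m))
    }
    storage.mode(m) <- "logical"
    m
  })
  d <- dim(masks[[1]])
  if (length(d) != 3L) stop("masks must be 3D arrays")
  for (m in masks) if (!identical(dim(m), d)) stop("all masks must share the grid shape")
  if (is.null(present)) present <- setNames(rep(TRUE, length(masks)), names(masks))
  present <- present[names(masks)]
  if (any(is.na(present))) stop("`present` must cover every structure")
  for (s in names(masks)) if (!present[[s]]) masks[[s]][] <- FALSE
  structure(list(masks = masks, present = as.logical(present),
                 names = names(masks), spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "structure_set")
}

#' Create a patient case
#'
#' One patient's paired pre- and mid-treatment data.  Each timepoint is a
#' list with elements `image` ([image_volume]) and `structures`
#' ([structure_set]); the two grids may differ before preprocessing and are
#' identical after [standardize_case()].
#'
#' @param patient_id character scalar.
#' @param pre,mid per-timepoint `list(image =, structures =)`.
#' @param interval_days integer >= 0, metadata only.
#' @export
patient_case <- function(patient_id, pre, mid, interval_days = 0L) {
  for (tp in list(pre, mid)) {
    stopifnot(inherits(tp$image, "image_volume"),
              inherits(tp$structures, "structure_set"))
    if (!same_grid(tp$image, tp$structures))
      stop("image and structure grids differ within one timepoint")
  }
  if (interval_days < 0) stop("`interval_days` must be >= 0")
  structure(list(patient_id = as.character(patient_id), pre = pre, mid = mid,
                 interval_days = as.integer(interval_days)),
            class = "patient_case")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures on %s grid: %s\n",
              length(x$masks), paste(dim(x$masks[[1]]), collapse = "x"),
              paste(sprintf("%s%s", x$names, ifelse(x$present, "", " [absent]")),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s (interval %d days)\n", x$patient_id,
              x$interval_days))
  print(x$pre$image)
  invisible(x)
}

grid_dim <- function(v) {
  if (inherits(v, "image_volume")) dim(v$voxels) else dim(v$masks[[1]])
}

grid_center <- function(v) v$origin + v$spacing * (grid_dim(v) - 1) / 2

#' Test whether two volumes share one grid
#' @param a,b `image_volume` or `structure_set` objects.
#' @param tol geometric tolerance in mm.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# low-level resample of one array between two grids under an optional rigid
# map (rot/trans/center in world mm); mode "linear" or "nearest"
resample_array <- function(arr, spacing, origin, tdim, tspacing, torigin,
                           rot = diag(3), trans = c(0, 0, 0),
                           center = c(0, 0, 0), mode = "linear",
                           background = 0) {
  out <- resample_affine_cpp(as.numeric(arr), as.integer(dim(arr)),
                             as.numeric(spacing), as.numeric(origin),
                             as.integer(tdim), as.numeric(tspacing),
                             as.numeric(torigin), rot, as.numeric(trans),
                             as.numeric(center),
                             if (mode == "linear") 1L else 0L,
                             as.numeric(background))
  array(out, dim = tdim)
}

#' Resample a volume to a new voxel spacing
#'
#' The output grid spans the same physical extent (within one voxel) and is
#' centred on the input grid.  Images are interpolated linearly, masks by
#' nearest neighbour so they remain strictly binary.
#'
#' @param v an `image_volume` or `structure_set`.
#' @param target_spacing length-3 numeric, mm; all > 0.
#' @param mode interpolation for images, `"linear"` (default) or `"nearest"`.
#' @return An object of the same class as `v` on the new grid.
#' @export
resample <- function(v, target_spacing, mode = "linear") UseMethod("resample")

resampled_grid <- function(v, target_spacing) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("`target_spacing` must be 3 positive values")
  d <- grid_dim(v)
  extent <- d * v$spacing
  ndim <- pmax(1L, as.integer(round(extent / target_spacing)))
  ctr <- grid_center(v)
  norigin <- ctr - target_spacing * (ndim - 1) / 2
  list(dim = ndim, spacing = target_spacing, origin = norigin)
}

#' @export
resample.image_volume <- function(v, target_spacing, mode = "linear") {
  g <- resampled_grid(v, target_spacing)
  bg <- min(v$voxels)
  image_volume(resample_array(v$voxels, v$spacing, v$origin, g$dim, g$spacing,
                              g$origin, mode = mode, background = bg),
               g$spacing, g$origin)
}

#' @export
resample.structure_set <- function(v, target_spacing, mode = "nearest") {
  g <- resampled_grid(v, target_spacing)
  masks <- lapply(v$masks, function(m)
    resample_array(m, v$spacing, v$origin, g$dim, g$spacing, g$origin,
                   mode = "nearest", background = 0) > 0.5)
  structure_set(masks, g$spacing, g$origin, present = setNames(v$present, v$names))
}

#' Crop (or pad) a volume to a physical region
#'
#' The output grid has the requested physical extent rounded to whole voxels
#' at the input spacing, centred on `center_mm`.  Voxels outside the input
#' field of view are filled with a background value: by default the input
#' minimum for images (a CT air analog) and 0 for masks.
#'
#' @param v an `image_volume` or `structure_set`.
#' @param center_mm,extent_mm length-3 numeric, world mm.
#' @param background optional numeric fill for images.
#' @export
crop_to_region <- function(v, center_mm, extent_mm, background = NULL)
  UseMethod("crop_to_region")

crop_grid <- function(v, center_mm, extent_mm) {
  center_mm <- as.numeric(center_mm); extent_mm <- as.numeric(extent_mm)
  if (any(extent_mm <= 0)) stop("`extent_mm` must be positive")
  ndim <- pmax(1L, as.integer(round(extent_mm / v$spacing)))
  norigin <- center_mm - v$spacing * (ndim - 1) / 2
  # overlap check in world space (voxel-centre bounds)
  lo <- pmax(norigin, v$origin)
  hi <- pmin(norigin + v$spacing * (ndim - 1),
             v$origin + v$spacing * (grid_dim(v) - 1))
  if (any(lo > hi)) stop("requested region does not overlap the volume")
  list(dim = ndim, spacing = v$spacing, origin = norigin)
}

#' @export
crop_to_region.image_volume <- function(v, center_mm, extent_mm, background = NULL) {
  g <- crop_grid(v, center_mm, extent_mm)
  bg <- if (is.null(background)) min(v$voxels) else background
  image_volume(resample_array(v$voxels, v$spacing, v$origin, g$dim, g$spacing,
                              g$origin, mode = "linear", background = bg),
               g$spacing, g$origin)
}

#' @export
crop_to_region.structure_set <- function(v, center_mm, extent_mm, background = NULL) {
  g <- crop_grid(v, center_mm, extent_mm)
  masks <- lapply(v$masks, function(m)
    resample_array(m, v$spacing, v$origin, g$dim, g$spacing, g$origin,
                   mode = "nearest", background = 0) > 0.5)
  structure_set(masks, g$spacing, g$origin, present = setNames(v$present, v$names))
}

# ---- NIfTI I/O ---------------------------------------------------------

nifti_xform <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  m
}

write_nifti_vol <- function(arr, spacing, origin, file) {
  img <- RNifti::asNifti(arr * 1)
  RNifti::sform(img) <- structure(nifti_xform(spacing, origin), code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

read_nifti_vol <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  img <- RNifti::readNifti(file)
  # reorient to the canonical right-handed convention before reading geometry
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  dirs <- sweep(rot, 2, spacing, "/")
  if (max(abs(dirs - diag(3))) > 1e-3)
    stop("oblique NIfTI orientations are not supported: ", file)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])  # plain array, no header attrs
  list(voxels = arr, spacing = as.numeric(spacing), origin = as.numeric(xf[1:3, 4]))
}

#' Write one patient case as NIfTI files
#'
#' Writes `<id>_<tp>_image.nii.gz` and one `<id>_<tp>_label_<structure>.nii.gz`
#' per present structure, and returns the manifest entry describing them.
#'
#' @param case a [patient_case()].
#' @param dir output directory, created if needed.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entry <- list(patient_id = case$patient_id,
                interval_days = case$interval_days)
  for (tp in c("pre", "mid")) {
    t <- case[[tp]]
    imgf <- file.path(dir, sprintf("%s_%s_image.nii.gz", case$patient_id, tp))
    write_nifti_vol(t$image$voxels, t$image$spacing, t$image$origin, imgf)
    labels <- list()
    ss <- t$structures
    for (i in seq_along(ss$names)) {
      s <- ss$names[i]
      if (!ss$present[i]) { labels[[s]] <- NA; next }
      lf <- file.path(dir, sprintf("%s_%s_label_%s.nii.gz", case$patient_id, tp, s))
      write_nifti_vol(ss$masks[[s]], ss$spacing, ss$origin, lf)
      labels[[s]] <- basename(lf)
    }
    entry[[tp]] <- list(image = basename(imgf), labels = labels)
  }
  entry
}

#' Read one patient case from NIfTI files
#'
#' @param entry a manifest entry as produced by [write_case()]:
#'   `list(patient_id, interval_days, pre = list(image, labels), mid = ...)`,
#'   with label entries `NA` for structures missing at that timepoint.
#' @param dir directory holding the files.
#' @param structures character vector fixing the structure order for the
#'   cohort; defaults to the order in the entry.
#' @return A [patient_case()]. Label volumes are binarized at 0.5.
#' @export
read_case <- function(entry, dir, structures = NULL) {
  if (is.null(structures)) structures <- names(entry$pre$labels)
  tps <- lapply(c(pre = "pre", mid = "mid"), function(tp) {
    t <- entry[[tp]]
    iv <- read_nifti_vol(file.path(dir, t$image))
    img <- image_volume(iv$voxels, iv$spacing, iv$origin)
    masks <- list()
    present <- logical(length(structures))
    names(present) <- structures
    for (s in structures) {
      lf <- t$labels[[s]]
      if (is.null(lf) || length(lf) != 1 || is.na(lf)) {
        masks[[s]] <- array(FALSE, dim(iv$voxels))
      } else {
        lv <- read_nifti_vol(file.path(dir, lf))
        if (!identical(dim(lv$voxels), dim(iv$voxels)) ||
            any(abs(lv$spacing - iv$spacing) > 1e-4) ||
            any(abs(lv$origin - iv$origin) > 1e-3))
          stop("label geometry differs from image geometry: ", lf)
        masks[[s]] <- lv$voxels >= 0.5
        present[s] <- TRUE
      }
    }
    list(image = img,
         structures = structure_set(masks, iv$spacing, iv$origin, present))
  })
  patient_case(entry$patient_id, tps$pre, tps$mid,
               interval_days = entry$interval_days %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort with its JSON manifest
#'
#' @param cohort list of [patient_case()] objects.
#' @param dir output directory.
#' @param extra named list merged into the manifest (e.g. phantom ground
#'   truth transforms).
#' @export
write_cohort <- function(cohort, dir, extra = list()) {
  entries <- lapply(cohort, write_case, dir = dir)
  manifest <- c(list(structures = cohort[[1]]$pre$structures$names,
                     patients = entries), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory holding `manifest.json` and the NIfTI files.
#' @export
read_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structures <- unlist(mf$structures)
  cases <- lapply(mf$patients, read_case, dir = dir, structures = structures)
  names(cases) <- vapply(cases, function(c) c$patient_id, "")
  attr(cases, "manifest") <- mf
  cases
}
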