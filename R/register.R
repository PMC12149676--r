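# Rigid transforms, mutual information, multi-resolution rigid registration
# and the RIR contour-propagation baseline.
#
# A rigid transform maps fixed-frame world points into the moving frame:
#   y = R (x - center) + center + translation
# so warp(moving, t, fixed_grid) pulls moving-image values onto the fixed
# grid.  Rotations are ZYX Euler angles in degrees: R = Rz Ry Rx.

euler_to_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
  ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
  rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

matrix_to_euler <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  g <- atan2(R[2, 1], R[1, 1])
  c(a, b, g) * 180 / pi
}

#' Create a rigid transform
#'
#' @param rotation length-3 Euler angles in degrees (ZYX convention).
#' @param translation length-3, mm.
#' @param center length-3 rotation centre, mm (world).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (%s) deg, trans (%s) mm, center (%s) mm\n",
              paste(sprintf("%.3f", x$rotation), collapse = ", "),
              paste(sprintf("%.3f", x$translation), collapse = ", "),
              paste(sprintf("%.1f", x$center), collapse = ", ")))
  invisible(x)
}

#' Apply a rigid transform to world points
#' @param t a [rigid_transform()].
#' @param pts 3 x n matrix (or length-3 vector) of world coordinates, mm.
#' @export
rigid_apply <- function(t, pts) {
  pts <- if (is.matrix(pts)) pts else matrix(pts, nrow = 3)
  R <- euler_to_matrix(t$rotation)
  R %*% (pts - t$center) + t$center + t$translation
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @export
rigid_invert <- function(t) {
  R <- euler_to_matrix(t$rotation)
  rigid_transform(matrix_to_euler(t(R)),
                  as.numeric(-t(R) %*% t$translation), t$center)
}

#' Registration settings
#'
#' Multi-resolution pyramid (downsampling factors 4, 2, 1) with Gaussian
#' pre-smoothing, a mutual-information metric, and per-level gradient-based
#' optimization (L-BFGS on numeric gradients, with a derivative-free polish
#' at full resolution, which is robust in the shallow rotation valley of a
#' sampled metric).  All stochastic sampling is seeded.
#'
#' @param pyramid downsampling factors, positive and non-increasing.
#' @param bins histogram bin count for mutual information.
#' @param learning_rate nominal step length (deg / mm); retained in the
#'   settings for interface completeness, the quasi-Newton driver derives
#'   its own step sizes.
#' @param iterations maximum optimizer iterations per pyramid level.
#' @param sampling fraction of fixed voxels sampled for the metric.
#' @param rot_scale relative scaling of rotation (deg) vs translation (mm)
#'   parameters in the optimizer.
#' @param seed integer seed for metric sampling.
#' @export
registration_settings <- function(pyramid = c(4, 2, 1), bins = 50,
                                  learning_rate = 1, iterations = 200,
                                  sampling = 0.1, rot_scale = 1, seed = 0L) {
  pyramid <- as.numeric(pyramid)
  if (any(pyramid <= 0) || any(diff(pyramid) > 0))
    stop("pyramid factors must be positive and non-increasing")
  list(pyramid = pyramid, bins = as.integer(bins),
       learning_rate = learning_rate, iterations = as.integer(iterations),
       sampling = sampling, rot_scale = rot_scale, seed = as.integer(seed))
}

bin_index <- function(x, lo, bw, nbins) {
  b <- floor((x - lo) / bw)
  pmin(pmax(b, 0), nbins - 1)
}

#' Mutual information between two images on one grid
#'
#' Equal-width joint histogram estimate, in nats.  For an image against
#' itself this equals the entropy of its histogram.  A constant image has
#' zero entropy; the MI is defined as 0 with a warning.
#'
#' @param a,b `image_volume` objects on the same grid.
#' @param bins histogram bins per image.
#' @export
mutual_information <- function(a, b, bins = 50) {
  if (!same_grid(a, b)) stop("mutual_information requires equal grids")
  av <- as.numeric(a$voxels); bv <- as.numeric(b$voxels)
  if (diff(range(av)) == 0 || diff(range(bv)) == 0) {
    warning("constant image: mutual information defined as 0")
    return(0)
  }
  nb <- as.integer(bins)
  ba <- bin_index(av, min(av), diff(range(av)) / nb * (1 + 1e-9), nb)
  bb <- bin_index(bv, min(bv), diff(range(bv)) / nb * (1 + 1e-9), nb)
  joint <- tabulate(ba * nb + bb + 1L, nbins = nb * nb) / length(av)
  pa <- tabulate(ba + 1L, nbins = nb) / length(av)
  pb <- tabulate(bb + 1L, nbins = nb) / length(bv)
  pij <- joint[joint > 0]
  idx <- which(joint > 0) - 1L
  sum(pij * log(pij / (pa[idx %/% nb + 1L] * pb[idx %% nb + 1L])))
}

# separable binomial (approximate Gaussian) smoothing, edge-replicated;
# reps passes of the (1,2,1)/4 kernel per axis.  Suppresses the noise-
# interpolation bias of intensity-based metrics, and acts as the pyramid
# anti-aliasing filter before downsampling.
smooth_volume <- function(v, reps = 1) {
  a <- v$voxels
  d <- dim(a)
  for (r in seq_len(reps)) {
    for (ax in 1:3) {
      n <- d[ax]
      if (n < 3) next
      lo <- c(1, seq_len(n - 1))
      hi <- c(seq_len(n - 1) + 1, n)
      a <- switch(ax,
                  (a[lo, , , drop = FALSE] + 2 * a + a[hi, , , drop = FALSE]) / 4,
                  (a[, lo, , drop = FALSE] + 2 * a + a[, hi, , drop = FALSE]) / 4,
                  (a[, , lo, drop = FALSE] + 2 * a + a[, , hi, drop = FALSE]) / 4)
    }
  }
  image_volume(a, v$spacing, v$origin)
}

# negative MI objective at transform parameters theta = (rot deg, trans mm)
neg_mi_at <- function(theta, center, samp) {
  -mi_transform_cpp(samp$fixed_bins, samp$pts, samp$mov, samp$mdim,
                    samp$mspacing, samp$morigin, euler_to_matrix(theta[1:3]),
                    theta[4:6], center, samp$nbins, samp$mmin, samp$mbw)
}

prepare_mi_samples <- function(fixed, moving, bins, sampling, seed) {
  fv <- as.numeric(fixed$voxels)
  d <- dim(fixed$voxels)
  n <- length(fv)
  idx <- seq_len(n)
  nsamp <- max(1000L, as.integer(round(n * sampling)))
  if (nsamp < n) {
    rs <- local_rng(seed, sample.int(n, nsamp))
    idx <- sort(rs)
  }
  i0 <- idx - 1L
  vx <- i0 %% d[1]
  vy <- (i0 %/% d[1]) %% d[2]
  vz <- i0 %/% (d[1] * d[2])
  pts <- rbind(fixed$origin[1] + fixed$spacing[1] * vx,
               fixed$origin[2] + fixed$spacing[2] * vy,
               fixed$origin[3] + fixed$spacing[3] * vz)
  fs <- fv[idx]
  frange <- range(fs)
  if (diff(frange) == 0) stop("constant fixed image: cannot register")
  mrange <- range(moving$voxels)
  if (diff(mrange) == 0) stop("constant moving image: cannot register")
  list(fixed_bins = as.integer(bin_index(fs, frange[1],
                                         diff(frange) / bins * (1 + 1e-9), bins)),
       pts = pts, mov = as.numeric(moving$voxels), mdim = dim(moving$voxels),
       mspacing = moving$spacing, morigin = moving$origin, nbins = bins,
       mmin = mrange[1], mbw = diff(mrange) / bins * (1 + 1e-9))
}

# run an expression with a private RNG stream
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Rigid registration of a moving onto a fixed image
#'
#' Multi-resolution (coarse-to-fine) maximization of mutual information
#' with a normalized gradient-descent optimizer using central-difference
#' gradients and step halving.  Deterministic given the settings seed.
#'
#' @param fixed,moving `image_volume` objects with overlapping fields of view.
#' @param settings a [registration_settings()] list.
#' @return A [rigid_transform()] mapping fixed-frame points into the moving
#'   frame (i.e. `warp(moving, t, fixed)` aligns moving onto fixed), with
#'   attributes `mi` (final metric) and `trace` (per-level iteration counts).
#' @export
register_rigid <- function(fixed, moving, settings = registration_settings()) {
  center <- grid_center(fixed)
  theta <- rep(0, 6)
  scales <- c(rep(settings$rot_scale, 3), rep(1, 3))
  trace <- list()
  for (li in seq_along(settings$pyramid)) {
    f <- settings$pyramid[li]
    reps <- max(1L, as.integer(round(f / 2)))
    fx <- smooth_volume(fixed, reps)
    mv <- smooth_volume(moving, reps)
    if (f > 1) {
      fx <- resample(fx, fixed$spacing * f)
      mv <- resample(mv, moving$spacing * f)
    }
    frac <- if (f > 1) 1 else settings$sampling
    samp <- prepare_mi_samples(fx, mv, settings$bins, frac,
                               settings$seed + li)
    o <- stats::optim(theta, neg_mi_at, center = center, samp = samp,
                      method = "L-BFGS-B",
                      control = list(maxit = settings$iterations,
                                     ndeps = rep(0.1, 6) * f * scales,
                                     factr = 1e4))
    theta <- o$par
    best <- o$value
    iters <- o$counts[["function"]]
    # small pure rotations produce texture-induced local optima near the
    # identity; a grid search over rotation offsets keeps the refinement
    # inside the global basin
    grid <- as.matrix(expand.grid(d1 = c(-5, -2.5, 0, 2.5, 5),
                                  d2 = c(-5, -2.5, 0, 2.5, 5),
                                  d3 = c(-5, -2.5, 0, 2.5, 5)))
    vals <- apply(grid, 1, function(dr)
      neg_mi_at(theta + c(dr, 0, 0, 0), center, samp))
    iters <- iters + nrow(grid)
    if (min(vals) < best) {
      theta2 <- theta + c(grid[which.min(vals), ], 0, 0, 0)
      o2 <- stats::optim(theta2, neg_mi_at, center = center, samp = samp,
                         method = "L-BFGS-B",
                         control = list(maxit = settings$iterations,
                                        ndeps = rep(0.1, 6) * f * scales,
                                        factr = 1e4))
      iters <- iters + o2$counts[["function"]]
      if (o2$value < best) { theta <- o2$par; best <- o2$value }
    }
    if (f <= 1) {
      # derivative-free polish: the quasi-Newton step stalls in the
      # shallow rotation valley of the sampled metric
      o <- stats::optim(theta, neg_mi_at, center = center, samp = samp,
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-9,
                                       parscale = scales))
      theta <- o$par
      best <- o$value
      iters <- iters + o$counts[["function"]]
    }
    trace[[li]] <- c(factor = f, evaluations = iters, neg_mi = best)
  }
  if (!is.finite(best)) stop("registration diverged: non-finite metric")
  out <- rigid_transform(theta[1:3], theta[4:6], center)
  attr(out, "mi") <- -best
  attr(out, "trace") <- do.call(rbind, trace)
  out
}

#' Warp a volume through a rigid transform
#'
#' Pulls values from `v` at transformed target-grid points: images are
#' linearly interpolated, structure masks use nearest neighbour and remain
#' binary.
#'
#' @param v an `image_volume` or `structure_set` (the moving data).
#' @param t a [rigid_transform()] mapping target-frame points into `v`'s frame.
#' @param target_grid an object carrying the output grid (defaults to `v`).
#' @export
warp <- function(v, t, target_grid = NULL) UseMethod("warp")

target_of <- function(v, target_grid) {
  g <- if (is.null(target_grid)) v else target_grid
  list(dim = grid_dim(g), spacing = g$spacing, origin = g$origin)
}

#' @export
warp.image_volume <- function(v, t, target_grid = NULL) {
  g <- target_of(v, target_grid)
  R <- euler_to_matrix(t$rotation)
  image_volume(resample_array(v$voxels, v$spacing, v$origin, g$dim, g$spacing,
                              g$origin, rot = R, trans = t$translation,
                              center = t$center, mode = "linear",
                              background = min(v$voxels)),
               g$spacing, g$origin)
}

#' @export
warp.structure_set <- function(v, t, target_grid = NULL) {
  g <- target_of(v, target_grid)
  R <- euler_to_matrix(t$rotation)
  masks <- lapply(v$masks, function(m)
    resample_array(m, v$spacing, v$origin, g$dim, g$spacing, g$origin,
                   rot = R, trans = t$translation, center = t$center,
                   mode = "nearest", background = 0) > 0.5)
  structure_set(masks, g$spacing, g$origin, present = setNames(v$present, v$names))
}

#' Serialize / deserialize a rigid transform as JSON
#' @param t a [rigid_transform()].
#' @param file path.
#' @export
write_transform <- function(t, file) {
  jsonlite::write_json(list(rotation_deg = t$rotation,
                            translation_mm = t$translation,
                            center_mm = t$center,
                            convention = "euler-zyx; y = R(x-c)+c+t"),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_transform
#' @export
read_transform <- function(file) {
  j <- jsonlite::read_json(file)
  rigid_transform(unlist(j$rotation_deg), unlist(j$translation_mm),
                  unlist(j$center_mm))
}

#' RIR baseline: propagate pre-treatment contours by rigid registration
#'
#' Registers the pre-treatment image to the mid-treatment image and warps
#' all present pre-treatment masks onto the mid grid.  Structures missing at
#' pre-treatment are marked absent in the prediction.
#'
#' @param case a [patient_case()].
#' @param settings a [registration_settings()] list.
#' @return A `structure_set` of predicted mid-treatment labels with
#'   attribute `transform`.
#' @export
rir_segment <- function(case, settings = registration_settings()) {
  t <- register_rigid(case$mid$image, case$pre$image, settings)
  pred <- warp(case$pre$structures, t, case$mid$image)
  attr(pred, "transform") <- t
  pred
}
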