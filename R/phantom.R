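# Synthetic paired-timepoint phantom cohorts.
#
# Each patient is a smooth "head" background plus ellipsoidal structures
# with per-patient jitter.  The mid-treatment timepoint is the pre-treatment
# anatomy under (a) a global rigid transform, (b) a smooth random local
# deformation applied to deformable structures, (c) tumor shrinkage, and
# (d) independently resampled additive noise.  Shapes are evaluated
# analytically at both timepoints, so labels follow their structures exactly
# and the sampled rigid transform is exact ground truth for rigid-role
# structures.

#' Specify one phantom structure
#'
#' @param name structure name.
#' @param role `"organ"` or `"tumor"`; tumor structures shrink between
#'   timepoints.
#' @param rigidity `"rigid"` (follows only the global rigid offset) or
#'   `"deformable"` (additionally displaced by the local deformation field).
#' @param center_mm offset of the structure centre from the grid centre, mm.
#' @param radius_mm length-3 ellipsoid radii, mm; all > 0.
#' @param radius_sd fractional between-patient variability of the radii.
#' @param contrast intensity offset from background tissue (HU-like a.u.);
#'   low-contrast structures are hard to see, high-contrast easy.
#' @param position_sd_mm between-patient positional variability, mm.
#' @param missing_prob probability a label is missing per timepoint, in
#'   `[0, 1]`.
#' @export
structure_spec <- function(name, role = c("organ", "tumor"),
                           rigidity = c("deformable", "rigid"),
                           center_mm = c(0, 0, 0), radius_mm = c(10, 10, 10),
                           radius_sd = 0.1, contrast = 100,
                           position_sd_mm = 3, missing_prob = 0) {
  role <- match.arg(role)
  rigidity <- match.arg(rigidity)
  if (any(radius_mm <= 0)) stop("radius_mm must be positive")
  if (!is.finite(contrast)) stop("contrast must be finite")
  if (missing_prob < 0 || missing_prob > 1) stop("missing_prob must be in [0,1]")
  structure(list(name = name, role = role, rigidity = rigidity,
                 center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm), radius_sd = radius_sd,
                 contrast = contrast, position_sd_mm = position_sd_mm,
                 missing_prob = missing_prob),
            class = "structure_spec")
}

#' Default desk-scale structure set
#'
#' Three structures capturing the contrast/variability regimes of a head and
#' neck cohort: a high-contrast rigid "bone" (mandible/vertebra analog), a
#' low-contrast deformable "plexus" (brachial-plexus/spinal-cord analog) and
#' a high-variability shrinking "tumor" (GTVp analog).
#' @export
default_structures <- function() {
  list(structure_spec("bone", role = "organ", rigidity = "rigid",
                      center_mm = c(0, -10, 0), radius_mm = c(11, 11, 20),
                      radius_sd = 0.05, contrast = 700, position_sd_mm = 2,
                      missing_prob = 0.05),
       structure_spec("plexus", role = "organ", rigidity = "deformable",
                      center_mm = c(14, 8, 0), radius_mm = c(5, 5, 14),
                      radius_sd = 0.08, contrast = 80, position_sd_mm = 3,
                      missing_prob = 0.15),
       # the GTVp analog is barely visible: its CT contrast is of the order
       # of the noise and soft-tissue texture (poor tumor-tissue contrast
       # is why MR is recommended for primary-tumor delineation), and its
       # position varies strongly across patients, which is what defeats
       # models without access to prior patient data
       structure_spec("tumor", role = "tumor", rigidity = "deformable",
                      center_mm = c(-12, 8, 0), radius_mm = c(10, 10, 10),
                      radius_sd = 0.2, contrast = 30, position_sd_mm = 12,
                      missing_prob = 0))
}

#' Phantom cohort configuration
#'
#' @param n_patients number of patients.
#' @param grid_shape length-3 voxel grid.
#' @param spacing voxel spacing, mm.
#' @param structures list of [structure_spec()]; at least one `role = "tumor"`.
#' @param translation_mm,rotation_deg half-ranges of the global rigid offset
#'   between timepoints (sampled uniformly per patient).
#' @param deform_amplitude_mm standard deviation of the smooth local
#'   deformation applied to deformable structures, mm.
#' @param deform_grid control-grid resolution of the band-limited
#'   deformation field.
#' @param shrinkage_range tumor volume ratio mid/pre, sampled uniformly;
#'   values in (0, 1].
#' @param noise_sd additive intensity noise, a.u.
#' @param seed integer; the whole cohort is deterministic given the seed.
#' @export
phantom_config <- function(n_patients = 20, grid_shape = c(48, 48, 48),
                           spacing = c(2, 2, 2),
                           structures = default_structures(),
                           translation_mm = 5, rotation_deg = 3,
                           deform_amplitude_mm = 3, deform_grid = 6,
                           shrinkage_range = c(0.4, 0.8), noise_sd = 20,
                           seed = 1L) {
  if (!any(vapply(structures, function(s) s$role == "tumor", TRUE)))
    stop("at least one structure must have role = \"tumor\"")
  if (any(shrinkage_range <= 0) || any(shrinkage_range > 1))
    stop("shrinkage fractions must be in (0, 1]")
  probs <- vapply(structures, function(s) s$missing_prob, 1)
  if (any(probs < 0 | probs > 1)) stop("missing probabilities must be in [0,1]")
  structure(list(n_patients = as.integer(n_patients),
                 grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing), structures = structures,
                 translation_mm = translation_mm, rotation_deg = rotation_deg,
                 deform_amplitude_mm = deform_amplitude_mm,
                 deform_grid = as.integer(deform_grid),
                 shrinkage_range = as.numeric(shrinkage_range),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# world coordinates of every voxel, as a 3 x V matrix
grid_coords <- function(dim, spacing, origin) {
  ix <- seq_len(dim[1]) - 1
  iy <- seq_len(dim[2]) - 1
  iz <- seq_len(dim[3]) - 1
  rbind(rep(origin[1] + spacing[1] * ix, times = dim[2] * dim[3]),
        rep(rep(origin[2] + spacing[2] * iy, each = dim[1]), times = dim[3]),
        rep(origin[3] + spacing[3] * iz, each = dim[1] * dim[2]))
}

# squared ellipsoid implicit at points (3 x V), with orientation Q
ellipsoid_q <- function(pts, center, radii, Q = NULL) {
  p <- pts - center
  if (!is.null(Q)) p <- t(Q) %*% p
  (p[1, ] / radii[1])^2 + (p[2, ] / radii[2])^2 + (p[3, ] / radii[3])^2
}

# band-limited random displacement field: coarse iid Gaussian control grid,
# trilinearly upsampled; returns V x 3 matrix of mm displacements
smooth_field <- function(dim, spacing, origin, amplitude, ngrid) {
  V <- prod(dim)
  if (amplitude == 0) return(matrix(0, V, 3))
  ext <- dim * spacing
  corigin <- origin - spacing / 2
  cspacing <- ext / (ngrid - 1)
  out <- matrix(0, V, 3)
  for (a in 1:3) {
    coarse <- array(rnorm(ngrid^3, sd = amplitude), rep(ngrid, 3))
    out[, a] <- resample_affine_cpp(as.numeric(coarse), rep(ngrid, 3L),
                                    cspacing, corigin, as.integer(dim),
                                    as.numeric(spacing), as.numeric(origin),
                                    diag(3), c(0, 0, 0), c(0, 0, 0), 1L, 0)
  }
  out
}

#' Generate a synthetic paired-timepoint cohort
#'
#' @param cfg a [phantom_config()].
#' @return A list with `cases` (named list of [patient_case()]) and
#'   `manifest` (structure names, per-patient ground-truth rigid transforms
#'   pre-to-mid, shrinkage fractions and presence flags).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  local_rng(cfg$seed, {
    d <- cfg$grid_shape
    sp <- cfg$spacing
    origin <- c(0, 0, 0)
    ctr <- origin + sp * (d - 1) / 2
    ext <- d * sp
    pts <- grid_coords(d, sp, origin)
    # anisotropic head with a bright skull shell: the sharp, asymmetric
    # bone surface anchors intensity-based rotation recovery, as in real
    # head CT
    head_r <- c(0.38, 0.42, 0.45) * ext
    snames <- vapply(cfg$structures, function(s) s$name, "")
    cases <- list()
    meta <- list()
    for (i in seq_len(cfg$n_patients)) {
      pid <- sprintf("P%03d", i)
      # per-patient shape sampling
      shapes <- lapply(cfg$structures, function(s) {
        # per-patient jitter, truncated to shapes that fit in the grid
        for (attempt in 1:50) {
          centre <- ctr + s$center_mm + rnorm(3, sd = s$position_sd_mm)
          radii <- s$radius_mm * pmax(0.3, 1 + rnorm(1, sd = s$radius_sd))
          if (all(centre - radii >= origin) &&
              all(centre + radii <= origin + sp * (d - 1)))
            return(list(spec = s, center = centre, radii = radii))
        }
        stop("structure '", s$name, "' does not fit in the grid")
      })
      # inter-timepoint changes
      rig <- rigid_transform(runif(3, -cfg$rotation_deg, cfg$rotation_deg),
                             runif(3, -cfg$translation_mm, cfg$translation_mm),
                             ctr)
      shrink <- runif(1, cfg$shrinkage_range[1], cfg$shrinkage_range[2])
      disp <- smooth_field(d, sp, origin, cfg$deform_amplitude_mm,
                           cfg$deform_grid)
      present <- matrix(runif(2 * length(shapes)), nrow = 2) >=
        matrix(rep(vapply(shapes, function(sh) sh$spec$missing_prob, 1),
                   each = 2), nrow = 2)
      # soft-tissue heterogeneity: a handful of randomly oriented plane
      # waves at anatomical length scales; gives the images enough
      # structure for intensity-based registration, like real CT
      tex_dir <- matrix(rnorm(3 * 5), 3)
      tex_dir <- sweep(tex_dir, 2, sqrt(colSums(tex_dir^2)), "/")
      tex_lambda <- c(16, 22, 30, 40, 56)
      tex_amp <- c(10, 12, 12, 15, 18)
      tex_phase <- runif(5, 0, 2 * pi)

      render <- function(timepoint) {
        # pre-frame evaluation points: identity for pre; for mid, undo the
        # rigid motion (and local deformation for deformable structures)
        if (timepoint == "pre") {
          p_rigid <- pts
          p_deform <- pts
        } else {
          inv <- rigid_invert(rig)
          p_rigid <- rigid_apply(inv, pts)
          p_deform <- rigid_apply(inv, pts + t(disp))
        }
        qh <- ellipsoid_q(p_rigid, ctr, head_r)
        img <- ifelse(qh <= 1, 40, -1000)
        img <- img + ifelse(qh <= 1 & qh >= 0.78, 750, 0)  # skull shell
        tex <- 0
        for (j in 1:5)
          tex <- tex + tex_amp[j] *
            sin(2 * pi * crossprod(tex_dir[, j], p_rigid)[1, ] / tex_lambda[j] +
                tex_phase[j])
        img <- img + ifelse(qh <= 1, tex, 0)
        masks <- list()
        for (j in seq_along(shapes)) {
          sh <- shapes[[j]]
          radii <- sh$radii
          if (timepoint == "mid" && sh$spec$role == "tumor")
            radii <- radii * shrink^(1 / 3)
          p <- if (timepoint == "mid" && sh$spec$rigidity == "deformable")
            p_deform else p_rigid
          q <- ellipsoid_q(p, sh$center, radii)
          img <- img + sh$spec$contrast * pmin(1, pmax(0, (1.2 - q) / 0.4))
          masks[[sh$spec$name]] <- array(q <= 1, d)
        }
        img <- img + rnorm(length(img), sd = cfg$noise_sd)
        ti <- if (timepoint == "pre") 1 else 2
        pr <- setNames(present[ti, ], snames)
        list(image = image_volume(array(img, d), sp, origin),
             structures = structure_set(masks, sp, origin, present = pr))
      }

      cases[[pid]] <- patient_case(pid, render("pre"), render("mid"),
                                   interval_days = round(runif(1, 14, 79)))
      meta[[pid]] <- list(transform_pre_to_mid = list(rotation_deg = rig$rotation,
                                                      translation_mm = rig$translation,
                                                      center_mm = rig$center),
                          shrinkage = shrink,
                          present_pre = as.list(setNames(present[1, ], snames)),
                          present_mid = as.list(setNames(present[2, ], snames)))
    }
    list(cases = cases,
         manifest = list(structures = snames, patients = meta,
                         seed = cfg$seed))
  })
}

#' Summarize a cohort: label counts and mean volumes
#'
#' Mirrors the style of a dataset descriptor table: per structure, counts of
#' present labels split by timepoint, and mean volumes in cm^3 (voxel count
#' times voxel volume, over present masks).
#'
#' @param cohort list of [patient_case()] objects (or the `cases` element of
#'   [generate_cohort()] output).
#' @return A data.frame with one row per structure.
#' @export
cohort_summary <- function(cohort) {
  if (!is.null(cohort$cases)) cohort <- cohort$cases
  if (length(cohort) == 0) stop("empty cohort")
  snames <- cohort[[1]]$pre$structures$names
  rows <- lapply(snames, function(s) {
    vols <- list(pre = c(), mid = c())
    for (case in cohort) {
      for (tp in c("pre", "mid")) {
        ss <- case[[tp]]$structures
        i <- match(s, ss$names)
        if (ss$present[i]) {
          vv <- prod(ss$spacing) / 1000  # mm^3 -> cm^3
          vols[[tp]] <- c(vols[[tp]], sum(ss$masks[[s]]) * vv)
        }
      }
    }
    data.frame(structure = s, n_pre = length(vols$pre), n_mid = length(vols$mid),
               n_total = length(vols$pre) + length(vols$mid),
               mean_volume_pre_cm3 = if (length(vols$pre)) mean(vols$pre) else NA_real_,
               mean_volume_mid_cm3 = if (length(vols$mid)) mean(vols$mid) else NA_real_)
  })
  do.call(rbind, rows)
}
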