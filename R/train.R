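# Training: cross-validation fold plans, the three regime's training-set
# construction (RM / PSM / GAM with time-order reversal), the hybrid
# dice + focal loss with class and volume weighting, spatial augmentation,
# and the training loop (Adam, best-validation model selection).

#' Patient-level k-fold plan
#'
#' Patients are split into k equally sized (+/- 1) folds; run r uses fold r
#' as the test set and draws its validation patients from the remaining
#' patients.  No patient's images ever straddle roles within a run.
#'
#' @param patient_ids character vector.
#' @param k number of folds (>= 2).
#' @param val_size validation patients per run: a count (>= 1) or a
#'   fraction of the non-test patients (< 1; default 0.2).
#' @param seed integer; the plan is deterministic given the seed.
#' @return An object of class `fold_plan` with elements `k`, `folds`,
#'   `runs` (per run: `train`, `validation`, `test`) and `seed`.
#' @export
make_fold_plan <- function(patient_ids, k, val_size = 0.2, seed = 1L) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("more folds than patients")
  local_rng(seed, {
    ids <- sample(patient_ids)
    folds <- lapply(seq_len(k), function(i) sort(ids[seq(i, n, by = k)]))
    runs <- lapply(seq_len(k), function(r) {
      test <- folds[[r]]
      rest <- sample(setdiff(patient_ids, test))
      nv <- if (val_size < 1) max(1L, round(val_size * length(rest)))
            else as.integer(val_size)
      if (nv >= length(rest)) stop("val_size leaves no training patients")
      list(train = sort(rest[-seq_len(nv)]),
           validation = sort(rest[seq_len(nv)]), test = test)
    })
    structure(list(k = as.integer(k), folds = folds, runs = runs,
                   patient_ids = patient_ids, seed = as.integer(seed)),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d patients in %d folds (%s per fold); run 1: %d train / %d validation / %d test\n",
              length(x$patient_ids), x$k,
              paste(unique(lengths(x$folds)), collapse = "/"),
              length(x$runs[[1]]$train), length(x$runs[[1]]$validation),
              length(x$runs[[1]]$test)))
  invisible(x)
}

#' Construct the training-sample list for a regime
#'
#' RM trains on all pre- and mid-treatment images of every non-test patient
#' (one sample per image).  PSM additionally pools the test patients'
#' pre-treatment images, removing an equal number of other samples (seeded
#' uniform choice) so counts match RM.  GAM builds one paired sample per
#' non-test patient (prior pre -> target mid) plus its time-reversed twin,
#' doubling the sample count.  No regime ever sees a test patient's
#' mid-treatment data; violation is a hard error.
#'
#' @param plan a [make_fold_plan()].
#' @param run run index, 1..k.
#' @param regime `"RM"`, `"PSM"` or `"GAM"`.
#' @param mode `"paper"` (default): non-test = training + validation
#'   patients, matching the published sample counts; `"strict"`: samples
#'   from the training split only, validation patients held out entirely.
#' @return data.frame with columns `patient_id`, `target_tp`, `prior_tp`
#'   (NA for single-channel regimes), `reversed`, `from_test_pre`.
#' @export
build_training_samples <- function(plan, run, regime = c("RM", "PSM", "GAM"),
                                   mode = c("paper", "strict")) {
  regime <- match.arg(regime)
  mode <- match.arg(mode)
  r <- plan$runs[[run]]
  pool <- if (mode == "paper") c(r$train, r$validation) else r$train
  pool <- sort(pool)
  samples <- switch(regime,
    RM = data.frame(patient_id = rep(pool, each = 2),
                    target_tp = rep(c("pre", "mid"), length(pool)),
                    prior_tp = NA_character_, reversed = FALSE,
                    from_test_pre = FALSE),
    PSM = {
      base <- data.frame(patient_id = rep(pool, each = 2),
                         target_tp = rep(c("pre", "mid"), length(pool)),
                         prior_tp = NA_character_, reversed = FALSE,
                         from_test_pre = FALSE)
      extra <- data.frame(patient_id = r$test, target_tp = "pre",
                          prior_tp = NA_character_, reversed = FALSE,
                          from_test_pre = TRUE)
      drop <- local_rng(plan$seed + 1000L * run,
                        sample.int(nrow(base), length(r$test)))
      rbind(base[-drop, ], extra)
    },
    GAM = rbind(data.frame(patient_id = pool, target_tp = "mid",
                           prior_tp = "pre", reversed = FALSE,
                           from_test_pre = FALSE),
                data.frame(patient_id = pool, target_tp = "pre",
                           prior_tp = "mid", reversed = TRUE,
                           from_test_pre = FALSE)))
  rownames(samples) <- NULL
  assert_no_leakage(samples, plan, run)
  attr(samples, "regime") <- regime
  attr(samples, "run") <- run
  samples
}

#' Assert that no test-patient mid-treatment data enters training
#'
#' @param samples a [build_training_samples()] data.frame.
#' @param plan,run the fold plan and run the samples were built for.
#' @export
assert_no_leakage <- function(samples, plan, run) {
  test <- plan$runs[[run]]$test
  bad <- samples$patient_id %in% test &
    (samples$target_tp == "mid" |
       (!is.na(samples$prior_tp) & samples$prior_tp == "mid"))
  if (any(bad))
    stop("data leakage: test-patient mid-treatment data in training samples")
  invisible(TRUE)
}

as_channel_matrix <- function(x) {
  if (is.list(x)) x <- simplify2array(x)
  d <- dim(x)
  if (is.null(d) || length(d) == 1) return(matrix(x, nrow = 1))
  if (length(d) == 2) return(x)            # already S x V
  if (length(d) == 3) return(matrix(x, nrow = 1))
  flatten_channels(x)
}

#' Soft dice loss
#'
#' Per present structure: `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)`,
#' aggregated as a weighted mean over present structures.  Absent
#' structures contribute nothing.
#'
#' @param pred,target probabilities and binary targets: vectors, `S x V`
#'   matrices, or `(x,y,z,S)` arrays.
#' @param present logical length-S (default all present).
#' @param weights per-structure weights (default equal).
#' @param eps numerical smoothing.
#' @return Scalar loss with attribute `per_structure`.
#' @export
dice_loss <- function(pred, target, present = NULL, weights = NULL,
                      eps = 1e-6) {
  p <- as_channel_matrix(pred)
  t <- as_channel_matrix(target)
  stopifnot(all(dim(p) == dim(t)))
  S <- nrow(p)
  if (is.null(present)) present <- rep(TRUE, S)
  if (is.null(weights)) weights <- rep(1, S)
  per <- numeric(S)
  for (s in seq_len(S))
    per[s] <- if (present[s])
      1 - (2 * sum(p[s, ] * t[s, ]) + eps) / (sum(p[s, ]) + sum(t[s, ]) + eps)
    else NA_real_
  w <- weights * present
  out <- sum(w[present] * per[present]) / max(sum(w[present]), .Machine$double.eps)
  attr(out, "per_structure") <- per
  out
}

#' Focal loss
#'
#' Mean over voxels of `-(1 - p_t)^gamma log(p_t)` with
#' `p_t = p` where the target is 1 and `1 - p` elsewhere; `gamma = 0`
#' reduces to binary cross-entropy.  Aggregation as in [dice_loss()].
#'
#' @inheritParams dice_loss
#' @param gamma focusing parameter (>= 0).
#' @export
focal_loss <- function(pred, target, gamma = 2, present = NULL,
                       weights = NULL) {
  p <- as_channel_matrix(pred)
  t <- as_channel_matrix(target)
  stopifnot(all(dim(p) == dim(t)))
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  S <- nrow(p)
  if (is.null(present)) present <- rep(TRUE, S)
  if (is.null(weights)) weights <- rep(1, S)
  per <- numeric(S)
  for (s in seq_len(S)) {
    if (!present[s]) { per[s] <- NA_real_; next }
    pt <- ifelse(t[s, ] > 0.5, p[s, ], 1 - p[s, ])
    per[s] <- mean(-(1 - pt)^gamma * log(pt))
  }
  w <- weights * present
  out <- sum(w[present] * per[present]) / max(sum(w[present]), .Machine$double.eps)
  attr(out, "per_structure") <- per
  out
}

#' Inverse-frequency class weights
#'
#' Weights proportional to the inverse of the fraction of training samples
#' in which each structure is present, normalized to mean 1.  A structure
#' present in no sample is excluded from training (weight 0) with a warning.
#'
#' @param present_matrix logical samples x structures matrix (named columns).
#' @export
class_weights <- function(present_matrix) {
  freq <- colMeans(present_matrix)
  w <- ifelse(freq > 0, 1 / pmax(freq, .Machine$double.eps), 0)
  if (any(freq == 0))
    warning("structures never present in training, excluded: ",
            paste(colnames(present_matrix)[freq == 0], collapse = ", "))
  live <- freq > 0
  w[live] <- w[live] / mean(w[live])
  w
}

#' Inverse-volume structure weights
#'
#' Proportional to the inverse of the mean structure volume over the
#' training split, normalized to mean 1.  These counteract the extreme
#' volume imbalance between large and small structures.
#'
#' @param mean_volumes named numeric, cm^3.
#' @export
volume_weights <- function(mean_volumes) {
  u <- 1 / mean_volumes
  u / mean(u[is.finite(u)])
}

#' Volume-weight schedule
#'
#' The volume weights are applied only for the first `t_max` training
#' epochs (epochs counted from 0); afterwards all multipliers are 1.
#'
#' @param epoch 0-based epoch.
#' @param u per-structure volume weights.
#' @param t_max epoch bound (default 200).
#' @export
volume_weight_schedule <- function(epoch, u, t_max = 200L) {
  if (epoch < t_max) u else setNames(rep(1, length(u)), names(u))
}

#' Loss configuration
#'
#' @param dice_weight,focal_weight mix weights of the hybrid loss.
#' @param gamma focal focusing parameter.
#' @param epochs training epochs.
#' @param volume_epochs epochs during which inverse-volume weights apply.
#' @param learning_rate Adam learning rate.
#' @param eps dice smoothing.
#' @export
loss_config <- function(dice_weight = 1, focal_weight = 1, gamma = 2,
                        epochs = 1000L, volume_epochs = 200L,
                        learning_rate = 0.001, eps = 1e-6) {
  if (volume_epochs > epochs) stop("volume_epochs must be <= epochs")
  list(dice_weight = dice_weight, focal_weight = focal_weight, gamma = gamma,
       epochs = as.integer(epochs), volume_epochs = as.integer(volume_epochs),
       learning_rate = learning_rate, eps = eps)
}

#' Augmentation configuration
#'
#' One random spatial transform (translation, rotation, isotropic scale) is
#' sampled per call and applied identically to every channel of a sample:
#' linear interpolation for image channels, nearest neighbour for labels.
#'
#' @param translation_mm half-range of the random translation (default 50).
#' @param rotation_deg half-range of the random rotation (default 5).
#' @param scale scaling range (default 0.8-1.2).
#' @param seed optional integer; if set, [augment()] is deterministic.
#' @export
augment_config <- function(translation_mm = 50, rotation_deg = 5,
                           scale = c(0.8, 1.2), seed = NULL) {
  list(translation_mm = translation_mm, rotation_deg = rotation_deg,
       scale = as.numeric(scale), seed = seed)
}

#' Apply one random spatial augmentation to a sample
#'
#' @param sample list with `input` array `(x,y,z,C)`, `target` array
#'   `(x,y,z,S)`, `input_modes` (character, `"linear"`/`"nearest"` per input
#'   channel) and `spacing` (mm).
#' @param cfg an [augment_config()].
#' @return The sample with transformed `input` and `target`.
#' @export
augment <- function(sample, cfg) {
  draw <- function() list(tr = runif(3, -cfg$translation_mm, cfg$translation_mm),
                          rot = runif(3, -cfg$rotation_deg, cfg$rotation_deg),
                          sc = runif(1, cfg$scale[1], cfg$scale[2]))
  par <- if (is.null(cfg$seed)) draw() else local_rng(cfg$seed, draw())
  if (all(par$tr == 0) && all(par$rot == 0) && par$sc == 1) return(sample)
  d <- dim(sample$input)[1:3]
  sp <- sample$spacing
  origin <- c(0, 0, 0)
  ctr <- origin + sp * (d - 1) / 2
  R <- euler_to_matrix(par$rot) / par$sc
  tfm_one <- function(arr, mode) {
    bg <- if (mode == "linear") min(arr) else 0
    array(resample_affine_cpp(as.numeric(arr), as.integer(d), sp, origin,
                              as.integer(d), sp, origin, R, par$tr, ctr,
                              if (mode == "linear") 1L else 0L, bg), d)
  }
  for (c in seq_len(dim(sample$input)[4]))
    sample$input[, , , c] <- tfm_one(sample$input[, , , c],
                                     sample$input_modes[c])
  for (s in seq_len(dim(sample$target)[4]))
    sample$target[, , , s] <- tfm_one(sample$target[, , , s], "nearest")
  sample
}

#' Normalize CT-analog intensities
#'
#' Clips to the CT analog range and scales linearly to `[0, 1]`; bounded
#' inputs stabilize small-scale training.
#'
#' @param x numeric array.
#' @param clip length-2 intensity window (default -1024..3071).
#' @export
intensity_normalize <- function(x, clip = c(-1024, 3071)) {
  (pmin(pmax(x, clip[1]), clip[2]) - clip[1]) / diff(clip)
}

# assemble one sample as flat channel matrices (C x V input, S x V target,
# voxels in x-then-y-then-z order); cohort cases must be standardized
# (shared, aligned grids)
assemble_sample <- function(case, row, structures, regime) {
  tgt <- case[[row$target_tp]]
  d <- grid_dim(tgt$image)
  V <- prod(d)
  S <- length(structures)
  target <- matrix(0, S, V)
  for (i in seq_len(S))
    target[i, ] <- as.numeric(tgt$structures$masks[[structures[i]]])
  present <- as.integer(tgt$structures$present)
  if (regime == "GAM") {
    pri <- case[[row$prior_tp]]
    input <- matrix(0, 2 + S, V)
    input[1, ] <- intensity_normalize(as.numeric(tgt$image$voxels))
    input[2, ] <- intensity_normalize(as.numeric(pri$image$voxels))
    for (i in seq_len(S))
      input[2 + i, ] <- as.numeric(pri$structures$masks[[structures[i]]])
    modes <- c("linear", "linear", rep("nearest", S))
  } else {
    input <- matrix(intensity_normalize(as.numeric(tgt$image$voxels)), 1, V)
    modes <- "linear"
  }
  list(input = input, target = target, present = present,
       input_modes = modes, spacing = tgt$image$spacing, dims = d,
       patient_id = row$patient_id, target_tp = row$target_tp)
}

# flat-sample version of augment(); same transform model, rows in place
augment_flat <- function(sample, cfg) {
  par <- list(tr = runif(3, -cfg$translation_mm, cfg$translation_mm),
              rot = runif(3, -cfg$rotation_deg, cfg$rotation_deg),
              sc = runif(1, cfg$scale[1], cfg$scale[2]))
  if (all(par$tr == 0) && all(par$rot == 0) && par$sc == 1) return(sample)
  d <- sample$dims
  sp <- sample$spacing
  ctr <- sp * (d - 1) / 2
  R <- euler_to_matrix(par$rot) / par$sc
  warp_row <- function(v, mode) {
    bg <- if (mode == "linear") min(v) else 0
    resample_affine_cpp(v, as.integer(d), sp, c(0, 0, 0), as.integer(d), sp,
                        c(0, 0, 0), R, par$tr, ctr,
                        if (mode == "linear") 1L else 0L, bg)
  }
  for (c in seq_len(nrow(sample$input)))
    sample$input[c, ] <- warp_row(sample$input[c, ], sample$input_modes[c])
  for (s in seq_len(nrow(sample$target)))
    sample$target[s, ] <- warp_row(sample$target[s, ], "nearest")
  sample
}

sample_volumes_cm3 <- function(samples_built, structures) {
  vols <- matrix(NA_real_, length(samples_built), length(structures))
  for (i in seq_along(samples_built)) {
    sm <- samples_built[[i]]
    vv <- prod(sm$spacing) / 1000
    for (s in seq_along(structures))
      if (sm$present[s] == 1L) vols[i, s] <- sum(sm$target[s, ]) * vv
  }
  setNames(colMeans(vols, na.rm = TRUE), structures)
}

#' Train a segmentation model
#'
#' Fits the 3D U-Net for one cross-validation run of one regime with the
#' hybrid dice + focal loss (inverse-frequency class weights throughout,
#' inverse-volume weights for the first `volume_epochs` epochs), Adam
#' updates, per-sample spatial augmentation, and selection of the epoch
#' with the best mean validation DSC.
#'
#' @param cohort named list of standardized [patient_case()] objects (see
#'   [standardize_cohort()]); all grids identical, pre aligned to mid.
#' @param plan a [make_fold_plan()].
#' @param run run index, 1..k.
#' @param regime `"RM"`, `"PSM"` or `"GAM"`.
#' @param width base U-Net width.
#' @param loss_cfg a [loss_config()].
#' @param augment_cfg an [augment_config()] (`NULL` disables augmentation).
#' @param mode sample-construction mode, see [build_training_samples()].
#' @param seed seed controlling weight init, sample order and augmentation.
#' @param verbose print per-epoch progress.
#' @return An object of class `adaptseg_model`: the trained network (best
#'   validation epoch), the full per-epoch validation DSC trace per
#'   structure, the loss history, and the weighting/bookkeeping used.
#' @export
train_model <- function(cohort, plan, run, regime = c("RM", "PSM", "GAM"),
                        width = 8L, loss_cfg = loss_config(),
                        augment_cfg = augment_config(), mode = "paper",
                        seed = 1L, verbose = FALSE) {
  regime <- match.arg(regime)
  if (!is.null(cohort$cases)) cohort <- cohort$cases
  structures <- cohort[[1]]$pre$structures$names
  S <- length(structures)
  d <- grid_dim(cohort[[1]]$pre$image)
  rows <- build_training_samples(plan, run, regime, mode)
  train_built <- lapply(seq_len(nrow(rows)), function(i)
    assemble_sample(cohort[[rows$patient_id[i]]], rows[i, ], structures, regime))

  # validation samples: same construction, validation patients, no augment
  vpat <- plan$runs[[run]]$validation
  vrows <- if (regime == "GAM")
    data.frame(patient_id = vpat, target_tp = "mid", prior_tp = "pre")
  else
    data.frame(patient_id = rep(vpat, each = 2),
               target_tp = rep(c("pre", "mid"), length(vpat)),
               prior_tp = NA_character_)
  val_built <- lapply(seq_len(nrow(vrows)), function(i)
    assemble_sample(cohort[[vrows$patient_id[i]]], vrows[i, ], structures, regime))

  presence <- do.call(rbind, lapply(train_built, function(s) s$present == 1L))
  colnames(presence) <- structures
  wclass <- class_weights(presence)
  excluded <- wclass == 0
  uvol <- volume_weights(sample_volumes_cm3(train_built, structures))
  uvol[!is.finite(uvol)] <- 1

  spec <- model_spec(structures, regime, width)
  net <- build_model(spec, d, seed = seed)
  m <- numeric(net$n_params)
  v <- numeric(net$n_params)
  tstep <- 0L
  n_epochs <- loss_cfg$epochs
  loss_hist <- matrix(NA_real_, n_epochs, 3,
                      dimnames = list(NULL, c("total", "dice", "focal")))
  val_trace <- matrix(NA_real_, n_epochs, S, dimnames = list(NULL, structures))
  best <- list(score = -Inf, par = net$par, epoch = NA_integer_)
  val_flat <- val_built

  local_rng(seed + 1L, {
    for (epoch in seq_len(n_epochs) - 1L) {
      u_eff <- volume_weight_schedule(epoch, uvol, loss_cfg$volume_epochs)
      w_eff <- wclass * u_eff
      ep_loss <- c(0, 0, 0)
      for (i in sample(length(train_built))) {
        fs <- train_built[[i]]
        if (!is.null(augment_cfg)) fs <- augment_flat(fs, augment_cfg)
        pres <- fs$present
        pres[excluded] <- 0L
        tstep <- tstep + 1L
        res <- unet_run_cpp(net$par, S, width, d, fs$input, fs$target,
                            as.integer(pres), w_eff,
                            lambda_d = loss_cfg$dice_weight,
                            lambda_f = loss_cfg$focal_weight,
                            gamma_f = loss_cfg$gamma, eps = loss_cfg$eps,
                            want_grad = TRUE)
        if (!is.finite(res$loss))
          stop(sprintf("non-finite loss at epoch %d, sample %s/%s",
                       epoch, fs$patient_id, fs$target_tp))
        adam_step_cpp(net$par, res$grad, m, v, tstep,
                      lr = loss_cfg$learning_rate)
        ep_loss <- ep_loss + c(res$loss, res$dice_loss, res$focal_loss)
      }
      loss_hist[epoch + 1L, ] <- ep_loss / length(train_built)
      # validation DSC per structure
      vd <- matrix(NA_real_, length(val_flat), S)
      for (j in seq_along(val_flat)) {
        fs <- val_flat[[j]]
        pr <- unet_run_cpp(net$par, S, width, d, fs$input, want_probs = TRUE)$probs
        for (s in seq_len(S))
          if (fs$present[s] == 1L)
            vd[j, s] <- dsc_vec(pr[s, ] >= 0.5, fs$target[s, ] >= 0.5)
      }
      val_trace[epoch + 1L, ] <- colMeans(vd, na.rm = TRUE)
      score <- mean(val_trace[epoch + 1L, ], na.rm = TRUE)
      if (is.finite(score) && score > best$score)
        best <- list(score = score, par = net$par, epoch = epoch + 1L)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val DSC %.3f", epoch,
                        loss_hist[epoch + 1L, 1], score))
    }
  })
  net$par <- best$par
  structure(list(net = net, regime = regime, structures = structures,
                 plan = plan, run = run, mode = mode,
                 samples = rows, val_trace = val_trace,
                 loss_history = loss_hist, best_epoch = best$epoch,
                 best_val_dsc = best$score, class_weights = wclass,
                 volume_weights = uvol, loss_cfg = loss_cfg,
                 augment_cfg = augment_cfg, seed = seed),
            class = "adaptseg_model")
}

# build the inference input for a standardized case
model_input <- function(case, regime, structures) {
  d <- grid_dim(case$mid$image)
  if (regime == "GAM") {
    S <- length(structures)
    input <- array(0, c(d, 2 + S))
    input[, , , 1] <- intensity_normalize(case$mid$image$voxels)
    input[, , , 2] <- intensity_normalize(case$pre$image$voxels)
    for (i in seq_len(S))
      input[, , , 2 + i] <- case$pre$structures$masks[[structures[i]]]
    input
  } else {
    array(intensity_normalize(case$mid$image$voxels), c(d, 1))
  }
}

#' Predict mid-treatment structures for a case
#'
#' @param object a trained `adaptseg_model`.
#' @param newdata a standardized [patient_case()] (pre aligned to mid for
#'   the GAM).
#' @param threshold binarization threshold (default 0.5).
#' @param ... unused.
#' @return A `structure_set` of predicted masks on the mid grid, with the
#'   probability array as attribute `probs`.
#' @export
predict.adaptseg_model <- function(object, newdata, threshold = 0.5, ...) {
  case <- newdata
  input <- model_input(case, object$regime, object$structures)
  probs <- unet_predict(object$net, input)
  g <- case$mid$image
  masks <- list()
  for (i in seq_along(object$structures))
    masks[[object$structures[i]]] <- probs[, , , i] >= threshold
  out <- structure_set(masks, g$spacing, g$origin)
  attr(out, "probs") <- probs
  out
}

#' @export
print.adaptseg_model <- function(x, ...) {
  cat(sprintf("<adaptseg_model> %s regime, run %d/%d (%d training samples)\n",
              x$regime, x$run, x$plan$k, nrow(x$samples)))
  print(x$net)
  cat(sprintf("  best epoch %s, mean validation DSC %.3f\n",
              x$best_epoch, x$best_val_dsc))
  invisible(x)
}

#' @export
summary.adaptseg_model <- function(object, tau = 0.01, ...) {
  tr <- object$val_trace
  best <- tr[object$best_epoch, ]
  out <- data.frame(structure = object$structures,
                    class_weight = as.numeric(object$class_weights),
                    volume_weight = as.numeric(object$volume_weights),
                    best_val_dsc = as.numeric(best),
                    max_val_dsc = apply(tr, 2, max, na.rm = TRUE))
  out$converged <- out$max_val_dsc > tau
  cat(sprintf("Regime %s, run %d: %d epochs, best epoch %d\n", object$regime,
              object$run, nrow(tr), object$best_epoch))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
plot.adaptseg_model <- function(x, ...) {
  tr <- x$val_trace
  matplot(seq_len(nrow(tr)) - 1L, tr, type = "l", lty = 1,
          xlab = "epoch", ylab = "validation DSC",
          main = sprintf("%s (run %d)", x$regime, x$run), ...)
  abline(v = x$best_epoch - 1L, lty = 3)
  legend("bottomright", legend = colnames(tr), lty = 1,
         col = seq_len(ncol(tr)), bty = "n")
  invisible(x)
}
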