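test_that("fold plans partition patients with the published split sizes", {
  ids <- sprintf("P%03d", 1:110)
  plan <- make_fold_plan(ids, k = 5, val_size = 18, seed = 1)
  expect_equal(lengths(plan$folds), rep(22L, 5))
  all_test <- unlist(lapply(plan$runs, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0L)
  for (r in plan$runs) {
    expect_equal(length(r$train), 70L)
    expect_equal(length(r$validation), 18L)
    expect_equal(length(r$test), 22L)
    expect_equal(anyDuplicated(c(r$train, r$validation, r$test)), 0L)
  }
  # deterministic given seed
  expect_identical(plan, make_fold_plan(ids, 5, 18, seed = 1))
  expect_false(identical(plan$folds, make_fold_plan(ids, 5, 18, seed = 2)$folds))
  expect_error(make_fold_plan(ids[1:3], k = 5), "folds")
})

test_that("regime sample construction reproduces the published counts", {
  ids <- sprintf("P%03d", 1:110)
  plan <- make_fold_plan(ids, k = 5, val_size = 18, seed = 1)
  rm <- build_training_samples(plan, 1, "RM")
  psm <- build_training_samples(plan, 1, "PSM")
  gam <- build_training_samples(plan, 1, "GAM")
  expect_equal(nrow(rm), 176L)
  expect_equal(nrow(psm), 176L)           # count matched to RM
  expect_equal(sum(psm$from_test_pre), 22L)
  expect_true(all(psm$target_tp[psm$from_test_pre] == "pre"))
  expect_equal(nrow(gam), 176L)           # 88 forward + 88 time-reversed
  expect_equal(sum(gam$reversed), 88L)
  expect_setequal(gam$prior_tp, c("pre", "mid"))
  # strict mode: training split only
  expect_equal(nrow(build_training_samples(plan, 1, "RM", mode = "strict")), 140L)
})

test_that("no regime ever uses test-patient mid-treatment data", {
  ids <- sprintf("P%02d", 1:20)
  plan <- make_fold_plan(ids, k = 4, val_size = 3, seed = 2)
  for (run in 1:4)
    for (regime in c("RM", "PSM", "GAM")) {
      s <- build_training_samples(plan, run, regime)
      test <- plan$runs[[run]]$test
      bad <- s$patient_id %in% test &
        (s$target_tp == "mid" | (!is.na(s$prior_tp) & s$prior_tp == "mid"))
      expect_equal(sum(bad), 0L)
      expect_true(assert_no_leakage(s, plan, run))
    }
  # a poisoned sample list is rejected
  s <- build_training_samples(plan, 1, "RM")
  s$patient_id[1] <- plan$runs[[1]]$test[1]
  s$target_tp[1] <- "mid"
  expect_error(assert_no_leakage(s, plan, 1), "leakage")
})

test_that("dice loss matches closed-form hand evaluations", {
  # uniform 0.5 prediction over 1000 voxels, 100 foreground:
  # 1 - (2 * 50) / (500 + 100) = 0.8333...
  p <- rep(0.5, 1000)
  t <- c(rep(1, 100), rep(0, 900))
  expect_equal(as.numeric(dice_loss(p, t)), 1 - 100 / 600, tolerance = 1e-5)
  # perfect and inverted predictions
  expect_lt(as.numeric(dice_loss(t, t)), 1e-5)
  expect_gt(as.numeric(dice_loss(1 - t, t)), 0.999)
  # absent structures contribute nothing
  pm <- rbind(p, p); tm <- rbind(t, 1 - t)
  l <- dice_loss(pm, tm, present = c(TRUE, FALSE))
  expect_equal(as.numeric(l), 1 - 100 / 600, tolerance = 1e-5)
  expect_true(is.na(attr(l, "per_structure")[2]))
})

test_that("focal loss reduces to cross-entropy at gamma 0 and matches hand values", {
  set.seed(21)
  p <- runif(200, 0.05, 0.95)
  t <- as.numeric(runif(200) > 0.7)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(as.numeric(focal_loss(p, t, gamma = 0)), bce, tolerance = 1e-9)
  # single voxel, p = 0.6, target 1, gamma 2: 0.16 * (-ln 0.6)
  expect_equal(as.numeric(focal_loss(0.6, 1, gamma = 2)), 0.16 * -log(0.6),
               tolerance = 1e-9)
  expect_lt(as.numeric(focal_loss(t * 0.999999 + 5e-7, t)), 1e-9)
})

test_that("R loss references agree with the C++ training loss", {
  s <- tiny_net_setup(seed = 77)
  w <- c(1.3, 0.7)
  r <- adaptseg:::unet_run_cpp(s$par, s$S, s$w, s$d, s$input, s$target,
                               rep(1L, s$S), w, 1, 1, 2, 1e-6, FALSE, TRUE)
  dl <- dice_loss(r$probs, s$target, weights = w)
  fl <- focal_loss(r$probs, s$target, gamma = 2, weights = w)
  expect_equal(r$dice_loss, as.numeric(dl), tolerance = 1e-5)
  expect_equal(r$focal_loss, as.numeric(fl), tolerance = 1e-4)
  # lambda_f = 0 recovers pure weighted dice
  r2 <- adaptseg:::unet_run_cpp(s$par, s$S, s$w, s$d, s$input, s$target,
                                rep(1L, s$S), w, 1, 0, 2, 1e-6, FALSE, FALSE)
  expect_equal(r2$loss, r2$dice_loss)
})

test_that("class weights follow inverse presence frequency", {
  pres <- cbind(a = c(rep(TRUE, 44), rep(FALSE, 44)), b = rep(TRUE, 88))
  w <- class_weights(pres)
  expect_equal(unname(w["a"] / w["b"]), 2)
  expect_equal(mean(w), 1)
  # all always present: all weights 1
  expect_equal(unname(class_weights(cbind(a = rep(TRUE, 10), b = rep(TRUE, 10)))),
               c(1, 1))
  # never-present structure excluded with a warning
  expect_warning(w2 <- class_weights(cbind(a = rep(TRUE, 4), b = rep(FALSE, 4))),
                 "excluded")
  expect_equal(unname(w2["b"]), 0)
})

test_that("volume weights and their schedule follow the epoch bound", {
  u <- volume_weights(c(big = 1000, small = 1))
  expect_equal(unname(u["small"] / u["big"]), 1000)
  expect_equal(mean(u), 1)
  expect_equal(volume_weight_schedule(0, u), u)
  expect_equal(volume_weight_schedule(199, u, 200), u)
  expect_equal(unname(volume_weight_schedule(200, u, 200)), c(1, 1))
  expect_error(loss_config(epochs = 100, volume_epochs = 200), "volume_epochs")
})

test_that("augmentation is deterministic, identity at zero, and scales volume", {
  co <- small_cohort()
  std <- standardize_case(co$cases[[1]], align = FALSE)$case
  row <- list(target_tp = "mid", prior_tp = NA)
  sm <- adaptseg:::assemble_sample(std, row, std$mid$structures$names, "RM")
  sm_arr <- list(input = array(t(sm$input), c(sm$dims, nrow(sm$input))),
                 target = array(t(sm$target), c(sm$dims, nrow(sm$target))),
                 input_modes = sm$input_modes, spacing = sm$spacing)
  idt <- augment(sm_arr, augment_config(0, 0, c(1, 1), seed = 1))
  expect_identical(idt$input, sm_arr$input)
  cfg <- augment_config(10, 5, c(0.8, 1.2), seed = 9)
  a1 <- augment(sm_arr, cfg)
  a2 <- augment(sm_arr, cfg)
  expect_identical(a1$input, a2$input)
  # pure scaling 1.2: mask voxel count ratio ~ 1.2^3
  sc <- augment(sm_arr, augment_config(0, 0, c(1.2, 1.2), seed = 2))
  s <- 1  # bone channel
  ratio <- sum(sc$target[, , , s]) / sum(sm_arr$target[, , , s])
  expect_gt(ratio, 1.728 * 0.85)
  expect_lt(ratio, 1.728 * 1.15)
  # labels stay binary
  expect_true(all(sc$target %in% c(0, 1)))
})

test_that("a tiny training run decreases the loss and stays finite", {
  cfg <- phantom_config(n_patients = 4, grid_shape = c(32, 32, 32),
                        spacing = c(3, 3, 3), seed = 41)
  co <- generate_cohort(cfg)
  std <- standardize_cohort(co)
  plan <- make_fold_plan(names(std$cases), k = 2, val_size = 1, seed = 1)
  fit <- train_model(std$cases, plan, 1, "RM", width = 4,
                     loss_cfg = loss_config(epochs = 6, volume_epochs = 2),
                     augment_cfg = NULL, seed = 1)
  expect_s3_class(fit, "adaptseg_model")
  expect_true(all(is.finite(fit$loss_history)))
  expect_lt(fit$loss_history[6, "total"], fit$loss_history[1, "total"])
  expect_equal(dim(fit$val_trace), c(6L, 3L))
  expect_false(is.na(fit$best_epoch))
  # prediction interface returns binary masks on the mid grid
  pred <- predict(fit, std$cases[[plan$runs[[1]]$test[1]]])
  expect_s3_class(pred, "structure_set")
  expect_true(all(vapply(pred$masks, is.logical, TRUE)))
  expect_equal(dim(attr(pred, "probs")), c(32L, 32L, 32L, 3L))
})
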