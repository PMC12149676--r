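test_that("DSC satisfies its defining identities", {
  m <- array(FALSE, c(8, 8, 8)); m[2:5, 2:5, 2:5] <- TRUE
  expect_equal(as.numeric(dsc(m, m)), 1)
  n <- array(FALSE, c(8, 8, 8)); n[7:8, 7:8, 7:8] <- TRUE
  expect_equal(as.numeric(dsc(m, n)), 0)
  # |A| = |B| = 100, |A n B| = 50 -> 0.5
  a <- array(FALSE, c(10, 10, 10)); a[1:4, 1:5, 1:5] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[3:6, 1:5, 1:5] <- TRUE
  expect_equal(as.numeric(dsc(a, b)), 0.5)
  e <- array(FALSE, c(8, 8, 8))
  both <- dsc(e, e)
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
  expect_error(dsc(m, array(FALSE, c(4, 4, 4))), "equal grids")
})

test_that("MSD matches hand geometry and is symmetric", {
  a <- array(FALSE, c(12, 12, 12)); a[3, 6, 6] <- TRUE
  b <- array(FALSE, c(12, 12, 12)); b[6, 6, 6] <- TRUE
  expect_equal(as.numeric(msd(a, b, c(1, 1, 1))), 3)
  expect_equal(as.numeric(msd(a, b, c(2, 1, 1))), 6)
  m <- array(FALSE, c(10, 10, 10)); m[2:5, 2:5, 2:5] <- TRUE
  expect_equal(as.numeric(msd(m, m, c(1, 1, 1))), 0)
  u <- msd(m, array(FALSE, c(10, 10, 10)))
  expect_true(is.na(u))
  expect_true(attr(u, "undefined"))
})

test_that("DSC and MSD agree with brute-force oracles on random masks", {
  set.seed(33)
  worst_d <- 0; worst_m <- 0
  for (i in 1:40) {
    d <- c(14, 14, 14)
    sp <- c(1, 1.5, 2)
    a <- random_blob(d); b <- random_blob(d)
    worst_d <- max(worst_d, abs(as.numeric(dsc(a, b)) - brute_dsc(a, b)))
    if (sum(a) > 0 && sum(b) > 0)
      worst_m <- max(worst_m, abs(as.numeric(msd(a, b, sp)) - brute_msd(a, b, sp)))
  }
  expect_lt(worst_d, 1e-9)
  expect_lt(worst_m, 1e-6)
})

test_that("prediction evaluation resamples, skips absent and flags empties", {
  co <- small_cohort()
  refs <- co$cases[1]
  case <- refs[[1]]
  snames <- case$mid$structures$names
  # prediction = reference at 1.5x coarser resolution, nearest-resampled back
  pred <- resample(case$mid$structures, case$mid$structures$spacing * 1.5)
  tab <- evaluate_predictions(setNames(list(pred), case$patient_id), refs,
                              method = "down-up")
  expect_equal(nrow(tab), sum(case$mid$structures$present))
  expect_true(all(tab$dsc > 0.7))
  # identical prediction: DSC exactly 1
  tab2 <- evaluate_predictions(setNames(list(case$mid$structures),
                                        case$patient_id), refs)
  expect_true(all(tab2$dsc == 1))
  expect_true(all(tab2$msd == 0))
  # all-empty prediction: DSC 0, MSD flagged undefined
  empty <- structure_set(setNames(lapply(snames, function(s)
    array(FALSE, dim(case$mid$image$voxels))), snames),
    case$mid$structures$spacing, case$mid$structures$origin)
  tab3 <- evaluate_predictions(setNames(list(empty), case$patient_id), refs)
  expect_true(all(tab3$dsc == 0))
  expect_true(all(tab3$msd_undefined))
  # missing channel is an error
  part <- structure_set(list(bone = case$mid$structures$masks$bone),
                        case$mid$structures$spacing)
  expect_error(evaluate_predictions(setNames(list(part), case$patient_id), refs),
               "missing prediction channel")
})

test_that("convergence audit applies the any-epoch threshold semantics", {
  tr <- cbind(a = c(0, 0, 0), b = c(0, 0.5, 0.2), c = c(0.005, 0.005, 0.005))
  conv <- convergence_audit(tr, tau = 0.01)
  expect_equal(unname(conv), c(FALSE, TRUE, FALSE))
  # list input: one row per run
  mat <- convergence_audit(list(tr, tr * 10), tau = 0.01)
  expect_equal(dim(mat), c(2L, 3L))
  expect_equal(unname(mat[2, ]), c(FALSE, TRUE, TRUE))
})

test_that("corrected resampled t-test matches the hand-evaluated formula", {
  a <- c(0.80, 0.75, 0.90, 0.70, 0.85)
  b <- a - c(0.20, 0.10, 0.15, 0.05, 0.10)
  tt <- corrected_resampled_ttest(a, b, n1 = 88, n2 = 22)
  expect_equal(tt$correction, 0.45)
  expect_equal(tt$t, 3.1378581622, tolerance = 1e-9)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0349197067, tolerance = 1e-8)
  # identical scores: degenerate, p = 1
  tt0 <- corrected_resampled_ttest(a, a, 88, 22)
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)
  expect_true(tt0$degenerate)
  # n2/n1 -> 0 recovers the naive resampled t-test
  d <- a - b
  naive <- mean(d) / sqrt(var(d) / 5)
  tt2 <- corrected_resampled_ttest(a, b, n1 = 1e9, n2 = 1)
  expect_equal(tt2$t, naive, tolerance = 1e-6)
})

test_that("corrected t-test maintains type-I error under correlated folds", {
  # simulated null: per-replicate fold scores share a common training-set
  # effect, the classic source of optimistic variance in resampled tests
  set.seed(71)
  k <- 5; reps <- 2000
  rho <- 22 / 110   # overlap-induced fold correlation, rho = n2/(n1+n2)
  rej_corr <- 0; rej_naive <- 0
  for (i in seq_len(reps)) {
    common <- rnorm(1, sd = sqrt(rho) * 0.05)
    d <- common + rnorm(k, sd = sqrt(1 - rho) * 0.05)
    tt <- corrected_resampled_ttest(d, rep(0, k), n1 = 88, n2 = 22)
    if (tt$p < 0.05) rej_corr <- rej_corr + 1
    tn <- mean(d) / sqrt(var(d) / k)
    if (2 * pt(-abs(tn), k - 1) < 0.05) rej_naive <- rej_naive + 1
  }
  expect_gte(rej_corr / reps, 0.025)
  expect_lte(rej_corr / reps, 0.085)
  expect_lte(rej_corr, rej_naive)
})

test_that("comparison report aggregates fold means and marks significance", {
  ids <- sprintf("P%02d", 1:20)
  plan <- make_fold_plan(ids, k = 5, val_size = 2, seed = 3)
  mk <- function(method, dscs) {
    do.call(rbind, lapply(seq_along(ids), function(i)
      data.frame(patient_id = ids[i], structure = "s1", method = method,
                 dsc = dscs[i], msd = 1, both_empty = FALSE,
                 msd_undefined = FALSE)))
  }
  set.seed(4)
  base <- runif(20, 0.5, 0.55)
  recs <- rbind(mk("A", base + 0.2), mk("B", base))
  rep <- comparison_report(recs, plan, pairs = list(c("A", "B")),
                           n1 = 16, n2 = 4)
  expect_equal(nrow(rep), 2)
  a <- rep[rep$method == "A", ]
  expect_true(a$sig_A_vs_B)
  expect_equal(a$mean, mean(base) + 0.2, tolerance = 1e-6)
  expect_equal(a$n_folds, 5)
  # identical methods: no markers
  recs2 <- rbind(mk("A", base), mk("B", base))
  rep2 <- comparison_report(recs2, plan, pairs = list(c("A", "B")))
  expect_false(rep2[rep2$method == "A", "sig_A_vs_B"])
  # marker set invariant to patient ordering within folds
  recs3 <- recs[sample(nrow(recs)), ]
  rep3 <- comparison_report(recs3, plan, pairs = list(c("A", "B")),
                            n1 = 16, n2 = 4)
  expect_equal(rep3[rep3$method == "A", "sig_A_vs_B"],
               rep[rep$method == "A", "sig_A_vs_B"])
})

test_that("single-fold structures report a mean without an sd", {
  ids <- sprintf("P%02d", 1:8)
  plan <- make_fold_plan(ids, k = 4, val_size = 1, seed = 5)
  one_fold <- plan$folds[[2]]
  recs <- do.call(rbind, lapply(one_fold, function(p)
    data.frame(patient_id = p, structure = "lens", method = "A", dsc = 0.4,
               msd = 1, both_empty = FALSE, msd_undefined = FALSE)))
  rep <- comparison_report(recs, plan)
  expect_equal(rep$mean, 0.4)
  expect_true(is.na(rep$sd))
  expect_equal(rep$n_folds, 1)
})
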