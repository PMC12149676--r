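# Evaluation: overlap and surface-distance metrics, prediction resampling
# to the reference grid, convergence auditing, the corrected resampled
# t-test for cross-validated comparisons, and the per-structure comparison
# report with significance markers.

dsc_vec <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`.  If both masks are empty the prediction of
#' absence is correct: DSC is defined as 1 and flagged.
#'
#' @param a,b binary masks (3D arrays or `structure_set` masks) on the same
#'   grid.
#' @return DSC in `[0, 1]`, with attribute `both_empty`.
#' @export
dsc <- function(a, b) {
  a <- as.array(a) >= 0.5
  b <- as.array(b) >= 0.5
  if (!identical(dim(a), dim(b))) stop("dsc requires equal grids")
  out <- dsc_vec(a, b)
  attr(out, "both_empty") <- (sum(a) + sum(b)) == 0
  out
}

surface_distances <- function(from, to, dim, spacing) {
  # distances (mm) from surface voxels of `from` to the surface of `to`
  sf <- surface_voxels_cpp(as.logical(from), dim)
  st <- surface_voxels_cpp(as.logical(to), dim)
  d2 <- edt_sq_cpp(st, dim, spacing)
  sqrt(d2[sf])
}

#' Mean surface distance
#'
#' Symmetric form: the average, over both directions, of the mean distance
#' from each boundary voxel of one mask to the nearest boundary voxel of
#' the other, in physical mm.  The boundary is the set of foreground voxels
#' with a face-adjacent background neighbour (the volume edge counts as
#' background).  Undefined (NA, flagged) if either mask is empty.
#'
#' @param a,b binary masks on the same grid.
#' @param spacing voxel spacing, mm.
#' @export
msd <- function(a, b, spacing = c(1, 1, 1)) {
  a <- as.array(a) >= 0.5
  b <- as.array(b) >= 0.5
  if (!identical(dim(a), dim(b))) stop("msd requires equal grids")
  if (sum(a) == 0 || sum(b) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  d <- dim(a)
  dab <- surface_distances(a, b, d, spacing)
  dba <- surface_distances(b, a, d, spacing)
  out <- (mean(dab) + mean(dba)) / 2
  attr(out, "undefined") <- FALSE
  out
}

#' Evaluate predictions against reference cases
#'
#' Predictions are resampled (nearest neighbour) to the reference
#' (original-resolution) grid and binarized before computing DSC and MSD.
#' Structures absent from the reference are skipped; empty predictions
#' against non-empty references give DSC 0 and an undefined (NA) MSD,
#' flagged in the `msd_undefined` column.
#'
#' @param predictions named list (by patient) of `structure_set` predictions.
#' @param references named list of reference [patient_case()]s at original
#'   resolution; the mid-treatment labels are the reference.
#' @param method label recorded in the output.
#' @return A data.frame (one row per patient x present structure) with
#'   columns `patient_id`, `structure`, `method`, `dsc`, `msd`,
#'   `both_empty`, `msd_undefined`.
#' @export
evaluate_predictions <- function(predictions, references, method = "model") {
  rows <- list()
  for (pid in names(predictions)) {
    pred <- predictions[[pid]]
    ref <- references[[pid]]$mid$structures
    refgrid <- list(dim = grid_dim(ref), spacing = ref$spacing,
                    origin = ref$origin)
    for (i in seq_along(ref$names)) {
      s <- ref$names[i]
      if (!ref$present[i]) next
      if (!(s %in% pred$names)) stop("missing prediction channel: ", s)
      pm <- pred$masks[[s]]
      if (!same_grid(pred, ref)) {
        pm <- resample_array(pm, pred$spacing, pred$origin, refgrid$dim,
                             refgrid$spacing, refgrid$origin,
                             mode = "nearest", background = 0) > 0.5
      }
      dv <- dsc(pm, ref$masks[[s]])
      mv <- msd(pm, ref$masks[[s]], ref$spacing)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, structure = s, method = method,
        dsc = as.numeric(dv), msd = as.numeric(mv),
        both_empty = isTRUE(attr(dv, "both_empty")),
        msd_undefined = isTRUE(attr(mv, "undefined")))
    }
  }
  do.call(rbind, rows)
}

#' Convergence audit of validation DSC traces
#'
#' A structure converged for a run when its validation DSC exceeded the
#' threshold at any epoch ("non-zero validation DSC"); the default
#' threshold 0.01 operationalizes "non-zero" against binarization noise.
#'
#' @param traces matrix epochs x structures (as stored in an
#'   `adaptseg_model`), or a list of such matrices (one per run).
#' @param tau convergence threshold.
#' @return Named logical vector per structure (or a runs x structures
#'   matrix for a list input).
#' @export
convergence_audit <- function(traces, tau = 0.01) {
  one <- function(tr) apply(tr, 2, function(x) any(x > tau, na.rm = TRUE))
  if (is.list(traces)) t(vapply(traces, one, logical(ncol(traces[[1]]))))
  else one(traces)
}

#' Corrected resampled t-test
#'
#' Paired comparison of per-fold cross-validation scores with the variance
#' inflation `c = 1/k + n2/n1` that accounts for training-set overlap
#' between folds: `t = mean(d) / sqrt(c * var(d))` on `k - 1` degrees of
#' freedom, two-sided.  With `n2/n1 -> 0` this recovers the naive resampled
#' t-test.
#'
#' @param scores_a,scores_b per-fold mean scores (length k >= 2), paired.
#' @param n1 training-set size, `n2` test-set size (per fold).
#' @param n2 see `n1`.
#' @return An object of class `corrected_ttest`: `d`, `k`, `n1`, `n2`,
#'   `correction`, `t`, `df`, `p`; degenerate zero-variance differences are
#'   flagged (`p = 1` if the mean difference is 0, else `p = 0`).
#' @export
corrected_resampled_ttest <- function(scores_a, scores_b, n1, n2) {
  if (length(scores_a) != length(scores_b)) stop("fold scores must be paired")
  k <- length(scores_a)
  if (k < 2) stop("need at least two folds")
  d <- scores_a - scores_b
  cfac <- 1 / k + n2 / n1
  s2 <- var(d)
  degenerate <- !is.finite(s2) || s2 == 0
  if (degenerate) {
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tval <- mean(d) / sqrt(cfac * s2)
    p <- 2 * pt(-abs(tval), df = k - 1)
  }
  structure(list(d = d, k = k, n1 = n1, n2 = n2, correction = cfac,
                 t = tval, df = k - 1, p = p, degenerate = degenerate),
            class = "corrected_ttest")
}

#' @export
print.corrected_ttest <- function(x, ...) {
  cat(sprintf("Corrected resampled t-test: t = %.4f on %d df, p = %.4g (c = %.3f%s)\n",
              x$t, x$df, x$p, x$correction,
              if (x$degenerate) "; degenerate zero-variance case" else ""))
  invisible(x)
}

fold_of <- function(plan, pid) {
  for (i in seq_along(plan$folds)) if (pid %in% plan$folds[[i]]) return(i)
  NA_integer_
}

#' Per-structure comparison report with significance markers
#'
#' Scores are first averaged per test fold over patients, then summarized
#' as mean +/- sd over folds per structure and method.  Pairwise
#' significance (default GAM over each comparator) uses the corrected
#' resampled t-test at `alpha`, two-sided, without multiplicity correction.
#' Structures with fewer than two contributing folds for a method are
#' reported without an sd.
#'
#' @param records metric data.frame from [evaluate_predictions()] (rbind
#'   several methods), using the `dsc` column by default.
#' @param plan the [make_fold_plan()] that produced the test folds.
#' @param metric `"dsc"` or `"msd"`.
#' @param pairs list of `c(method_a, method_b)` to test (a vs b).
#' @param n1,n2 training/test sample sizes for the correction factor.
#' @param alpha significance level.
#' @return data.frame, one row per structure x method, columns `mean`,
#'   `sd`, `n_folds` and one `sig_vs_<b>` column per tested pair.
#' @export
comparison_report <- function(records, plan, metric = "dsc", pairs = NULL,
                              n1 = NULL, n2 = NULL, alpha = 0.05) {
  if (metric == "msd") records <- records[!records$msd_undefined, ]
  records$fold <- vapply(records$patient_id, function(p) fold_of(plan, p), 1L)
  methods <- unique(records$method)
  structures <- unique(records$structure)
  if (is.null(n2)) n2 <- length(plan$folds[[1]])
  if (is.null(n1)) n1 <- length(plan$patient_ids) - n2
  # fold means per structure x method
  fm <- function(m, s) {
    r <- records[records$method == m & records$structure == s, ]
    if (nrow(r) == 0) stop("method absent from records: ", m)
    v <- tapply(r[[metric]], r$fold, mean)
    full <- rep(NA_real_, plan$k)
    full[as.integer(names(v))] <- v
    full
  }
  out <- list()
  for (s in structures) {
    folds <- lapply(methods, fm, s = s)
    names(folds) <- methods
    for (m in methods) {
      v <- folds[[m]][!is.na(folds[[m]])]
      row <- data.frame(structure = s, method = m, mean = mean(v),
                        sd = if (length(v) >= 2) sd(v) else NA_real_,
                        n_folds = length(v))
      if (!is.null(pairs)) {
        for (pr in pairs) {
          cn <- paste0("sig_", pr[1], "_vs_", pr[2])
          if (m == pr[1]) {
            ok <- !is.na(folds[[pr[1]]]) & !is.na(folds[[pr[2]]])
            row[[cn]] <- if (sum(ok) >= 2) {
              tt <- corrected_resampled_ttest(folds[[pr[1]]][ok],
                                              folds[[pr[2]]][ok], n1, n2)
              better <- if (metric == "msd") tt$t < 0 else tt$t > 0
              tt$p < alpha && better
            } else NA
          } else row[[cn]] <- NA
        }
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
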