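# Center-of-geometry motion tracking and segmentation-overlap metrics.
#
# The COG (mean physical position of the segmented voxels) tracked across
# breathing phases gives the target's motion trajectory; Dice, sensitivity
# and PPV quantify agreement between a test segmentation and ground truth:
#
#   dice        = 2 |T ∩ S| / (|T| + |S|)
#   sensitivity = |T ∩ S| / |T|     (fraction of truth captured)
#   ppv         = |T ∩ S| / |S|     (fraction of the test mask that is true)

#' Center of geometry of a binary mask, in mm
#'
#' @param mask A non-empty [binary_mask].
#' @return Numeric `(x, y, z)` position in mm.
#' @export
mask_cog <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  mask_cog_mm(mask)
}

#' COG/volume trajectory of a segmented 4D series
#'
#' @param results List of `mpsl_result` (from [segment_series]) or of
#'   [binary_mask]s, one per phase.
#' @param phases Phase labels; defaults to the labels carried by the
#'   results, or 0, 10, ... when absent.
#' @return A `trajectory`: data frame with columns
#'   `phase, cog_x_mm, cog_y_mm, cog_z_mm, volume_cc`, one row per phase,
#'   with the voxel spacing attached as attribute `"spacing"`.
#' @export
compute_trajectory <- function(results, phases = NULL) {
  if (!length(results)) stop("'results' is empty")
  masks <- lapply(results, function(r) {
    if (inherits(r, "mpsl_result")) r$gtv_mask
    else if (inherits(r, "binary_mask")) r
    else stop("'results' must contain mpsl_result or binary_mask objects")
  })
  if (is.null(phases)) {
    phases <- vapply(seq_along(results), function(i) {
      r <- results[[i]]
      if (inherits(r, "mpsl_result") && !is.null(r$phase_label))
        r$phase_label else PHASE_LABELS[i]
    }, integer(1))
  }
  if (length(phases) != length(masks))
    stop("'phases' must have one label per result")
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    if (!any(m$voxels))
      stop("empty segmentation mask at phase ", phases[i])
    cog <- mask_cog_mm(m)
    data.frame(phase = phases[i], cog_x_mm = cog[1], cog_y_mm = cog[2],
               cog_z_mm = cog[3], volume_cc = volume_cc(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("trajectory", "data.frame"),
            spacing = masks[[1]]$spacing)
}

#' Overlap metrics between a test mask and ground truth
#'
#' Computes Dice, sensitivity and positive predictive value from the raw
#' voxel counts. When both masks are empty the masks agree perfectly on
#' absence and all three metrics are 1; when exactly one is empty all
#' three are 0.
#'
#' @param truth,test [binary_mask]s on identical grids.
#' @return An `overlap_metrics` list: `dice`, `sensitivity`, `ppv`,
#'   `n_truth`, `n_test`, `n_intersect`.
#' @export
overlap_metrics <- function(truth, test) {
  stopifnot(inherits(truth, "binary_mask"), inherits(test, "binary_mask"))
  if (!identical(dim(truth$voxels), dim(test$voxels)) ||
      max(abs(truth$spacing - test$spacing)) > 1e-9)
    stop("truth and test masks are on different grids")
  nt <- sum(truth$voxels)
  ns <- sum(test$voxels)
  ni <- sum(truth$voxels & test$voxels)
  if (nt == 0L && ns == 0L) {
    m <- list(dice = 1, sensitivity = 1, ppv = 1)
  } else {
    m <- list(dice = 2 * ni / (nt + ns),
              sensitivity = if (nt > 0) ni / nt else 0,
              ppv = if (ns > 0) ni / ns else 0)
  }
  structure(c(m, list(n_truth = nt, n_test = ns, n_intersect = ni)),
            class = "overlap_metrics")
}

#' @export
print.overlap_metrics <- function(x, ...) {
  cat(sprintf(
    "<overlap_metrics> dice %.3f, sensitivity %.3f, ppv %.3f (|truth| %d, |test| %d, |intersect| %d)\n",
    x$dice, x$sensitivity, x$ppv, x$n_truth, x$n_test, x$n_intersect))
  invisible(x)
}

#' Per-case overlap metrics with summary rows
#'
#' Builds the usual per-case table of Dice/sensitivity/PPV plus trailing
#' `Average` and `St.dev.` rows (sample standard deviation, n-1). With a
#' single case the SD is reported as 0 and the table carries the
#' attribute `sd_undefined = TRUE`.
#'
#' @param pairs List of `list(case_id =, truth =, test =)` entries, with
#'   `truth`/`test` [binary_mask]s.
#' @return Data frame with columns `case_id, dice, sensitivity, ppv`.
#' @export
metrics_table <- function(pairs) {
  if (!length(pairs)) stop("'pairs' must contain at least one case")
  rows <- lapply(pairs, function(p) {
    m <- overlap_metrics(p$truth, p$test)
    data.frame(case_id = as.character(p$case_id), dice = m$dice,
               sensitivity = m$sensitivity, ppv = m$ppv)
  })
  df <- do.call(rbind, rows)
  one <- nrow(df) == 1L
  sdv <- function(x) if (one) 0 else sd(x)
  out <- rbind(df,
               data.frame(case_id = "Average", dice = mean(df$dice),
                          sensitivity = mean(df$sensitivity),
                          ppv = mean(df$ppv)),
               data.frame(case_id = "St.dev.", dice = sdv(df$dice),
                          sensitivity = sdv(df$sensitivity),
                          ppv = sdv(df$ppv)))
  rownames(out) <- NULL
  attr(out, "sd_undefined") <- one
  out
}

#' Per-phase trajectory errors against ground truth
#'
#' For each phase, reports the relative volume error
#' `|v_est - v_true| / v_true`, the absolute COG error (mm), and the
#' error of the COG displacement-from-phase-0 vector: absolute
#' (`|d_est - d_true|`, mm) and relative
#' (`|d_est - d_true| / max(|d_true|, eps)`). The displacement convention
#' measures motion amplitude rather than absolute position. Phases whose
#' true displacement magnitude is below `eps_mm` (default: one voxel
#' diagonal of the estimated trajectory's grid) are flagged `below_eps`
#' and their relative displacement error is `NA` — the absolute error in
#' mm is the meaningful quantity there (the first phase is always such a
#' phase, its displacement being identically zero).
#'
#' @param est,truth `trajectory` objects with identical phase labels.
#' @param eps_mm Displacement guard in mm; defaults to the voxel diagonal
#'   when the trajectory carries its grid spacing, else 1 mm.
#' @return Data frame with one row per phase and columns `phase`,
#'   `vol_true_cc`, `vol_est_cc`, `rel_vol_err`, `abs_cog_err_mm`,
#'   `disp_true_mm`, `disp_est_mm`, `abs_disp_err_mm`, `rel_disp_err`,
#'   `below_eps`.
#' @export
trajectory_error <- function(est, truth, eps_mm = NULL) {
  if (is.null(eps_mm)) {
    sp <- attr(est, "spacing")
    if (is.null(sp)) sp <- attr(truth, "spacing")
    eps_mm <- if (!is.null(sp)) sqrt(sum(sp^2)) else 1
  }
  est <- as.data.frame(est)
  truth <- as.data.frame(truth)
  if (!identical(as.numeric(est$phase), as.numeric(truth$phase)))
    stop("estimated and truth trajectories have different phase labels")
  ce <- as.matrix(est[c("cog_x_mm", "cog_y_mm", "cog_z_mm")])
  ct <- as.matrix(truth[c("cog_x_mm", "cog_y_mm", "cog_z_mm")])
  de <- sweep(ce, 2, ce[1, ], `-`)   # displacement from phase 0
  dt <- sweep(ct, 2, ct[1, ], `-`)
  dt_mag <- sqrt(rowSums(dt^2))
  abs_disp_err <- sqrt(rowSums((de - dt)^2))
  below <- dt_mag < eps_mm
  rel_disp <- ifelse(below, NA_real_, abs_disp_err / dt_mag)
  data.frame(
    phase = est$phase,
    vol_true_cc = truth$volume_cc,
    vol_est_cc = est$volume_cc,
    rel_vol_err = abs(est$volume_cc - truth$volume_cc) / truth$volume_cc,
    abs_cog_err_mm = sqrt(rowSums((ce - ct)^2)),
    disp_true_mm = dt_mag,
    disp_est_mm = sqrt(rowSums(de^2)),
    abs_disp_err_mm = abs_disp_err,
    rel_disp_err = rel_disp,
    below_eps = below)
}
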