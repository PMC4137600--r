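# The MPSL pipeline: dual-range intensity masking -> erosion (disconnects
# the target from surrounding tissue of similar intensity) -> union-find
# labeling with per-region volumes -> tumor-volume window filter ->
# candidate selection -> dilation with the same element, masked against
# the original threshold mask so the restored target never annexes
# background. "Successive localization" across phases restricts candidate
# selection to the neighborhood of the previous phase's target.

#' Closed intensity interval in HU
#'
#' @param lo,hi Interval bounds in HU, `lo <= hi`.
#' @return An `intensity_range`.
#' @export
intensity_range <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || lo > hi)
    stop("intensity range requires lo <= hi")
  structure(c(lo = lo, hi = hi), class = "intensity_range")
}

as_intensity_range <- function(x) {
  if (inherits(x, "intensity_range")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(intensity_range(x[1], x[2]))
  stop("cannot interpret as an intensity range: ", deparse(x))
}

#' MPSL configuration
#'
#' Bundles every tunable of the pipeline. The two intensity ranges define
#' the initial binary mask (a voxel is kept when its HU falls in either
#' closed interval); the volume window `[volume_min_cc, volume_max_cc]` is
#' applied to the *eroded* region volumes, so it should bracket the
#' expected tumor volume after erosion by `radius_mm`; erosion and the
#' restoring dilation always use the identical structuring element.
#'
#' Defaults are pragmatic choices for water-equivalent lung tumors
#' (soft-tissue intensity ranges, a 5 mm ball, a 1-300 cc window) and are
#' expected to be adapted per protocol.
#'
#' @param tumor_range,surround_range [intensity_range]s (or length-2
#'   numeric vectors) for the tumor and the surrounding tissue.
#' @param volume_min_cc,volume_max_cc Volume window (cc) applied to eroded
#'   candidate regions; `0 <= volume_min_cc < volume_max_cc`.
#' @param radius_mm Erosion/dilation radius in mm.
#' @param element_shape `"ball"` or `"box"`.
#' @param mode `"3d"` (volumetric) or `"2d"` (per-slice; the volume window
#'   is then applied to the per-slice slab volume, i.e. in-plane area times
#'   slice thickness).
#' @param connectivity Labeling connectivity (see [label_regions]).
#' @param seed_point Optional 1-based voxel index `(i, j, k)` of a click
#'   inside the tumor; enables seeded segmentation.
#' @param seed_neighborhood_halfwidth Half-width (voxels) of the cubic
#'   neighborhood around the seed whose HU min/max replace `tumor_range`.
#' @param localization_margin_mm Margin (mm) by which the previous phase's
#'   target bounding box is expanded when restricting candidate selection
#'   in [segment_series], and the maximum seed-to-candidate centroid
#'   distance accepted when the seed survives in no region.
#' @return An `mpsl_config`.
#' @export
mpsl_config <- function(tumor_range = intensity_range(-150, 150),
                        surround_range = intensity_range(-120, 250),
                        volume_min_cc = 1,
                        volume_max_cc = 300,
                        radius_mm = 5,
                        element_shape = c("ball", "box"),
                        mode = c("3d", "2d"),
                        connectivity = "face",
                        seed_point = NULL,
                        seed_neighborhood_halfwidth = 2L,
                        localization_margin_mm = 15) {
  tumor_range <- as_intensity_range(tumor_range)
  surround_range <- as_intensity_range(surround_range)
  if (!(volume_min_cc >= 0 && volume_min_cc < volume_max_cc))
    stop("need 0 <= volume_min_cc < volume_max_cc")
  if (radius_mm <= 0) stop("'radius_mm' must be positive")
  element_shape <- match.arg(element_shape)
  mode <- match.arg(mode)
  connectivity <- match.arg(connectivity, CONNECTIVITIES)
  if (!is.null(seed_point)) {
    seed_point <- as.integer(seed_point)
    if (length(seed_point) != 3L) stop("'seed_point' must be (i, j, k)")
    if (seed_neighborhood_halfwidth < 1L)
      stop("'seed_neighborhood_halfwidth' must be >= 1")
  }
  structure(
    list(tumor_range = tumor_range, surround_range = surround_range,
         volume_min_cc = volume_min_cc, volume_max_cc = volume_max_cc,
         radius_mm = radius_mm, element_shape = element_shape, mode = mode,
         connectivity = connectivity, seed_point = seed_point,
         seed_neighborhood_halfwidth =
           as.integer(seed_neighborhood_halfwidth),
         localization_margin_mm = localization_margin_mm),
    class = "mpsl_config")
}

#' Dual-range intensity mask
#'
#' A voxel is foreground iff its HU lies in `tumor_range` OR in
#' `surround_range` (closed intervals). When the tissue classes do not
#' overlap in intensity a single range would suffice; the union handles
#' the usual case where they do.
#'
#' @param vol A [phase_volume].
#' @param tumor_range,surround_range [intensity_range]s.
#' @return A [binary_mask].
#' @export
build_mask <- function(vol, tumor_range, surround_range) {
  stopifnot(inherits(vol, "phase_volume"))
  tr <- as_intensity_range(tumor_range)
  sr <- as_intensity_range(surround_range)
  v <- vol$voxels
  m <- (v >= tr[1] & v <= tr[2]) | (v >= sr[1] & v <= sr[2])
  binary_mask(m, vol$spacing, vol$origin)
}

#' Single-threshold baseline mask
#'
#' The initialization used by semi-automated workflows: a voxel is kept
#' iff its HU is strictly above the threshold (default -83 HU). No
#' morphology is applied; this is the comparison baseline, not the MPSL
#' pipeline.
#'
#' @param vol A [phase_volume].
#' @param threshold HU threshold; voxels strictly above it are kept.
#' @return A [binary_mask].
#' @export
threshold_baseline <- function(vol, threshold = -83) {
  stopifnot(inherits(vol, "phase_volume"))
  binary_mask(vol$voxels > threshold, vol$spacing, vol$origin)
}

mpsl_no_target <- function(msg, candidate_table) {
  stop(errorCondition(msg, candidate_table = candidate_table,
                      class = c("mpsl_no_target_error", "mpsl_error")))
}

# Selection rules ------------------------------------------------------------

# Each selector receives the survivor rows and the full region table and
# returns list(labels = <integer labels to keep>, flags = <character>).

select_largest <- function(surv, rt) {
  if (nrow(surv) > 1L) {
    warning(sprintf(
      "%d regions survive the volume filter (labels %s); selecting the largest (label %d, %.2f cc)",
      nrow(surv), paste(surv$label, collapse = ","),
      surv$label[which.max(surv$volume_cc)], max(surv$volume_cc)))
  }
  list(labels = surv$label[which.max(surv$volume_cc)], flags = character(0))
}

make_seed_selector <- function(seed_point, margin_mm) {
  force(seed_point); force(margin_mm)
  function(surv, rt) {
    seed_lab <- rt$label_map[seed_point[1], seed_point[2], seed_point[3]]
    if (seed_lab > 0 && seed_lab %in% surv$label)
      return(list(labels = seed_lab, flags = character(0)))
    seed_mm <- rt$origin + (seed_point - 1) * rt$spacing
    d <- sqrt((surv$cx - seed_mm[1])^2 + (surv$cy - seed_mm[2])^2 +
                (surv$cz - seed_mm[3])^2)
    if (!length(d) || min(d) > margin_mm)
      mpsl_no_target(sprintf(
        "seed lies in no surviving region and none within %.1f mm",
        margin_mm), rt)
    list(labels = surv$label[which.min(d)], flags = "seed_nearest_centroid")
  }
}

make_localization_selector <- function(prev_bbox_mm, prev_cog, margin_mm) {
  force(prev_bbox_mm); force(prev_cog); force(margin_mm)
  function(surv, rt) {
    lo <- prev_bbox_mm[1, ] - margin_mm
    hi <- prev_bbox_mm[2, ] + margin_mm
    inside <- surv$cx >= lo[1] & surv$cx <= hi[1] &
      surv$cy >= lo[2] & surv$cy <= hi[2] &
      surv$cz >= lo[3] & surv$cz <= hi[3]
    if (!any(inside)) {
      sel <- select_largest(surv, rt)
      sel$flags <- c(sel$flags, "localization_fallback")
      return(sel)
    }
    cand <- surv[inside, , drop = FALSE]
    d <- sqrt((cand$cx - prev_cog[1])^2 + (cand$cy - prev_cog[2])^2 +
                (cand$cz - prev_cog[3])^2)
    list(labels = cand$label[which.min(d)], flags = character(0))
  }
}

# In 2D mode every slice keeps its largest surviving region.
select_per_slice <- function(surv, rt) {
  labs <- integer(0)
  for (z in unique(surv$z0)) {
    s <- surv[surv$z0 == z, , drop = FALSE]
    labs <- c(labs, s$label[which.max(s$volume_cc)])
  }
  list(labels = labs, flags = character(0))
}

# The pipeline engine shared by all entry points.
segment_phase_engine <- function(vol, cfg, selector,
                                 tumor_range = cfg$tumor_range) {
  m0 <- build_mask(vol, tumor_range, cfg$surround_range)
  se <- structuring_element(cfg$element_shape, cfg$radius_mm, vol$spacing,
                            mode = cfg$mode)
  er <- mpsl_erode(m0, se)
  rt <- region_statistics(
    label_regions(er, cfg$connectivity, per_slice = cfg$mode == "2d"))
  keep <- rt$regions$volume_cc >= cfg$volume_min_cc &
    rt$regions$volume_cc <= cfg$volume_max_cc
  rt$regions$survivor <- keep
  surv <- rt$regions[keep, , drop = FALSE]
  if (nrow(surv) == 0L)
    mpsl_no_target(sprintf(
      "no eroded region has volume within [%.2f, %.2f] cc (%d regions found)",
      cfg$volume_min_cc, cfg$volume_max_cc, nrow(rt$regions)), rt)
  sel <- selector(surv, rt)
  sel_vox <- array(rt$label_map %in% sel$labels, dim(rt$label_map))
  dil <- mpsl_dilate(binary_mask(sel_vox, vol$spacing, vol$origin), se)
  gtv_vox <- dil$voxels & m0$voxels
  if (cfg$mode == "3d") {
    # Keep only the connected component of the restored mask that contains
    # the eroded selected region, so the result is a single target.
    comp <- cc_label_uf(gtv_vox, dim(gtv_vox),
                        connectivity_order(cfg$connectivity), FALSE)
    root <- comp[which(sel_vox)[1L]]
    gtv_vox <- array(comp == root, dim(gtv_vox))
  }
  gtv <- binary_mask(gtv_vox, vol$spacing, vol$origin)
  structure(
    list(gtv_mask = gtv,
         candidate_table = rt,
         selected_label = sel$labels,
         diagnostics = list(
           n_mask = sum(m0$voxels), n_eroded = sum(er$voxels),
           n_regions = nrow(rt$regions), n_survivors = nrow(surv),
           n_selected = sum(sel_vox), n_dilated = sum(dil$voxels),
           n_gtv = sum(gtv_vox), flags = sel$flags),
         config = cfg, phase_label = vol$phase_label),
    class = "mpsl_result")
}

default_selector_for <- function(cfg) {
  if (cfg$mode == "2d") select_per_slice else select_largest
}

#' Segment one phase with the MPSL pipeline
#'
#' Runs, in order: (1) dual-range intensity mask; (2) erosion with the
#' configured element; (3) union-find labeling and per-region volumes;
#' (4) volume-window filter; (5) candidate selection (largest surviving
#' region by default, with a warning listing all survivors when more than
#' one passes the filter); (6) dilation of the selected region with the
#' same element; (7) intersection with the stage-(1) mask, so dilation
#' restores the target to its approximate original extent without
#' annexing background. If `cfg$seed_point` is set the seeded variant
#' ([segment_phase_with_seed]) is used instead.
#'
#' @param vol A [phase_volume].
#' @param cfg An [mpsl_config].
#' @return An `mpsl_result` with elements `gtv_mask` ([binary_mask]),
#'   `candidate_table` (`region_table` of the eroded regions, with a
#'   `survivor` column), `selected_label`, and `diagnostics` (per-stage
#'   voxel counts and flags).
#' @seealso [segment_series] for 4D series, [threshold_baseline] for the
#'   no-morphology baseline.
#' @export
segment_phase <- function(vol, cfg = mpsl_config()) {
  stopifnot(inherits(vol, "phase_volume"), inherits(cfg, "mpsl_config"))
  if (!is.null(cfg$seed_point)) return(segment_phase_with_seed(vol, cfg))
  segment_phase_engine(vol, cfg, default_selector_for(cfg))
}

#' Seeded MPSL segmentation from a click inside the tumor
#'
#' The tumor intensity range is replaced by the min/max HU over the cubic
#' neighborhood of half-width `cfg$seed_neighborhood_halfwidth` around
#' `cfg$seed_point`, and among the volume-filter survivors the region
#' containing the seed is selected (falling back to the nearest centroid
#' within `cfg$localization_margin_mm` when erosion removed the seed
#' voxel itself).
#'
#' @inheritParams segment_phase
#' @return An `mpsl_result`.
#' @export
segment_phase_with_seed <- function(vol, cfg) {
  stopifnot(inherits(vol, "phase_volume"), inherits(cfg, "mpsl_config"))
  seed <- cfg$seed_point
  if (is.null(seed)) stop("cfg$seed_point is not set")
  d <- dim(vol$voxels)
  if (any(seed < 1L) || any(seed > d))
    stop("seed point (", paste(seed, collapse = ","),
         ") is outside the volume bounds")
  h <- cfg$seed_neighborhood_halfwidth
  nb <- vol$voxels[max(1, seed[1] - h):min(d[1], seed[1] + h),
                   max(1, seed[2] - h):min(d[2], seed[2] + h),
                   max(1, seed[3] - h):min(d[3], seed[3] + h)]
  tr <- intensity_range(min(nb), max(nb))
  segment_phase_engine(
    vol, cfg, make_seed_selector(seed, cfg$localization_margin_mm),
    tumor_range = tr)
}

mask_bbox_mm <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  lo <- mask$origin + (apply(idx, 2, min) - 1) * mask$spacing
  hi <- mask$origin + (apply(idx, 2, max) - 1) * mask$spacing
  rbind(lo = lo, hi = hi)
}

mask_cog_mm <- function(mask) {
  pos <- voxel_positions_mm(mask$voxels, mask$spacing, mask$origin)
  if (nrow(pos) == 0L) stop("mask is empty")
  colMeans(pos)
}

#' Segment every phase of a 4D series with successive localization
#'
#' The first phase is segmented with [segment_phase] (seeded if
#' `cfg$seed_point` is set). For every later phase, candidate selection is
#' restricted to eroded regions whose centroid lies inside the previous
#' phase's target bounding box expanded by `cfg$localization_margin_mm`
#' on every axis (ties resolved by proximity to the previous center of
#' geometry); if no candidate lies inside the expanded box the selection
#' falls back to the unrestricted rule and the phase is flagged
#' `localization_fallback` in its diagnostics.
#'
#' @param series A [series_4d].
#' @param cfg An [mpsl_config].
#' @return A list of `mpsl_result`, one per phase, in phase order. Any
#'   per-phase failure is rethrown with the phase label attached.
#' @export
segment_series <- function(series, cfg = mpsl_config()) {
  stopifnot(inherits(series, "series_4d"), inherits(cfg, "mpsl_config"))
  results <- vector("list", length(series$phases))
  prev_bbox <- NULL
  prev_cog <- NULL
  for (i in seq_along(series$phases)) {
    vol <- series$phases[[i]]
    res <- tryCatch({
      if (i == 1L) {
        segment_phase(vol, cfg)
      } else if (cfg$mode == "2d") {
        segment_phase_engine(vol, cfg, select_per_slice)
      } else {
        segment_phase_engine(
          vol, cfg,
          make_localization_selector(prev_bbox, prev_cog,
                                     cfg$localization_margin_mm))
      }
    }, mpsl_error = function(e) {
      stop(errorCondition(
        sprintf("phase %d%%: %s", vol$phase_label, conditionMessage(e)),
        candidate_table = e$candidate_table,
        class = setdiff(class(e), c("error", "condition"))))
    })
    if (cfg$mode == "3d") {
      prev_bbox <- mask_bbox_mm(res$gtv_mask)
      prev_cog <- mask_cog_mm(res$gtv_mask)
    }
    results[[i]] <- res
  }
  results
}

#' @export
print.mpsl_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<mpsl_result>%s gtv %d voxels (%.2f cc); stages: mask %d -> eroded %d -> %d region(s), %d survivor(s) -> dilated %d -> gtv %d%s\n",
    if (is.null(x$phase_label)) "" else sprintf(" phase %d%%,",
                                                x$phase_label),
    d$n_gtv, volume_cc(x$gtv_mask), d$n_mask, d$n_eroded, d$n_regions,
    d$n_survivors, d$n_dilated, d$n_gtv,
    if (length(d$flags)) paste0(" [", paste(d$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}
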