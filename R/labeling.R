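# Connected-component labeling via union-find (disjoint sets with path
# compression), with per-region voxel counts, volumes and centroids.

CONNECTIVITIES <- c("face", "face-edge", "face-edge-corner")

connectivity_order <- function(connectivity) {
  connectivity <- match.arg(connectivity, CONNECTIVITIES)
  match(connectivity, CONNECTIVITIES)
}

#' Label connected components of a binary mask
#'
#' Two foreground voxels share a label iff they are joined by a path of
#' foreground voxels under the chosen connectivity: `"face"` (6-neighbors
#' in 3D, 4 in a slice), `"face-edge"` (18/8) or `"face-edge-corner"`
#' (26/8). Labeling uses a union-find structure with path compression;
#' labels are consecutive `1..K`, assigned in ascending order of each
#' region's first voxel in x-fastest scan order, so the assignment is
#' deterministic.
#'
#' @param mask A [binary_mask]; may be empty (then `K = 0`).
#' @param connectivity One of `"face"`, `"face-edge"`,
#'   `"face-edge-corner"`.
#' @param per_slice If `TRUE`, label each z-slice independently (2D mode).
#' @return A `region_table`: list with `label_map` (integer 3D array, 0 =
#'   background) and `regions` (data frame with one row per region; see
#'   [region_statistics] for the filled statistics columns).
#' @export
label_regions <- function(mask, connectivity = "face", per_slice = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  ord <- connectivity_order(connectivity)
  lab <- cc_label_uf(mask$voxels, dim(mask$voxels), ord, per_slice)
  k <- max(lab)
  structure(
    list(label_map = lab,
         regions = data.frame(label = seq_len(k),
                              voxel_count = rep(NA_integer_, k),
                              volume_cc = rep(NA_real_, k)),
         spacing = mask$spacing, origin = mask$origin,
         connectivity = CONNECTIVITIES[ord], per_slice = per_slice),
    class = "region_table")
}

#' Per-region statistics: voxel counts, volumes, centroids, bounding boxes
#'
#' Fills the `regions` data frame of a `region_table` with
#' `voxel_count`, `volume_cc = voxel_count * dx*dy*dz / 1000`, the centroid
#' in physical mm (mean position of member voxels under the
#' node-at-voxel-center convention), and the 1-based index bounding box
#' per axis.
#'
#' @param rt A `region_table` from [label_regions].
#' @param spacing Optional spacing override, mm (defaults to the mask's).
#' @param origin Optional origin override, mm.
#' @return The `region_table` with statistics filled.
#' @export
region_statistics <- function(rt, spacing = NULL, origin = NULL) {
  stopifnot(inherits(rt, "region_table"))
  if (is.null(spacing)) spacing <- rt$spacing
  if (is.null(origin)) origin <- rt$origin
  k <- nrow(rt$regions)
  if (k == 0L) {
    rt$regions <- data.frame(label = integer(0), voxel_count = integer(0),
                             volume_cc = numeric(0), cx = numeric(0),
                             cy = numeric(0), cz = numeric(0),
                             x0 = integer(0), x1 = integer(0),
                             y0 = integer(0), y1 = integer(0),
                             z0 = integer(0), z1 = integer(0))
    return(rt)
  }
  st <- cc_region_stats(rt$label_map, dim(rt$label_map), k)
  n <- st$count
  vox_cc <- prod(spacing) / 1000
  rt$regions <- data.frame(
    label = seq_len(k),
    voxel_count = as.integer(n),
    volume_cc = n * vox_cc,
    cx = origin[1] + spacing[1] * st$sx / n,
    cy = origin[2] + spacing[2] * st$sy / n,
    cz = origin[3] + spacing[3] * st$sz / n,
    x0 = st$x0 + 1L, x1 = st$x1 + 1L,
    y0 = st$y0 + 1L, y1 = st$y1 + 1L,
    z0 = st$z0 + 1L, z1 = st$z1 + 1L)
  rt
}

#' Extract one labeled region as a binary mask
#'
#' @param rt A `region_table`.
#' @param label Region label to extract.
#' @return A [binary_mask] containing only that region.
#' @export
region_mask <- function(rt, label) {
  stopifnot(inherits(rt, "region_table"))
  binary_mask(rt$label_map == label, rt$spacing, rt$origin)
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf("<region_table> %d regions (%s connectivity)\n",
              nrow(x$regions), x$connectivity))
  if (nrow(x$regions)) print(utils::head(x$regions, 10))
  invisible(x)
}

#' Write a region table to CSV
#'
#' Columns: `label,voxel_count,volume_cc,cx,cy,cz`.
#'
#' @param rt A `region_table` with statistics filled.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(rt, path) {
  stopifnot(inherits(rt, "region_table"))
  cols <- c("label", "voxel_count", "volume_cc", "cx", "cy", "cz")
  if (!all(cols %in% names(rt$regions)))
    stop("region statistics not filled; call region_statistics() first")
  write.csv(rt$regions[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
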