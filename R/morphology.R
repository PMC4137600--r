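# Set-theoretic binary morphology.
#
# Dilation:  A (+) B = { c | c = a + b for some a in A, b in B }
# Erosion:   A (-) B = { x | x + b in A for every b in B }
#
# with A a voxel set (binary mask) and B a structuring element given as a
# finite set of integer offsets containing the origin. Boundary handling:
# out-of-bounds voxels are background, so erosion treats the outside as
# empty and dilation results falling outside the array are discarded (the
# grid is never grown). This never fabricates foreground outside the
# scanned field of view.

round_half_up <- function(x) floor(x + 0.5)

#' Build a structuring element from a physical radius
#'
#' The element is expressed in voxel offsets derived from a radius in mm,
#' so the same configuration behaves consistently on anisotropic grids
#' (e.g. sub-mm in-plane spacing with 2.5 mm slices). The per-axis voxel
#' radius is `round(radius_mm / spacing_axis)` with half-way cases rounded
#' up. A `ball` keeps offsets `o` with `sum((o/r)^2) <= 1` (axes whose
#' radius rounds to 0 only contribute a 0 offset); a `box` keeps all
#' offsets with `|o_axis| <= r_axis`. The origin is always a member, so
#' erosion is anti-extensive and dilation extensive.
#'
#' @param shape `"ball"` (ellipsoid in voxel units) or `"box"`.
#' @param radius_mm Physical radius, mm; must be positive.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm.
#' @param mode `"3d"` (default) or `"2d"`; in 2D mode the z radius is
#'   forced to 0 so the element acts within each slice.
#' @return A `structuring_element`: an integer matrix of offsets (one row
#'   per member) with the shape/radius recorded as attributes.
#' @export
structuring_element <- function(shape = c("ball", "box"), radius_mm,
                                spacing, mode = c("3d", "2d")) {
  shape <- match.arg(shape)
  mode <- match.arg(mode)
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0)
    stop("'radius_mm' must be a single positive number")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive values")
  r <- round_half_up(radius_mm / spacing)
  if (mode == "2d") r[3] <- 0
  if (all(r == 0)) {
    warning("radius ", radius_mm,
            " mm rounds to zero voxels on every axis; ",
            "returning the degenerate {origin} element")
    off <- matrix(0L, 1L, 3L)
  } else {
    g <- as.matrix(expand.grid(x = -r[1]:r[1], y = -r[2]:r[2],
                               z = -r[3]:r[3]))
    if (shape == "ball") {
      rr <- pmax(r, 1)  # axes with r = 0 only ever see offset 0
      keep <- rowSums(sweep(g, 2, rr, `/`)^2) <= 1 + 1e-12
      g <- g[keep, , drop = FALSE]
    }
    off <- g
  }
  storage.mode(off) <- "integer"
  dimnames(off) <- NULL
  structure(off, class = "structuring_element", shape = shape,
            radius_mm = radius_mm, radius_vox = r)
}

#' Structuring element from an explicit offset list
#'
#' @param offsets Integer matrix with 3 columns (one offset per row); the
#'   origin is added if absent.
#' @return A `structuring_element`.
#' @export
structuring_element_offsets <- function(offsets) {
  offsets <- as.matrix(offsets)
  if (ncol(offsets) == 2L) offsets <- cbind(offsets, 0L)
  if (ncol(offsets) != 3L) stop("offsets must have 2 or 3 columns")
  if (nrow(offsets) == 0L) stop("structuring element must be non-empty")
  if (!any(rowSums(abs(offsets)) == 0))
    offsets <- rbind(c(0L, 0L, 0L), offsets)
  storage.mode(offsets) <- "integer"
  dimnames(offsets) <- NULL
  structure(offsets, class = "structuring_element", shape = "explicit",
            radius_mm = NA_real_, radius_vox = apply(abs(offsets), 2, max))
}

#' Reflect a structuring element through the origin
#'
#' @param se A `structuring_element`.
#' @return The element with every offset negated.
#' @export
reflect_element <- function(se) {
  stopifnot(inherits(se, "structuring_element"))
  out <- -unclass(se)
  attributes(out) <- attributes(se)
  out
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element> %s, %d offsets, voxel radii (%s)\n",
              attr(x, "shape"), nrow(x),
              paste(attr(x, "radius_vox"), collapse = ",")))
  invisible(x)
}

# Translate a logical array by an integer offset, filling with FALSE.
shift_logical <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

check_morph_args <- function(mask, se) {
  if (!inherits(mask, "binary_mask"))
    stop("'mask' must be a binary_mask")
  if (!inherits(se, "structuring_element"))
    stop("'se' must be a structuring_element")
  if (ncol(se) != 3L)
    stop("structuring element dimensionality does not match the mask")
}

#' Binary dilation
#'
#' Output voxel `c` is foreground iff `c = a + b` for some foreground `a`
#' and offset `b` in the element; results outside the array bounds are
#' discarded.
#'
#' @param mask A [binary_mask] (the set A).
#' @param se A [structuring_element] (the set B).
#' @return The dilated [binary_mask].
#' @export
mpsl_dilate <- function(mask, se) {
  check_morph_args(mask, se)
  a <- mask$voxels
  out <- array(FALSE, dim(a))
  for (i in seq_len(nrow(se)))
    out <- out | shift_logical(a, se[i, ])
  binary_mask(out, mask$spacing, mask$origin)
}

#' Binary erosion
#'
#' Output voxel `x` is foreground iff `x + b` is foreground for every
#' offset `b` in the element; positions for which some `x + b` falls
#' outside the array are background (the outside is treated as empty).
#'
#' @inheritParams mpsl_dilate
#' @return The eroded [binary_mask].
#' @export
mpsl_erode <- function(mask, se) {
  check_morph_args(mask, se)
  a <- mask$voxels
  out <- array(TRUE, dim(a))
  for (i in seq_len(nrow(se))) {
    out <- out & shift_logical(a, -se[i, ])
    if (!any(out)) break
  }
  binary_mask(out, mask$spacing, mask$origin)
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same element; removes structures
#' thinner than the element and is idempotent.
#'
#' @inheritParams mpsl_dilate
#' @return The opened [binary_mask].
#' @export
mpsl_open <- function(mask, se) {
  mpsl_dilate(mpsl_erode(mask, se), se)
}
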