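#' Structuring elements for 3D morphology
#'
#' Builds a flat, centre-symmetric 3D structuring element. `"ball"` rasterises
#' the Euclidean ellipsoid `sum((offset/radius)^2) <= 1` (per-axis radii allow
#' anisotropic voxels), `"cube"` the full box, and `"cross"` axis-aligned arms
#' only. Radius `(0,0,0)` yields the identity element; `struct_el("cross", 1)`
#' is the smallest unit element (the 6-connected neighbourhood) used by
#' morphological reconstruction.
#'
#' @param shape one of `"ball"`, `"cube"`, `"cross"`.
#' @param radius non-negative integer radius, scalar or per-axis length 3
#'   (voxels).
#' @return An object of class `struct_el` with the offset list.
#' @examples
#' nrow(struct_el("cross", 1)$offsets)  # 7: centre + 6 neighbours
#' @export
struct_el <- function(shape = c("ball", "cube", "cross"), radius = 1L) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (length(radius) == 1L) radius <- rep(radius, 3L)
  if (length(radius) != 3L || any(radius < 0L) || any(is.na(radius)))
    stop("'radius' must be non-negative integers, scalar or length 3")
  g <- expand.grid(dx = -radius[1]:radius[1],
                   dy = -radius[2]:radius[2],
                   dz = -radius[3]:radius[3])
  keep <- switch(shape,
    cube = rep(TRUE, nrow(g)),
    cross = rowSums(g != 0L) <= 1L,
    ball = {
      r <- pmax(radius, 1L)  # zero-radius axes already restricted by the grid
      (g$dx / r[1])^2 + (g$dy / r[2])^2 + (g$dz / r[3])^2 <= 1 + 1e-9
    })
  structure(list(shape = shape, radius = radius,
                 offsets = as.matrix(g[keep, , drop = FALSE])),
            class = "struct_el")
}

#' @export
print.struct_el <- function(x, ...) {
  cat(sprintf("<struct_el> %s, radius (%d,%d,%d), %d offsets\n",
              x$shape, x$radius[1], x$radius[2], x$radius[3], nrow(x$offsets)))
  invisible(x)
}

is_identity_se <- function(se) nrow(se$offsets) == 1L

# Core flat min/max filter. Accepts logical or numeric arrays, or ct_volume.
morph_filter <- function(x, se, take_max) {
  stopifnot(inherits(se, "struct_el"))
  arr <- vol_data(x)
  was_logical <- is.logical(arr)
  a <- arr
  storage.mode(a) <- "double"
  out <- .morph_minmax_cpp(as.vector(a), dim(a), se$offsets, take_max)
  out <- array(out, dim(a))
  if (was_logical) out <- out > 0.5
  vol_like(out, x)
}

#' Grayscale/binary dilation and erosion
#'
#' Flat dilation (local maximum) and erosion (local minimum) over the
#' structuring element's reflected neighbourhood. Out-of-grid voxels do not
#' contribute.
#'
#' @param x logical or numeric 3D array, or [ct_volume].
#' @param se a [struct_el].
#' @return Same type as `x`.
#' @export
dilate <- function(x, se) morph_filter(x, se, take_max = TRUE)

#' @rdname dilate
#' @export
erode <- function(x, se) morph_filter(x, se, take_max = FALSE)

#' Morphological opening and closing
#'
#' Opening is erosion followed by dilation (anti-extensive); closing is
#' dilation followed by erosion (extensive). Both are idempotent.
#'
#' @inheritParams dilate
#' @return Same type as `x`.
#' @export
morph_open <- function(x, se) dilate(erode(x, se), se)

#' @rdname morph_open
#' @export
morph_close <- function(x, se) erode(dilate(x, se), se)

#' One geodesic dilation step
#'
#' Dilates `marker` by `se` and clips the result voxel-wise by `mask`:
#' `min(dilate(marker, se), mask)`. Requires `marker <= mask` everywhere.
#'
#' @param marker,mask numeric arrays or [ct_volume]s of identical shape.
#' @param se a [struct_el]; defaults to the unit 6-connected cross.
#' @return Same type as `marker`, bounded between `marker` and `mask`.
#' @export
geodesic_dilate <- function(marker, mask, se = struct_el("cross", 1)) {
  check_same_grid(marker, mask, "marker and mask")
  m <- vol_data(marker); k <- vol_data(mask)
  if (any(m > k)) renalws_error("geodesic dilation requires marker <= mask everywhere")
  vol_like(pmin(vol_data(dilate(marker, se)), k), marker)
}

#' Morphological reconstruction by dilation
#'
#' Iterates geodesic dilation of `marker` under `mask` with the unit
#' 6-connected element until idempotence, yielding the largest image below
#' `mask` that can grow out of `marker`. Implemented with a hybrid
#' raster-scan/queue algorithm that is exactly equivalent to the literal
#' fixed-point iteration (the test suite asserts this against a brute-force
#' oracle).
#'
#' @param marker,mask numeric or logical arrays, or [ct_volume]s; identical
#'   shape, `marker <= mask` voxel-wise.
#' @return Same type as `marker`.
#' @export
reconstruct_by_dilation <- function(marker, mask) {
  check_same_grid(marker, mask, "marker and mask")
  m <- vol_data(marker); k <- vol_data(mask)
  was_logical <- is.logical(m) && is.logical(k)
  storage.mode(m) <- "double"; storage.mode(k) <- "double"
  if (any(m > k)) renalws_error("reconstruction requires marker <= mask everywhere")
  out <- array(.reconstruct_cpp(as.vector(m), as.vector(k), dim(m)), dim(m))
  if (was_logical) out <- out > 0.5
  vol_like(out, marker)
}

#' H-maxima transform
#'
#' Suppresses all regional intensity maxima whose dynamic (height above the
#' lowest surrounding pass) is at most `h`, by reconstructing `image - h`
#' under `image`. The result never exceeds the input and never falls more
#' than `h` below it.
#'
#' @param image numeric array or [ct_volume].
#' @param h non-negative suppression level (HU).
#' @return Same type as `image`.
#' @export
hmax <- function(image, h) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0)
    renalws_error("'h' must be a single non-negative number")
  arr <- vol_data(image)
  storage.mode(arr) <- "double"
  out <- array(.reconstruct_cpp(as.vector(arr - h), as.vector(arr), dim(arr)), dim(arr))
  vol_like(out, image)
}

#' Fill enclosed background cavities
#'
#' Background components not connected to the grid border become foreground.
#' Background connectivity defaults to 6 (the complement of 26-connected
#' foreground).
#'
#' @param mask logical 3D array.
#' @param connectivity background connectivity, 6 or 26.
#' @return logical 3D array.
#' @export
fill_holes <- function(mask, connectivity = 6L) {
  mask <- vol_data(mask)
  stopifnot(is.logical(mask))
  lab <- array(.label_components_cpp(as.vector(!mask), dim(mask), as.integer(connectivity)),
               dim(mask))
  dm <- dim(mask)
  border <- integer(0)
  # faces along singleton axes are the whole grid; only real faces count
  if (dm[1] > 1L) border <- c(border, lab[1, , ], lab[dm[1], , ])
  if (dm[2] > 1L) border <- c(border, lab[, 1, ], lab[, dm[2], ])
  if (dm[3] > 1L) border <- c(border, lab[, , 1], lab[, , dm[3]])
  border <- unique(border)
  border <- border[border != 0L]
  mask | array(!(lab %in% c(0L, border)), dim(mask))
}

#' Connected-component labelling
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26 (default; the standard object-counting
#'   connectivity in this package).
#' @return integer 3D array of labels, 0 = background; labels are numbered in
#'   first-encounter order along the linear scan, so the result is
#'   deterministic.
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- vol_data(mask)
  stopifnot(is.logical(mask))
  array(.label_components_cpp(as.vector(mask), dim(mask), as.integer(connectivity)),
        dim(mask))
}

#' Remove small connected components
#'
#' Deletes 26-connected components with fewer than `min_voxels` voxels.
#'
#' @param mask logical 3D array.
#' @param min_voxels non-negative integer; components of size `>= min_voxels`
#'   are kept, so `0` is the identity.
#' @param connectivity component connectivity (default 26).
#' @return logical 3D array.
#' @export
remove_small_objects <- function(mask, min_voxels, connectivity = 26L) {
  mask <- vol_data(mask)
  if (min_voxels < 0) renalws_error("'min_voxels' must be >= 0")
  if (min_voxels <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}

#' Remove components touching a box's lateral faces
#'
#' Deletes 26-connected components that have at least one voxel on the faces
#' of `box` perpendicular to the x or y axis (the in-plane rectangle borders);
#' the z faces are exempt, since an organ may legitimately span the full
#' slice range of its search box. Equivalent to subtracting the binary
#' reconstruction grown from a border-seed marker.
#'
#' @param mask logical 3D array (assumed contained in `box`).
#' @param box a [bbox] within the grid.
#' @return logical 3D array.
#' @export
remove_border_touching <- function(mask, box) {
  mask <- vol_data(mask)
  if (!bbox_in_grid(box, dim(mask))) renalws_error("box exceeds grid bounds")
  sub <- crop_to_box(mask, box)
  if (!any(sub)) return(mask & FALSE)
  lab <- label_components(sub, 26L)
  d <- dim(sub)
  touching <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ]))
  touching <- touching[touching != 0L]
  sub[lab %in% touching] <- FALSE
  out <- array(FALSE, dim(mask))
  out <- paste_into_grid(sub, box, dim(mask))
  out
}
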