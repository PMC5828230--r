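#' @useDynLib renalws, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd rnorm quantile runif
NULL

#' CT volume in Hounsfield units
#'
#' A `ct_volume` couples a 3D scalar grid of Hounsfield-unit (HU) values with
#' its physical voxel spacing. The axis convention throughout the package is
#' `(x, y, z)`: `x` runs left-right, `y` anterior-posterior, and `z` is the
#' inter-slice (transverse) axis. Readers for all supported formats permute
#' data into this convention.
#'
#' @param data numeric 3D array of HU values; at least 2 voxels per axis,
#'   all finite.
#' @param spacing numeric length-3 vector `(dx, dy, dz)` of voxel sizes in
#'   millimetres; strictly positive and finite.
#' @return An object of class `ct_volume` with elements `data` and `spacing`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2.5))
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels along every axis")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume contains non-finite voxel values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite values (mm)")
  structure(list(data = data, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

is_ct_volume <- function(x) inherits(x, "ct_volume")

# Accept either a ct_volume or a bare 3D array; return the array.
vol_data <- function(x) {
  if (is_ct_volume(x)) x$data else x
}

# Re-wrap a result like its input (ct_volume in -> ct_volume out).
vol_like <- function(data, template) {
  if (is_ct_volume(template)) ct_volume(data, template$spacing) else data
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    stop(sprintf("%s must share the same grid shape", what))
  invisible(TRUE)
}

#' Axis-aligned bounding box (1-based, inclusive)
#'
#' @param lo,hi integer length-3 voxel indices of the lowest and highest
#'   corner, inclusive, with `lo <= hi` on every axis.
#' @return An object of class `bbox`.
#' @export
bbox <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(lo < 1L) || any(lo > hi))
    stop("invalid bounding box: need 1 <= lo <= hi on every axis")
  structure(list(lo = lo, hi = hi), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox> x %d..%d, y %d..%d, z %d..%d\n",
              x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3]))
  invisible(x)
}

bbox_extent <- function(box) box$hi - box$lo + 1L

bbox_in_grid <- function(box, dm) {
  all(box$lo >= 1L) && all(box$hi <= dm)
}

# Extract / assign the subvolume of an array covered by a box.
crop_to_box <- function(arr, box) {
  arr[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3], drop = FALSE]
}

paste_into_grid <- function(sub, box, dm, fill = FALSE) {
  out <- array(fill, dm)
  out[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- sub
  out
}

#' Bounding box of a nonempty binary mask
#'
#' @param mask logical 3D array.
#' @return A [bbox] covering all `TRUE` voxels.
#' @export
mask_bbox <- function(mask) {
  mask <- vol_data(mask)
  if (!any(mask)) stop("mask is empty; no bounding box")
  w <- which(mask, arr.ind = TRUE)
  bbox(apply(w, 2, min), apply(w, 2, max))
}

# Error signalling for the graceful agenesis / nephrectomy path.
no_seed_error <- function(msg) {
  stop(errorCondition(msg, class = c("renalws_no_seed", "renalws_error", "error")))
}

renalws_error <- function(msg) {
  stop(errorCondition(msg, class = c("renalws_error", "error")))
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
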