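#' Pre-smooth a volume before gradient computation
#'
#' Gradient operators are noise sensitive, so a 3D box-mean filter followed
#' by a grayscale morphological opening is applied first. Radius 0 together
#' with the identity element is a no-op.
#'
#' @param vol a [ct_volume] or numeric array.
#' @param mean_radius box-mean half-width in voxels (scalar or per axis).
#' @param open_se structuring element for the opening.
#' @return Same type as `vol`.
#' @export
presmooth <- function(vol, mean_radius = 1L, open_se = struct_el("ball", 1)) {
  mean_radius <- as.integer(mean_radius)
  if (length(mean_radius) == 1L) mean_radius <- rep(mean_radius, 3L)
  if (any(mean_radius < 0L)) renalws_error("'mean_radius' must be >= 0")
  arr <- vol_data(vol)
  storage.mode(arr) <- "double"
  out <- array(.boxmean_cpp(as.vector(arr), dim(arr), mean_radius), dim(arr))
  out <- vol_like(out, vol)
  if (!is_identity_se(open_se)) out <- morph_open(out, open_se)
  out
}

#' 3D gradient magnitude
#'
#' Central differences in the interior, one-sided differences at the grid
#' faces, each partial derivative divided by its axis spacing (HU/mm):
#' `sqrt((dI/dx)^2 + (dI/dy)^2 + (dI/dz)^2)`.
#'
#' @param vol a [ct_volume] (spacing taken from the object) or numeric array
#'   (unit spacing).
#' @return A [ct_volume] (or array) of non-negative gradient magnitudes.
#' @export
gradient_magnitude <- function(vol) {
  arr <- vol_data(vol)
  sp <- if (is_ct_volume(vol)) vol$spacing else c(1, 1, 1)
  dm <- dim(arr)
  axis_diff <- function(a, axis, h) {
    n <- dm[axis]
    idx_hi <- pmin(seq_len(n) + 1L, n)
    idx_lo <- pmax(seq_len(n) - 1L, 1L)
    denom <- (idx_hi - idx_lo) * h   # 2h interior, h at the faces
    pick <- function(i) switch(axis,
                               a[i, , , drop = FALSE],
                               a[, i, , drop = FALSE],
                               a[, , i, drop = FALSE])
    d <- pick(idx_hi) - pick(idx_lo)
    sweep(d, axis, denom, "/")
  }
  gx <- axis_diff(arr, 1L, sp[1])
  gy <- axis_diff(arr, 2L, sp[2])
  gz <- axis_diff(arr, 3L, sp[3])
  g <- sqrt(gx * gx + gy * gy + gz * gz)
  vol_like(g, vol)
}

#' Marker-controlled watershed transform
#'
#' Floods the gradient-magnitude relief from exactly two sources - the
#' object and background markers - suppressing every other local minimum.
#' Flooding uses a priority queue over 6-connected neighbours ordered by
#' (altitude, FIFO insertion order); voxels where the two floods meet become
#' watershed-line voxels (dams, label 0). Every voxel ends up labelled 0, 1
#' (object catchment) or 2 (background catchment), and the labelling is
#' invariant under adding a constant to the altitudes.
#'
#' @param grad gradient [ct_volume] or numeric array.
#' @param markers a `marker_pair` from [make_marker_pair()], or a list with
#'   logical `object` and `background` masks (disjoint, both nonempty).
#' @return integer 3D array with labels 0 (dam), 1 (object), 2 (background).
#' @export
mcwt <- function(grad, markers) {
  arr <- vol_data(grad)
  storage.mode(arr) <- "double"
  obj <- vol_data(markers$object)
  bg <- vol_data(markers$background)
  check_same_grid(arr, obj, "gradient and markers")
  check_same_grid(arr, bg, "gradient and markers")
  if (!any(obj) || !any(bg)) renalws_error("both markers must be nonempty")
  if (any(obj & bg)) renalws_error("markers must be disjoint")
  mk <- array(0L, dim(arr))
  mk[obj] <- 1L
  mk[bg] <- 2L
  array(.watershed_cpp(as.vector(arr), as.vector(mk), dim(arr)), dim(arr))
}
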