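#' Segment the patient body
#'
#' Thresholds the volume at HU > 0 (soft tissue and bone are positive, the
#' surrounding air is strongly negative), removes components smaller than
#' `min_voxels`, keeps the largest 26-connected component, and fills enclosed
#' cavities slice by slice in the transverse plane (so hypodense pockets,
#' e.g. fat, inside the trunk are retained).
#'
#' @param vol a [ct_volume] in HU.
#' @param min_voxels minimum component size retained before selecting the
#'   largest component.
#' @return logical 3D array; one connected body mask.
#' @export
segment_body <- function(vol, min_voxels = 10000L) {
  arr <- vol_data(vol)
  bin <- arr > 0
  bin <- remove_small_objects(bin, min_voxels)
  if (!any(bin)) renalws_error("no body found: no positive-HU component survives")
  lab <- label_components(bin, 26L)
  sizes <- tabulate(lab[lab > 0L])
  body <- lab == which.max(sizes)
  # 2D hole fill per transverse slice
  for (z in seq_len(dim(body)[3])) {
    sl <- body[, , z, drop = FALSE]
    if (any(sl)) body[, , z] <- fill_holes(sl, connectivity = 6L)
  }
  body
}

#' Detect the skeleton
#'
#' Thresholds at the bone HU level inside the body, applies a 3D opening, and
#' removes small residual 2D components in every transverse and sagittal
#' plane (vessel calcifications, table parts), leaving the spine and major
#' bone structures.
#'
#' @param vol a [ct_volume].
#' @param body body mask from [segment_body()].
#' @param bone_hu threshold separating bone from enhanced soft tissue
#'   (default 200 HU).
#' @param se structuring element for the opening.
#' @param min_area_2d minimum in-plane component area (voxels) kept in the
#'   transverse and sagittal passes.
#' @return logical 3D array (nonempty).
#' @export
detect_skeleton <- function(vol, body, bone_hu = 200,
                            se = struct_el("ball", 1), min_area_2d = 8L) {
  if (bone_hu <= 0) renalws_error("'bone_hu' must be positive")
  arr <- vol_data(vol)
  check_same_grid(arr, body)
  bone <- (arr >= bone_hu) & body
  bone <- morph_open(bone, se)
  dm <- dim(bone)
  for (z in seq_len(dm[3])) {  # transverse planes
    sl <- bone[, , z, drop = FALSE]
    if (any(sl)) bone[, , z] <- remove_small_objects(sl, min_area_2d)
  }
  for (x in seq_len(dm[1])) {  # sagittal planes
    sl <- bone[x, , , drop = FALSE]
    if (any(sl)) bone[x, , ] <- remove_small_objects(sl, min_area_2d)
  }
  if (!any(bone)) renalws_error("no skeleton found above the bone threshold")
  bone
}

# Signed posterior direction along y: +1 if the spine centroid lies at larger
# y than the body centroid, else -1. Patient positioning is not assumed.
posterior_sign <- function(body, skeleton) {
  wb <- which(body, arr.ind = TRUE)
  ws <- which(skeleton, arr.ind = TRUE)
  if (nrow(ws) == 0L) renalws_error("empty skeleton mask")
  if (mean(ws[, 2]) >= mean(wb[, 2])) 1L else -1L
}

#' Crop the posterior abdomen
#'
#' Removes the posterior `fraction` of the body's anterior-posterior (y)
#' extent with one straight cut applied to every slice. The posterior
#' direction is inferred from the spine centroid relative to the body
#' centroid, so the result does not depend on scanner orientation
#' conventions. With the kidneys' retroperitoneal-but-not-dorsal position,
#' removing 30% of the abdomen discards the spine and back muscles while
#' keeping both kidneys.
#'
#' @param body body mask.
#' @param skeleton skeleton mask (defines the posterior side).
#' @param fraction fraction of the AP extent to remove, in `[0, 1)`.
#' @return list with `body` (cropped mask) and `box` (its bounding [bbox]).
#' @export
crop_posterior <- function(body, skeleton, fraction = 0.30) {
  if (fraction < 0 || fraction >= 1) renalws_error("'fraction' must be in [0, 1)")
  body <- vol_data(body)
  ys <- which(apply(body, 2, any))
  y0 <- min(ys); y1 <- max(ys)
  nrem <- floor(fraction * (y1 - y0 + 1L))
  out <- body
  if (nrem > 0) {
    if (posterior_sign(body, vol_data(skeleton)) > 0L)
      out[, (y1 - nrem + 1L):y1, ] <- FALSE
    else
      out[, y0:(y0 + nrem - 1L), ] <- FALSE
  }
  if (!any(out)) renalws_error("posterior crop removed the whole body")
  list(body = out, box = mask_bbox(out))
}

# Rasterise a 3D digital line from a to b (inclusive): one point per step of
# the dominant axis, max(extent) points in total.
digital_line <- function(a, b) {
  n <- max(abs(b - a)) + 1L
  t <- if (n == 1L) 0 else seq(0, 1, length.out = n)
  cbind(as.integer(round(a[1] + t * (b[1] - a[1]))),
        as.integer(round(a[2] + t * (b[2] - a[2]))),
        as.integer(round(a[3] + t * (b[3] - a[3]))))
}

#' Build per-kidney search boxes and diagonals
#'
#' Computes the bounding box of the cropped body, splits it left/right at the
#' spine's mean left-right (x) position, and rasterises one 3D diagonal per
#' sub-box running from the medial-posterior corner on the lowest slice to
#' the lateral-anterior corner on the highest slice, so that it traverses the
#' expected kidney position lateral to the spine.
#'
#' @param cropped_body cropped body mask from [crop_posterior()].
#' @param skeleton skeleton mask.
#' @return list of class `roi_boxes`: `box` (parent [bbox]), `split_x`,
#'   `left`/`right`, each with `box` and `diag` (n x 3 voxel index matrix);
#'   `left` is the low-x side.
#' @export
kidney_boxes <- function(cropped_body, skeleton) {
  cropped_body <- vol_data(cropped_body)
  skeleton <- vol_data(skeleton)
  if (!any(cropped_body) || !any(skeleton)) renalws_error("empty input mask")
  box <- mask_bbox(cropped_body)
  ws <- which(skeleton, arr.ind = TRUE)
  split_x <- as.integer(round(mean(ws[, 1])))
  split_x <- min(max(split_x, box$lo[1]), box$hi[1])
  if (split_x <= box$lo[1] || split_x >= box$hi[1])
    renalws_error("degenerate left/right split: spine at the box edge")
  post <- posterior_sign(cropped_body, skeleton)
  left_box <- bbox(box$lo, c(split_x, box$hi[2], box$hi[3]))
  right_box <- bbox(c(split_x + 1L, box$lo[2], box$lo[3]), box$hi)
  make_diag <- function(b, medial_x, lateral_x) {
    y_post <- if (post > 0L) b$hi[2] else b$lo[2]
    y_ant <- if (post > 0L) b$lo[2] else b$hi[2]
    digital_line(c(medial_x, y_post, b$lo[3]), c(lateral_x, y_ant, b$hi[3]))
  }
  structure(list(
    box = box, split_x = split_x, posterior = post,
    left = list(box = left_box, diag = make_diag(left_box, left_box$hi[1], left_box$lo[1])),
    right = list(box = right_box, diag = make_diag(right_box, right_box$lo[1], right_box$hi[1]))
  ), class = "roi_boxes")
}

#' Window a volume to the enhanced-kidney HU range
#'
#' Contrast-enhanced renal parenchyma in the portal venous phase falls in a
#' 0-200 HU window; voxels outside `[lo, hi]` are set to 0 (treated as
#' non-kidney), voxels inside keep their value. The windowed image is the
#' intensity image used by all later segmentation stages.
#'
#' @param vol a [ct_volume].
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return A [ct_volume].
#' @export
window_kidney_hu <- function(vol, lo = 0, hi = 200) {
  if (lo >= hi) renalws_error("'lo' must be smaller than 'hi'")
  arr <- vol_data(vol)
  arr[arr < lo | arr > hi] <- 0
  vol_like(arr, vol)
}
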