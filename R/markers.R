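#' Sample the windowed image along a box diagonal
#'
#' Collects the nonzero windowed HU values on the diagonal voxels. Their mean
#' plus sample standard deviation (n-1 denominator) gives the suppression
#' level `h` used by the h-maxima smoothing of the preliminary segmentation.
#'
#' @param windowed windowed [ct_volume] (see [window_kidney_hu()]).
#' @param diag n x 3 matrix of voxel indices (a digital line from
#'   [kidney_boxes()]).
#' @return list of class `diag_sample`: `values`, `coords` (their voxel
#'   indices), `mean`, `sd`, `h`.
#' @export
sample_diagonal <- function(windowed, diag) {
  if (is.null(dim(diag)) || ncol(diag) != 3L || nrow(diag) == 0L)
    renalws_error("'diag' must be a nonempty n x 3 index matrix")
  arr <- vol_data(windowed)
  vals <- arr[diag]
  nz <- vals > 0
  if (sum(nz) < 2L)
    no_seed_error("kidney not on diagonal: fewer than 2 nonzero samples")
  v <- vals[nz]
  structure(list(values = v, coords = diag[nz, , drop = FALSE],
                 mean = mean(v), sd = sd(v), h = mean(v) + sd(v)),
            class = "diag_sample")
}

#' Preliminary kidney segmentation within one box
#'
#' Smooths the windowed image inside the box with the h-maxima transform at
#' the diagonal-derived level `h` and takes `th = mean + sd` of the smoothed
#' values on the diagonal voxels; the smoothing flattens noise peaks so the
#' threshold statistic is stable. The windowed image is then binarised at
#' `I > th`, the result is opened, objects below a physical minimum volume
#' are removed, and objects touching the box's in-plane borders are deleted.
#' The surviving objects are kidney seed candidates.
#'
#' @param windowed windowed [ct_volume].
#' @param sample a `diag_sample` from [sample_diagonal()].
#' @param box the kidney search [bbox].
#' @param open_se structuring element for the cleanup opening.
#' @param min_seed_ml minimum candidate volume in millilitres; smaller blobs
#'   (noise clusters, vessel fragments) are discarded.
#' @return logical full-grid mask of candidate objects (all inside `box`).
#' @export
preliminary_segment <- function(windowed, sample, box,
                                open_se = struct_el("ball", 1),
                                min_seed_ml = 15) {
  arr <- vol_data(windowed)
  if (!bbox_in_grid(box, dim(arr))) renalws_error("box exceeds grid bounds")
  sub <- crop_to_box(arr, box)
  if (!any(sub > 0)) no_seed_error("no seed in box: windowed image is zero")
  smoothed <- hmax(sub, sample$h)
  # diagonal coordinates relative to the box
  rel <- sweep(sample$coords, 2L, box$lo - 1L)
  inside <- rel[, 1] >= 1 & rel[, 1] <= dim(sub)[1] &
            rel[, 2] >= 1 & rel[, 2] <= dim(sub)[2] &
            rel[, 3] >= 1 & rel[, 3] <= dim(sub)[3]
  D <- smoothed[rel[inside, , drop = FALSE]]
  if (length(D) < 2L) no_seed_error("no seed in box: diagonal leaves the box")
  th <- mean(D) + sd(D)
  bin <- sub > th
  bin <- morph_open(bin, open_se)
  spacing <- if (is_ct_volume(windowed)) windowed$spacing else c(1, 1, 1)
  min_vox <- ceiling(min_seed_ml * 1000 / prod(spacing))
  bin <- remove_small_objects(bin, min_vox)
  sub_box <- bbox(c(1L, 1L, 1L), dim(sub))
  bin <- remove_border_touching(bin, sub_box)
  if (!any(bin)) no_seed_error("no seed in box")
  paste_into_grid(bin, box, dim(arr))
}

#' Select kidney objects among candidates
#'
#' Iteratively discards the smallest 26-connected component while more than
#' two remain, or while exactly two remain whose volumes are not comparable
#' (smaller/larger below `comparable_ratio`). One object is the normal
#' outcome per box; two comparable objects are kept to tolerate a kidney
#' split by the preliminary threshold.
#'
#' @param candidates logical mask of candidate objects.
#' @param comparable_ratio minimum smaller/larger volume ratio for two
#'   objects to be considered comparable (default 0.5).
#' @return logical mask with 1 or 2 components.
#' @export
select_kidney_objects <- function(candidates, comparable_ratio = 0.5) {
  candidates <- vol_data(candidates)
  if (!any(candidates)) no_seed_error("no candidate objects")
  lab <- label_components(candidates, 26L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- order(sizes, decreasing = TRUE)
  while (length(keep) > 2L ||
         (length(keep) == 2L && sizes[keep[2]] / sizes[keep[1]] < comparable_ratio)) {
    keep <- keep[-length(keep)]
  }
  array(lab %in% keep, dim(candidates))
}

#' Build the background marker for one kidney seed
#'
#' For every transverse slice containing seed voxels the axis-aligned
#' bounding rectangle of the seed's footprint is filled; the stacked result
#' is extended one slice beyond the seed's z range, dilated in 3D with a ball
#' whose per-axis radius is `ceil(se_fraction x smallest seed extent)` (10%
#' of the smallest kidney dimension by default), and inverted. The unlabeled
#' corridor between seed and background contains the true kidney boundary.
#'
#' @param seed logical full-grid seed mask (nonempty).
#' @param se_fraction fraction of the smallest seed extent used as the
#'   dilation radius (default 0.10); the radius is rounded up so that even
#'   small seeds get a nonempty corridor.
#' @return list: `background` (logical mask, disjoint from `seed` by
#'   construction), `hull` (the dilated rectangular hull), `radius`.
#' @export
make_background_marker <- function(seed, se_fraction = 0.10) {
  seed <- vol_data(seed)
  if (!any(seed)) renalws_error("empty seed")
  dm <- dim(seed)
  ext <- bbox_extent(mask_bbox(seed))
  radius <- as.integer(ceiling(se_fraction * min(ext)))
  hull <- array(FALSE, dm)
  zs <- which(apply(seed, 3, any))
  for (z in zs) {
    sl <- seed[, , z]
    xs <- range(which(apply(sl, 1, any)))
    ys <- range(which(apply(sl, 2, any)))
    hull[xs[1]:xs[2], ys[1]:ys[2], z] <- TRUE
  }
  # extend one slice beyond the seed's z range
  z0 <- min(zs); z1 <- max(zs)
  if (z0 > 1L) hull[, , z0 - 1L] <- hull[, , z0]
  if (z1 < dm[3]) hull[, , z1 + 1L] <- hull[, , z1]
  hull <- dilate(hull, struct_el("ball", radius))
  list(background = !hull, hull = hull, radius = radius)
}

#' Assemble the object/background marker pair
#'
#' The object marker is the union of the per-box seeds; the background
#' marker is the intersection of the per-box background markers, so that the
#' corridor around every kidney stays unlabeled.
#'
#' @param seeds list of logical full-grid seed masks (one per kidney box;
#'   `NULL` entries, e.g. after nephrectomy, are skipped).
#' @param se_fraction passed to [make_background_marker()].
#' @return list of class `marker_pair`: `object`, `background` (disjoint,
#'   both nonempty).
#' @export
make_marker_pair <- function(seeds, se_fraction = 0.10) {
  seeds <- Filter(Negate(is.null), seeds)
  if (length(seeds) == 0L) renalws_error("no kidney found: both boxes are seedless")
  object <- Reduce(`|`, lapply(seeds, vol_data))
  bgs <- lapply(seeds, function(s) make_background_marker(s, se_fraction)$background)
  background <- Reduce(`&`, bgs)
  if (!any(background)) renalws_error("background marker is empty")
  stopifnot(!any(object & background))
  structure(list(object = object, background = background), class = "marker_pair")
}
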