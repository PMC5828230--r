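#' Extract the kidney catchment from the watershed labels
#'
#' The object marker seeded catchment 1, so the kidney region is exactly the
#' label-1 set; watershed-line (dam) voxels are boundary, not kidney, and are
#' never included.
#'
#' @param labels integer label image from [mcwt()].
#' @param object_marker the object marker mask (used for validation).
#' @return logical kidney mask.
#' @export
select_kidney_labels <- function(labels, object_marker) {
  mask <- labels == 1L
  if (!any(mask)) renalws_error("empty kidney region in watershed labels")
  check_same_grid(mask, object_marker, "labels and marker")
  if (!all(mask[vol_data(object_marker)]))
    renalws_error("internal error: object marker escaped its catchment")
  mask
}

#' Smooth the kidney mask
#'
#' Morphological filtering - opening, then closing, then volumetric hole
#' filling - smooths the kidney edges and closes internal cavities (e.g. the
#' vascular cavity). Every 26-connected component of the input is preserved:
#' if smoothing annihilates a component entirely, that component is restored
#' unsmoothed with a warning.
#'
#' @param mask logical kidney mask.
#' @param se structuring element (default ball of radius 1 voxel).
#' @return logical mask.
#' @export
smooth_kidney <- function(mask, se = struct_el("ball", 1)) {
  mask <- vol_data(mask)
  out <- fill_holes(morph_close(morph_open(mask, se), se))
  lab <- label_components(mask, 26L)
  ncomp <- max(lab)
  for (k in seq_len(ncomp)) {
    comp <- lab == k
    if (!any(out & comp)) {
      warning(sprintf("smoothing annihilated component %d; restoring it unsmoothed", k))
      out <- out | comp
    }
  }
  out
}
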