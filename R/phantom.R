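#' Specification of a synthetic abdominal CT phantom
#'
#' Describes a deterministic contrast-enhanced abdominal CT phantom: an
#' elliptic-cylinder trunk of positive HU surrounded by air, a subcutaneous
#' posterior spine column at bone HU, an internal hypodense fat pocket, and
#' two kidney ellipsoids inside the 0-200 HU contrast window, placed lateral
#' to the spine and anterior to the posterior 30% band. Optional pathologies:
#' a hypodense cyst or a hyperdense tumour carved into a kidney (the carved
#' voxels stay part of the kidney ground truth, matching whole-kidney
#' delineation practice), or an absent kidney (nephrectomy / agenesis).
#'
#' Sides are named in image coordinates: `"left"` is the low-x half.
#'
#' @param shape grid size in voxels, default `c(128, 128, 96)`.
#' @param spacing voxel size in mm, default `c(3, 3, 2.5)` (a clinical
#'   in-plane grid downsampled 4x, typical slice spacing).
#' @param air_hu,body_hu,fat_hu,bone_hu,kidney_hu tissue HU levels.
#' @param noise_sd additive zero-mean Gaussian noise, HU (default 10,
#'   typical portal-venous noise).
#' @param body_semiaxes trunk ellipse semi-axes (x, y) in mm.
#' @param spine_offset_mm,spine_radius_mm spine position behind the body
#'   centre and its radius, mm.
#' @param kidney_semiaxes kidney ellipsoid semi-axes (x, y, z) in mm.
#' @param kidney_lateral_mm,kidney_ap_mm kidney centre offsets from the body
#'   centre: lateral (+/- x) and anterior-posterior (y, negative =
#'   anterior), mm.
#' @param fat_pocket logical; include the internal fat pocket.
#' @param pathology one of `"none"`, `"cyst"`, `"tumor"`, `"nephrectomy"`,
#'   `"agenesis"`.
#' @param pathology_side `"left"` or `"right"`.
#' @param cyst_radius_mm,cyst_hu,tumor_radius_mm,tumor_hu lesion geometry.
#' @param seed RNG seed; the same spec yields a bit-identical phantom.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 96L),
                         spacing = c(3, 3, 2.5),
                         air_hu = -1000, body_hu = 40, fat_hu = -80,
                         bone_hu = 700, kidney_hu = 140, noise_sd = 10,
                         body_semiaxes = c(160, 110),
                         spine_offset_mm = 70, spine_radius_mm = 14,
                         kidney_semiaxes = c(27, 22, 50),
                         kidney_lateral_mm = 75, kidney_ap_mm = -30,
                         fat_pocket = TRUE,
                         pathology = c("none", "cyst", "tumor", "nephrectomy", "agenesis"),
                         pathology_side = c("left", "right"),
                         cyst_radius_mm = 10, cyst_hu = -5,
                         tumor_radius_mm = 12, tumor_hu = 80,
                         seed = 1L) {
  pathology <- match.arg(pathology)
  pathology_side <- match.arg(pathology_side)
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               air_hu = air_hu, body_hu = body_hu, fat_hu = fat_hu,
               bone_hu = bone_hu, kidney_hu = kidney_hu, noise_sd = noise_sd,
               body_semiaxes = body_semiaxes,
               spine_offset_mm = spine_offset_mm, spine_radius_mm = spine_radius_mm,
               kidney_semiaxes = kidney_semiaxes,
               kidney_lateral_mm = kidney_lateral_mm, kidney_ap_mm = kidney_ap_mm,
               fat_pocket = isTRUE(fat_pocket),
               pathology = pathology, pathology_side = pathology_side,
               cyst_radius_mm = cyst_radius_mm, cyst_hu = cyst_hu,
               tumor_radius_mm = tumor_radius_mm, tumor_hu = tumor_hu,
               seed = as.integer(seed))
  if (!(spec$kidney_hu > 0 && spec$kidney_hu < 200))
    renalws_error("kidney HU must lie inside (0, 200)")
  if (!(spec$air_hu < 0 && spec$body_hu > 0 && spec$bone_hu > spec$body_hu))
    renalws_error("need air HU < 0 < body HU < bone HU")
  structure(spec, class = "phantom_spec")
}

#' Generate a synthetic CT phantom with ground truth
#'
#' Rasterises the geometry of a [phantom_spec()] on its voxel grid, adds
#' seeded Gaussian noise, and returns voxel-level ground truth per kidney.
#' The caller's RNG state is left untouched; identical specs give
#' bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom`: `volume` ([ct_volume]), `truth` (list
#'   with logical masks `left`, `right`; all-`FALSE` for an absent kidney),
#'   `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$shape; sp <- spec$spacing
  # voxel-centre coordinates (mm), origin at the grid centre
  cx <- (seq_len(dm[1]) - (dm[1] + 1) / 2) * sp[1]
  cy <- (seq_len(dm[2]) - (dm[2] + 1) / 2) * sp[2]
  cz <- (seq_len(dm[3]) - (dm[3] + 1) / 2) * sp[3]
  X <- array(rep(cx, times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(cy, each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(cz, each = dm[1] * dm[2]), dm)

  body <- (X / spec$body_semiaxes[1])^2 + (Y / spec$body_semiaxes[2])^2 <= 1
  vol <- array(spec$air_hu, dm)
  vol[body] <- spec$body_hu

  if (spec$fat_pocket) {
    fat <- ((X - 0) / 35)^2 + ((Y + 0.55 * spec$body_semiaxes[2]) / 22)^2 +
      (Z / 45)^2 <= 1
    fat <- fat & body
    vol[fat] <- spec$fat_hu
  }

  spine <- (X / spec$spine_radius_mm)^2 +
    ((Y - spec$spine_offset_mm) / spec$spine_radius_mm)^2 <= 1
  spine <- spine & body
  vol[spine] <- spec$bone_hu

  ellipsoid <- function(cx0, cy0, cz0, ax) {
    ((X - cx0) / ax[1])^2 + ((Y - cy0) / ax[2])^2 + ((Z - cz0) / ax[3])^2 <= 1
  }
  kid <- function(side) {
    sgn <- if (side == "left") -1 else 1
    ellipsoid(sgn * spec$kidney_lateral_mm, spec$kidney_ap_mm, 0, spec$kidney_semiaxes)
  }
  truth <- list(left = kid("left"), right = kid("right"))
  for (side in c("left", "right")) {
    if (spec$pathology %in% c("nephrectomy", "agenesis") && spec$pathology_side == side) {
      truth[[side]] <- array(FALSE, dm)
      next
    }
    if (any(truth[[side]] & !body)) renalws_error("kidney outside the body")
    vol[truth[[side]]] <- spec$kidney_hu
  }

  if (spec$pathology %in% c("cyst", "tumor")) {
    side <- spec$pathology_side
    sgn <- if (side == "left") -1 else 1
    r <- if (spec$pathology == "cyst") spec$cyst_radius_mm else spec$tumor_radius_mm
    hu <- if (spec$pathology == "cyst") spec$cyst_hu else spec$tumor_hu
    # lesion offset towards the upper pole, fully inside the kidney
    les <- ellipsoid(sgn * spec$kidney_lateral_mm, spec$kidney_ap_mm,
                     0.4 * spec$kidney_semiaxes[3], c(r, r, r))
    les <- les & truth[[side]]
    vol[les] <- hu   # ground truth keeps the lesion voxels
  }

  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(spec$seed, array(rnorm(prod(dm), 0, spec$noise_sd), dm))
  }
  structure(list(volume = ct_volume(vol, sp), truth = truth, spec = spec),
            class = "phantom")
}

#' Generate a reproducible suite of phantoms
#'
#' Draws `n` phantoms with jittered geometry and tissue HU around a base
#' specification and a deterministic pathology allocation at the given
#' proportions (largest-remainder rounding, then a seeded shuffle across
#' cases).
#'
#' @param n number of phantoms.
#' @param base_spec base [phantom_spec()].
#' @param seed suite seed; drives jitter, pathology placement and per-case
#'   noise seeds.
#' @param proportions named numeric vector of pathology proportions over
#'   `none`, `cyst`, `tumor`, `nephrectomy`, `agenesis` (summing to 1).
#' @return list of `phantom` objects (see [make_phantom()]).
#' @export
make_suite <- function(n, base_spec = phantom_spec(), seed = 1L,
                       proportions = c(none = 0.5, cyst = 0.2, tumor = 0.1,
                                       nephrectomy = 0.1, agenesis = 0.1)) {
  if (n < 1L) renalws_error("'n' must be >= 1")
  if (abs(sum(proportions) - 1) > 1e-8) renalws_error("proportions must sum to 1")
  # largest-remainder allocation: exact counts for exact proportions
  raw <- proportions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  pathologies <- rep(names(proportions), times = cnt)
  with_seed(seed, {
    pathologies <- sample(pathologies)
    sides <- sample(c("left", "right"), n, replace = TRUE)
    jit <- function(x, f) x * runif(length(x), 1 - f, 1 + f)
    lapply(seq_len(n), function(i) {
      spec <- base_spec
      spec$kidney_semiaxes <- jit(spec$kidney_semiaxes, 0.12)
      spec$kidney_lateral_mm <- jit(spec$kidney_lateral_mm, 0.10)
      spec$kidney_ap_mm <- spec$kidney_ap_mm + runif(1, -8, 8)
      spec$kidney_hu <- spec$kidney_hu + runif(1, -20, 20)
      spec$body_hu <- spec$body_hu + runif(1, -10, 10)
      spec$body_semiaxes <- jit(spec$body_semiaxes, 0.06)
      spec$pathology <- pathologies[i]
      spec$pathology_side <- sides[i]
      spec$seed <- (spec$seed + 7919L * i) %% 2147483647L
      make_phantom(spec)
    })
  })
}
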