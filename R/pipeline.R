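#' Pipeline configuration
#'
#' All tunables of the segmentation workflow with their defaults. Unknown
#' names are rejected.
#'
#' @param hu_window contrast-enhanced kidney HU window, default `c(0, 200)`.
#' @param posterior_fraction fraction of the AP body extent removed, 0.30.
#' @param bone_hu skeleton threshold, 200 HU.
#' @param body_min_voxels small-object floor before body selection.
#' @param bone_min_area_2d per-plane minimum bone component area (voxels).
#' @param comparable_ratio smaller/larger volume ratio treated as comparable.
#' @param marker_se_fraction background-marker dilation radius as a fraction
#'   of the smallest seed extent, 0.10.
#' @param min_seed_ml minimum physical seed volume (ml).
#' @param prelim_open_radius opening radius (voxels) after seed thresholding.
#' @param presmooth_radius box-mean half-width (voxels) before the gradient.
#' @param presmooth_open_radius grayscale opening radius before the gradient.
#' @param smooth_se_max_mm physical cap of the final smoothing ball radius;
#'   the per-axis voxel radius is `floor(smooth_se_max_mm / spacing)` capped
#'   at 1 voxel so thin kidney poles survive.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(hu_window = c(0, 200),
                            posterior_fraction = 0.30,
                            bone_hu = 200,
                            body_min_voxels = 10000L,
                            bone_min_area_2d = 8L,
                            comparable_ratio = 0.5,
                            marker_se_fraction = 0.10,
                            min_seed_ml = 15,
                            prelim_open_radius = 1L,
                            presmooth_radius = 1L,
                            presmooth_open_radius = 1L,
                            smooth_se_max_mm = 2) {
  cfg <- list(hu_window = as.numeric(hu_window),
              posterior_fraction = posterior_fraction,
              bone_hu = bone_hu,
              body_min_voxels = as.integer(body_min_voxels),
              bone_min_area_2d = as.integer(bone_min_area_2d),
              comparable_ratio = comparable_ratio,
              marker_se_fraction = marker_se_fraction,
              min_seed_ml = min_seed_ml,
              prelim_open_radius = as.integer(prelim_open_radius),
              presmooth_radius = as.integer(presmooth_radius),
              presmooth_open_radius = as.integer(presmooth_open_radius),
              smooth_se_max_mm = smooth_se_max_mm)
  stopifnot(length(cfg$hu_window) == 2L, cfg$hu_window[1] < cfg$hu_window[2],
            cfg$posterior_fraction >= 0, cfg$posterior_fraction < 1,
            cfg$bone_hu > 0, cfg$comparable_ratio > 0, cfg$comparable_ratio <= 1,
            cfg$marker_se_fraction > 0, cfg$min_seed_ml >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a key = value text file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Unknown keys are rejected.
#'
#' @param path config file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad)) renalws_error(sprintf("malformed config line: %s", bad[1]))
  args <- lapply(kv, function(m) as.numeric(strsplit(m[3], "[, \t]+")[[1]]))
  names(args) <- vapply(kv, `[`, character(1), 2L)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) renalws_error(sprintf("unknown config key: %s",
                                             paste(unknown, collapse = ", ")))
  do.call(pipeline_config, args)
}

# Leading dots avoid partial matching against stage parameters passed in `...`
log_stage <- function(.log, .stage, ...) {
  .log[[length(.log) + 1L]] <- list(stage = .stage, ...)
  .log
}

#' Run the full kidney-segmentation pipeline
#'
#' Executes the whole workflow on a CT volume: body segmentation, skeleton
#' detection, posterior crop, kidney search boxes with diagonals, HU
#' windowing, per-box preliminary segmentation and object selection, marker
#' generation, gradient-magnitude computation, marker-controlled watershed,
#' and morphological post-processing. A seedless box (nephrectomy, agenesis)
#' degrades gracefully to a single-kidney result with a logged notice; only
#' when both boxes are seedless does the run return a `"no_kidney"` status
#' (never a crash). The pipeline contains no randomness: identical input and
#' configuration reproduce bit-identical masks.
#'
#' @param vol a [ct_volume] in HU.
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_result`:
#'   `mask` (final logical kidney mask), `kidneys` (list `left`/`right` of
#'   per-side masks or `NULL`), `status` (`"ok"`, `"single_kidney"`,
#'   `"no_kidney"`), `log` (list of stage records), and `stages`
#'   (intermediate artifacts: body, skeleton, boxes, markers, labels).
#' @export
run_pipeline <- function(vol, cfg = pipeline_config()) {
  stopifnot(is_ct_volume(vol), inherits(cfg, "pipeline_config"))
  log <- list()

  body <- segment_body(vol, cfg$body_min_voxels)
  log <- log_stage(log, "segment_body", voxels = sum(body))

  skeleton <- detect_skeleton(vol, body, cfg$bone_hu,
                              struct_el("ball", 1), cfg$bone_min_area_2d)
  log <- log_stage(log, "detect_skeleton", voxels = sum(skeleton),
                   bone_hu = cfg$bone_hu)

  crop <- crop_posterior(body, skeleton, cfg$posterior_fraction)
  log <- log_stage(log, "crop_posterior", fraction = cfg$posterior_fraction,
                   voxels = sum(crop$body))

  boxes <- kidney_boxes(crop$body, skeleton)
  log <- log_stage(log, "kidney_boxes", split_x = boxes$split_x)

  windowed <- window_kidney_hu(vol, cfg$hu_window[1], cfg$hu_window[2])
  log <- log_stage(log, "window_kidney_hu", lo = cfg$hu_window[1],
                   hi = cfg$hu_window[2])

  seeds <- list(left = NULL, right = NULL)
  for (side in c("left", "right")) {
    bx <- boxes[[side]]
    seed <- tryCatch({
      smp <- sample_diagonal(windowed, bx$diag)
      cand <- preliminary_segment(windowed, smp, bx$box,
                                  struct_el("ball", cfg$prelim_open_radius),
                                  cfg$min_seed_ml)
      select_kidney_objects(cand, cfg$comparable_ratio)
    }, renalws_no_seed = function(e) {
      NULL
    })
    if (is.null(seed)) {
      log <- log_stage(log, paste0("seed_", side), found = FALSE,
                       note = "no seed in box (possible agenesis/nephrectomy)")
    } else {
      log <- log_stage(log, paste0("seed_", side), found = TRUE,
                       voxels = sum(seed))
    }
    seeds[[side]] <- seed
  }

  n_seeds <- sum(!vapply(seeds, is.null, logical(1)))
  if (n_seeds == 0L) {
    log <- log_stage(log, "result", status = "no_kidney")
    return(structure(list(mask = array(FALSE, dim(vol$data)),
                          kidneys = list(left = NULL, right = NULL),
                          status = "no_kidney", log = log, stages = NULL),
                     class = "pipeline_result"))
  }

  markers <- make_marker_pair(seeds, cfg$marker_se_fraction)
  log <- log_stage(log, "make_marker_pair",
                   object_voxels = sum(markers$object),
                   background_voxels = sum(markers$background))

  smoothvol <- presmooth(windowed, cfg$presmooth_radius,
                         struct_el("ball", cfg$presmooth_open_radius))
  grad <- gradient_magnitude(smoothvol)
  log <- log_stage(log, "gradient_magnitude", max = max(vol_data(grad)))

  labels <- mcwt(grad, markers)
  log <- log_stage(log, "mcwt",
                   object = sum(labels == 1L), dam = sum(labels == 0L))

  kidney <- select_kidney_labels(labels, markers$object)
  smooth_r <- pmin(1L, as.integer(floor(cfg$smooth_se_max_mm / vol$spacing)))
  final <- smooth_kidney(kidney, struct_el("ball", smooth_r))
  final <- final | markers$object   # the object marker is certainly kidney
  log <- log_stage(log, "smooth_kidney", voxels = sum(final),
                   radius = paste(smooth_r, collapse = "x"))

  # map final components to sides through their seed overlap
  lab <- label_components(final, 26L)
  kidneys <- list(left = NULL, right = NULL)
  for (side in c("left", "right")) {
    if (is.null(seeds[[side]])) next
    ids <- setdiff(unique(lab[seeds[[side]]]), 0L)
    if (length(ids)) kidneys[[side]] <- array(lab %in% ids, dim(lab))
  }
  status <- if (n_seeds == 2L) "ok" else "single_kidney"
  log <- log_stage(log, "result", status = status)
  structure(list(mask = final, kidneys = kidneys, status = status, log = log,
                 stages = list(body = body, skeleton = skeleton, crop = crop,
                               boxes = boxes, markers = markers,
                               labels = labels)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> status %s, %d kidney voxels\n",
              x$status, sum(x$mask)))
  for (e in x$log) {
    rest <- e[-1]
    cat(sprintf("  %-18s %s\n", e$stage,
                paste(names(rest), unlist(lapply(rest, format)), sep = "=",
                      collapse = " ")))
  }
  invisible(x)
}

#' Evaluate a segmentation against a reference mask
#'
#' @param pred predicted logical mask (or a `pipeline_result`, whose `mask`
#'   is used).
#' @param ref reference logical mask on the same grid.
#' @return a `metrics_report` (see [compute_metrics()]).
#' @export
evaluate_segmentation <- function(pred, ref) {
  if (inherits(pred, "pipeline_result")) pred <- pred$mask
  compute_metrics(contingency_counts(pred, ref))
}

#' Run the pipeline over a phantom suite and score it
#'
#' Segments every phantom and evaluates each present kidney against its
#' ground truth on the full grid. An absent predicted kidney scores an
#' all-`FALSE` mask.
#'
#' @param suite list of phantoms from [make_suite()].
#' @param cfg a [pipeline_config()].
#' @return list: `cases` (data frame with one row per present kidney:
#'   case, side, pathology, status and all metrics), `reports` (list of
#'   `metrics_report`), `results` (pipeline results).
#' @export
evaluate_suite <- function(suite, cfg = pipeline_config()) {
  rows <- list(); reports <- list(); results <- list()
  empty <- function(dm) array(FALSE, dm)
  for (i in seq_along(suite)) {
    ph <- suite[[i]]
    res <- run_pipeline(ph$volume, cfg)
    results[[i]] <- res
    for (side in c("left", "right")) {
      truth <- ph$truth[[side]]
      if (!any(truth)) next   # absent kidney: nothing to score
      pred <- res$kidneys[[side]]
      if (is.null(pred)) pred <- empty(dim(truth))
      rep <- evaluate_segmentation(pred, truth)
      reports[[length(reports) + 1L]] <- rep
      rows[[length(rows) + 1L]] <- data.frame(
        case = i, side = side, pathology = ph$spec$pathology,
        status = res$status, as.data.frame(unclass(rep)))
    }
  }
  list(cases = do.call(rbind, rows), reports = reports, results = results)
}
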