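#' Voxel-wise contingency counts
#'
#' Compares a predicted binary mask against a reference mask on the full
#' grid and counts true positives (kidney voxels found), true negatives,
#' false positives and false negatives.
#'
#' @param pred,ref logical 3D arrays on the same grid.
#' @return list of class `contingency` with `tp`, `tn`, `fp`, `fn`
#'   (doubles, since voxel counts can exceed the integer range on large
#'   grids).
#' @export
contingency_counts <- function(pred, ref) {
  pred <- vol_data(pred); ref <- vol_data(ref)
  check_same_grid(pred, ref, "pred and ref")
  stopifnot(is.logical(pred), is.logical(ref))
  structure(list(
    tp = as.double(sum(pred & ref)), tn = as.double(sum(!pred & !ref)),
    fp = as.double(sum(pred & !ref)), fn = as.double(sum(!pred & ref))
  ), class = "contingency")
}

#' Segmentation-agreement metrics
#'
#' Computes the full agreement suite from a 2x2 voxel contingency table:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, Dice
#' `2TP/(2TP+FP+FN)`, Jaccard `D/(2-D)`, accuracy (observed agreement),
#' random accuracy (chance agreement
#' `((TN+FP)(TN+FN)+(FN+TP)(FP+TP))/total^2`), Cohen's kappa
#' `(Acc-randAcc)/(1-randAcc)`, false-positive volume fraction
#' `FP/(TN+FP)`, and the similarity measure `1-|FN-FP|/(2TP+FN+FP)`.
#' All values are proportions in `[0, 1]` (kappa in `[-1, 1]`); any 0/0 is
#' reported as `NA`, never silently as 0. Use [format_metrics()] for the
#' percent rendering.
#'
#' @param counts a `contingency` from [contingency_counts()], or a list with
#'   `tp`, `tn`, `fp`, `fn`.
#' @return list of class `metrics_report` with elements `sens`, `spec`,
#'   `dice`, `jaccard`, `acc`, `rand_acc`, `kappa`, `fpvf`, `sim`.
#' @examples
#' compute_metrics(list(tp = 8, fp = 2, fn = 2, tn = 88))$dice  # 0.8
#' @export
compute_metrics <- function(counts) {
  tp <- as.double(counts$tp); tn <- as.double(counts$tn)
  fp <- as.double(counts$fp); fn <- as.double(counts$fn)
  if (any(c(tp, tn, fp, fn) < 0)) renalws_error("negative counts")
  total <- tp + tn + fp + fn
  if (total == 0) renalws_error("empty contingency table")
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- sdiv(tp, tp + fn)
  spec <- sdiv(tn, tn + fp)
  dice <- sdiv(2 * tp, 2 * tp + fp + fn)
  jaccard <- if (is.na(dice)) NA_real_ else dice / (2 - dice)
  acc <- (tp + tn) / total
  rand_acc <- ((tn + fp) * (tn + fn) + (fn + tp) * (fp + tp)) / total^2
  kappa <- sdiv(acc - rand_acc, 1 - rand_acc)
  fpvf <- sdiv(fp, tn + fp)
  sim <- if ((2 * tp + fn + fp) == 0) NA_real_ else 1 - abs(fn - fp) / (2 * tp + fn + fp)
  structure(list(sens = sens, spec = spec, dice = dice, jaccard = jaccard,
                 acc = acc, rand_acc = rand_acc, kappa = kappa,
                 fpvf = fpvf, sim = sim),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(format_metrics(x))
  invisible(x)
}

#' Render a metrics report on the percent scale
#'
#' @param report a `metrics_report`.
#' @param digits decimal places (default 2).
#' @return named character vector of percentages.
#' @export
format_metrics <- function(report, digits = 2) {
  vapply(unclass(report),
         function(v) if (is.na(v)) "NA" else sprintf(paste0("%.", digits, "f%%"), 100 * v),
         character(1))
}

#' Altman interpretation of Cohen's kappa
#'
#' Bands a kappa value on the percent scale into the agreement-strength
#' classes: `(80, 100]` Very good, `(60, 80]` Good, `(40, 60]` Moderate,
#' `(20, 40]` Fair, `[0, 20]` Poor; negative kappa is Poor.
#'
#' @param kappa_percent numeric vector of kappa values in percent (<= 100).
#' @return factor with levels Very good, Good, Moderate, Fair, Poor.
#' @export
altman_class <- function(kappa_percent) {
  if (any(kappa_percent > 100 + 1e-9, na.rm = TRUE))
    renalws_error("kappa cannot exceed 100%")
  lv <- c("Very good", "Good", "Moderate", "Fair", "Poor")
  out <- ifelse(kappa_percent > 80, "Very good",
         ifelse(kappa_percent > 60, "Good",
         ifelse(kappa_percent > 40, "Moderate",
         ifelse(kappa_percent > 20, "Fair", "Poor"))))
  factor(out, levels = lv)
}

#' Cohort summary of metric reports
#'
#' Five-number summary plus mean for every metric across a set of cases, and
#' the Altman class tally of the kappa values.
#'
#' @param reports list of `metrics_report` objects.
#' @return list: `metrics` (data frame, one row per metric: min, q1, median,
#'   q3, max, mean over the non-`NA` cases) and `altman` (named class
#'   counts).
#' @export
cohort_summary <- function(reports) {
  if (length(reports) == 0L) renalws_error("no reports to summarise")
  nm <- names(unclass(reports[[1]]))
  mat <- vapply(reports, function(r) unlist(unclass(r)[nm]), numeric(length(nm)))
  mat <- matrix(mat, nrow = length(nm), dimnames = list(nm, NULL))
  stats_row <- function(v) {
    v <- v[!is.na(v)]
    q <- quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
    c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5], mean = mean(v))
  }
  metrics <- as.data.frame(t(apply(mat, 1, stats_row)))
  kap <- mat["kappa", ]
  altman <- table(altman_class(100 * kap[!is.na(kap)]))
  list(metrics = metrics, altman = altman)
}
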