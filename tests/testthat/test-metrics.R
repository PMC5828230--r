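test_that("contingency counts come from voxel-wise set arithmetic", {
  dm <- c(10, 10, 1)
  ref <- array(FALSE, dm); ref[1:10, 1, 1] <- TRUE
  expect_equal(unclass(contingency_counts(ref, ref))[c("tp", "tn", "fp", "fn")],
               list(tp = 10, tn = 90, fp = 0, fn = 0))
  flip <- !ref
  ct <- contingency_counts(flip, ref)
  expect_equal(ct$tp, 0); expect_equal(ct$tn, 0)
  pred <- array(FALSE, dm); pred[3:12] <- TRUE       # 10 voxels, 8 overlapping
  ref2 <- array(FALSE, dm); ref2[1:10] <- TRUE
  ct2 <- contingency_counts(pred, ref2)
  expect_equal(unclass(ct2)[c("tp", "fp", "fn", "tn")],
               list(tp = 8, fp = 2, fn = 2, tn = 88))
  expect_error(contingency_counts(pred, array(FALSE, c(5, 5, 5))), "same grid")
})

test_that("the worked contingency example reproduces every metric", {
  r <- compute_metrics(list(tp = 8, fp = 2, fn = 2, tn = 88))
  expect_equal(r$sens, 0.8, tolerance = 1e-12)
  expect_equal(r$spec, 88 / 90, tolerance = 1e-12)
  expect_equal(r$dice, 0.8, tolerance = 1e-12)
  expect_equal(r$jaccard, 2 / 3, tolerance = 1e-12)
  expect_equal(r$acc, 0.96, tolerance = 1e-12)
  expect_equal(r$rand_acc, 0.82, tolerance = 1e-12)
  expect_equal(r$kappa, 0.14 / 0.18, tolerance = 1e-12)
  expect_equal(r$fpvf, 2 / 90, tolerance = 1e-12)
  expect_equal(r$sim, 1, tolerance = 1e-12)
})

test_that("metric identities and bounds hold on random tables", {
  set.seed(2)
  for (i in 1:500) {
    ct <- as.list(setNames(sample(0:200, 4, TRUE), c("tp", "tn", "fp", "fn")))
    if (sum(unlist(ct)) == 0) next
    r <- compute_metrics(ct)
    # Jaccard from Dice equals the set-theoretic form
    if (!is.na(r$dice))
      expect_equal(r$jaccard, ct$tp / (ct$tp + ct$fp + ct$fn), tolerance = 1e-12)
    # kappa equals the independent two-rater closed form
    if (!is.na(r$kappa)) {
      k2 <- 2 * (ct$tp * ct$tn - ct$fn * ct$fp) /
        ((ct$tp + ct$fp) * (ct$fp + ct$tn) + (ct$tp + ct$fn) * (ct$fn + ct$tn))
      expect_equal(r$kappa, k2, tolerance = 1e-12)
      expect_true(r$kappa >= -1 - 1e-12 && r$kappa <= 1 + 1e-12)
    }
    for (nm in c("sens", "spec", "dice", "jaccard", "acc", "rand_acc", "fpvf", "sim")) {
      v <- r[[nm]]
      if (!is.na(v)) expect_true(v >= -1e-12 && v <= 1 + 1e-12)
    }
  }
})

test_that("Dice is symmetric in pred/ref while FPVF and sensitivity are not", {
  set.seed(8)
  found_asym <- FALSE
  for (i in 1:20) {
    a <- rand_mask(c(6, 6, 6), 0.3); b <- rand_mask(c(6, 6, 6), 0.3)
    r1 <- compute_metrics(contingency_counts(a, b))
    r2 <- compute_metrics(contingency_counts(b, a))
    expect_equal(r1$dice, r2$dice, tolerance = 1e-12)
    expect_equal(r1$sim, r2$sim, tolerance = 1e-12)
    if (!isTRUE(all.equal(r1$fpvf, r2$fpvf)) || !isTRUE(all.equal(r1$sens, r2$sens)))
      found_asym <- TRUE
  }
  expect_true(found_asym)
})

test_that("degenerate tables report NA rather than a silent zero", {
  r <- compute_metrics(list(tp = 0, fn = 0, fp = 3, tn = 97))   # no reference kidney
  expect_true(is.na(r$sens))
  r2 <- compute_metrics(list(tp = 0, fn = 0, fp = 0, tn = 100)) # chance agreement 1
  expect_true(is.na(r2$kappa))
  expect_error(compute_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)), "empty")
  # perfect agreement with both classes present
  p <- compute_metrics(list(tp = 10, tn = 90, fp = 0, fn = 0))
  expect_equal(unlist(p[c("sens", "spec", "dice", "jaccard", "acc", "kappa", "sim")]),
               c(sens = 1, spec = 1, dice = 1, jaccard = 1, acc = 1, kappa = 1, sim = 1))
  expect_equal(p$fpvf, 0)
  # fn == fp always gives sim = 1
  q <- compute_metrics(list(tp = 5, tn = 50, fp = 7, fn = 7))
  expect_equal(q$sim, 1)
})

test_that("Altman banding follows the half-open percent bands", {
  kp <- c(91.62, 80, 61, 60, 41, 40, 21, 20, 0, -5)
  expect_equal(as.character(altman_class(kp)),
               c("Very good", "Good", "Good", "Moderate", "Moderate",
                 "Fair", "Fair", "Poor", "Poor", "Poor"))
  expect_error(altman_class(120), "exceed")
})

test_that("cohort summaries aggregate metrics and Altman classes", {
  mk <- function(tp, fp, fn, tn) compute_metrics(list(tp = tp, fp = fp, fn = fn, tn = tn))
  one <- mk(8, 2, 2, 88)
  s1 <- cohort_summary(list(one))
  expect_equal(s1$metrics["dice", "min"], 0.8)
  expect_true(all(s1$metrics["dice", c("q1", "median", "q3", "max", "mean")] == 0.8))
  s2 <- cohort_summary(list(one, one))
  expect_equal(s2$metrics["kappa", "q3"] - s2$metrics["kappa", "q1"], 0)
  # kappa values 0.85 / 0.95 / 0.70 -> two Very good, one Good
  forge <- function(k) { r <- unclass(one); r$kappa <- k; structure(r, class = "metrics_report") }
  cs <- cohort_summary(list(forge(0.85), forge(0.95), forge(0.70)))
  expect_equal(as.integer(cs$altman[c("Very good", "Good")]), c(2L, 1L))
  expect_equal(sum(cs$altman), 3L)
  expect_error(cohort_summary(list()), "no reports")
})

test_that("percent formatting renders proportions at two decimals", {
  r <- compute_metrics(list(tp = 8, fp = 2, fn = 2, tn = 88))
  f <- format_metrics(r)
  expect_equal(unname(f["sens"]), "80.00%")
  expect_equal(unname(f["spec"]), "97.78%")
  expect_equal(unname(f["kappa"]), "77.78%")
})
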