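# shared noisy compact phantom with precomputed ROI stages
mk_ph <- make_phantom(small_phantom_spec(seed = 3))
mk_body <- segment_body(mk_ph$volume, min_voxels = 5000)
mk_skel <- detect_skeleton(mk_ph$volume, mk_body, bone_hu = 200)
mk_crop <- crop_posterior(mk_body, mk_skel, 0.3)
mk_boxes <- kidney_boxes(mk_crop$body, mk_skel)
mk_win <- window_kidney_hu(mk_ph$volume, 0, 200)

test_that("diagonal sampling computes h = mean + sample sd of nonzero voxels", {
  v <- ct_volume(array(0, c(5, 2, 2)))
  v$data[1:3, 1, 1] <- c(100, 120, 140)
  d <- cbind(1:5, 1L, 1L)
  s <- sample_diagonal(v, d)
  expect_equal(s$mean, 120)
  expect_equal(s$sd, 20)             # sample sd, n - 1 denominator
  expect_equal(s$h, 140)
  v$data[1:3, 1, 1] <- 90
  expect_equal(sample_diagonal(v, d)$h, 90)   # sd = 0 for constants
  v$data[1:3, 1, 1] <- c(0, 0, 50)   # a single nonzero sample is not enough
  expect_error(sample_diagonal(v, d), class = "renalws_no_seed")
  # h is a statistic of the value multiset only: permutation invariant
  v$data[1:5, 1, 1] <- c(80, 0, 120, 40, 160)
  h1 <- sample_diagonal(v, d)$h
  v$data[1:5, 1, 1] <- c(160, 40, 0, 120, 80)
  expect_equal(sample_diagonal(v, d)$h, h1)
})

test_that("preliminary segmentation finds a seed inside the kidney", {
  for (side in c("left", "right")) {
    bx <- mk_boxes[[side]]
    smp <- sample_diagonal(mk_win, bx$diag)
    cand <- preliminary_segment(mk_win, smp, bx$box)
    seed <- select_kidney_objects(cand)
    truth <- mk_ph$truth[[side]]
    # seed within the (1-voxel dilated) kidney, with a substantial volume
    expect_true(all(dilate(truth, struct_el("cube", 1))[seed]))
    expect_gte(sum(seed) / sum(truth), 0.4)
    expect_lte(sum(seed) / sum(truth), 1.05)
    # never touches the box's lateral faces
    expect_false(any(seed[c(bx$box$lo[1], bx$box$hi[1]), , ]))
    expect_false(any(seed[, c(bx$box$lo[2], bx$box$hi[2]), ]))
  }
  # identically zero box -> graceful no-seed signal
  zero <- ct_volume(array(0, c(12, 12, 8)))
  zero$data[6, 6, 4] <- 0
  fake <- structure(list(values = c(50, 60), coords = cbind(5:6, 6L, 4L),
                         mean = 55, sd = sd(c(50, 60)), h = 55 + sd(c(50, 60))),
                    class = "diag_sample")
  expect_error(preliminary_segment(zero, fake, bbox(c(1, 1, 1), c(12, 12, 8))),
               class = "renalws_no_seed")
})

test_that("object selection keeps one object, or two only when comparable", {
  blob <- function(dm, x0, n) {
    m <- array(FALSE, dm)
    w <- ceiling(n^(1 / 3))
    m[x0:(x0 + w - 1), 1:w, 1:ceiling(n / w^2)] <- TRUE
    m
  }
  dm <- c(40, 8, 8)
  two_eq <- blob(dm, 1, 64) | blob(dm, 20, 48)      # ratio 0.75: comparable
  out <- select_kidney_objects(two_eq, comparable_ratio = 0.5)
  expect_equal(max(label_components(out)), 2L)
  two_neq <- blob(dm, 1, 64) | blob(dm, 30, 8)      # ratio 0.125: drop smaller
  out2 <- select_kidney_objects(two_neq, comparable_ratio = 0.5)
  expect_equal(max(label_components(out2)), 1L)
  expect_equal(sum(out2), 64)
  single <- blob(dm, 5, 27)
  expect_equal(select_kidney_objects(single), single)
  # three objects collapse to at most two comparable ones
  three <- blob(dm, 1, 64) | blob(dm, 15, 60) | blob(dm, 30, 6)
  out3 <- select_kidney_objects(three, comparable_ratio = 0.5)
  expect_equal(max(label_components(out3)), 2L)
  expect_error(select_kidney_objects(array(FALSE, dm)), class = "renalws_no_seed")
})

test_that("the background marker leaves a corridor around the seed", {
  dm <- c(30, 30, 20)
  seed <- array(FALSE, dm)
  seed[10:19, 10:19, 5:14] <- TRUE                  # 10^3 cube
  bgm <- make_background_marker(seed)
  expect_equal(bgm$radius, 1L)                      # ceil(0.1 * 10)
  expect_false(any(bgm$background & seed))          # always disjoint
  # the hull grown by one voxel per axis (dilation + z-extension) is excluded
  expect_false(any(bgm$background[9:20, 10:19, 5:14]))
  expect_false(any(bgm$background[10:19, 9:20, 5:14]))
  expect_false(any(bgm$background[10:19, 10:19, 4:15]))
  expect_true(any(bgm$background))
  # seed touching the volume border still leaves background on the far side
  edge <- array(FALSE, dm); edge[1:5, 1:5, 1:5] <- TRUE
  bge <- make_background_marker(edge)
  expect_true(any(bge$background[25:30, 25:30, 15:20]))
})

test_that("marker pairs stay disjoint and handle a missing seed", {
  dm <- c(24, 24, 12)
  s1 <- array(FALSE, dm); s1[4:8, 10:14, 4:8] <- TRUE
  s2 <- array(FALSE, dm); s2[16:20, 10:14, 4:8] <- TRUE
  mp <- make_marker_pair(list(s1, s2))
  expect_equal(max(label_components(mp$object)), 2L)
  expect_false(any(mp$object & mp$background))
  # the corridor of each seed is respected: intersection of backgrounds
  bg1 <- make_background_marker(s1)$background
  bg2 <- make_background_marker(s2)$background
  expect_equal(mp$background, bg1 & bg2)
  # single-seed (nephrectomy) path
  mp1 <- make_marker_pair(list(s1, NULL))
  expect_equal(max(label_components(mp1$object)), 1L)
  expect_error(make_marker_pair(list(NULL, NULL)), "no kidney")
  # invariant on random phantom-like seeds
  set.seed(9)
  for (i in 1:10) {
    r1 <- array(FALSE, dm); r1[sample(6:10, 1) + 0:3, 4:9, 3:6] <- TRUE
    r2 <- array(FALSE, dm); r2[sample(14:18, 1) + 0:3, 4:9, 3:6] <- TRUE
    mp <- make_marker_pair(list(r1, r2))
    expect_false(any(mp$object & mp$background))
  }
})
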