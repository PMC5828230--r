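test_that("structuring elements have the documented geometry", {
  expect_equal(nrow(struct_el("cube", 0)$offsets), 1L)     # identity
  expect_equal(nrow(struct_el("cross", 1)$offsets), 7L)    # unit element
  expect_equal(nrow(struct_el("ball", 1)$offsets), 7L)     # radius-1 ball = cross
  expect_equal(nrow(struct_el("cube", 1)$offsets), 27L)
  # centre symmetry
  for (sh in c("ball", "cube", "cross")) {
    o <- struct_el(sh, c(2, 1, 1))$offsets
    key <- function(m) sort(unname(apply(m, 1, paste, collapse = ",")))
    expect_equal(key(o), key(-o))
  }
  # anisotropic ball: radius 0 along z restricts offsets to the plane
  o <- struct_el("ball", c(2, 2, 0))$offsets
  expect_true(all(o[, 3] == 0))
  expect_error(struct_el("ball", -1), "non-negative")
})

test_that("geodesic dilation follows min(dilate, mask) and its contract", {
  line <- struct_el("cross", c(1, 0, 0))
  marker <- arr1d(c(0, 0, 0, 2, 0))
  mask <- arr1d(c(1, 0, 3, 5, 2))
  expect_equal(geodesic_dilate(marker, mask, line), arr1d(c(0, 0, 2, 2, 2)))
  # fixed point when marker == mask
  expect_equal(geodesic_dilate(mask, mask, line), mask)
  # constant global-minimum marker cannot grow anywhere
  cmin <- arr1d(rep(0, 5))
  expect_equal(geodesic_dilate(cmin, mask, line), pmin(arr1d(rep(0, 5)), mask))
  expect_error(geodesic_dilate(mask, marker, line), "marker <= mask")
})

test_that("reconstruction by dilation reaches the fixed point of the iteration", {
  marker <- arr1d(c(0, 0, 0, 2, 0))
  mask <- arr1d(c(1, 0, 3, 5, 2))
  expect_equal(reconstruct_by_dilation(marker, mask), arr1d(c(0, 0, 2, 2, 2)))
  expect_equal(reconstruct_by_dilation(mask, mask), mask)
  # binary flooding: a single seed voxel recovers its whole component
  m <- array(FALSE, c(7, 7, 3))
  m[2:3, 2:3, 1:2] <- TRUE      # component A
  m[5:6, 5:6, 2:3] <- TRUE      # component B
  seed <- array(FALSE, dim(m)); seed[2, 2, 1] <- TRUE
  rec <- reconstruct_by_dilation(seed, m)
  expect_equal(rec, m & (label_components(m, 6) == label_components(m, 6)[2, 2, 1]))
})

test_that("reconstruction matches the naive fixed-point oracle on random volumes", {
  set.seed(11)
  for (i in 1:25) {
    mask <- array(as.double(sample(0:9, 6^3, TRUE)), c(6, 6, 6))
    marker <- pmin(mask, array(as.double(sample(0:9, 6^3, TRUE)), c(6, 6, 6)))
    expect_identical(reconstruct_by_dilation(marker, mask),
                     naive_reconstruct(marker, mask))
  }
})

test_that("hmax suppresses shallow maxima per its reconstruction definition", {
  img <- arr1d(c(0, 3, 1, 5, 0))
  expect_equal(hmax(img, 0), img)                          # identity at h = 0
  expect_equal(hmax(array(7, c(3, 3, 3)), 2), array(5, c(3, 3, 3)))  # constant
  # the peak of dynamic 2 is levelled, the tall peak drops by h
  expect_equal(hmax(img, 2), naive_reconstruct(img - 2, img))
  expect_equal(hmax(img, 2), arr1d(c(0, 1, 1, 3, 0)))
  expect_error(hmax(img, -1), "non-negative")
})

test_that("hmax is monotone in h, bounded, and never drops more than h", {
  set.seed(7)
  for (i in 1:10) {
    img <- array(as.double(sample(0:20, 5^3, TRUE)), c(5, 5, 5))
    h1 <- hmax(img, 3); h2 <- hmax(img, 8)
    expect_true(all(h1 >= h2))            # monotone
    expect_true(all(h1 <= img) && all(img - h1 <= 3 + 1e-12))
    expect_true(all(h2 <= img) && all(img - h2 <= 8 + 1e-12))
  }
})

test_that("opening and closing are idempotent and act as expected on blobs", {
  se <- struct_el("ball", 1)
  # isolated voxel is erased by opening
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  expect_false(any(morph_open(m, se)))
  # identity element leaves masks unchanged
  expect_equal(morph_open(m, struct_el("cube", 0)), m)
  # two slabs one voxel apart are bridged into one component by closing
  m2 <- array(FALSE, c(7, 5, 5))
  m2[2:3, 2:4, 2:4] <- TRUE
  m2[5:6, 2:4, 2:4] <- TRUE
  expect_equal(max(label_components(m2)), 2L)
  closed <- morph_close(m2, se)
  expect_equal(max(label_components(closed)), 1L)
  expect_true(all(closed[m2]))            # closing is extensive
  # idempotence on random masks and volumes
  set.seed(21)
  for (i in 1:5) {
    r <- rand_mask(c(6, 6, 6), 0.4)
    expect_equal(morph_open(morph_open(r, se), se), morph_open(r, se))
    expect_equal(morph_close(morph_close(r, se), se), morph_close(r, se))
    v <- array(as.double(sample(0:9, 6^3, TRUE)), c(6, 6, 6))
    expect_equal(morph_open(morph_open(v, se), se), morph_open(v, se))
  }
})

test_that("hole filling closes enclosed cavities but not border-connected tunnels", {
  shell <- array(FALSE, c(5, 5, 5))
  shell[1:5, 1:5, 1:5] <- TRUE
  shell[2:4, 2:4, 2:4] <- FALSE           # hollow cube
  expect_true(all(fill_holes(shell)))
  solid <- array(TRUE, c(4, 4, 4))
  expect_equal(fill_holes(solid), solid)  # no holes: unchanged
  # tunnel open to the border stays open
  tun <- array(TRUE, c(5, 5, 5))
  tun[3, 3, 1:5] <- FALSE
  expect_equal(fill_holes(tun), tun)
})

test_that("small-object removal filters by 26-connected component size", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:2, 1:2, 1:2] <- TRUE                       # 8 voxels... make it 3
  m[1:2, 1:2, 1:2] <- FALSE
  m[1, 1:3, 1] <- TRUE                           # size 3
  m[5:9, 5:9, 5:6] <- TRUE                       # size 50
  expect_equal(sort(unique(tabulate(label_components(m)[label_components(m) > 0]))),
               c(3L, 50L))
  out <- remove_small_objects(m, 10)
  expect_equal(sum(out), 50)
  expect_equal(remove_small_objects(m, 0), m)    # identity
  empty <- array(FALSE, c(4, 4, 4))
  expect_equal(remove_small_objects(empty, 5), empty)
  # surviving components all reach the floor
  set.seed(3)
  r <- rand_mask(c(8, 8, 8), 0.2)
  out <- remove_small_objects(r, 4)
  sz <- tabulate(label_components(out)[label_components(out) > 0])
  expect_true(all(sz >= 4))
})

test_that("border-touching objects are removed on the box's lateral faces only", {
  dm <- c(10, 10, 6)
  box <- bbox(c(2, 2, 1), c(9, 9, 6))
  inner <- array(FALSE, dm); inner[6:7, 6:7, 2:5] <- TRUE
  expect_equal(remove_border_touching(inner, box), inner)   # interior kept
  crossing <- array(FALSE, dm); crossing[2:4, 2:3, 2:4] <- TRUE  # touches x face
  expect_false(any(remove_border_touching(crossing, box)))
  both <- inner | crossing
  expect_equal(remove_border_touching(both, box), inner)    # exactly one survives
  # z faces are exempt: a column spanning the full z range survives
  column <- array(FALSE, dm); column[5, 5, 1:6] <- TRUE
  expect_equal(remove_border_touching(column, box), column)
})
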