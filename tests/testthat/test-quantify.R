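# Core quantification: local-contrast map, thresholding, per-slice
# clustering, grading, volume normalization, enlargement criterion.

vol_from <- function(arr, spacing = c(0.8, 0.8, 4.4)) {
  image_volume(arr, spacing = spacing, modality = "T2")
}

full_mask <- function(vol) binary_mask(array(TRUE, dim(vol$voxels)), vol)

test_that("difference map: closed forms on constant and single-voxel inputs", {
  arr <- array(1000, c(7, 7, 3))
  t2 <- vol_from(arr)
  dm <- neighborhood_difference_map(t2, full_mask(t2))
  expect_true(all(dm$values == 0))

  arr[4, 4, 2] <- 1300
  t2 <- vol_from(arr)
  dm <- neighborhood_difference_map(t2, full_mask(t2))
  # bright voxel: value minus mean of its 8 in-plane neighbours
  expect_equal(dm$values[4, 4, 2], 300)
  # each in-plane neighbour of the bright voxel: one neighbour is bright
  expect_equal(dm$values[3, 3, 2], 1000 - (7 * 1000 + 1300) / 8)
  # adjacent slice untouched (in-plane neighbourhood)
  expect_true(all(dm$values[, , 1] == 0))
})

test_that("difference map is zero outside the mask and errors on bad input", {
  arr <- array(1000, c(5, 5, 2))
  arr[2, 2, 1] <- 1200
  t2 <- vol_from(arr)
  m <- array(FALSE, c(5, 5, 2)); m[2:4, 2:4, 1] <- TRUE
  dm <- neighborhood_difference_map(t2, binary_mask(m, t2))
  expect_true(all(dm$values[!m] == 0))
  expect_error(neighborhood_difference_map(t2, binary_mask(array(FALSE, c(5, 5, 2)), t2)),
               "empty")
  expect_error(neighborhood_spec(radius = 0), "radius")
})

test_that("difference map matches the brute-force oracle on random grids", {
  set.seed(42)
  for (rep in 1:10) {
    arr <- array(rnorm(7 * 7 * 3, 1000, 50), c(7, 7, 3))
    m <- array(runif(7 * 7 * 3) < 0.7, c(7, 7, 3))
    m[4, 4, 2] <- TRUE  # never empty
    t2 <- vol_from(arr)
    mask <- binary_mask(m, t2)
    for (incl in c(TRUE, FALSE)) {
      dm <- neighborhood_difference_map(
        t2, mask, neighborhood_spec(include_outside_mask = incl))
      expect_equal(dm$values,
                   oracle_diff_map(arr, m, include_outside_mask = incl),
                   tolerance = 1e-12)
    }
    # 3D 26-neighbour mode against the oracle too
    dm3 <- neighborhood_difference_map(t2, mask, neighborhood_spec(type = "3d"))
    expect_equal(dm3$values, oracle_diff_map(arr, m, inplane = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("detection threshold is strict: exactly 60 is not PVS", {
  arr <- array(1000, c(5, 5, 1))
  arr[3, 3, 1] <- 1000 + 60 * 8 / 8  # diff of exactly 60
  t2 <- vol_from(arr)
  dm <- neighborhood_difference_map(t2, full_mask(t2))
  expect_equal(dm$values[3, 3, 1], 60)
  expect_false(detect_pvs_voxels(dm, 60)$voxels[3, 3, 1])

  arr[3, 3, 1] <- 1000 + 60 + 1e-6
  dm <- neighborhood_difference_map(vol_from(arr), full_mask(t2))
  expect_true(detect_pvs_voxels(dm, 60)$voxels[3, 3, 1])

  expect_error(detect_pvs_voxels(dm, Inf), "finite")
})

test_that("raising the threshold never increases detected counts", {
  set.seed(7)
  arr <- array(rnorm(16 * 16 * 4, 1000, 80), c(16, 16, 4))
  t2 <- vol_from(arr)
  dm <- neighborhood_difference_map(t2, full_mask(t2))
  prev <- Inf
  for (thr in c(20, 40, 60, 80, 120)) {
    n <- sum(detect_pvs_voxels(dm, thr)$voxels)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("clustering: corner touch joins, adjacent slices split", {
  ref <- vol_from(array(0, c(6, 6, 2)))
  m <- array(FALSE, c(6, 6, 2))
  m[2, 2, 1] <- TRUE; m[3, 3, 1] <- TRUE  # corner contact only
  cl <- label_clusters_per_slice(binary_mask(m, ref))
  expect_equal(cl$counts, c(1L, 0L))

  m2 <- array(FALSE, c(6, 6, 2))
  m2[4, 4, 1] <- TRUE; m2[4, 4, 2] <- TRUE  # same in-plane spot, 2 slices
  cl2 <- label_clusters_per_slice(binary_mask(m2, ref))
  expect_equal(cl2$counts, c(1L, 1L))
  expect_equal(length(unique(cl2$labels[cl2$labels > 0])), 2L)
})

test_that("clustering matches the flood-fill oracle on 50 random masks", {
  set.seed(99)
  for (rep in 1:50) {
    m <- array(runif(16 * 16 * 4) < 0.25, c(16, 16, 4))
    ref <- vol_from(array(0, dim(m)))
    cl <- label_clusters_per_slice(binary_mask(m, ref))
    orc <- oracle_label_slices(m)
    expect_identical(cl$counts, orc$counts)
    # labellings agree as partitions: same co-membership per slice
    for (k in 1:4) {
      a <- cl$labels[, , k][m[, , k]]
      b <- orc$labels[, , k][m[, , k]]
      expect_equal(length(unique(a)), length(unique(b)))
      expect_true(all(tapply(b, a, function(v) length(unique(v))) == 1))
    }
  }
})

test_that("slice axis is inferred from the dominant spacing", {
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  iso <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_error(label_clusters_per_slice(binary_mask(m, iso)), "ambiguous")
  expect_silent(label_clusters_per_slice(binary_mask(m, iso), slice_axis = 3))
  # thick axis = 1: slices must be split along axis 1
  v1 <- image_volume(array(0, c(4, 4, 4)), spacing = c(4.4, 0.8, 0.8))
  m1 <- array(FALSE, c(4, 4, 4)); m1[1, 2, 2] <- TRUE; m1[2, 2, 2] <- TRUE
  cl <- label_clusters_per_slice(binary_mask(m1, v1))
  expect_equal(cl$slice_axis, 1L)
  expect_equal(cl$counts, c(1L, 1L, 0L, 0L))
})

test_that("grade bins follow the 5-point scale at every boundary", {
  cases <- c(0, 1, 10, 11, 20, 21, 40, 41, 100, 1000)
  grades <- c(0, 1, 1, 2, 2, 3, 3, 4, 4, 4)
  for (i in seq_along(cases))
    expect_identical(grade_from_max_count(cases[i]), as.integer(grades[i]))
  expect_identical(grade_from_max_count(c(0, 3, 17, 2)), 2L)
  expect_error(grade_from_max_count(integer(0)), "empty")
  expect_error(grade_from_max_count(-1), "non-negative")
  sc <- grade_scale()
  expect_equal(sc$min_count[-1] - 1, sc$max_count[-5])  # contiguous bins
})

test_that("summarize_pvs: normalization, empty mask handling", {
  ref <- vol_from(array(0, c(20, 20, 5)))
  wm <- array(FALSE, c(20, 20, 5)); wm[3:18, 3:18, ] <- TRUE  # 1280 voxels
  pvs <- array(FALSE, c(20, 20, 5))
  pvs[5, 5, 2] <- TRUE; pvs[10:11, 10, 3] <- TRUE
  res <- summarize_pvs(binary_mask(pvs, ref), binary_mask(wm, ref))
  expect_equal(res$pvs_voxel_count, 3)
  expect_equal(res$normalized_volume, 3 / sum(wm))
  expect_equal(res$max_slice_count, 1L)
  expect_equal(res$grade, 1L)

  empty <- binary_mask(array(FALSE, c(20, 20, 5)), ref)
  res0 <- summarize_pvs(empty, binary_mask(wm, ref))
  expect_equal(res0$pvs_voxel_count, 0)
  expect_equal(res0$grade, 0L)
  expect_false(res0$enlargement)
  expect_error(summarize_pvs(empty, empty), "empty white-matter")
})

test_that("enlargement: at least 3 clusters wider than 3 mm, minor axis", {
  ref <- image_volume(array(0, c(40, 40, 3)), spacing = c(0.4, 0.4, 4.4))
  mk <- function(blocks) {
    m <- array(FALSE, c(40, 40, 3))
    for (b in blocks) m[b$i, b$j, b$k] <- TRUE
    label_clusters_per_slice(binary_mask(m, ref))
  }
  # 8 voxels across at 0.4 mm = 3.2 mm > 3 mm; three such clusters -> TRUE
  wide3 <- mk(list(list(i = 1:8, j = 2, k = 1), list(i = 1:8, j = 6, k = 2),
                   list(i = 20:27, j = 30, k = 3)))
  expect_false(enlargement_flag(wide3))  # 8x1 line: minor axis 1 voxel
  # 8x8 squares are wide along BOTH axes
  sq3 <- mk(list(list(i = 1:8, j = 1:8, k = 1), list(i = 20:27, j = 20:27, k = 2),
                 list(i = 30:37, j = 1:8, k = 3)))
  expect_true(enlargement_flag(sq3))
  # only 2 wide clusters plus many thin ones -> FALSE ("at least 3")
  two <- mk(list(list(i = 1:8, j = 1:8, k = 1), list(i = 20:27, j = 20:27, k = 2),
                 list(i = 35, j = 30, k = 1), list(i = 38, j = 30, k = 2),
                 list(i = 35, j = 35, k = 3)))
  expect_false(enlargement_flag(two))
  # no clusters -> FALSE
  expect_false(enlargement_flag(mk(list())))
})

test_that("minor diameter uses the minimum-area box, not the axis-aligned one", {
  ref <- image_volume(array(0, c(30, 30, 1)), spacing = c(0.4, 0.4, 4.4))
  # diagonal line of voxels: axis-aligned box is square, true minor axis ~1 voxel
  m <- array(FALSE, c(30, 30, 1))
  for (t in 0:9) m[5 + t, 5 + t, 1] <- TRUE
  d <- cluster_minor_diameters(label_clusters_per_slice(binary_mask(m, ref)))
  expect_lt(d, 3)            # a thin diagonal PVS is not "enlarged"
  expect_lt(d, 10 * 0.4)     # much smaller than its length
  # single voxel: one voxel extent
  m1 <- array(FALSE, c(30, 30, 1)); m1[4, 4, 1] <- TRUE
  expect_equal(cluster_minor_diameters(label_clusters_per_slice(binary_mask(m1, ref))),
               0.4)
})

test_that("permuting slices permutes counts and preserves max and grade", {
  set.seed(3)
  m <- array(runif(12 * 12 * 6) < 0.2, c(12, 12, 6))
  ref <- vol_from(array(0, dim(m)))
  cl <- label_clusters_per_slice(binary_mask(m, ref))
  perm <- sample(6)
  clp <- label_clusters_per_slice(binary_mask(m[, , perm], ref))
  expect_identical(clp$counts, cl$counts[perm])
  expect_identical(max(clp$counts), max(cl$counts))
  expect_identical(grade_from_max_count(clp$counts), grade_from_max_count(cl$counts))
})
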