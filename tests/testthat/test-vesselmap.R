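test_that("vesselness of a constant frame is all zero", {
  expect_true(all(vesselness_filter(matrix(0.7, 40, 40)) == 0))
})

test_that("vesselness ridge peaks on the band midline", {
  n <- 64
  fr <- band_frame(n, 10, 0)
  resp <- vesselness_filter(fr)
  mid <- (n + 1) / 2
  # the band is mirror-symmetric, so maxima come in symmetric near-ties;
  # the centroid of the per-column maximal set must sit on the midline and
  # the midline response itself must be at (or within a hair of) the max
  for (j in 10:(n - 10)) {
    col <- resp[, j]
    top <- which(col >= max(col) * (1 - 1e-6))
    expect_lt(abs(mean(top) - mid), 1)
    expect_gte(col[32], 0.95 * max(col))
  }
})

test_that("widely different vessel widths both respond with covering scales", {
  n <- 96
  fr <- matrix(0.8, n, n)
  fr[abs(row(fr) - 24) <= 3] <- 0.3   # width-6 horizontal band at row 24
  fr[abs(row(fr) - 72) <= 15] <- 0.3  # width-30 band at row 72
  resp <- vesselness_filter(fr)
  expect_gt(resp[24, 48] / max(resp), 0.5)
  expect_gt(resp[72, 48] / max(resp), 0.5)
})

test_that("binarize handles zero response and recovers a band", {
  empty <- binarize(matrix(0, 30, 30))
  expect_false(any(empty$binary))
  n <- 64
  fr <- band_frame(n, 10, 30)
  mask <- binarize(vesselness_filter(fr), frame = fr)
  truth <- band_truth_mask(n, 10, 30)
  covered <- sum(mask$binary & truth) / sum(truth)
  false_pos <- sum(mask$binary & !truth) / max(1, sum(mask$binary))
  expect_gte(covered, 0.9)
  expect_lte(false_pos, 0.1)
  expect_equal(max(EBImage::bwlabel(mask$binary * 1)), 1)
})

test_that("hysteresis keeps only ridges seeded above the high threshold", {
  resp <- matrix(0, 40, 40)
  resp[10, 5:35] <- 1.0    # strong ridge
  resp[30, 5:35] <- 0.08   # weak ridge below the high fraction
  mask <- binarize(resp, low = 0.05, high = 0.15, min_area = 5)
  expect_true(any(mask$binary[10, ]))
  expect_false(any(mask$binary[30, ]))
  expect_equal(max(EBImage::bwlabel(mask$binary * 1)), 1)
})

test_that("skeleton of a straight band is its midline, 1 px wide", {
  n <- 64
  bin <- band_truth_mask(n, 10, 0)
  sk <- skeletonize_mask(bin)
  mid <- (n + 1) / 2
  pts <- which(sk, arr.ind = TRUE)
  expect_true(all(abs(pts[, 1] - mid) <= 1))
  expect_true(all(table(pts[, 2]) == 1))
  expect_false(any(skeletonize_mask(matrix(FALSE, 20, 20))))
})

test_that("skeletonization preserves the number of components", {
  n <- 80
  comb <- matrix(FALSE, n, n)
  comb[20:27, 10:70] <- TRUE   # horizontal bar
  comb[50:70, 15:22] <- TRUE   # disjoint vertical bar
  comb[55:62, 40:75] <- TRUE   # another disjoint bar
  sk <- skeletonize_mask(comb)
  expect_equal(max(EBImage::bwlabel(sk * 1)),
               max(EBImage::bwlabel(comb * 1)))
})

test_that("plus-shaped mask yields exactly one branch cluster", {
  n <- 61
  bin <- matrix(FALSE, n, n)
  bin[28:34, 6:56] <- TRUE
  bin[6:56, 28:34] <- TRUE
  sk <- skeletonize_mask(bin)
  nd <- detect_nodes(sk)
  expect_equal(length(unique(nd$branch_points$cluster)), 1)
  expect_equal(nrow(nd$end_points), 4)
})

test_that("node detection matches line, Y and loop topologies", {
  line <- matrix(FALSE, 20, 20)
  line[10, 3:17] <- TRUE
  nd <- detect_nodes(line)
  expect_equal(nrow(nd$end_points), 2)
  expect_equal(nrow(nd$branch_points), 0)

  ys <- matrix(FALSE, 30, 30)
  ys[15, 3:15] <- TRUE
  for (k in 1:10) { ys[15 - k, 15 + k] <- TRUE; ys[15 + k, 15 + k] <- TRUE }
  nd <- detect_nodes(ys)
  expect_equal(nrow(nd$end_points), 3)
  expect_equal(length(unique(nd$branch_points$cluster)), 1)

  th <- seq(0, 2 * pi, length.out = 200)
  loop <- matrix(FALSE, 40, 40)
  loop[cbind(round(20 + 12 * cos(th)), round(20 + 12 * sin(th)))] <- TRUE
  loop <- skeletonize_mask(loop)
  nd <- detect_nodes(loop)
  expect_equal(nrow(nd$end_points), 0)
  expect_equal(nrow(nd$branch_points), 0)
})

test_that("a single band becomes one segment with the band diameter", {
  n <- 64
  fr <- band_frame(n, 10, 20)
  vm <- suppressMessages(map_vessels(fr, cal_2um()))
  expect_equal(nrow(vm$segments), 1)
  expect_equal(vm$segments$diameter_um, 20, tolerance = 0.1)  # 10 px at 2 um/px
})

test_that("a Y-shaped vessel splits into three segments", {
  n <- 81
  fr <- matrix(0.8, n, n)
  stem <- abs(row(fr) - 41) <= 3 & col(fr) <= 41
  arm1 <- abs((row(fr) - 41) - (col(fr) - 41)) <= 3 & col(fr) >= 41
  arm2 <- abs((row(fr) - 41) + (col(fr) - 41)) <= 3 & col(fr) >= 41
  fr[stem | arm1 | arm2] <- 0.3
  vm <- suppressMessages(map_vessels(fr, cal_2um(), min_length_px = 8))
  expect_equal(nrow(vm$segments), 3)
})

test_that("narrow band lands in diameter group 1", {
  n <- 64
  fr <- band_frame(n, 3, 0)
  vm <- suppressMessages(map_vessels(fr, calibration_profile(1.5, 60),
                                     scales = c(1, 1.5, 3, 6)))
  expect_equal(nrow(vm$segments), 1)
  expect_equal(vm$segments$diameter_um, 4.5, tolerance = 1.5)
  expect_equal(assign_group(vm$segments$diameter_um), 1L)
})

test_that("segment pixels and node pixels partition the skeleton", {
  n <- 81
  fr <- matrix(0.8, n, n)
  stem <- abs(row(fr) - 41) <= 3 & col(fr) <= 41
  arm1 <- abs((row(fr) - 41) - (col(fr) - 41)) <= 3 & col(fr) >= 41
  arm2 <- abs((row(fr) - 41) + (col(fr) - 41)) <= 3 & col(fr) >= 41
  fr[stem | arm1 | arm2] <- 0.3
  resp <- vesselness_filter(fr)
  mask <- binarize(resp, frame = fr)
  sk <- skeletonize_mask(mask)
  nd <- detect_nodes(sk)
  segs <- suppressMessages(split_segments(sk, nd, mask, cal_2um(),
                                          min_length_px = 0))
  node_keys <- c(paste(nd$branch_points$row, nd$branch_points$col),
                 paste(nd$end_points$row, nd$end_points$col))
  seg_keys <- unlist(lapply(segs$points, function(p) paste(p[, 1], p[, 2])))
  interior <- setdiff(unique(seg_keys), node_keys)
  # every interior pixel claimed exactly once, and the union is the skeleton
  interior_counts <- table(seg_keys[!(seg_keys %in% node_keys)])
  expect_true(all(interior_counts == 1))
  expect_setequal(union(interior, node_keys),
                  apply(which(sk, arr.ind = TRUE), 1, paste, collapse = " "))
})

test_that("diameter estimation is rotation invariant within 2 percent", {
  n <- 72
  fr <- band_frame(n, 12, 25)
  d0 <- suppressMessages(map_vessels(fr, cal_1um()))$segments$diameter_um[1]
  d90 <- suppressMessages(map_vessels(t(fr)[n:1, ], cal_1um()))$segments$diameter_um[1]
  expect_equal(d90, d0, tolerance = 0.02)
})

test_that("diameters across widths and orientations stay within 1.5 px", {
  # compact sweep; the acceptance suite runs the full grid
  for (w in c(4, 12, 28)) {
    for (th in c(0, 45, 105)) {
      vm <- suppressMessages(map_vessels(band_frame(96, w, th), cal_1um()))
      expect_gt(nrow(vm$segments), 0)
      d <- vm$segments$diameter_um[which.max(vm$segments$n_points)]
      expect_lt(abs(d - w), 1.5)
    }
  }
})
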