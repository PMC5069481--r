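test_that("Otsu matches exhaustive between-class-variance search", {
  for (seed in 1:8) {
    data <- withr::with_seed(seed, {
      n <- 6
      x <- c(stats::rnorm(80, 40, 12), stats::rnorm(136, 180, 25))
      array(x[sample.int(216)], c(n, n, n))
    })
    vol <- voxel_volume(data, 1)
    expect_equal(otsu_threshold(vol), brute_otsu(as.vector(data)),
                 tolerance = 1e-12)
  }
})

test_that("Otsu on a two-level image splits the levels; constant image errors", {
  data <- array(10, c(4, 4, 4))
  data[1:2, , ] <- 200
  t <- otsu_threshold(voxel_volume(data, 1))
  expect_gt(t, 10)
  expect_lt(t, 200)
  expect_error(otsu_threshold(voxel_volume(array(7, c(3, 3, 3)), 1)),
               "constant")
  # ROI-restricted histogram ignores intensities outside the ROI
  roi <- binary_mask(array(rep(c(TRUE, FALSE), each = 32), c(4, 4, 4)), 1, "roi")
  data2 <- data
  data2[!roi$data] <- 5000
  expect_equal(otsu_threshold(voxel_volume(data2, 1), roi), t)
})

test_that("binarize honours polarity and thresholds are complementary", {
  data <- withr::with_seed(5, array(sample(0:255, 125, TRUE), c(5, 5, 5)))
  vol <- voxel_volume(data, 2)
  above <- binarize(vol, 100, "above")
  below <- binarize(vol, 100, "below")
  expect_identical(above$data, !below$data)
  expect_true(all(binarize(vol, -1, "above")$data))
  expect_equal(above$voxel_size_um, 2)
  expect_equal(above$phase_name, "bone")
  expect_equal(below$phase_name, "pore")
})

test_that("ball closing fills small gaps, keeps closed sets, is idempotent", {
  cube <- binary_mask(array(TRUE, c(5, 5, 5)), 1, "bone")
  expect_identical(morphological_closing(cube, 2)$data, cube$data)
  # single-voxel hole in a 3-voxel-thick plate, radius 1 fills it
  pl <- array(FALSE, c(9, 9, 7))
  pl[2:8, 2:8, 3:5] <- TRUE
  pl[5, 5, 4] <- FALSE
  closed <- morphological_closing(binary_mask(pl, 1, "bone"), 1)
  expect_true(closed$data[5, 5, 4])
  for (seed in 1:4) {
    m <- binary_mask(random_mask(seed, c(9, 9, 9), 0.25), 1, "bone")
    once <- morphological_closing(m, 1)
    twice <- morphological_closing(once, 1)
    expect_identical(once$data, twice$data)
    expect_true(all(once$data >= m$data))  # extensive
  }
})

test_that("volume-to-voxel conversion reproduces the despeckle voxel counts", {
  expect_identical(volume_to_voxels(280, 2), 35L)
  expect_identical(volume_to_voxels(280, 1), 280L)
  expect_identical(volume_to_voxels(8, 2), 1L)
  expect_error(volume_to_voxels(0, 2), "positive")
  expect_error(volume_to_voxels(280, 0), "positive")
})

test_that("component labelling matches a flood-fill oracle at all connectivities", {
  # two disjoint cubes
  m <- array(FALSE, c(8, 8, 8))
  m[1:3, 1:3, 1:3] <- TRUE
  m[6:8, 6:8, 6:8] <- TRUE
  lc <- label_components(binary_mask(m, 2, "pore"), 26)
  expect_equal(nrow(lc$table), 2)
  expect_equal(sort(lc$table$voxels), c(27, 27))
  expect_equal(lc$table$volume_um3, lc$table$voxels * 8)
  # corner-touching voxels join at 26 but not at 6
  c2 <- array(FALSE, c(3, 3, 3))
  c2[1, 1, 1] <- TRUE
  c2[2, 2, 2] <- TRUE
  expect_equal(nrow(label_components(binary_mask(c2, 1, "p"), 6)$table), 2)
  expect_equal(nrow(label_components(binary_mask(c2, 1, "p"), 26)$table), 1)
  for (seed in 1:5) {
    mm <- random_mask(seed, c(8, 8, 8), 0.2)
    for (conn in c(6L, 18L, 26L)) {
      got <- label_components(binary_mask(mm, 1, "p"), conn)
      oracle <- flood_fill_components(mm, conn)
      expect_equal(nrow(got$table), length(oracle$counts))
      expect_equal(sort(got$table$voxels), sort(oracle$counts))
    }
  }
})

test_that("despeckle removes sub-threshold components and is monotone", {
  # one 10-voxel and one 50-voxel component at 2 um; 280 um^3 keeps only
  # the 50-voxel (400 um^3) component
  m <- array(FALSE, c(20, 10, 6))
  m[1:5, 1:2, 1] <- TRUE               # 10 voxels = 80 um^3
  m[8:17, 1:5, 2] <- TRUE              # 50 voxels = 400 um^3
  mask <- binary_mask(m, 2, "pore")
  out <- despeckle(mask, 280, "white")
  expect_equal(sum(out$data), 50)
  expect_identical(despeckle(mask, 0, "white")$data, mask$data)
  # survival is inclusive: a 35-voxel component at 2 um (= 280 um^3) survives,
  # 34 voxels (272 um^3) does not
  m2 <- array(FALSE, c(40, 6, 6))
  m2[1:35, 1, 1] <- TRUE
  expect_equal(sum(despeckle(binary_mask(m2, 2, "p"), 280, "white")$data), 35)
  m2[35, 1, 1] <- FALSE
  expect_equal(sum(despeckle(binary_mask(m2, 2, "p"), 280, "white")$data), 0)
  for (seed in 1:4) {
    mm <- binary_mask(random_mask(seed, c(10, 10, 10), 0.15), 1, "p")
    d1 <- despeckle(mm, 3, "white")
    d2 <- despeckle(mm, 7, "white")
    expect_true(all(d1$data >= d2$data))           # monotone in threshold
    expect_true(all(mm$data >= d1$data))           # pure filter
    expect_identical(despeckle(d1, 7, "white")$data, d2$data)  # composition
  }
})

test_that("black-phase despeckle fills small background holes", {
  m <- array(TRUE, c(7, 7, 7))
  m[4, 4, 4] <- FALSE                   # 1-voxel hole
  m[1, 1, ] <- FALSE                    # border-touching background channel
  out <- despeckle(binary_mask(m, 1, "bone"), 2, "black")
  expect_true(out$data[4, 4, 4])
  expect_false(any(out$data[1, 1, ]))   # 7-voxel channel survives at 2 um^3
})

test_that("upper despeckle isolates the lacunar class", {
  m <- array(FALSE, c(30, 30, 10))
  m[1:10, 1:10, 1:5] <- TRUE            # 500 voxels = 4000 um^3 at 2 um
  m[20:24, 20:24, 1:5] <- TRUE          # 125 voxels = 1000 um^3
  mask <- binary_mask(m, 2, "pore")
  out <- despeckle_upper(mask, 4000)
  expect_equal(sum(out$data), 625)      # exactly 4000 survives (> only)
  out2 <- despeckle_upper(mask, 3999)
  expect_equal(sum(out2$data), 125)
  expect_identical(despeckle_upper(mask, Inf)$data, mask$data)
})

test_that("cortical ROI recovers the annulus and excludes only the marrow", {
  ph <- make_cortical_phantom(small_cortical_spec(2))
  bone <- binarize(ph$volume, 110, "above")
  roi <- fit_cortical_roi(bone, closing_radius_um = 10)
  # ROI volume close to the analytic wall volume
  v3 <- ph$volume$voxel_size_um^3
  expect_lt(abs(sum(roi$data) * v3 - ph$truth$wall_volume_um3) /
              ph$truth$wall_volume_um3, 0.02)
  # ROI minus bone is exactly the rasterized pore set (pores are interior)
  pores_direct <- ph$volume$data < 110 & roi$data
  expect_identical(roi$data & !bone$data, pores_direct)
  expect_gte(sum(roi$data & !bone$data), 1)
  # ROI contains the cortex bone
  expect_true(all(roi$data[bone$data & roi$data]))
  expect_error(fit_cortical_roi(binary_mask(array(FALSE, c(4, 4, 4)), 1, "b")),
               "empty")
})

test_that("marrow filling turns the annulus into the full disc", {
  m <- tube_mask(40, 12, 8, 16)
  roi <- binary_mask(m, 1, "roi")
  filled <- fill_marrow(roi)
  expect_true(all(filled$data >= roi$data))
  # per-slice area close to pi * ro^2
  a <- sum(filled$data[, , 6])
  expect_lt(abs(a - pi * 16^2) / (pi * 16^2), 0.02)
})

test_that("principal-axis alignment straightens a tilted rod", {
  d <- c(40, 40, 60)
  co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  tilt <- 10 * pi / 180
  ax <- c(sin(tilt), 0, cos(tilt))
  ctr <- c(20, 20, 30)
  rel <- sweep(co, 2, ctr)
  along <- rel %*% ax
  rad2 <- rowSums((rel - along %*% t(ax))^2)
  rod <- array(as.numeric(rad2 <= 36 & abs(along) <= 25) * 180 + 20, d)
  vol <- voxel_volume(rod, 1)
  out <- align_to_axis(vol, threshold = 100)
  fg <- which(out$data >= 100, arr.ind = TRUE)
  pc <- stats::prcomp(fg)
  angle <- acos(abs(pc$rotation[3, 1])) * 180 / pi
  expect_lt(angle, 1)
  # a sphere has no principal axis: warn and return unchanged
  sph <- array(20, c(20, 20, 20))
  co2 <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  sph[rowSums(sweep(co2, 2, c(10, 10, 10))^2) <= 49] <- 200
  expect_warning(align_to_axis(voxel_volume(sph, 1), 100), "principal axis")
})
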