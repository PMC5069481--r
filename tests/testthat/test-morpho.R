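test_that("local thickness matches the exhaustive maximal-sphere oracle", {
  shapes <- list(
    { m <- array(FALSE, c(7, 7, 7)); m[, , 3:5] <- TRUE; m },           # slab
    { m <- array(FALSE, c(9, 9, 9))
      co <- as.matrix(expand.grid(1:9, 1:9, 1:9))
      m[rowSums(sweep(co, 2, c(5, 5, 5))^2) <= 9] <- TRUE; m },          # ball
    random_mask(21, c(7, 7, 7), 0.3),
    random_mask(22, c(8, 8, 6), 0.25))
  for (m in shapes) {
    for (bb in c(TRUE, FALSE)) {
      if (!any(m)) next
      if (!bb && all(m)) next
      mask <- binary_mask(m, 1, "bone")
      got <- local_thickness(mask, border = if (bb) "background" else "extend",
                             exact = TRUE)
      oracle <- brute_local_thickness(m, border_bg = bb)
      expect_equal(got$data[m], oracle[m], tolerance = 1e-9)
    }
  }
})

test_that("thickness is bounded by twice the EDT, with equality at sphere centers", {
  m <- random_mask(31, c(10, 10, 10), 0.35)
  mask <- binary_mask(m, 1, "bone")
  th <- local_thickness(mask, border = "background", exact = TRUE)
  e2 <- poroct:::cpp_edt_sq(m, dim(m), TRUE)
  expect_true(all(th$data[m] <= 2 * sqrt(e2[m]) + 1e-9))
  # the center of the globally largest inscribed sphere achieves equality
  l <- which.max(e2)
  expect_equal(th$data[l], 2 * sqrt(e2[l]))
})

test_that("slab and sphere thickness recover their analytic dimensions", {
  m <- array(FALSE, c(30, 30, 20))
  m[, , 6:13] <- TRUE                   # 8-voxel slab
  th <- local_thickness(binary_mask(m, 2, "bone"), border = "extend")
  vals <- th$data[m]
  expect_true(all(abs(vals - 16) <= 2 + 1e-9))   # t = 16 um, +/- 1 voxel
  expect_lt(abs(mean(vals) - 16), 2)
  sph <- array(FALSE, c(21, 21, 21))
  co <- as.matrix(expand.grid(1:21, 1:21, 1:21))
  sph[rowSums(sweep(co, 2, c(11, 11, 11))^2) <= 7.5^2] <- TRUE
  ths <- local_thickness(binary_mask(sph, 1, "bone"))
  expect_lt(abs(max(ths$data, na.rm = TRUE) - 15), 1.01)
})

test_that("thickness maps are invariant under 90-degree rotations", {
  m <- random_mask(44, c(9, 9, 9), 0.3)
  th0 <- local_thickness(binary_mask(m, 1, "b"), exact = TRUE)$data
  rot <- aperm(m, c(2, 3, 1))
  th1 <- local_thickness(binary_mask(rot, 1, "b"), exact = TRUE)$data
  expect_equal(aperm(th0, c(2, 3, 1)), th1)
})

test_that("BV/TV is a plain volume ratio with complement closure", {
  roi <- binary_mask(array(TRUE, c(6, 6, 6)), 1, "roi")
  bone <- binary_mask(array(FALSE, c(6, 6, 6)), 1, "bone")
  expect_equal(bvtv(bone, roi), 0)
  bone$data[1:3, , ] <- TRUE
  expect_equal(bvtv(bone, roi), 50)
  inv <- binary_mask(!bone$data, 1, "bone")
  expect_equal(bvtv(bone, roi) + bvtv(inv, roi), 100)
  full <- binary_mask(array(TRUE, c(6, 6, 6)), 1, "bone")
  expect_equal(bvtv(full, roi), 100)
  expect_error(bvtv(bone, binary_mask(array(FALSE, c(6, 6, 6)), 1, "roi")),
               "empty ROI")
})

test_that("plate lattice recovers Tb.Th, Tb.Sp, BV/TV and Tb.N", {
  ph <- make_trabecular_phantom(trabecular_phantom_spec("plates",
    element_thickness_um = 40, element_spacing_um = 200,
    domain_size_um = 600, render_voxel_um = 2))
  bone <- binarize(ph$volume, 110, "above")
  # interior ROI: inset by the largest separation sphere radius so border
  # clipping does not bias the means
  d <- dim(bone$data)
  roi <- array(FALSE, d)
  roi[41:(d[1] - 40), 41:(d[2] - 40), ] <- TRUE
  roi <- binary_mask(roi, 2, "roi")
  m <- trabecular_metrics(bone, roi)
  expect_equal(m$bvtv_pct, ph$truth$bvtv_pct, tolerance = 0.01)
  expect_lt(abs(m$tb_th_um - ph$truth$tb_th_um), 2.01)   # +/- 1 voxel
  expect_lt(abs(m$tb_sp_um - ph$truth$tb_sp_um), 2.01)
  expect_equal(m$tb_n_per_mm, ph$truth$tb_n_per_mm, tolerance = 0.06)
  expect_equal(sum(m$thickness_histogram$fraction), 1)
  # all-bone ROI flags the undefined separation
  allb <- binary_mask(array(TRUE, d), 2, "bone")
  expect_error(trabecular_metrics(allb, roi), "Tb.Sp undefined")
})

test_that("trabecular indices scale as lengths: Tb.N halves when sizes double", {
  s1 <- trabecular_phantom_spec("plates", element_thickness_um = 40,
                                element_spacing_um = 200,
                                domain_size_um = 400, render_voxel_um = 2)
  s2 <- trabecular_phantom_spec("plates", element_thickness_um = 80,
                                element_spacing_um = 400,
                                domain_size_um = 800, render_voxel_um = 4)
  p1 <- make_trabecular_phantom(s1)
  p2 <- make_trabecular_phantom(s2)
  # identical voxel grids at doubled physical scale
  expect_identical(p1$volume$data, p2$volume$data)
  b1 <- binarize(p1$volume, 110, "above")
  b2 <- binarize(p2$volume, 110, "above")
  roi1 <- binary_mask(array(TRUE, dim(b1$data)), 2, "roi")
  roi2 <- binary_mask(array(TRUE, dim(b2$data)), 4, "roi")
  m1 <- trabecular_metrics(b1, roi1)
  m2 <- trabecular_metrics(b2, roi2)
  expect_equal(m2$bvtv_pct, m1$bvtv_pct)
  expect_equal(m2$tb_th_um, 2 * m1$tb_th_um)
  expect_equal(m2$tb_sp_um, 2 * m1$tb_sp_um)
  expect_equal(m2$tb_n_per_mm, m1$tb_n_per_mm / 2)
})

test_that("cortical thickness recovers the wall of an ideal tube", {
  m <- tube_mask(120, 60, 35, 55)       # 20 um wall at 1 um
  roi <- binary_mask(m, 1, "roi")
  expect_lt(abs(ct_thickness(roi) - 20), 1.01)
  # 2 um rendering of the same tube agrees within 2%
  m2 <- tube_mask(60, 30, 35, 55, voxel = 2)
  roi2 <- binary_mask(m2, 2, "roi")
  expect_lt(abs(ct_thickness(roi2) - ct_thickness(roi)) / ct_thickness(roi),
            0.06)
  # thicker wall gives larger Ct.Th
  m3 <- tube_mask(120, 60, 25, 55)
  expect_gt(ct_thickness(binary_mask(m3, 1, "roi")), ct_thickness(roi))
})

test_that("outer diameter variants behave as radius and diameter of a disc", {
  n <- 160
  xs <- seq_len(n) - (n + 1) / 2
  disc <- outer(xs^2, xs^2, "+") <= 60^2
  filled <- binary_mask(array(rep(disc, 4), c(n, n, 4)), 1, "roi")
  expect_equal(ct_outer_diameter(filled, "as_printed"), 60, tolerance = 0.01)
  expect_equal(ct_outer_diameter(filled, "cylinder_corrected"), 120,
               tolerance = 0.01)
  # doubling the radius doubles both variants
  disc2 <- outer(xs^2, xs^2, "+") <= 30^2
  filled2 <- binary_mask(array(rep(disc2, 4), c(n, n, 4)), 1, "roi")
  expect_equal(ct_outer_diameter(filled, "as_printed") /
               ct_outer_diameter(filled2, "as_printed"), 2, tolerance = 0.02)
  expect_error(ct_outer_diameter(
    binary_mask(array(FALSE, c(4, 4, 2)), 1, "roi")), "empty slice")
})

test_that("filled tube phantom recovers its outer diameter within 2%", {
  ph <- make_cortical_phantom(small_cortical_spec(3))
  rep <- run_cortical_pipeline(ph$volume, bone_threshold = 110)
  expect_lt(abs(rep$cortical$ct_od_cylinder_corrected_um - ph$truth$ct_od_um) /
              ph$truth$ct_od_um, 0.02)
  expect_equal(rep$cortical$ct_od_um,
               rep$cortical$ct_od_cylinder_corrected_um / 2)
})
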