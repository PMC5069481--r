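test_that("pore extraction is the ROI minus bone, always a subset of the ROI", {
  m <- tube_mask(40, 10, 8, 16)
  roi <- binary_mask(m, 2, "roi")
  bone <- binary_mask(m, 2, "bone")
  pores <- extract_pores(roi, bone)
  expect_equal(sum(pores$data), 0)            # pore-free tube
  bone$data[20, 32, 5] <- FALSE               # poke one pore voxel in the wall
  pores <- extract_pores(roi, bone)
  expect_equal(sum(pores$data), 1)
  expect_true(all(!pores$data | roi$data))
  expect_error(extract_pores(binary_mask(array(FALSE, c(2, 2, 2)), 1, "roi"),
                             bone), "empty ROI")
})

test_that("volume classes partition pores at the 280/4000 um^3 boundaries", {
  # three boxes of 100, 1000 and 5000 um^3 at 1 um voxel
  m <- array(FALSE, c(30, 30, 60))
  m[2:6, 2:6, 2:5] <- TRUE                    # 100 voxels -> removed
  m[12:21, 2:11, 2:11] <- TRUE                # 1000 -> lacuna
  m[2:11, 20:29, 2:51] <- TRUE                # 5000 -> canal (10x10x50)
  tab <- classify_pores(binary_mask(m, 1, "pore"))
  expect_setequal(tab$class, c("removed", "lacuna", "canal"))
  expect_equal(tab$class[order(tab$volume_um3)], c("removed", "lacuna", "canal"))
  # exact boundaries: 280 -> lacuna (inclusive), 4000 -> canal (inclusive)
  b2 <- array(FALSE, c(24, 24, 24))
  b2[2:8, 2:9, 2:6] <- TRUE                   # 7*8*5 = 280 um^3
  b2[12:21, 12:21, 2:21] <- TRUE              # 10*10*20 = 2000 um^3
  tab2 <- classify_pores(binary_mask(b2, 1, "pore"))
  expect_equal(sort(tab2$class), c("lacuna", "lacuna"))
  b3 <- array(FALSE, c(14, 14, 44))
  b3[2:11, 2:11, 2:41] <- TRUE                # 10*10*40 = 4000 um^3 exactly
  expect_equal(classify_pores(binary_mask(b3, 1, "pore"))$class, "canal")
  b3[2, 2, 2] <- FALSE                        # 3999 um^3
  expect_equal(classify_pores(binary_mask(b3, 1, "pore"))$class, "lacuna")
  # the 2 um lower bound acts at 35 voxels
  c35 <- array(FALSE, c(40, 6, 6))
  c35[1:35, 2, 2] <- TRUE
  t35 <- classify_pores(binary_mask(c35, 2, "pore"))
  expect_equal(t35$class, "lacuna")
  c34 <- array(FALSE, c(40, 6, 6))
  c34[1:34, 2, 2] <- TRUE
  expect_equal(classify_pores(binary_mask(c34, 2, "pore"))$class, "removed")
})

test_that("classified volumes conserve the total pore volume exactly", {
  for (seed in 1:3) {
    m <- random_mask(seed + 50, c(14, 14, 14), 0.25)
    mask <- binary_mask(m, 4, "pore")       # 64 um^3 voxels
    tab <- classify_pores(mask, 280, 4000)
    expect_equal(sum(tab$volume_um3), sum(m) * 64)
    expect_true(all(tab$volume_um3[tab$class == "removed"] < 280))
    expect_true(all(tab$volume_um3[tab$class == "lacuna"] >= 280 &
                    tab$volume_um3[tab$class == "lacuna"] < 4000))
    expect_true(all(tab$volume_um3[tab$class == "canal"] >= 4000))
  }
})

test_that("per-class metrics are simple ratios over Ct.TV", {
  tab <- data.frame(id = 1:12,
                    voxels = 1,
                    volume_um3 = c(rep(1e5, 10), 500, 90),
                    class = c(rep("canal", 10), "lacuna", "removed"),
                    mean_diameter_um = c(rep(20, 10), 6, 2),
                    eqsphere_diameter_um = 1)
  cm <- pore_class_metrics(tab, "canal", ct_tv_mm3 = 1)
  expect_equal(cm$porosity_pct, 0.1)          # 10 x 1e5 um^3 in 1 mm^3
  expect_equal(cm$density_per_mm3, 10)
  expect_equal(cm$diameter_um, 20)
  lm <- pore_class_metrics(tab, "lacuna", ct_tv_mm3 = 0.5)
  expect_equal(lm$density_per_mm3, 2)
  none <- pore_class_metrics(tab[tab$class == "removed", ], "canal", 1)
  expect_equal(none$porosity_pct, 0)
  expect_equal(none$density_per_mm3, 0)
  expect_true(is.na(none$diameter_um))
  expect_error(pore_class_metrics(tab, "canal", 0), "positive")
})

test_that("despeckle sweep: lacuna counts decrease, canals untouched", {
  ph <- make_cortical_phantom(small_cortical_spec(5))
  bone <- binarize(ph$volume, 110, "above")
  roi <- fit_cortical_roi(bone, 10)
  pores <- extract_pores(roi, bone)
  sweep_tab <- despeckle_sensitivity(pores, ct_tv_mm3 = sum(roi$data) / 1e9)
  expect_true(all(diff(sweep_tab$lacuna_count) <= 0))
  expect_true(all(diff(sweep_tab$lacunar_porosity_pct) <= 1e-12))
  # all phantom lacunae are >= 320 um^3 by construction (rasterization can
  # shave a few percent): counts are flat up to 280 and equal to the truth
  expect_equal(sweep_tab$lacuna_count[sweep_tab$despeckle_volume_um3 <= 280],
               rep(ph$truth$lacuna_count, 4))
  # canal class metrics do not depend on the lower bound
  canal_counts <- vapply(sweep_tab$despeckle_volume_um3, function(v) {
    tab <- classify_pores(pores, lower_um3 = v)
    sum(tab$class == "canal")
  }, numeric(1))
  expect_equal(length(unique(canal_counts)), 1L)
})

test_that("the cortical pipeline is deterministic and clean on pore-free tubes", {
  sp <- small_cortical_spec(6, canal_count = 0, lacuna_count = 0)
  ph <- make_cortical_phantom(sp)
  r1 <- run_cortical_pipeline(ph$volume, bone_threshold = 110)
  r2 <- run_cortical_pipeline(ph$volume, bone_threshold = 110)
  expect_equal(r1$canal$porosity_pct, 0)
  expect_equal(r1$lacuna$porosity_pct, 0)
  expect_identical(r1$cortical, r2$cortical)
  expect_identical(as.data.frame(r1$pores), as.data.frame(r2$pores))
})

test_that("vascular plus lacunar porosity equals total porosity after despeckle", {
  ph <- make_cortical_phantom(small_cortical_spec(10))
  rep <- run_cortical_pipeline(ph$volume, bone_threshold = 110)
  tab <- rep$pores
  kept <- tab[tab$class != "removed", ]
  total_after_despeckle <- sum(kept$volume_um3)
  expect_equal(rep$canal$volume_um3 + rep$lacuna$volume_um3,
               total_after_despeckle)
  expect_equal(rep$canal$porosity_pct + rep$lacuna$porosity_pct,
               100 * total_after_despeckle / (rep$cortical$ct_tv_mm3 * 1e9))
})

test_that("viable osteocyte density scales lacunar density by survival", {
  expect_equal(viable_osteocyte_density(5000, 0), 5000)
  expect_equal(viable_osteocyte_density(5000, 1), 0)
  expect_equal(viable_osteocyte_density(18397.7, 0.3322), 18397.7 * 0.6678)
  expect_error(viable_osteocyte_density(100, 1.2), "\\[0, 1\\]")
})
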