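#' Extract the intracortical pore phase
#'
#' The pore mask is the set difference between the solid cortical ROI and
#' the bone phase: every non-bone voxel inside the annulus. By construction
#' the pores are a subset of the ROI.
#'
#' @param roi solid cortical ROI [binary_mask()] (from [fit_cortical_roi()]).
#' @param bone bone [binary_mask()].
#' @return A [binary_mask()] with phase `"pore"`.
#' @export
extract_pores <- function(roi, bone) {
  stopifnot(inherits(roi, "binary_mask"), inherits(bone, "binary_mask"))
  if (!any(roi$data)) stop("empty ROI")
  binary_mask(roi$data & !bone$data, roi$voxel_size_um, "pore")
}

#' Classify pores into volume classes
#'
#' Labels the pore mask (26-connectivity) and assigns each component to a
#' volume class: components below `lower_um3` are speckle noise
#' (`"removed"`), components in `[lower_um3, upper_um3)` are osteocyte
#' lacunae, components at or above `upper_um3` are vascular canals. The
#' half-open boundaries make the classes a partition. Per-component mean
#' diameter is the volume-weighted mean local thickness of the component;
#' an equivalent-sphere diameter is stored alongside for comparison.
#'
#' @param pores pore [binary_mask()].
#' @param lower_um3 lower despeckle bound (default 280 um^3 — 35 voxels at
#'   2 um, 280 voxels at 1 um).
#' @param upper_um3 lacuna/canal class boundary (default 4000 um^3).
#' @param exclude_border drop components touching the volume border
#'   (default `FALSE`: border-crossing canals are counted).
#' @return A `pore_table`: data frame with one row per component (`id`,
#'   `voxels`, `volume_um3`, `class`, `mean_diameter_um`,
#'   `eqsphere_diameter_um`), with the voxel size and class bounds as
#'   attributes.
#' @export
classify_pores <- function(pores, lower_um3 = 280, upper_um3 = 4000,
                           exclude_border = FALSE) {
  stopifnot(inherits(pores, "binary_mask"))
  if (lower_um3 >= upper_um3) stop("`lower_um3` must be below `upper_um3`")
  v <- pores$voxel_size_um
  lab <- cpp_label_components(pores$data, dim(pores$data), 26L)
  n <- length(lab$counts)
  tab <- data.frame(id = seq_len(n),
                    voxels = as.integer(lab$counts),
                    volume_um3 = lab$counts * v^3)
  tab$class <- ifelse(tab$volume_um3 < lower_um3, "removed",
                      ifelse(tab$volume_um3 < upper_um3, "lacuna", "canal"))
  if (exclude_border && n > 0) {
    d <- dim(pores$data)
    la <- lab$labels
    dim(la) <- d
    btouch <- unique(c(la[1, , ], la[d[1], , ], la[, 1, ], la[, d[2], ],
                       la[, , 1], la[, , d[3]]))
    btouch <- btouch[btouch > 0]
    tab$class[tab$id %in% btouch] <- "removed"
  }
  tab$mean_diameter_um <- rep(NA_real_, nrow(tab))
  tab$eqsphere_diameter_um <- (6 * tab$volume_um3 / pi)^(1 / 3)
  keep <- tab$class != "removed"
  if (any(keep)) {
    km <- array(lab$labels %in% tab$id[keep], dim(pores$data))
    th <- local_thickness(binary_mask(km, v, "pore"), border = "extend")
    sums <- tapply(th$data[km], lab$labels[km], mean)
    tab$mean_diameter_um[match(as.integer(names(sums)), tab$id)] <- as.numeric(sums)
  }
  attr(tab, "voxel_size_um") <- v
  attr(tab, "lower_um3") <- lower_um3
  attr(tab, "upper_um3") <- upper_um3
  class(tab) <- c("pore_table", "data.frame")
  tab
}

#' Per-class porosity, density and diameter
#'
#' @param table a `pore_table` from [classify_pores()].
#' @param which `"canal"` or `"lacuna"`.
#' @param ct_tv_mm3 cortical total volume (the solid ROI volume, pores
#'   included) in mm^3 — the densities are per mm^3 of cortex.
#' @return A list of class `pore_class_metrics`: `porosity_pct`
#'   (class volume / Ct.TV, %), `density_per_mm3` (count / Ct.TV),
#'   `diameter_um` (volume-weighted mean of member diameters; `NA` when the
#'   class is empty), `count`, `volume_um3`.
#' @export
pore_class_metrics <- function(table, which = c("canal", "lacuna"), ct_tv_mm3) {
  which <- match.arg(which)
  if (ct_tv_mm3 <= 0) stop("`ct_tv_mm3` must be positive")
  rows <- table[table$class == which, , drop = FALSE]
  n <- nrow(rows)
  vol <- sum(rows$volume_um3)
  dia <- if (n > 0) sum(rows$mean_diameter_um * rows$volume_um3) / vol else NA_real_
  structure(list(which = which,
                 porosity_pct = 100 * vol / (ct_tv_mm3 * 1e9),
                 density_per_mm3 = n / ct_tv_mm3,
                 diameter_um = dia,
                 count = n,
                 volume_um3 = vol),
            class = "pore_class_metrics")
}

#' @export
print.pore_class_metrics <- function(x, ...) {
  cat(sprintf("%s: porosity %.4f%%, density %.1f /mm^3, diameter %s um (n = %d)\n",
              x$which, x$porosity_pct, x$density_per_mm3,
              ifelse(is.na(x$diameter_um), "NA", sprintf("%.2f", x$diameter_um)),
              x$count))
  invisible(x)
}

#' Sensitivity of lacunar metrics to the despeckle volume
#'
#' Re-runs the volume-class classification for a range of lower despeckle
#' bounds (the upper canal bound held fixed) and tabulates the lacunar
#' count, volume, diameter and porosity per bound. Used to verify that the
#' chosen despeckle volume sits on a stable plateau.
#'
#' @param pores pore [binary_mask()].
#' @param volumes_um3 ascending despeckle volumes to test; the default
#'   spans 150-550 um^3 around the working value of 280 um^3.
#' @param upper_um3 fixed canal class boundary.
#' @param ct_tv_mm3 optional cortical volume for porosity columns.
#' @return A data frame with one row per despeckle volume.
#' @export
despeckle_sensitivity <- function(pores,
                                  volumes_um3 = c(150, 220, 250, 280, 310, 340, 450, 550),
                                  upper_um3 = 4000,
                                  ct_tv_mm3 = NULL) {
  stopifnot(inherits(pores, "binary_mask"))
  if (is.unsorted(volumes_um3)) stop("`volumes_um3` must be sorted ascending")
  base <- classify_pores(pores, lower_um3 = min(volumes_um3), upper_um3 = upper_um3)
  rows <- lapply(volumes_um3, function(vth) {
    lac <- base[base$volume_um3 >= vth & base$volume_um3 < upper_um3, , drop = FALSE]
    vol <- sum(lac$volume_um3)
    data.frame(despeckle_volume_um3 = vth,
               lacuna_count = nrow(lac),
               lacuna_volume_um3 = vol,
               lacuna_diameter_um = if (nrow(lac) > 0)
                 sum(lac$mean_diameter_um * lac$volume_um3) / vol else NA_real_,
               lacunar_porosity_pct = if (is.null(ct_tv_mm3)) NA_real_ else
                 100 * vol / (ct_tv_mm3 * 1e9))
  })
  do.call(rbind, rows)
}

#' Run the cortical analysis pipeline
#'
#' End-to-end cortical chain on a grayscale volume: bone binarization
#' (global threshold, Otsu if not given), automatic cortical ROI, cortical
#' thickness (on the pore-free ROI), marrow filling and outer diameter,
#' pore extraction, volume-class classification with the despeckle cascade,
#' and per-class metrics. Fully deterministic given the configuration.
#'
#' @param vol a [voxel_volume()].
#' @param bone_threshold global intensity threshold for bone; Otsu when
#'   `NULL`.
#' @param closing_radius_um ROI closing ball radius (um).
#' @param lower_um3,upper_um3 despeckle / class bounds (um^3).
#' @param ct_od_variant outer diameter variant, see [ct_outer_diameter()].
#' @param exclude_border drop pore components touching the volume border.
#' @return A list of class `cortical_report`: `cortical` (Ct.Th, Ct.OD both
#'   variants, Ct.TV), `canal` and `lacuna` ([pore_class_metrics()]),
#'   `pores` (the pore table) and `params`.
#' @export
run_cortical_pipeline <- function(vol, bone_threshold = NULL,
                                  closing_radius_um = 10,
                                  lower_um3 = 280, upper_um3 = 4000,
                                  ct_od_variant = "as_printed",
                                  exclude_border = FALSE) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (is.null(bone_threshold)) bone_threshold <- otsu_threshold(vol)
  bone <- binarize(vol, bone_threshold, "above")
  roi <- fit_cortical_roi(bone, closing_radius_um)
  v <- vol$voxel_size_um
  ct_tv_mm3 <- sum(roi$data) * v^3 / 1e9
  ct_th <- ct_thickness(roi)
  filled <- fill_marrow(roi)
  ct_od <- ct_outer_diameter(filled, ct_od_variant)
  ct_od_cc <- ct_outer_diameter(filled, "cylinder_corrected")
  pores <- extract_pores(roi, bone)
  tab <- classify_pores(pores, lower_um3, upper_um3, exclude_border)
  structure(list(
    cortical = list(ct_th_um = ct_th, ct_od_um = ct_od,
                    ct_od_cylinder_corrected_um = ct_od_cc,
                    ct_tv_mm3 = ct_tv_mm3),
    canal = pore_class_metrics(tab, "canal", ct_tv_mm3),
    lacuna = pore_class_metrics(tab, "lacuna", ct_tv_mm3),
    pores = tab,
    params = list(bone_threshold = bone_threshold,
                  closing_radius_um = closing_radius_um,
                  lower_um3 = lower_um3, upper_um3 = upper_um3,
                  ct_od_variant = ct_od_variant,
                  exclude_border = exclude_border,
                  voxel_size_um = v)),
    class = "cortical_report")
}

#' @export
print.cortical_report <- function(x, ...) {
  cat(sprintf("Ct.Th %.2f um   Ct.OD %.2f um (%s)   Ct.TV %.5f mm^3\n",
              x$cortical$ct_th_um, x$cortical$ct_od_um,
              x$params$ct_od_variant, x$cortical$ct_tv_mm3))
  print(x$canal)
  print(x$lacuna)
  invisible(x)
}

#' Run the trabecular analysis pipeline
#'
#' Trabecular chain on a grayscale volume: Otsu binarization, ball closing
#' (radius 1 voxel), double despeckling (white then black speckles below a
#' voxel-count threshold), then the trabecular indices within the region of
#' interest.
#'
#' @param vol a [voxel_volume()].
#' @param roi trabecular VOI [binary_mask()]; whole volume when `NULL` (the
#'   VOI is normally drawn manually and supplied as a mask).
#' @param threshold global threshold; Otsu when `NULL`.
#' @param closing_radius_voxels closing ball radius (voxels).
#' @param despeckle_voxels white/black speckle size limit in voxels.
#' @return A list: `metrics` ([trabecular_metrics()]), `bone` (the cleaned
#'   mask) and `params`.
#' @export
run_trabecular_pipeline <- function(vol, roi = NULL, threshold = NULL,
                                    closing_radius_voxels = 1L,
                                    despeckle_voxels = 200L) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (is.null(roi))
    roi <- binary_mask(array(TRUE, dim(vol$data)), vol$voxel_size_um, "roi")
  if (is.null(threshold)) threshold <- otsu_threshold(vol, roi)
  bone <- binarize(vol, threshold, "above")
  bone <- morphological_closing(bone, closing_radius_voxels)
  min_um3 <- despeckle_voxels * vol$voxel_size_um^3
  bone <- despeckle(bone, min_um3, "white")
  bone <- despeckle(bone, min_um3, "black")
  list(metrics = trabecular_metrics(bone, roi),
       bone = bone,
       params = list(threshold = threshold,
                     closing_radius_voxels = closing_radius_voxels,
                     despeckle_voxels = despeckle_voxels))
}

#' Density of viable (TUNEL-negative) osteocytes
#'
#' Combines an image-based lacunar density with the apoptotic fraction from
#' TUNEL staining: viable density = lacunar density x (1 - TUNEL-positive
#' fraction).
#'
#' @param lacunar_density_per_mm3 lacunar density (#/mm^3).
#' @param tunel_pos_fraction fraction of TUNEL-positive (apoptotic)
#'   osteocytes, in `[0, 1]`.
#' @return Viable osteocyte density (#/mm^3).
#' @export
viable_osteocyte_density <- function(lacunar_density_per_mm3, tunel_pos_fraction) {
  if (any(tunel_pos_fraction < 0 | tunel_pos_fraction > 1))
    stop("`tunel_pos_fraction` must lie in [0, 1]")
  lacunar_density_per_mm3 * (1 - tunel_pos_fraction)
}
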