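#' Construct a binary mask
#'
#' @param data logical 3D array.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param phase_name label for the segmented phase (`"bone"`, `"pore"`,
#'   `"roi"`, ...).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_size_um, phase_name = "bone") {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("`data` must be a logical 3D array")
  if (voxel_size_um <= 0) stop("`voxel_size_um` must be positive")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 phase_name = phase_name),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask:%s> %d x %d x %d @ %g um, %d foreground voxels (%.2f%%)\n",
              x$phase_name, d[1], d[2], d[3], x$voxel_size_um,
              sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

#' Otsu threshold of a volume
#'
#' Computes the intensity threshold maximizing the between-class variance of
#' the histogram (256 bins over the observed range), restricted to an
#' optional region of interest. The histogram is taken over the full 3D
#' dataset rather than per slice, so that a single global threshold is used
#' for all volume metrics.
#'
#' @param vol a [voxel_volume()].
#' @param roi optional [binary_mask()] restricting the histogram.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold intensity; voxels with intensity `>=` threshold
#'   belong to the upper (bright) class.
#' @export
otsu_threshold <- function(vol, roi = NULL, n_bins = 256L) {
  stopifnot(inherits(vol, "voxel_volume"))
  x <- if (is.null(roi)) as.vector(vol$data) else vol$data[roi$data]
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("constant image: Otsu threshold is undefined")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1L),
                                n_bins), nbins = n_bins))
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]
  mu <- m[n_bins]
  k <- seq_len(n_bins - 1L)
  w0 <- w[k]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, n_bins - 1L)
  sb[valid] <- (n * m[k][valid] - mu * w0[valid])^2 / (w0[valid] * w1[valid])
  kbest <- which.max(sb)
  breaks[kbest + 1L]
}

#' Binarize a volume at a global threshold
#'
#' @param vol a [voxel_volume()].
#' @param threshold intensity threshold.
#' @param polarity `"above"`: foreground iff intensity `>=` threshold (bone
#'   segmentation); `"below"`: foreground iff intensity `<` threshold (pore
#'   segmentation).
#' @param phase_name phase label for the resulting mask.
#' @return A [binary_mask()].
#' @export
binarize <- function(vol, threshold, polarity = c("above", "below"),
                     phase_name = NULL) {
  stopifnot(inherits(vol, "voxel_volume"))
  polarity <- match.arg(polarity)
  fg <- if (polarity == "above") vol$data >= threshold else vol$data < threshold
  if (is.null(phase_name))
    phase_name <- if (polarity == "above") "bone" else "pore"
  binary_mask(fg, vol$voxel_size_um, phase_name)
}

#' Morphological closing with a 3D ball
#'
#' Dilation followed by erosion with a Euclidean ball of the given radius (in
#' voxels). Implemented exactly through distance transforms: dilation keeps
#' voxels within `radius` of the foreground, erosion keeps voxels farther
#' than `radius` from the dilated background. The volume is padded so
#' structures touching the border are not clipped.
#'
#' @param mask a [binary_mask()].
#' @param radius_voxels ball radius in voxels (>= 1).
#' @return The closed [binary_mask()].
#' @export
morphological_closing <- function(mask, radius_voxels = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  r <- as.integer(radius_voxels)
  if (r < 1L) stop("`radius_voxels` must be >= 1")
  d <- dim(mask$data)
  p <- r + 1L
  pd <- d + 2L * p
  padded <- array(FALSE, pd)
  padded[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- mask$data
  r2 <- as.numeric(r)^2
  dil <- cpp_dist_sq_to(padded, dim(padded)) <= r2
  dim(dil) <- pd
  ero <- cpp_dist_sq_to(!dil, dim(dil)) > r2
  dim(ero) <- pd
  out <- ero[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), drop = FALSE]
  binary_mask(out, mask$voxel_size_um, mask$phase_name)
}

#' Volume threshold in voxels
#'
#' Converts a despeckle volume in cubic micrometres to a voxel count at a
#' given voxel size: 280 um^3 is 35 voxels at 2 um and 280 voxels at 1 um.
#'
#' @param volume_um3 volume in cubic micrometres (> 0).
#' @param voxel_size_um voxel size in micrometres (> 0).
#' @return `round(volume_um3 / voxel_size_um^3)` as an integer.
#' @export
volume_to_voxels <- function(volume_um3, voxel_size_um) {
  if (volume_um3 <= 0 || voxel_size_um <= 0)
    stop("arguments must be positive")
  as.integer(round(volume_um3 / voxel_size_um^3))
}

#' Label connected components of a binary mask
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
#' @return A `labeled_components` object: integer label array (labels
#'   contiguous from 1, 0 = background) and a table with per-component voxel
#'   counts and volumes in um^3.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  res <- cpp_label_components(mask$data, dim(mask$data), as.integer(connectivity))
  v3 <- mask$voxel_size_um^3
  tab <- data.frame(label = seq_along(res$counts),
                    voxels = res$counts,
                    volume_um3 = res$counts * v3)
  structure(list(labels = res$labels, table = tab,
                 voxel_size_um = mask$voxel_size_um,
                 connectivity = as.integer(connectivity)),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components> %d components (%d-connectivity)\n",
              nrow(x$table), x$connectivity))
  invisible(x)
}

#' Remove small speckles from a binary mask
#'
#' Connected components of the stated phase with volume strictly below
#' `min_volume_um3` are flipped to the other phase. White speckles are
#' foreground islands (26-connectivity); black speckles are background holes
#' (6-connectivity) — the standard complementary connectivity pair.
#'
#' @param mask a [binary_mask()].
#' @param min_volume_um3 minimum surviving component volume, um^3; components
#'   with volume `< min_volume_um3` are removed, so survival means volume
#'   `>= min_volume_um3`.
#' @param phase `"white"` (foreground speckles) or `"black"` (background
#'   holes filled in).
#' @return The filtered [binary_mask()].
#' @export
despeckle <- function(mask, min_volume_um3, phase = c("white", "black")) {
  stopifnot(inherits(mask, "binary_mask"))
  phase <- match.arg(phase)
  if (min_volume_um3 < 0) stop("`min_volume_um3` must be >= 0")
  if (min_volume_um3 == 0) return(mask)
  work <- if (phase == "white") mask$data else !mask$data
  conn <- if (phase == "white") 26L else 6L
  res <- cpp_label_components(work, dim(work), conn)
  v3 <- mask$voxel_size_um^3
  small <- which(res$counts * v3 < min_volume_um3)
  if (length(small) > 0) {
    kill <- res$labels %in% small
    dim(kill) <- dim(work)
    out <- if (phase == "white") mask$data & !kill else mask$data | kill
  } else out <- mask$data
  binary_mask(out, mask$voxel_size_um, mask$phase_name)
}

#' Remove large foreground components from a binary mask
#'
#' Foreground components (26-connectivity) with volume strictly above
#' `max_volume_um3` are removed; used to isolate the lacunar size class after
#' the vascular canals have been identified.
#'
#' @param mask a [binary_mask()].
#' @param max_volume_um3 maximum surviving component volume, um^3.
#' @return The filtered [binary_mask()].
#' @export
despeckle_upper <- function(mask, max_volume_um3) {
  stopifnot(inherits(mask, "binary_mask"))
  if (max_volume_um3 <= 0) stop("`max_volume_um3` must be > 0")
  if (!is.finite(max_volume_um3)) return(mask)
  res <- cpp_label_components(mask$data, dim(mask$data), 26L)
  v3 <- mask$voxel_size_um^3
  big <- which(res$counts * v3 > max_volume_um3)
  out <- mask$data
  if (length(big) > 0) {
    kill <- res$labels %in% big
    dim(kill) <- dim(out)
    out <- out & !kill
  }
  binary_mask(out, mask$voxel_size_um, mask$phase_name)
}

# per-slice hole filling; holes are in-slice background components (4-conn)
# not touching the slice border. If keep_largest, the largest hole per slice
# (the marrow cavity) is left open.
fill_holes_slices <- function(data, keep_largest = FALSE) {
  d <- dim(data)
  out <- data
  any_hole <- FALSE
  for (k in seq_len(d[3])) {
    sl <- data[, , k, drop = FALSE]
    res <- cpp_label_components(!sl, dim(sl), 6L)
    if (length(res$counts) == 0L) next
    lab <- res$labels
    dim(lab) <- d[1:2]
    border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
    holes <- setdiff(seq_along(res$counts), border[border > 0])
    if (length(holes) == 0L) next
    any_hole <- TRUE
    if (keep_largest) {
      marrow <- holes[which.max(res$counts[holes])]
      holes <- setdiff(holes, marrow)
    }
    if (length(holes) > 0L) {
      sl2 <- out[, , k]
      sl2[lab %in% holes] <- TRUE
      out[, , k] <- sl2
    }
  }
  attr(out, "any_hole") <- any_hole
  out
}

#' Automatic cortical region of interest
#'
#' Builds the solid cortical annulus from a bone mask: the largest bone
#' component is closed with a Euclidean ball (bridging intracortical pores
#' without annexing the marrow cavity), then remaining intracortical holes
#' are filled per slice while the marrow cavity — the largest in-slice hole —
#' is left open. The resulting ROI hugs the cortex and contains no pore
#' voids, so the mean ROI thickness is the cortical thickness and
#' `ROI & !bone` is exactly the intracortical pore set.
#'
#' @param bone a bone [binary_mask()] containing one dominant shaft-like
#'   component.
#' @param closing_radius_um closing ball radius in micrometres (default
#'   10 um: larger than an osteocyte lacuna, much smaller than the marrow
#'   radius).
#' @return A [binary_mask()] with phase `"roi"`.
#' @export
fit_cortical_roi <- function(bone, closing_radius_um = 10) {
  stopifnot(inherits(bone, "binary_mask"))
  if (!any(bone$data)) stop("empty bone mask")
  res <- cpp_label_components(bone$data, dim(bone$data), 26L)
  main <- which.max(res$counts)
  comp <- res$labels == main
  dim(comp) <- dim(bone$data)
  shaft <- binary_mask(comp, bone$voxel_size_um, "roi")
  r_vox <- max(1L, as.integer(round(closing_radius_um / bone$voxel_size_um)))
  closed <- morphological_closing(shaft, r_vox)
  filled <- fill_holes_slices(closed$data, keep_largest = TRUE)
  if (!attr(filled, "any_hole"))
    stop("no annular topology: no enclosed cavity found in any slice")
  attr(filled, "any_hole") <- NULL
  binary_mask(filled, bone$voxel_size_um, "roi")
}

#' Fill the marrow cavity of a cortical ROI
#'
#' Per-slice filling of every enclosed cavity, turning the annular ROI into
#' solid shaft cross-sections (used for the outer-diameter computation).
#'
#' @param roi an annular ROI [binary_mask()].
#' @return A [binary_mask()] of the filled shaft.
#' @export
fill_marrow <- function(roi) {
  stopifnot(inherits(roi, "binary_mask"))
  filled <- fill_holes_slices(roi$data, keep_largest = FALSE)
  attr(filled, "any_hole") <- NULL
  binary_mask(filled, roi$voxel_size_um, "roi")
}

#' Align the principal axis of an object with the slice axis
#'
#' Thresholds the volume (Otsu), finds the principal axis of the foreground
#' by PCA of voxel coordinates, and resamples the volume (nearest neighbour)
#' so that the principal axis lies along the third (slice) dimension.
#'
#' @param vol a [voxel_volume()] containing one elongated object.
#' @param threshold optional intensity threshold; Otsu when `NULL`.
#' @return The rotated [voxel_volume()] (same grid and voxel size).
#' @export
align_to_axis <- function(vol, threshold = NULL) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (is.null(threshold)) threshold <- otsu_threshold(vol)
  fg <- which(vol$data >= threshold, arr.ind = TRUE)
  if (nrow(fg) < 10L) stop("too few foreground voxels to orient")
  pc <- stats::prcomp(fg, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] / pc$sdev[2] < 1.05) {
    warning("object has no clear principal axis; returning volume unchanged")
    return(vol)
  }
  # rotation mapping the principal axis onto the slice axis (3rd dim)
  v <- pc$rotation[, c(2, 3, 1)]
  if (det(v) < 0) v[, 1] <- -v[, 1]
  ctr <- colMeans(fg)
  d <- dim(vol$data)
  tgt <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  src <- sweep(sweep(tgt, 2, ctr) %*% t(v), 2, ctr, "+")
  src <- round(src)
  ok <- src[, 1] >= 1 & src[, 1] <= d[1] &
        src[, 2] >= 1 & src[, 2] <= d[2] &
        src[, 3] >= 1 & src[, 3] <= d[3]
  out <- array(min(vol$data), d)
  out[ok] <- vol$data[src[ok, , drop = FALSE]]
  voxel_volume(out, vol$voxel_size_um, vol$provenance)
}
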