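#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D grayscale grid with an isotropic voxel size in
#' micrometres. The array is indexed `[row, column, slice]`; the third
#' dimension is the scan axis (the bone long axis after alignment), so that
#' per-slice quantities such as the cortical outer diameter are computed on
#' `data[, , k]` cross-sections.
#'
#' @param data numeric 3D array of intensities.
#' @param voxel_size_um isotropic voxel size in micrometres (> 0).
#' @param provenance free-text metadata (scan settings, phantom spec id).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size_um, provenance = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) == 0L)) stop("volume grid must be non-empty")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      is.na(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  structure(list(data = data,
                 voxel_size_um = as.numeric(voxel_size_um),
                 provenance = as.character(provenance)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %g um (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3],
              x$voxel_size_um,
              d[1] * x$voxel_size_um / 1000,
              d[2] * x$voxel_size_um / 1000,
              d[3] * x$voxel_size_um / 1000))
  if (nzchar(x$provenance)) cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

#' Contiguous slice window
#'
#' @param start_slice 0-based index of the first slice.
#' @param n_slices number of slices (>= 1).
#' @return An object of class `slice_window`.
#' @export
slice_window <- function(start_slice, n_slices) {
  if (start_slice < 0 || start_slice != round(start_slice))
    stop("`start_slice` must be a non-negative integer")
  if (n_slices < 1 || n_slices != round(n_slices))
    stop("`n_slices` must be a positive integer")
  structure(list(start_slice = as.integer(start_slice),
                 n_slices = as.integer(n_slices)),
            class = "slice_window")
}

#' Number of slices spanning a physical height
#'
#' With CT convention this converts a dataset height in millimetres to a
#' slice count: a 1.2 mm dataset is 600 slices at 2 um voxel size and 1200
#' slices at 1 um.
#'
#' @param height_mm dataset height in millimetres (> 0).
#' @param voxel_size_um isotropic voxel size in micrometres (> 0).
#' @return Integer slice count, `round(height_mm * 1000 / voxel_size_um)`.
#' @export
slices_for_height <- function(height_mm, voxel_size_um) {
  if (height_mm <= 0 || voxel_size_um <= 0)
    stop("`height_mm` and `voxel_size_um` must be positive")
  as.integer(round(height_mm * 1000 / voxel_size_um))
}

#' Extract a contiguous slice window from a volume
#'
#' @param vol a [voxel_volume()].
#' @param window a [slice_window()].
#' @return A `voxel_volume` with `window$n_slices` slices.
#' @export
select_window <- function(vol, window) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(window, "slice_window"))
  n3 <- dim(vol$data)[3]
  lo <- window$start_slice + 1L
  hi <- window$start_slice + window$n_slices
  if (hi > n3)
    stop(sprintf("slice window [%d, %d) overruns the stack (%d slices)",
                 window$start_slice, hi, n3))
  voxel_volume(vol$data[, , lo:hi, drop = FALSE], vol$voxel_size_um,
               vol$provenance)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yaml")
}

read_one_slice <- function(f) {
  ext <- tolower(tools::file_ext(f))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(f, as.is = TRUE)
  } else if (ext == "png") {
    m <- round(png::readPNG(f) * 255)
  } else {
    stop("unsupported slice format: ", f)
  }
  if (length(dim(m)) == 3L) m <- m[, , 1]   # drop colour channels
  m
}

#' Read an image stack into a voxel volume
#'
#' Reads either a multipage grayscale TIFF or a directory of equally sized
#' single-slice images (TIFF/PNG, in lexical order). The voxel size is never
#' inferred from image headers: it must be given explicitly or found in a
#' YAML sidecar (`<stem>.yaml` with a `voxel_size_um` field) next to the
#' stack, because resolution tags in CT exports are unreliable.
#'
#' @param path multipage TIFF file or slice directory.
#' @param voxel_size_um voxel size in micrometres; if `NULL`, taken from the
#'   sidecar file.
#' @return A [voxel_volume()]. Slice order equals file/page order.
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  provenance <- ""
  sc <- sidecar_path(path)
  if (is.null(voxel_size_um) || file.exists(sc)) {
    if (file.exists(sc)) {
      meta <- yaml::read_yaml(sc)
      if (is.null(voxel_size_um)) voxel_size_um <- meta$voxel_size_um
      if (!is.null(meta$provenance)) provenance <- meta$provenance
    }
  }
  if (is.null(voxel_size_um))
    stop("voxel size not given and no sidecar found at ", sc)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
    if (length(files) == 0L) stop("no slice images found in ", path)
    slices <- lapply(files, read_one_slice)
  } else {
    slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (is.matrix(slices)) slices <- list(slices)
    slices <- lapply(slices, function(m) {
      if (length(dim(m)) == 3L) m[, , 1] else m
    })
  }
  shp <- dim(slices[[1]])
  ok <- vapply(slices, function(m) identical(dim(m), shp), logical(1))
  if (!all(ok)) stop("heterogeneous slice shapes in ", path)
  data <- array(0, dim = c(shp[1], shp[2], length(slices)))
  for (k in seq_along(slices)) data[, , k] <- slices[[k]]
  voxel_volume(data, voxel_size_um, provenance)
}

#' Write a voxel volume as a multipage TIFF with a YAML sidecar
#'
#' Integer intensities in `[0, 65535]` are stored losslessly as 16-bit
#' grayscale so that [read_stack()] recovers the data bit-exactly. The voxel
#' size and provenance are written to `<stem>.yaml`.
#'
#' @param vol a [voxel_volume()] with integer-valued data in `[0, 65535]`.
#' @param path output TIFF path (parent directory must exist).
#' @export
write_stack <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  d <- vol$data
  if (any(d != round(d)) || min(d) < 0 || max(d) > 65535)
    stop("write_stack() requires integer intensities in [0, 65535]; round/rescale first")
  pages <- lapply(seq_len(dim(d)[3]), function(k) d[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(voxel_size_um = vol$voxel_size_um,
                        provenance = vol$provenance),
                   sidecar_path(path))
  invisible(path)
}
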