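#' Cortical phantom specification
#'
#' Parameters of a synthetic cortical shaft: a hollow tube (bone at high
#' intensity) pierced by quasi-longitudinal cylindrical vascular canals and
#' dispersed ellipsoidal osteocyte lacunae, with analytic ground truth for
#' every structure. The defaults define the package's reference phantom: a
#' desk-scale shaft (280 um outer diameter, 60 um wall) carrying 10 canals
#' of mean diameter 12 um and 200 lacunae of mean volume 600 um^3 — sizes in
#' the range reported for murine cortical bone (canal diameters of order
#' 5-30 um, lacuna volumes of order 100-4000 um^3), chosen so every canal
#' falls in the vascular volume class (>= 4000 um^3) and every lacuna in the
#' lacunar class ([280, 4000) um^3) at 1 um voxel size.
#'
#' @param outer_diameter_um,wall_thickness_um,length_um tube geometry (um).
#' @param canal_count number of vascular canals.
#' @param canal_diameter_um `c(mean, sd)` of canal diameters, truncated to
#'   `canal_diameter_range_um`.
#' @param canal_diameter_range_um allowed canal diameter range.
#' @param canal_tilt_deg_max maximal tilt of a canal from the shaft axis.
#' @param lacuna_count number of lacunae.
#' @param lacuna_volume_um3 `c(mean, sd)` of lacuna volumes, truncated to
#'   `lacuna_volume_range_um3`.
#' @param lacuna_volume_range_um3 allowed lacuna volume range.
#' @param lacuna_aspect_ratios relative semi-axes (descending) of the
#'   ellipsoidal lacunae.
#' @param render_voxel_um voxel size of the rendering.
#' @param intensity_bone,intensity_background gray levels of mineralized and
#'   soft phases.
#' @param clearance_um minimal clearance between structures and to the wall
#'   surfaces, so rasterized components never touch (keeps component counts
#'   exact).
#' @param rng_seed seed controlling all structure placement.
#' @return An object of class `cortical_phantom_spec`.
#' @export
cortical_phantom_spec <- function(outer_diameter_um = 280,
                                  wall_thickness_um = 60,
                                  length_um = 180,
                                  canal_count = 10,
                                  canal_diameter_um = c(12, 3),
                                  canal_diameter_range_um = c(7, 20),
                                  canal_tilt_deg_max = 10,
                                  lacuna_count = 200,
                                  lacuna_volume_um3 = c(600, 200),
                                  lacuna_volume_range_um3 = c(320, 3500),
                                  lacuna_aspect_ratios = c(1, 0.65, 0.35),
                                  render_voxel_um = 1,
                                  intensity_bone = 200,
                                  intensity_background = 20,
                                  clearance_um = 4,
                                  rng_seed = 1L) {
  if (wall_thickness_um >= outer_diameter_um / 2)
    stop("wall thickness must be smaller than the outer radius")
  if (canal_diameter_range_um[2] >= wall_thickness_um)
    stop("canal diameter must be smaller than the wall thickness")
  if (canal_count < 0 || lacuna_count < 0) stop("counts must be >= 0")
  if (render_voxel_um <= 0) stop("render voxel must be positive")
  structure(as.list(environment()), class = "cortical_phantom_spec")
}

#' Trabecular phantom specification
#'
#' A lattice of plates (parallel slabs perpendicular to the slice axis),
#' rods (cylinders along all three axes on a cubic lattice), or a mixed
#' plate-rod structure, with analytic BV/TV, thickness and spacing. The
#' defaults (40 um elements on a 200 um lattice, 2 um voxel) mimic murine
#' trabecular dimensions at the scan resolution used for trabecular
#' analysis.
#'
#' @param lattice_type `"plates"`, `"rods"` or `"mixed"`.
#' @param element_thickness_um plate thickness / rod diameter (um).
#' @param element_spacing_um lattice period (um); must exceed the thickness.
#' @param domain_size_um edge length of the cubic domain (um).
#' @param render_voxel_um voxel size of the rendering.
#' @param jitter_fraction random jitter of rod positions as a fraction of
#'   the half-period (0 = perfect lattice; the analytic truth assumes 0).
#' @param intensity_bone,intensity_background gray levels.
#' @param rng_seed seed for the jitter.
#' @return An object of class `trabecular_phantom_spec`.
#' @export
trabecular_phantom_spec <- function(lattice_type = c("plates", "rods", "mixed"),
                                    element_thickness_um = 40,
                                    element_spacing_um = 200,
                                    domain_size_um = 600,
                                    render_voxel_um = 2,
                                    jitter_fraction = 0,
                                    intensity_bone = 200,
                                    intensity_background = 20,
                                    rng_seed = 1L) {
  lattice_type <- match.arg(lattice_type)
  if (element_thickness_um >= element_spacing_um)
    stop("element thickness must be smaller than the spacing")
  if (domain_size_um <= 0 || render_voxel_um <= 0)
    stop("dimensions must be positive")
  structure(as.list(environment()), class = "trabecular_phantom_spec")
}

#' Scan acquisition model
#'
#' Emulates acquisition of a finely rendered volume at a coarser voxel size:
#' Gaussian system blur (point-spread function given as FWHM), block
#' averaging down to the target voxel (the partial-volume effect), and
#' additive Gaussian noise. The default PSF FWHM of twice the target voxel
#' is a typical detector blur scale.
#'
#' @param target_voxel_um voxel size of the simulated scan.
#' @param psf_fwhm_um full width at half maximum of the Gaussian PSF (um).
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units).
#' @param rng_seed seed for the noise.
#' @return An object of class `scan_model`.
#' @export
scan_model <- function(target_voxel_um, psf_fwhm_um = 2 * target_voxel_um,
                       noise_sd = 0, rng_seed = 1L) {
  if (target_voxel_um <= 0) stop("target voxel must be positive")
  if (psf_fwhm_um < 0 || noise_sd < 0) stop("psf_fwhm_um and noise_sd must be >= 0")
  structure(list(target_voxel_um = target_voxel_um, psf_fwhm_um = psf_fwhm_um,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "scan_model")
}

rand_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rtruncnorm1 <- function(mean, sd, lo, hi, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("could not sample within the truncation range")
}

# minimal distance between two straight segments param. by z in [0, L],
# offsets p(z) = p0 + z*t (2D in-plane positions of tilted canal axes)
min_axis_distance <- function(dp0, dt, L) {
  a <- sum(dt * dt)
  if (a == 0) return(sqrt(sum(dp0 * dp0)))
  zstar <- max(0, min(L, -sum(dp0 * dt) / a))
  sqrt(sum((dp0 + zstar * dt)^2))
}

#' Generate a cortical phantom with ground truth
#'
#' Renders the hollow shaft of a [cortical_phantom_spec()] with
#' partial-volume gray levels (4x4x4 subvoxel sampling per voxel, so
#' boundary voxels take intermediate intensities as in a real
#' reconstruction) and returns the volume together with the analytic truth
#' for every structure. Canals are straight circular cylinders crossing the
#' full shaft length with tilt at most `canal_tilt_deg_max`; lacunae are
#' non-touching triaxial ellipsoids with random orientation. Identical spec
#' and seed give a bit-identical volume.
#'
#' @param spec a [cortical_phantom_spec()].
#' @param supersample subvoxel sampling rate per axis (default 4).
#' @return A list: `volume` (a [voxel_volume()]) and `truth` (a list with
#'   the analytic geometry: wall/canal/lacuna tables, Ct.Th, Ct.OD,
#'   volumes and porosities).
#' @export
make_cortical_phantom <- function(spec, supersample = 4L) {
  stopifnot(inherits(spec, "cortical_phantom_spec"))
  v <- spec$render_voxel_um
  ro <- spec$outer_diameter_um / 2
  ri <- ro - spec$wall_thickness_um
  L <- spec$length_um
  n1 <- as.integer(ceiling(spec$outer_diameter_um / v)) + 4L
  n2 <- n1
  n3 <- as.integer(round(L / v))
  cx <- n1 * v / 2
  cy <- n2 * v / 2
  m <- spec$clearance_um

  geom <- withr::with_seed(spec$rng_seed, {
    canals <- NULL
    if (spec$canal_count > 0) {
      canals <- matrix(NA_real_, spec$canal_count, 5,
                       dimnames = list(NULL, c("x0", "y0", "tx", "ty", "radius")))
      for (ci in seq_len(spec$canal_count)) {
        placed <- FALSE
        for (try in 1:500) {
          dia <- rtruncnorm1(spec$canal_diameter_um[1], spec$canal_diameter_um[2],
                             spec$canal_diameter_range_um[1],
                             spec$canal_diameter_range_um[2])
          r <- dia / 2
          theta <- stats::runif(1, 0, spec$canal_tilt_deg_max) * pi / 180
          phi <- stats::runif(1, 0, 2 * pi)
          tx <- tan(theta) * cos(phi)
          ty <- tan(theta) * sin(phi)
          rad_lo <- ri + r + m
          rad_hi <- ro - r - m
          if (rad_hi <= rad_lo) next
          rho <- stats::runif(1, rad_lo, rad_hi)
          ang <- stats::runif(1, 0, 2 * pi)
          # axis position at mid-height; derive z = 0 intercept
          xm <- cx + rho * cos(ang)
          ym <- cy + rho * sin(ang)
          x0 <- xm - tx * L / 2
          y0 <- ym - ty * L / 2
          # both ends must stay inside the wall with clearance
          rr0 <- sqrt((x0 - cx)^2 + (y0 - cy)^2)
          xe <- x0 + tx * L
          ye <- y0 + ty * L
          rrL <- sqrt((xe - cx)^2 + (ye - cy)^2)
          if (rr0 < rad_lo || rr0 > rad_hi || rrL < rad_lo || rrL > rad_hi) next
          ok <- TRUE
          if (ci > 1) {
            for (cj in seq_len(ci - 1)) {
              dmin <- min_axis_distance(c(x0 - canals[cj, 1], y0 - canals[cj, 2]),
                                        c(tx - canals[cj, 3], ty - canals[cj, 4]), L)
              if (dmin <= r + canals[cj, 5] + m) { ok <- FALSE; break }
            }
          }
          if (!ok) next
          canals[ci, ] <- c(x0, y0, tx, ty, r)
          placed <- TRUE
          break
        }
        if (!placed) stop("infeasible packing: could not place canal ", ci)
      }
    }
    lacunae <- NULL
    ells <- NULL
    if (spec$lacuna_count > 0) {
      q <- spec$lacuna_aspect_ratios / spec$lacuna_aspect_ratios[1]
      lacunae <- matrix(NA_real_, spec$lacuna_count, 7,
                        dimnames = list(NULL, c("cx", "cy", "cz", "a", "b", "c",
                                                "volume_um3")))
      ells <- matrix(NA_real_, spec$lacuna_count, 13)
      for (li in seq_len(spec$lacuna_count)) {
        placed <- FALSE
        for (try in 1:500) {
          vol <- rtruncnorm1(spec$lacuna_volume_um3[1], spec$lacuna_volume_um3[2],
                             spec$lacuna_volume_range_um3[1],
                             spec$lacuna_volume_range_um3[2])
          a <- (3 * vol / (4 * pi * q[2] * q[3]))^(1 / 3)
          b <- q[2] * a
          cc <- q[3] * a
          rot <- rand_rotation()
          rad_lo <- ri + a + m
          rad_hi <- ro - a - m
          if (rad_hi <= rad_lo) next
          rho <- sqrt(stats::runif(1, rad_lo^2, rad_hi^2))
          ang <- stats::runif(1, 0, 2 * pi)
          px <- cx + rho * cos(ang)
          py <- cy + rho * sin(ang)
          pz <- stats::runif(1, a + m, L - a - m)
          ok <- TRUE
          if (!is.null(canals)) {
            for (cj in seq_len(nrow(canals))) {
              dmin <- min_axis_distance(
                c(px - canals[cj, 1] - canals[cj, 3] * pz,
                  py - canals[cj, 2] - canals[cj, 4] * pz), c(0, 0), L)
              # conservative: in-plane distance at the lacuna's height
              if (dmin <= a + canals[cj, 5] / cos(atan(sqrt(
                    canals[cj, 3]^2 + canals[cj, 4]^2))) + m) { ok <- FALSE; break }
            }
          }
          if (ok && li > 1) {
            for (lj in seq_len(li - 1)) {
              d2 <- (px - lacunae[lj, 1])^2 + (py - lacunae[lj, 2])^2 +
                    (pz - lacunae[lj, 3])^2
              if (sqrt(d2) <= a + lacunae[lj, 4] + m) { ok <- FALSE; break }
            }
          }
          if (!ok) next
          lacunae[li, ] <- c(px, py, pz, a, b, cc, 4 / 3 * pi * a * b * cc)
          minv <- diag(1 / c(a, b, cc)) %*% t(rot)
          ells[li, ] <- c(px, py, pz, as.vector(t(minv)), a)
          placed <- TRUE
          break
        }
        if (!placed) stop("infeasible packing: could not place lacuna ", li)
      }
    }
    list(canals = canals, lacunae = lacunae, ells = ells)
  })

  ss <- as.integer(supersample)
  # annulus cross-section fraction (z-invariant), ss x ss subsamples in-plane
  sub <- (seq_len(ss) - 0.5) / ss
  px <- (rep(seq_len(n1) - 1L, each = ss) + rep(sub, n1)) * v
  py <- (rep(seq_len(n2) - 1L, each = ss) + rep(sub, n2)) * v
  d2 <- outer((px - cx)^2, (py - cy)^2, "+")
  inside <- d2 >= ri^2 & d2 <= ro^2
  tube2d <- matrix(0, n1, n2)
  for (si in seq_len(ss)) {
    for (sj in seq_len(ss)) {
      tube2d <- tube2d + inside[seq(si, by = ss, length.out = n1),
                                seq(sj, by = ss, length.out = n2)]
    }
  }
  tube2d <- tube2d / (ss * ss)

  dims <- c(n1, n2, n3)
  pore <- numeric(prod(dims))
  dim(pore) <- dims
  if (!is.null(geom$canals))
    cpp_add_cylinders(pore, dims, v, geom$canals, ss)
  if (!is.null(geom$ells))
    cpp_add_ellipsoids(pore, dims, v, geom$ells, ss)
  bone <- array(tube2d, dims)
  bone <- pmin(pmax(bone - pore, 0), 1)
  dim(bone) <- dims
  gray <- round(spec$intensity_background +
                (spec$intensity_bone - spec$intensity_background) * bone)
  dim(gray) <- dims

  wall_volume <- pi * (ro^2 - ri^2) * L
  canal_tab <- NULL
  canal_volume <- 0
  if (!is.null(geom$canals)) {
    cv <- pi * geom$canals[, "radius"]^2 * L *
      sqrt(1 + geom$canals[, "tx"]^2 + geom$canals[, "ty"]^2)
    canal_tab <- data.frame(geom$canals, volume_um3 = cv,
                            diameter_um = 2 * geom$canals[, "radius"])
    canal_volume <- sum(cv)
  }
  lac_tab <- if (!is.null(geom$lacunae)) as.data.frame(geom$lacunae) else NULL
  lac_volume <- if (is.null(lac_tab)) 0 else sum(lac_tab$volume_um3)
  truth <- list(
    ct_th_um = spec$wall_thickness_um,
    ct_od_um = spec$outer_diameter_um,
    wall_volume_um3 = wall_volume,
    canal_count = spec$canal_count,
    canals = canal_tab,
    canal_volume_um3 = canal_volume,
    canal_porosity_pct = 100 * canal_volume / wall_volume,
    canal_density_per_mm3 = spec$canal_count / (wall_volume / 1e9),
    lacuna_count = spec$lacuna_count,
    lacunae = lac_tab,
    lacuna_volume_um3 = lac_volume,
    lacunar_porosity_pct = 100 * lac_volume / wall_volume,
    lacuna_density_per_mm3 = spec$lacuna_count / (wall_volume / 1e9))
  vol <- voxel_volume(gray, v,
                      sprintf("cortical phantom seed=%d voxel=%gum", spec$rng_seed, v))
  list(volume = vol, truth = truth)
}

# fraction of [lo, hi] covered by the periodic union of [i*p, i*p + t]
periodic_overlap <- function(lo, hi, p, t) {
  i0 <- floor(lo / p) - 1
  i1 <- ceiling(hi / p) + 1
  tot <- 0
  for (i in i0:i1) tot <- tot + max(0, min(hi, i * p + t) - max(lo, i * p))
  tot / (hi - lo)
}

#' Generate a trabecular phantom with ground truth
#'
#' Renders the lattice of a [trabecular_phantom_spec()] with partial-volume
#' gray levels, and returns the analytic truth (BV/TV, Tb.Th = element
#' thickness, Tb.Sp, plate-model Tb.N). Plates are slabs perpendicular to
#' the slice axis starting at z = 0 with period `element_spacing_um`; rods
#' are cylinders along all three axes centred in the cells of a cubic
#' lattice. For rods the analytic BV/TV uses the inclusion-exclusion volume
#' of three orthogonal intersecting cylinders per unit cell.
#'
#' @param spec a [trabecular_phantom_spec()].
#' @param supersample subvoxel sampling rate per axis (default 4).
#' @return A list: `volume` (a [voxel_volume()]) and `truth`.
#' @export
make_trabecular_phantom <- function(spec, supersample = 4L) {
  stopifnot(inherits(spec, "trabecular_phantom_spec"))
  v <- spec$render_voxel_um
  D <- spec$domain_size_um
  t <- spec$element_thickness_um
  p <- spec$element_spacing_um
  n <- as.integer(round(D / v))
  dims <- c(n, n, n)
  ss <- as.integer(supersample)
  sub <- (seq_len(ss) - 0.5) / ss

  plate_frac_1d <- function() {
    vapply(seq_len(n), function(k)
      periodic_overlap((k - 1) * v, k * v, p, t), numeric(1))
  }

  disc_union_frac_2d <- function(centers) {
    # fraction of each pixel covered by the union of discs of radius t/2
    pxs <- (rep(seq_len(n) - 1L, each = ss) + rep(sub, n)) * v
    r <- t / 2
    ins <- matrix(FALSE, n * ss, n * ss)
    for (ci in seq_len(nrow(centers))) {
      dx2 <- (pxs - centers[ci, 1])^2
      dy2 <- (pxs - centers[ci, 2])^2
      ins <- ins | outer(dx2, dy2, "+") <= r^2
    }
    f <- matrix(0, n, n)
    for (si in seq_len(ss))
      for (sj in seq_len(ss))
        f <- f + ins[seq(si, by = ss, length.out = n),
                     seq(sj, by = ss, length.out = n)]
    f / (ss * ss)
  }

  nodes_1d <- function() {
    pos <- seq(p / 2, D - p / 2 + 1e-9, by = p)
    if (spec$jitter_fraction > 0)
      pos <- pos + stats::runif(length(pos), -1, 1) * spec$jitter_fraction * p / 2
    pos
  }

  out <- withr::with_seed(spec$rng_seed, {
    if (spec$lattice_type == "plates") {
      f1 <- plate_frac_1d()
      frac <- array(rep(f1, each = n * n), dims)
      bv_frac <- periodic_overlap(0, D, p, t)
      list(frac = frac, bv_frac = bv_frac, tb_th = t, tb_sp = p - t)
    } else if (spec$lattice_type == "rods") {
      nx <- nodes_1d(); ny <- nodes_1d(); nz <- nodes_1d()
      cz <- as.matrix(expand.grid(nx, ny))   # rods along z at (x, y)
      cxm <- as.matrix(expand.grid(ny, nz))  # rods along x at (y, z)
      cym <- as.matrix(expand.grid(nx, nz))  # rods along y at (x, z)
      Fz <- disc_union_frac_2d(cz)
      Fx <- disc_union_frac_2d(cxm)
      Fy <- disc_union_frac_2d(cym)
      frac <- array(0, dims)
      for (k in seq_len(n)) {
        # voxel (i,j,k): along-z rods depend on (x=i, y=j); along-x on (y=j, z=k);
        # along-y on (x=i, z=k)
        frac[, , k] <- 1 - (1 - Fz) * (1 - matrix(Fx[, k], n, n, byrow = TRUE)) *
          (1 - matrix(Fy[, k], n, n))
      }
      r <- t / 2
      cell <- (3 * pi * r^2 * p - 16 * r^3 + 8 * (2 - sqrt(2)) * r^3) / p^3
      list(frac = frac, bv_frac = cell, tb_th = t, tb_sp = p - t)
    } else { # mixed: plates plus vertical rods bridging the gaps
      f1 <- plate_frac_1d()
      nx <- nodes_1d(); ny <- nodes_1d()
      cz <- as.matrix(expand.grid(nx, ny))
      Fz <- disc_union_frac_2d(cz)
      frac <- array(0, dims)
      for (k in seq_len(n)) frac[, , k] <- 1 - (1 - Fz) * (1 - f1[k])
      phi <- nrow(cz) * pi * (t / 2)^2 / D^2
      bvp <- periodic_overlap(0, D, p, t)
      list(frac = frac, bv_frac = bvp + (1 - bvp) * phi, tb_th = t, tb_sp = p - t)
    }
  })

  gray <- round(spec$intensity_background +
                (spec$intensity_bone - spec$intensity_background) * out$frac)
  dim(gray) <- dims
  truth <- list(bvtv_pct = 100 * out$bv_frac,
                tb_th_um = out$tb_th,
                tb_sp_um = out$tb_sp,
                tb_n_per_mm = out$bv_frac / out$tb_th * 1000)
  vol <- voxel_volume(gray, v,
                      sprintf("trabecular phantom (%s) seed=%d voxel=%gum",
                              spec$lattice_type, spec$rng_seed, v))
  list(volume = vol, truth = truth)
}

#' Simulate acquisition at a coarser voxel size
#'
#' Applies the [scan_model()] to a finely rendered volume: Gaussian blur
#' with the stated FWHM, block-average downsampling by the integer voxel
#' ratio (trailing voxels that do not fill a block are dropped), and
#' additive Gaussian noise. With unit factor, zero FWHM and zero noise this
#' is the identity. Blur and block averaging preserve the mean intensity of
#' a constant volume exactly.
#'
#' @param vol a [voxel_volume()].
#' @param model a [scan_model()]; its target voxel must be an integer
#'   multiple of the source voxel.
#' @return The simulated [voxel_volume()] at the target voxel size.
#' @export
simulate_scan <- function(vol, model) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(model, "scan_model"))
  fac <- model$target_voxel_um / vol$voxel_size_um
  if (fac < 1 - 1e-9)
    stop("target voxel must be >= source voxel")
  k <- as.integer(round(fac))
  if (abs(fac - k) > 1e-9)
    stop("target voxel must be an integer multiple of the source voxel")
  data <- vol$data
  if (model$psf_fwhm_um > 0) {
    sigma_vox <- model$psf_fwhm_um / (2 * sqrt(2 * log(2))) / vol$voxel_size_um
    data <- cpp_gaussian_blur(data, dim(data), sigma_vox)
  }
  if (k > 1L) {
    d <- dim(data)
    dk <- (d %/% k) * k
    data <- data[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3]), drop = FALSE]
    data <- cpp_block_mean(data, dim(data), k)
  }
  if (model$noise_sd > 0) {
    data <- withr::with_seed(model$rng_seed,
      data + stats::rnorm(length(data), 0, model$noise_sd))
  }
  voxel_volume(data, model$target_voxel_um,
               paste0(vol$provenance,
                      sprintf(" | scanned at %gum (fwhm %gum, noise %g)",
                              model$target_voxel_um, model$psf_fwhm_um,
                              model$noise_sd)))
}
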