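# Independent brute-force oracles and small fixture builders, kept free of
# the package's own C++ paths.

# squared EDT by exhaustive search; border_bg: outside grid = background
brute_edt2 <- function(mask, border_bg = TRUE) {
  d <- dim(mask)
  co <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                              k = seq_len(d[3])))
  fg <- which(mask)
  bg <- which(!mask)
  out <- array(0, d)
  if (length(fg) == 0) return(out)
  bgco <- co[bg, , drop = FALSE]
  for (l in fg) {
    p <- co[l, ]
    d2 <- Inf
    if (nrow(bgco) > 0)
      d2 <- min(colSums((t(bgco) - p)^2))
    if (border_bg) {
      db <- min(p - 0, d + 1L - p)  # distance to first virtual bg layer
      d2 <- min(d2, db^2)
    }
    out[l] <- d2
  }
  out
}

# maximal-sphere local thickness by definition: thickness(p) = 2 * max r(q)
# over foreground q whose strict sphere {x : |x-q|^2 <= r(q)^2 - 1} covers p
brute_local_thickness <- function(mask, border_bg = TRUE) {
  e2 <- brute_edt2(mask, border_bg)
  d <- dim(mask)
  co <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                              k = seq_len(d[3])))
  fg <- which(mask)
  out <- array(0, d)
  for (q in fg) {
    r2 <- e2[q]
    covered <- fg[colSums((t(co[fg, , drop = FALSE]) - co[q, ])^2) <= r2 - 1]
    val <- 2 * sqrt(r2)
    out[covered] <- pmax(out[covered], val)
  }
  out
}

# connected components by BFS flood fill over an explicit neighbour list
flood_fill_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  maxn <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs^2) > 0 & rowSums(offs^2) <= maxn, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  counts <- integer(0)
  idx <- which(mask, arr.ind = TRUE)
  key <- function(p) (p[3] - 1) * d[1] * d[2] + (p[2] - 1) * d[1] + p[1]
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (lab[p0[1], p0[2], p0[3]] != 0L) next
    cur <- cur + 1L
    queue <- list(p0)
    lab[p0[1], p0[2], p0[3]] <- cur
    n <- 0L
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      n <- n + 1L
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    counts <- c(counts, n)
  }
  list(labels = lab, counts = counts)
}

# Otsu by direct evaluation of the between-class variance at every split
brute_otsu <- function(x, n_bins = 256L) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1L), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  best <- -Inf
  best_k <- NA
  for (k in seq_len(n_bins - 1L)) {
    lo <- bin <= k
    n0 <- sum(lo)
    n1 <- sum(!lo)
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(mids[bin[lo]])
    mu1 <- mean(mids[bin[!lo]])
    sb <- (n0 / length(x)) * (n1 / length(x)) * (mu0 - mu1)^2
    if (sb > best) {
      best <- sb
      best_k <- k
    }
  }
  breaks[best_k + 1L]
}

# small random blob mask (connected-ish sparse foreground)
random_mask <- function(seed, dims = c(10, 10, 10), p = 0.12) {
  withr::with_seed(seed, {
    m <- array(stats::runif(prod(dims)) < p, dims)
    m
  })
}

# ideal annulus mask stack (voxel centers at half-integers)
tube_mask <- function(n, L, ri, ro, voxel = 1) {
  xs <- (seq_len(n) - 0.5) * voxel
  cx <- n * voxel / 2
  d2 <- outer((xs - cx)^2, (xs - cx)^2, "+")
  ann <- d2 >= ri^2 & d2 <= ro^2
  array(rep(ann, L), c(n, n, L))
}

# small cortical phantom spec used across tests (fast: ~1.4M voxels)
small_cortical_spec <- function(seed = 1L, ...) {
  args <- list(outer_diameter_um = 140, wall_thickness_um = 40,
               length_um = 80, canal_count = 3,
               canal_diameter_um = c(11, 0.5),
               canal_diameter_range_um = c(10, 12),
               lacuna_count = 15,
               lacuna_volume_um3 = c(450, 100),
               lacuna_volume_range_um3 = c(320, 600),
               render_voxel_um = 1, rng_seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(cortical_phantom_spec, args)
}
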