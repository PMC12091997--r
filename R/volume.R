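#' Molecular packing volume by union of vdW spheres
#'
#' Volume of the union of atomic van der Waals spheres, each optionally
#' inflated by a probe radius, computed by counting regular-grid points inside
#' any sphere over the padded bounding box. Decreasing the grid spacing
#' converges to the true union volume; 0.3 Angstrom gives < 3 % error on
#' analytic test spheres. A Monte-Carlo rejection estimator is available as an
#' alternative method.
#'
#' @param s A `pdb_structure`.
#' @param grid_spacing Grid spacing in Angstrom (grid method). Default 0.3.
#' @param probe_radius Probe inflation added to every radius, Angstrom
#'   (0 = bare vdW union). Default 0.
#' @param method `"grid"` (default) or `"monte-carlo"`.
#' @param n_samples Sample count for the Monte-Carlo method. Default 1e6.
#' @param seed RNG seed for the Monte-Carlo method.
#'
#' @return An object of class `molecular_volume`: list with `volume` (cubic
#'   Angstrom), `method`, `grid_spacing_or_samples`, `probe_radius`.
#' @export
molecular_volume <- function(s, grid_spacing = 0.3, probe_radius = 0,
                             method = c("grid", "monte-carlo"),
                             n_samples = 1e6, seed = 1L) {
  method <- match.arg(method)
  stopifnot(grid_spacing > 0, probe_radius >= 0)
  xyz <- coords(s)
  r <- s$atoms$radius + probe_radius
  stopifnot(all(r > 0))

  if (method == "monte-carlo") {
    vol <- mc_union_volume(xyz, r, n_samples, seed)
    res <- list(volume = vol, method = "monte-carlo",
                grid_spacing_or_samples = n_samples, probe_radius = probe_radius)
  } else {
    vol <- grid_union_volume(xyz, r, grid_spacing)
    if (vol == 0) stop("grid_spacing ", grid_spacing,
                       " too coarse: no grid point falls inside any sphere")
    res <- list(volume = vol, method = "grid-union",
                grid_spacing_or_samples = grid_spacing, probe_radius = probe_radius)
  }
  class(res) <- "molecular_volume"
  res
}

#' @export
print.molecular_volume <- function(x, ...) {
  cat(sprintf("<molecular_volume> %.1f A^3 (%s, %s = %g, probe = %g A)\n",
              x$volume, x$method,
              if (x$method == "grid-union") "spacing" else "samples",
              x$grid_spacing_or_samples, x$probe_radius))
  invisible(x)
}

grid_union_volume <- function(xyz, r, h) {
  rmax <- max(r)
  lo <- apply(xyz, 2, min) - rmax - h
  hi <- apply(xyz, 2, max) + rmax + h
  gx <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  inside <- logical(nx * ny * nz)
  for (a in seq_len(nrow(xyz))) {
    c0 <- xyz[a, ]; ra <- r[a]
    ix <- which(abs(gx - c0[1]) <= ra)
    iy <- which(abs(gy - c0[2]) <= ra)
    iz <- which(abs(gz - c0[3]) <= ra)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - c0[1])^2
    dy2 <- (gy[iy] - c0[2])^2
    dz2 <- (gz[iz] - c0[3])^2
    # sub-box occupancy mask, then scatter into the flat global mask
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= ra^2
    idx <- rep(ix, times = length(iy) * length(iz)) +
      nx * (rep(rep(iy - 1L, each = length(ix)), times = length(iz))) +
      nx * ny * rep(iz - 1L, each = length(ix) * length(iy))
    inside[idx[as.vector(sub)]] <- TRUE
  }
  sum(inside) * h^3
}

mc_union_volume <- function(xyz, r, n_samples, seed) {
  rmax <- max(r)
  lo <- apply(xyz, 2, min) - rmax
  hi <- apply(xyz, 2, max) + rmax
  box <- prod(hi - lo)
  hits <- 0L
  with_seed(seed, {
    chunk <- 200000L
    left <- as.integer(n_samples)
    while (left > 0L) {
      m <- min(chunk, left)
      p <- cbind(stats::runif(m, lo[1], hi[1]),
                 stats::runif(m, lo[2], hi[2]),
                 stats::runif(m, lo[3], hi[3]))
      inside <- rep(FALSE, m)
      for (a in seq_len(nrow(xyz))) {
        notin <- which(!inside)
        if (!length(notin)) break
        d2 <- (p[notin, 1] - xyz[a, 1])^2 + (p[notin, 2] - xyz[a, 2])^2 +
          (p[notin, 3] - xyz[a, 3])^2
        inside[notin[d2 <= r[a]^2]] <- TRUE
      }
      hits <- hits + sum(inside)
      left <- left - m
    }
  })
  box * hits / n_samples
}
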