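# Independent oracles and in-code fixtures. Everything here is deliberately
# naive (brute force, rejection sampling, voxel counting) and shares no code
# with the package internals it checks.

# fixed-column PDB ATOM record writer for tiny fixtures
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1.00, alt = " ", element = "C") {
  namef <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, namef, alt, resn, chain, resno, x, y, z, occ, 0, element)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# independent fixed-column parse: returns a data.frame of ATOM records
hand_parse_pdb <- function(path) {
  ln <- readLines(path)
  ln <- ln[startsWith(ln, "ATOM")]
  data.frame(
    serial = as.integer(substr(ln, 7, 11)),
    name = trimws(substr(ln, 13, 16)),
    alt = substr(ln, 17, 17),
    resn = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resno = as.integer(substr(ln, 23, 26)),
    x = as.numeric(substr(ln, 31, 38)),
    y = as.numeric(substr(ln, 39, 46)),
    z = as.numeric(substr(ln, 47, 54)),
    occ = as.numeric(substr(ln, 55, 60))
  )
}

# closed-form union volume of two equal spheres at distance d (lens overlap)
two_sphere_union <- function(r, d) {
  if (d >= 2 * r) return(2 * 4 / 3 * pi * r^3)
  lens <- pi * (2 * r - d)^2 * (d^2 + 4 * d * r) / (12 * d)
  2 * 4 / 3 * pi * r^3 - lens
}

# Monte-Carlo rejection estimate of a sphere-union volume, independent of the
# package's estimator (different sampling loop, plain vapply membership test)
mc_volume_oracle <- function(xyz, r, n = 1e6, seed = 99) {
  set.seed(seed)
  lo <- apply(xyz, 2, min) - max(r)
  hi <- apply(xyz, 2, max) + max(r)
  p <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
  hit <- rep(FALSE, n)
  for (a in seq_len(nrow(xyz))) {
    hit <- hit | ((p[, 1] - xyz[a, 1])^2 + (p[, 2] - xyz[a, 2])^2 +
                    (p[, 3] - xyz[a, 3])^2 <= r[a]^2)
  }
  prod(hi - lo) * mean(hit)
}

# brute-force O(n^2) maximum pairwise distance
brute_max_dist <- function(xyz) {
  n <- nrow(xyz)
  best <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# voxel-counting volume of the outward shell of a spherocylinder
voxel_shell_oracle <- function(diameter, total_length, thickness, h = 1) {
  r <- diameter / 2
  lcyl <- total_length - diameter
  inside <- function(p, rad) {
    # distance from p to the cylinder axis segment z in [-lcyl/2, lcyl/2]
    z <- pmin(pmax(p[, 3], -lcyl / 2), lcyl / 2)
    sqrt(p[, 1]^2 + p[, 2]^2 + (p[, 3] - z)^2) <= rad
  }
  rmax <- r + thickness
  gx <- seq(-rmax, rmax, by = h)
  gz <- seq(-lcyl / 2 - rmax, lcyl / 2 + rmax, by = h)
  xy <- cbind(rep(gx, times = length(gx)), rep(gx, each = length(gx)))
  total <- 0
  for (z in gz) {    # slice-wise to keep memory flat
    g <- cbind(xy, z)
    total <- total + sum(inside(g, r + thickness) & !inside(g, r))
  }
  total * h^3
}

# numerical surface area of a spherocylinder by fine revolution integration
numeric_spherocyl_area <- function(diameter, total_length, n = 20000) {
  r <- diameter / 2
  lcyl <- total_length - diameter
  lat <- 2 * pi * r * lcyl
  # two hemispherical caps by surface-of-revolution quadrature
  th <- seq(0, pi / 2, length.out = n)
  caps <- 2 * sum(2 * pi * r * sin(th) * r * diff(th)[1])
  lat + caps
}

# random rigid-body transform applied to an n x 3 matrix
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  a <- rnorm(3); a <- a / sqrt(sum(a^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  sweep(xyz %*% t(R), 2, rnorm(3, 0, 50), "+")
}
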