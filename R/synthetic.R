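#' Synthetic coating titration
#'
#' Generates a dose-response coating table (fraction of bacteria coated vs
#' protein concentration) from the Hill model plus Gaussian noise, clipped to
#' [0, 1]. Defaults emulate a two-fold dilution series from 2000 nM with the
#' cooperative coating curve reported for the reconstituted GBP1 coat
#' (half-max 225 nM, Hill slope ~5).
#'
#' @param km,hill_slope,bottom,top Generating Hill parameters.
#' @param conc_grid Concentrations in nM; default 2-fold dilutions
#'   2000 -> 15.625 nM (8 points).
#' @param noise_sd Gaussian noise SD in fraction units; default 0.03.
#' @param replicates Replicates per concentration; default 3.
#' @param seed RNG seed.
#' @return data.frame `conc_nM`, `fraction`, `replicate`, with the generating
#'   truth stored in `attr(, "truth")`.
#' @export
gen_titration <- function(km = 225, hill_slope = 5.122, bottom = 0, top = 1,
                          conc_grid = 2000 / 2^(0:7), noise_sd = 0.03,
                          replicates = 3, seed = 42) {
  stopifnot(km > 0, all(conc_grid > 0), noise_sd >= 0, replicates >= 1)
  conc <- rep(conc_grid, each = replicates)
  mu <- hill_model(conc, km, hill_slope, bottom, top)
  frac <- with_seed(seed, mu + stats::rnorm(length(conc), 0, noise_sd))
  frac <- pmin(pmax(frac, 0), 1)
  out <- data.frame(conc_nM = conc, fraction = frac,
                    replicate = rep(seq_len(replicates), times = length(conc_grid)))
  attr(out, "truth") <- list(km = km, hill_slope = hill_slope, bottom = bottom,
                             top = top, noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic anisotropy titration
#'
#' Single-site binding isotherm signal over a protein concentration grid plus
#' Gaussian noise whose SD is a fraction of the dynamic range, emulating a
#' fluorescence-anisotropy titration against a fixed labeled-LPS probe.
#'
#' @param kd Generating dissociation constant, nM.
#' @param r_free,r_bound Free/bound signal levels (arbitrary units).
#' @param conc_grid Protein concentrations, nM; default 10 log-spaced points
#'   100 nM - 30 uM.
#' @param noise_frac Noise SD as a fraction of `r_bound - r_free`; default 0.02.
#' @param seed RNG seed.
#' @return data.frame `conc_nM`, `signal`, truth in `attr(, "truth")`.
#' @export
gen_anisotropy <- function(kd, r_free = 50, r_bound = 200,
                           conc_grid = exp(seq(log(100), log(30000), length.out = 10)),
                           noise_frac = 0.02, seed = 7) {
  stopifnot(kd > 0, all(conc_grid > 0), noise_frac >= 0)
  mu <- isotherm(conc_grid, kd, r_free, r_bound)
  sd_abs <- noise_frac * abs(r_bound - r_free)
  sig <- with_seed(seed, mu + stats::rnorm(length(conc_grid), 0, sd_abs))
  out <- data.frame(conc_nM = conc_grid, signal = sig)
  attr(out, "truth") <- list(kd = kd, r_free = r_free, r_bound = r_bound,
                             noise_frac = noise_frac, seed = seed)
  out
}

#' Synthetic assembly trajectory
#'
#' Cumulative molecule counts rising at a constant mean rate until a plateau
#' at the full coat size, with optional Poisson counting noise on the
#' per-interval increments. Defaults emulate live volumetric imaging of coat
#' assembly (~10^2 molecules/s to ~3 x 10^4 molecules).
#'
#' @param rate Mean assembly rate, molecules/sec.
#' @param total Plateau (complete coat) count.
#' @param dt Sampling interval, seconds.
#' @param noise `"none"` or `"poisson"`.
#' @param plateau_points Extra samples recorded after the plateau; default 10.
#' @param seed RNG seed (Poisson mode).
#' @return An [assembly_trajectory()]; truth in `attr(, "truth")`.
#' @export
gen_trajectory <- function(rate = 103, total = 29542, dt = 1,
                           noise = c("none", "poisson"), plateau_points = 10,
                           seed = 5) {
  noise <- match.arg(noise)
  stopifnot(rate > 0, total > 0, dt > 0)
  t_end <- ceiling(total / rate / dt) * dt + plateau_points * dt
  times <- seq(0, t_end, by = dt)
  if (noise == "none") {
    counts <- pmin(rate * times, total)
  } else {
    inc <- with_seed(seed, stats::rpois(length(times) - 1, rate * dt))
    counts <- pmin(cumsum(c(0, inc)), total)
  }
  out <- assembly_trajectory(times, counts)
  attr(out, "truth") <- list(rate = rate, total = total, dt = dt,
                             noise = noise, seed = seed)
  out
}

#' Synthetic minicell conformer field
#'
#' Apex points placed area-uniformly over a spherical minicell membrane at
#' radial distance `radius + true_length` plus Gaussian length noise, labeled
#' by equal-area latitude bands; returns the field together with the band
#' areas so the density-enumeration loop closes. Defaults emulate the
#' tomographic minicell datasets (150 nm radius, ~10^4 conformers of true
#' length 28 nm with ~1.5 nm measurement spread).
#'
#' @param radius Membrane sphere radius, nm.
#' @param n_conformers Number of apex points.
#' @param true_length True conformer length, nm.
#' @param length_noise_sd Gaussian length noise SD, nm.
#' @param n_segments Number of equal-area latitude-band segments.
#' @param seed RNG seed.
#' @return List with `field` (a [conformer_field()]), `segment_areas` (nm^2,
#'   one per band), `truth`.
#' @export
gen_minicell_field <- function(radius = 150, n_conformers = 11760,
                               true_length = 28, length_noise_sd = 1.5,
                               n_segments = 20, seed = 11) {
  stopifnot(radius > 0, n_conformers > 0, true_length > 0,
            length_noise_sd >= 0, n_segments >= 1)
  dat <- with_seed(seed, {
    # area-uniform directions: z uniform in [-1, 1], azimuth uniform
    z <- stats::runif(n_conformers, -1, 1)
    phi <- stats::runif(n_conformers, 0, 2 * pi)
    len <- true_length + stats::rnorm(n_conformers, 0, length_noise_sd)
    list(z = z, phi = phi, len = pmax(len, 0))
  })
  s <- sqrt(1 - dat$z^2)
  dir <- cbind(s * cos(dat$phi), s * sin(dat$phi), dat$z)
  apex <- dir * (radius + dat$len)
  # equal-area latitude bands partition z uniformly
  labels <- pmin(floor((dat$z + 1) / 2 * n_segments) + 1L, n_segments)
  field <- conformer_field(apex, membrane_sphere(c(0, 0, 0), radius), labels)
  list(field = field,
       segment_areas = rep(4 * pi * radius^2 / n_segments, n_segments),
       truth = list(radius = radius, n_conformers = n_conformers,
                    true_length = true_length,
                    length_noise_sd = length_noise_sd,
                    n_segments = n_segments, seed = seed))
}

#' Constructive coat volume
#'
#' Inverse of the molecule census: the measured volume that a coat of
#' `n_molecules` would produce, `correction_factor * n * per_molecule_volume`.
#'
#' @param n_molecules Molecule count.
#' @param per_molecule_volume nm^3 per molecule.
#' @param correction_factor Fluorescence-enhancement factor; default 3.0.
#' @return Measured volume, nm^3.
#' @export
gen_coat_volume <- function(n_molecules, per_molecule_volume,
                            correction_factor = 3.0) {
  stopifnot(n_molecules > 0, per_molecule_volume > 0, correction_factor > 0)
  correction_factor * n_molecules * per_molecule_volume
}

#' Synthetic toy structures
#'
#' Deterministic small structures for exercising the coordinate operations:
#' `"sphere-cluster"` is a seeded uniform cloud of carbon atoms in a ball;
#' `"ideal-helix"` builds poly-alanine-like residues (N, CA, C, CB) on ideal
#' alpha-helical geometry (1.5 A rise and 100 degrees twist per residue, CA
#' radius 2.3 A), so Cbeta positions are well defined and the end-to-end
#' extent grows linearly with residue count.
#'
#' @param kind `"sphere-cluster"` or `"ideal-helix"`.
#' @param n For the cluster, the atom count; for the helix, the residue count.
#' @param seed RNG seed (cluster only).
#' @param ball_radius Cluster ball radius, Angstrom.
#' @param glycine_at Helix residue numbers emitted as glycine without a CB
#'   atom (to exercise the virtual-Cbeta path); default none.
#' @return A `pdb_structure`.
#' @export
gen_toy_structure <- function(kind = c("sphere-cluster", "ideal-helix"),
                              n = 50, seed = 1, ball_radius = 10,
                              glycine_at = integer(0)) {
  kind <- match.arg(kind)
  if (kind == "sphere-cluster") {
    xyz <- with_seed(seed, {
      m <- matrix(stats::rnorm(3 * n), ncol = 3)
      u <- stats::runif(n)^(1 / 3)
      m / sqrt(rowSums(m^2)) * u * ball_radius
    })
    atoms <- data.frame(name = "C", resname = "UNK", resno = seq_len(n),
                        chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        element = "C")
    return(as_structure(atoms, id = sprintf("sphere-cluster-%d", n)))
  }
  helix_structure(n, glycine_at)
}

# ideal alpha-helix backbone: each backbone atom type sits on its own helix
# with the common 100 deg/residue twist and 1.5 A/residue rise
helix_structure <- function(n_res, glycine_at = integer(0)) {
  twist <- 100 * pi / 180
  rise <- 1.5
  place <- function(i, r, dphi, dz) {
    a <- (i - 1) * twist + dphi
    c(r * cos(a), r * sin(a), (i - 1) * rise + dz)
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    gly <- i %in% glycine_at
    resn <- if (gly) "GLY" else "ALA"
    rows[[length(rows) + 1]] <- c(i, "N", resn, place(i, 1.56, -0.50, -0.95))
    rows[[length(rows) + 1]] <- c(i, "CA", resn, place(i, 2.30, 0, 0))
    rows[[length(rows) + 1]] <- c(i, "C", resn, place(i, 2.00, 0.70, 1.05))
    if (!gly)
      rows[[length(rows) + 1]] <- c(i, "CB", resn, place(i, 3.30, -0.35, -0.30))
  }
  m <- do.call(rbind, rows)
  atoms <- data.frame(name = m[, 2], resname = m[, 3],
                      resno = as.integer(m[, 1]), chain = "A",
                      x = as.numeric(m[, 4]), y = as.numeric(m[, 5]),
                      z = as.numeric(m[, 6]),
                      element = substr(m[, 2], 1, 1))
  as_structure(atoms, id = sprintf("ideal-helix-%d", n_res))
}

#' Synthetic FSC half-map pair
#'
#' Two cubic volumes sharing a band-limited random signal (white noise
#' sharply low-passed at `signal_resolution`) with independent Gaussian noise
#' added to each, emulating half-map reconstructions: their FSC is ~1 below
#' the band limit and ~0 above, crossing near the band limit.
#'
#' @param signal_resolution Band limit of the shared signal, Angstrom.
#' @param noise_sd Independent noise SD (signal is normalized to unit SD and
#'   scaled by `signal_amplitude`).
#' @param n Cube edge, voxels; default 64.
#' @param voxel_size Voxel edge, Angstrom; default 2.5.
#' @param signal_amplitude Signal SD in noise-SD units; default 5.
#' @param seed Seed for the shared signal.
#' @param noise_seeds Length-2 seeds for the two noise realizations; default
#'   `seed + 1:2` (pass the same value twice to make the noise identical).
#' @return List with `vol1`, `vol2`, `voxel_size`, `truth`.
#' @export
gen_halfmaps <- function(signal_resolution = 20, noise_sd = 1, n = 64,
                         voxel_size = 2.5, signal_amplitude = 5, seed = 101,
                         noise_seeds = seed + 1:2) {
  stopifnot(signal_resolution > 2 * voxel_size, n >= 16,
            length(noise_seeds) == 2)
  raw <- with_seed(seed, array(stats::rnorm(n^3), dim = c(n, n, n)))
  fr <- stats::fft(raw)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  kr <- sqrt(outer(outer(k^2, k^2, "+"), k^2, "+")) / (n * voxel_size)
  fr[kr > 1 / signal_resolution] <- 0         # brickwall low-pass
  signal <- Re(stats::fft(fr, inverse = TRUE)) / n^3
  signal <- signal / stats::sd(signal) * signal_amplitude * noise_sd
  v1 <- signal + with_seed(noise_seeds[1], array(stats::rnorm(n^3, 0, noise_sd),
                                                 dim = c(n, n, n)))
  v2 <- signal + with_seed(noise_seeds[2], array(stats::rnorm(n^3, 0, noise_sd),
                                                 dim = c(n, n, n)))
  list(vol1 = v1, vol2 = v2, voxel_size = voxel_size,
       truth = list(signal_resolution = signal_resolution, noise_sd = noise_sd,
                    signal_amplitude = signal_amplitude, seed = seed,
                    noise_seeds = noise_seeds))
}
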