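#' Membrane surface representations
#'
#' A segmented outer-membrane surface, either analytic (sphere given center
#' and radius, exact distances) or a point cloud sampled on the surface
#' (nearest-neighbor distances).
#'
#' @param center 3-vector, nm.
#' @param radius Sphere radius, nm (> 0).
#' @return A `membrane_surface` object.
#' @export
membrane_sphere <- function(center = c(0, 0, 0), radius) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(representation = "analytic-sphere",
                 center = as.numeric(center), radius = radius),
            class = "membrane_surface")
}

#' @rdname membrane_sphere
#' @param points n x 3 matrix of surface points, nm (>= 100 points).
#' @export
membrane_cloud <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 100)
  structure(list(representation = "point-cloud", points = points),
            class = "membrane_surface")
}

#' Conformer field
#'
#' Apex points of membrane-bound conformers (positions of the distal GTPase
#' domain) over a membrane surface, optionally labeled by tomogram segment.
#'
#' @param apex_points n x 3 matrix, nm.
#' @param membrane A `membrane_surface`.
#' @param segment_labels Optional integer label per apex point.
#' @return A `conformer_field` object.
#' @export
conformer_field <- function(apex_points, membrane, segment_labels = NULL) {
  apex_points <- as.matrix(apex_points)
  stopifnot(ncol(apex_points) == 3, nrow(apex_points) >= 1,
            inherits(membrane, "membrane_surface"))
  if (!is.null(segment_labels))
    stopifnot(length(segment_labels) == nrow(apex_points))
  structure(list(apex_points = apex_points, membrane = membrane,
                 segment_labels = segment_labels),
            class = "conformer_field")
}

#' Measure conformer lengths
#'
#' For every apex point, the shortest Euclidean distance to the membrane
#' surface: `| ||p - c|| - R |` for an analytic sphere, nearest surface point
#' for a point cloud. This is the apex-to-outer-leaflet length of each
#' membrane-inserted conformer. Apexes found inside an analytic sphere by
#' more than `tol` trigger a warning (the absolute distance is still used).
#'
#' @param field A [conformer_field()].
#' @param tol Inside-sphere tolerance, nm; default 0.5.
#' @return A `length_distribution` object: `lengths_A` (Angstrom), `n`,
#'   `mean_A`, `sd_A`.
#' @export
measure_lengths <- function(field, tol = 0.5) {
  stopifnot(inherits(field, "conformer_field"))
  p <- field$apex_points
  m <- field$membrane
  if (m$representation == "analytic-sphere") {
    radial <- sqrt(rowSums(sweep(p, 2, m$center)^2))
    signed <- radial - m$radius
    if (any(signed < -tol))
      warning(sum(signed < -tol), " apex point(s) inside the membrane sphere ",
              "by more than ", tol, " nm; using absolute distance")
    d_nm <- abs(signed)
  } else {
    d_nm <- nn_distance(p, m$points)
  }
  lengths_A <- d_nm * 10
  structure(list(lengths_A = lengths_A, n = length(lengths_A),
                 mean_A = mean(lengths_A), sd_A = stats::sd(lengths_A)),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("<length_distribution> n = %s, mean = %.1f A, sd = %.1f A\n",
              format(x$n, big.mark = ","), x$mean_A, x$sd_A))
  invisible(x)
}

# blockwise nearest-neighbor distance from each query point to a point cloud
nn_distance <- function(query, cloud, block = 2000L) {
  n <- nrow(query)
  out <- numeric(n)
  c2 <- rowSums(cloud^2)
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    q <- query[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(q^2), c2, "+") - 2 * tcrossprod(q, cloud)
    out[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Enumerate whole-cell conformer count from per-segment densities
#'
#' Per tomogram segment, the surface density is count / area; the whole-cell
#' count is the mean density multiplied by the total cell surface area, with
#' the standard error of the mean density propagated linearly to the count.
#'
#' @param field A [conformer_field()] whose every apex carries a segment label.
#' @param segment_areas Named or ordered vector of segment areas, nm^2 (> 0);
#'   one per distinct label.
#' @param cell_area Total cell surface area, nm^2. Defaults to the sum of the
#'   segment areas (segments covering the whole cell).
#' @return List with `count`, `sd`, `mean_density`, `density_sd`,
#'   `per_segment` (data.frame of label, n, area, density).
#' @export
enumerate_density <- function(field, segment_areas, cell_area = sum(segment_areas)) {
  stopifnot(inherits(field, "conformer_field"),
            !is.null(field$segment_labels))
  if (any(segment_areas <= 0)) stop("segment areas must be positive")
  labels <- sort(unique(field$segment_labels))
  if (length(segment_areas) != length(labels))
    stop("need one area per segment label (", length(labels), " labels)")
  n_seg <- as.numeric(table(factor(field$segment_labels, levels = labels)))
  dens <- n_seg / segment_areas
  mean_d <- mean(dens)
  sd_d <- stats::sd(dens)
  se_d <- sd_d / sqrt(length(dens))
  list(count = mean_d * cell_area,
       sd = se_d * cell_area,
       mean_density = mean_d, density_sd = sd_d,
       per_segment = data.frame(label = labels, n = n_seg,
                                area_nm2 = segment_areas, density = dens))
}

#' Closed-vs-open conformer feasibility for a measured coat thickness
#'
#' How many folded ("closed") conformers must stack vertically to span a
#' measured coat thickness, and whether a single extended ("open") conformer
#' is consistent with that thickness within a tolerance.
#'
#' @param measured_thickness Coat thickness, nm.
#' @param closed_length Closed-conformer length, nm (e.g. 12.89).
#' @param open_length Open-conformer length, nm (e.g. 27.8).
#' @param tolerance Consistency tolerance, nm; default 2.
#' @return A `feasibility_report`: `measured_thickness`, `closed_length`,
#'   `open_length`, `stacked_closed_count` (= ceiling(thickness / closed)),
#'   `open_consistent`.
#' @export
feasibility <- function(measured_thickness, closed_length, open_length,
                        tolerance = 2) {
  stopifnot(measured_thickness > 0, closed_length > 0, open_length > 0,
            tolerance >= 0)
  structure(list(
    measured_thickness = measured_thickness,
    closed_length = closed_length, open_length = open_length,
    stacked_closed_count = as.integer(ceiling(measured_thickness / closed_length)),
    open_consistent = abs(open_length - measured_thickness) <= tolerance,
    tolerance = tolerance), class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat(sprintf("<feasibility_report> thickness %.4g nm: %d stacked closed conformer(s); open (%.4g nm) %s within %.3g nm\n",
              x$measured_thickness, x$stacked_closed_count, x$open_length,
              if (x$open_consistent) "consistent" else "NOT consistent",
              x$tolerance))
  invisible(x)
}

#' Fourier shell correlation between two half-volumes
#'
#' Normalized cross-correlation of the Fourier coefficients of two equal-shape
#' cubic volumes within concentric spatial-frequency shells. The resolution is
#' read at the first downward crossing of the threshold (default 0.143, the
#' gold-standard half-map criterion), with linear interpolation between
#' shells; if the curve never crosses, the Nyquist limit is reported and
#' flagged.
#'
#' @param vol1,vol2 3-D numeric arrays of identical cubic shape.
#' @param voxel_size Voxel edge, Angstrom.
#' @param threshold FSC threshold; default 0.143.
#' @return An `fsc_curve`: data.frame `shell`, `freq` (1/A), `fsc`; plus
#'   `resolution_A`, `crossed` (FALSE when Nyquist-limited), `threshold`,
#'   `voxel_size`.
#' @export
fsc <- function(vol1, vol2, voxel_size, threshold = 0.143) {
  stopifnot(length(dim(vol1)) == 3, identical(dim(vol1), dim(vol2)),
            voxel_size > 0)
  n <- dim(vol1)[1]
  stopifnot(all(dim(vol1) == n))
  f1 <- stats::fft(vol1)
  f2 <- stats::fft(vol2)

  # integer frequency index per axis, accounting for FFT wrap-around
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  kr <- sqrt(outer(outer(k^2, k^2, "+"), k^2, "+"))
  shell <- pmin(round(kr), floor(n / 2))

  num <- Re(f1 * Conj(f2))
  p1 <- Mod(f1)^2
  p2 <- Mod(f2)^2
  sh <- factor(shell, levels = 0:floor(n / 2))
  s_num <- tapply(num, sh, sum)
  s_p1 <- tapply(p1, sh, sum)
  s_p2 <- tapply(p2, sh, sum)
  fsc_vals <- as.numeric(s_num / sqrt(s_p1 * s_p2))
  fsc_vals[!is.finite(fsc_vals)] <- 0
  shells <- 0:floor(n / 2)
  freq <- shells / (n * voxel_size)

  res <- resolution_at(freq, fsc_vals, threshold)
  curve <- data.frame(shell = shells, freq = freq, fsc = fsc_vals)
  structure(list(curve = curve, resolution_A = res$resolution,
                 crossed = res$crossed, threshold = threshold,
                 voxel_size = voxel_size),
            class = "fsc_curve")
}

resolution_at <- function(freq, fsc_vals, threshold) {
  nyquist_res <- 1 / max(freq)
  for (i in seq(2, length(fsc_vals))) {
    if (fsc_vals[i] < threshold && fsc_vals[i - 1] >= threshold) {
      # linear interpolation in frequency between bracketing shells
      f <- freq[i - 1] + (freq[i] - freq[i - 1]) *
        (fsc_vals[i - 1] - threshold) / (fsc_vals[i - 1] - fsc_vals[i])
      return(list(resolution = 1 / f, crossed = TRUE))
    }
  }
  list(resolution = nyquist_res, crossed = FALSE)
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells, threshold %.3f: resolution %.2f A%s\n",
              nrow(x$curve), x$threshold, x$resolution_A,
              if (!x$crossed) " (Nyquist-limited, no crossing)" else ""))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, ...) {
  plot(x$curve$freq, x$curve$fsc, type = "l", xlab = "spatial frequency (1/A)",
       ylab = "FSC", ylim = c(min(0, min(x$curve$fsc)), 1), ...)
  graphics::abline(h = x$threshold, lty = 2)
  if (x$crossed) graphics::abline(v = 1 / x$resolution_A, lty = 3)
  invisible(x)
}
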