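#' Van der Waals radii by element
#'
#' Bondi-style van der Waals radii (Angstrom) for the elements commonly found
#' in protein structures. Used by [read_pdb()] to annotate atoms; pass a named
#' vector to override individual elements.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    "F" = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    FE = 2.00, ZN = 1.39, MG = 1.73, CA = 1.97, MN = 2.00, "NA" = 2.27,
    K = 2.75, SE = 1.90)
}

.default_vdw <- 1.70

#' Read a PDB structure
#'
#' Parses ATOM (and optionally HETATM) records of a PDB file into an atom
#' table annotated with van der Waals radii. Alternate locations are resolved
#' by keeping the highest-occupancy record, ties broken by altloc label order.
#' Only the first model of a multi-model file is read.
#'
#' @param path Path to a PDB file.
#' @param het Logical; include HETATM records (default `FALSE`).
#' @param radii Named vector mapping element symbols to vdW radii in Angstrom;
#'   defaults to [vdw_radii()]. Elements absent from the table get a default
#'   carbon-like radius of 1.7 Angstrom with a warning.
#' @param id Label for the structure; defaults to the file name.
#'
#' @return An object of class `pdb_structure`: a list with `atoms` (data.frame
#'   with columns `serial`, `name`, `resname`, `resno`, `chain`, `x`, `y`,
#'   `z`, `element`, `radius`) and `id`.
#' @export
read_pdb <- function(path, het = FALSE, radii = vdw_radii(), id = basename(path)) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no parseable atom records in ", path)

  # resolve altlocs: highest occupancy wins, ties by altloc label order
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$eleno), , drop = FALSE]

  element <- toupper(trimws(at$elesy))
  miss <- is.na(element) | element == ""
  if (any(miss)) element[miss] <- guess_element(at$elety[miss])
  radius <- unname(radii[element])
  unknown <- is.na(radius)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
            "; assigning default radius ", .default_vdw, " A")
    radius[unknown] <- .default_vdw
  }

  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), resname = trimws(at$resid),
    resno = at$resno, chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    element = element, radius = radius,
    stringsAsFactors = FALSE
  )
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)))
  structure(list(atoms = atoms, id = id), class = "pdb_structure")
}

# element from an atom name per PDB conventions: strip digits/primes, take
# leading letters; two-letter elements only when the name starts in column 13
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", trimws(name)))
  el <- substr(nm, 1, 1)
  two <- nm %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "SE")
  el[two] <- nm[two]
  el
}

#' Build a structure from an atom table
#'
#' Lightweight constructor used by the synthetic-structure generators and by
#' tests; validates the same invariants as [read_pdb()].
#'
#' @param atoms data.frame with at least `name`, `resname`, `resno`, `chain`,
#'   `x`, `y`, `z`; `element`/`radius`/`serial` filled in when missing.
#' @param id Free-text label.
#' @param radii Named element-to-radius table.
#' @return A `pdb_structure`.
#' @export
as_structure <- function(atoms, id = "structure", radii = vdw_radii()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms$radius)) {
    atoms$radius <- unname(radii[atoms$element])
    atoms$radius[is.na(atoms$radius)] <- .default_vdw
  }
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)),
            all(atoms$radius > 0))
  structure(list(atoms = atoms, id = id), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("<pdb_structure> ", x$id, ": ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Maximal extent of a structure
#'
#' The maximal pairwise Euclidean distance between atom centers, i.e. the
#' diameter of the atom-center point set. Optionally adds the two endpoint
#' vdW radii to give a surface-to-surface extent.
#'
#' @param s A `pdb_structure`.
#' @param add_radii Logical; add the vdW radii of the two extreme atoms
#'   (default `FALSE`).
#' @return Length in Angstrom.
#' @export
max_extent <- function(s, add_radii = FALSE) {
  xyz <- coords(s)
  n <- nrow(xyz)
  if (n < 2) stop("max_extent needs at least 2 atoms")
  # exact diameter restricted to convex-hull-free approach: block pairwise max
  best <- 0; bi <- 1L; bj <- 2L
  block <- 512L
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    a <- xyz[i0:i1, , drop = FALSE]
    for (j0 in seq(i0, n, by = block)) {
      j1 <- min(j0 + block - 1L, n)
      b <- xyz[j0:j1, , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      m <- which.max(d2)
      if (d2[m] > best) {
        best <- d2[m]
        bi <- i0 + (m - 1L) %% nrow(a)
        bj <- j0 + (m - 1L) %/% nrow(a)
      }
    }
  }
  d <- sqrt(max(best, 0))
  if (add_radii) d <- d + s$atoms$radius[bi] + s$atoms$radius[bj]
  d
}
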