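#' Screen residue pairs for disulfide cross-link candidates
#'
#' Measures Cbeta-Cbeta distances between two residue sets and reports the
#' pairs whose distance falls inside a window compatible with an engineered
#' disulfide staple (2-7 Angstrom by convention). Glycines lack a Cbeta; a
#' virtual Cbeta is constructed from the backbone N/CA/C atoms with ideal
#' tetrahedral geometry so glycine positions can still be screened.
#'
#' @param s A `pdb_structure`.
#' @param residues_a,residues_b Integer residue numbers of the two sets.
#' @param d_min,d_max Distance window in Angstrom; default 2 and 7.
#' @param chain Chain id to screen within; default the first chain in the file.
#'
#' @return A `cys_pair_screen` object: list with `pairs` (data.frame `resno_a`,
#'   `resno_b`, `cb_distance`, ascending by distance, window-filtered),
#'   `nearest` (for each residue in `residues_a`, its single nearest partner in
#'   `residues_b` regardless of window), `chain`, `window`.
#' @export
cys_pair_screen <- function(s, residues_a, residues_b, d_min = 2, d_max = 7,
                            chain = NULL) {
  stopifnot(d_min >= 0, d_min < d_max,
            length(residues_a) > 0, length(residues_b) > 0)
  if (is.null(chain)) chain <- s$atoms$chain[1]
  cb_a <- t(vapply(residues_a, function(r) cbeta_position(s, r, chain), numeric(3)))
  cb_b <- t(vapply(residues_b, function(r) cbeta_position(s, r, chain), numeric(3)))
  d <- sqrt(outer(rowSums(cb_a^2), rowSums(cb_b^2), "+") - 2 * tcrossprod(cb_a, cb_b))
  d[d < 0 | is.nan(d)] <- 0

  all_pairs <- data.frame(
    resno_a = rep(residues_a, times = length(residues_b)),
    resno_b = rep(residues_b, each = length(residues_a)),
    cb_distance = as.vector(d)
  )
  keep <- all_pairs$cb_distance >= d_min & all_pairs$cb_distance <= d_max
  pairs <- all_pairs[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$cb_distance, pairs$resno_a, pairs$resno_b), , drop = FALSE]
  rownames(pairs) <- NULL

  jmin <- apply(d, 1, which.min)
  nearest <- data.frame(
    resno_a = residues_a,
    resno_b = residues_b[jmin],
    cb_distance = d[cbind(seq_along(residues_a), jmin)]
  )
  structure(list(pairs = pairs, nearest = nearest, chain = chain,
                 window = c(d_min, d_max)),
            class = "cys_pair_screen")
}

#' @export
print.cys_pair_screen <- function(x, ...) {
  cat(sprintf("<cys_pair_screen> chain %s, window [%g, %g] A: %d candidate pair(s)\n",
              x$chain, x$window[1], x$window[2], nrow(x$pairs)))
  if (nrow(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}

# Cbeta coordinates of one residue; glycine (or any residue without a CB
# atom) gets a virtual Cbeta built from N/CA/C ideal geometry
cbeta_position <- function(s, resno, chain) {
  at <- s$atoms
  sel <- at$resno == resno & at$chain == chain
  if (!any(sel)) stop("residue ", resno, " not found in chain ", chain)
  res <- at[sel, , drop = FALSE]
  cb <- res[res$name == "CB", , drop = FALSE]
  if (nrow(cb) >= 1) return(c(cb$x[1], cb$y[1], cb$z[1]))
  need <- c("N", "CA", "C")
  if (!all(need %in% res$name)) {
    stop("residue ", resno, " (", res$resname[1],
         ") has no CB and incomplete backbone; cannot build virtual Cbeta")
  }
  message("residue ", resno, " (", res$resname[1],
          "): no CB atom, using virtual Cbeta from backbone geometry")
  g <- function(nm) { r <- res[res$name == nm, ][1, ]; c(r$x, r$y, r$z) }
  virtual_cbeta(g("N"), g("CA"), g("C"))
}

# ideal Cbeta from backbone frame: the standard linear combination of
# b = CA-N, c = C-CA and a = b x c reproducing tetrahedral side-chain geometry
virtual_cbeta <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  ca + (-0.58273431 * a + 0.56802827 * b - 0.54067466 * cc)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
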