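#' Single-site binding isotherm
#'
#' Ligand-excess (hyperbolic) anisotropy isotherm:
#' `r_free + (r_bound - r_free) * conc / (kd + conc)`. Appropriate when the
#' titrated protein is well in excess of the fluorescent probe, as in an
#' anisotropy titration against a fixed low-nanomolar labeled-LPS probe.
#'
#' @param conc Protein concentration(s), nM (>= 0).
#' @param kd Dissociation constant, nM.
#' @param r_free Signal of free probe (mP or % of maximal polarization).
#' @param r_bound Signal of fully bound probe.
#' @return Predicted signal.
#' @export
isotherm <- function(conc, kd, r_free, r_bound) {
  stopifnot(kd > 0, all(conc >= 0))
  r_free + (r_bound - r_free) * conc / (kd + conc)
}

# exact (quadratic) bound fraction when probe depletion matters, i.e. when
# kd is comparable to the probe concentration
isotherm_exact <- function(conc, kd, r_free, r_bound, probe_nM) {
  b <- conc + probe_nM + kd
  bound <- (b - sqrt(pmax(b^2 - 4 * conc * probe_nM, 0))) / (2 * probe_nM)
  r_free + (r_bound - r_free) * pmin(pmax(bound, 0), 1)
}

#' Fit an equilibrium dissociation constant from an anisotropy titration
#'
#' Nonlinear least-squares fit of (kd, r_free, r_bound) to anisotropy signal
#' vs titrated protein concentration. The default model is the single-site
#' ligand-excess isotherm; `exact_binding = TRUE` switches to the quadratic
#' probe-depletion form, relevant when kd approaches the probe concentration.
#' Deterministic given the data: Levenberg-Marquardt from a small fixed grid
#' of kd starting values, best residual sum of squares kept.
#'
#' @param titration data.frame with columns `conc_nM` and `signal`, e.g. from
#'   [gen_anisotropy()].
#' @param exact_binding Logical; use the probe-depletion quadratic model.
#' @param probe_nM Probe concentration for the exact model (default 250 nM,
#'   a typical labeled-LPS assay concentration).
#' @return A `kd_fit` object with `kd` (nM), `r_free`, `r_bound`, `rss`,
#'   `converged`, plus coef/print/predict/residuals methods.
#' @export
fit_kd <- function(titration, exact_binding = FALSE, probe_nM = 250) {
  stopifnot(all(c("conc_nM", "signal") %in% names(titration)))
  conc <- titration$conc_nM
  y <- titration$signal
  stopifnot(all(conc > 0), length(conc) >= 5)
  rng <- diff(range(y))
  if (rng <= 0.1 * max(abs(y))) {
    out <- list(kd = NA_real_, r_free = NA_real_, r_bound = NA_real_,
                rss = Inf, converged = FALSE, exact_binding = exact_binding,
                data = data.frame(conc = conc, y = y), nls = NULL,
                diagnostics = "signal dynamic range <= 10% of max; unidentifiable")
    class(out) <- "kd_fit"
    return(out)
  }

  dat <- data.frame(conc = conc, y = y)
  kd_starts <- exp(mean(log(conc))) * c(0.1, 0.5, 1, 2, 10)
  best <- NULL
  for (kd0 in kd_starts) {
    fit <- if (exact_binding) {
      try(minpack.lm::nlsLM(
        y ~ isotherm_exact(conc, kd, rf, rb, probe_nM), data = dat,
        start = list(kd = kd0, rf = min(y), rb = max(y)),
        lower = c(kd = 1e-6, rf = -Inf, rb = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(
        y ~ rf + (rb - rf) * conc / (kd + conc), data = dat,
        start = list(kd = kd0, rf = min(y), rb = max(y)),
        lower = c(kd = 1e-6, rf = -Inf, rb = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    out <- list(kd = NA_real_, r_free = NA_real_, r_bound = NA_real_,
                rss = Inf, converged = FALSE, exact_binding = exact_binding,
                data = dat, nls = NULL, diagnostics = "no start converged")
  } else {
    p <- stats::coef(best$fit)
    out <- list(kd = unname(p["kd"]), r_free = unname(p["rf"]),
                r_bound = unname(p["rb"]), rss = best$rss, converged = TRUE,
                exact_binding = exact_binding, probe_nM = probe_nM,
                data = dat, nls = best$fit, diagnostics = NULL)
  }
  class(out) <- "kd_fit"
  out
}

#' @export
coef.kd_fit <- function(object, ...) {
  c(kd = object$kd, r_free = object$r_free, r_bound = object$r_bound)
}

#' @export
predict.kd_fit <- function(object, conc = NULL, ...) {
  if (is.null(conc)) conc <- object$data$conc
  if (isTRUE(object$exact_binding))
    isotherm_exact(conc, object$kd, object$r_free, object$r_bound, object$probe_nM)
  else
    isotherm(conc, object$kd, object$r_free, object$r_bound)
}

#' @export
residuals.kd_fit <- function(object, ...) object$data$y - predict(object)

#' @export
print.kd_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<kd_fit> did not converge:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("<kd_fit> Kd = %.4g nM (%.4g uM), r_free = %.3g, r_bound = %.3g%s\n",
              x$kd, x$kd / 1000, x$r_free, x$r_bound,
              if (isTRUE(x$exact_binding)) " [probe-depletion model]" else ""))
  invisible(x)
}

#' LPS release budget
#'
#' Accounts released LPS molecules against the total per-cell pool (about
#' 2e6 LPS molecules for a Salmonella cell) and optionally converts the
#' released amount to a molar concentration in a stated assay volume, for
#' comparison against receptor affinity scales such as the caspase-4 Kd.
#'
#' @param released Released LPS molecules (0 <= released <= total).
#' @param total Total LPS molecules per cell; default 2e6.
#' @param n_cells Number of cells contributing; default 1.
#' @param assay_volume_uL Optional assay volume for concentration conversion.
#' @return An `lps_budget` object: `released`, `total_per_cell`,
#'   `released_fraction`, `sub_percent` (TRUE when the fraction is below 1 %),
#'   `effective_concentration_nM` (NA without a volume).
#' @export
lps_budget <- function(released, total = 2e6, n_cells = 1, assay_volume_uL = NULL) {
  if (released < 0 || released > total * n_cells)
    stop("released must lie in [0, total * n_cells]")
  frac <- released / (total * n_cells)
  conc <- if (is.null(assay_volume_uL)) NA_real_ else {
    # molecules -> nmol -> nM in the stated volume
    released / 6.02214076e23 * 1e9 / (assay_volume_uL * 1e-6)
  }
  structure(list(released = released, total_per_cell = total, n_cells = n_cells,
                 released_fraction = frac, sub_percent = frac < 0.01,
                 effective_concentration_nM = conc),
            class = "lps_budget")
}

#' @export
print.lps_budget <- function(x, ...) {
  cat(sprintf("<lps_budget> %.4g of %.4g molecules released (%.3g%%)%s\n",
              x$released, x$total_per_cell * x$n_cells,
              100 * x$released_fraction,
              if (x$sub_percent) " [< 1% of pool]" else ""))
  if (!is.na(x$effective_concentration_nM))
    cat(sprintf("  effective concentration: %.4g nM\n", x$effective_concentration_nM))
  invisible(x)
}

#' @export
plot.kd_fit <- function(x, ...) {
  plot(x$data$conc, x$data$y, log = "x", xlab = "concentration (nM)",
       ylab = "anisotropy signal", ...)
  cg <- exp(seq(log(min(x$data$conc)), log(max(x$data$conc)), length.out = 200))
  graphics::lines(cg, predict(x, conc = cg))
  graphics::abline(v = x$kd, lty = 3)
  invisible(x)
}
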