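#' Assembly trajectory
#'
#' Cumulative molecule counts over time from live volumetric imaging of coat
#' assembly on a single bacterium.
#'
#' @param times Seconds, strictly increasing.
#' @param counts Cumulative molecule counts (non-negative).
#' @return An `assembly_trajectory` data.frame with columns `time_s`, `count`.
#' @export
assembly_trajectory <- function(times, counts) {
  stopifnot(length(times) == length(counts), length(times) >= 3,
            all(diff(times) > 0), all(counts >= 0))
  structure(data.frame(time_s = times, count = counts),
            class = c("assembly_trajectory", "data.frame"))
}

#' Coat assembly rate from a cumulative-count trajectory
#'
#' Ordinary least-squares slope of count against time over the growth phase,
#' defined as the points where the count lies between `lower` and `upper`
#' fractions of the final count (default 10-90 %). Windowing removes the
#' nucleation lag and the plateau so the slope estimates the steady assembly
#' rate in molecules per second.
#'
#' @param traj An [assembly_trajectory()] (or data.frame with `time_s`, `count`).
#' @param lower,upper Growth-phase window as fractions of the final count.
#' @return List with `rate` (molecules/sec), `se`, `n_points`, `window`.
#' @export
estimate_rate <- function(traj, lower = 0.1, upper = 0.9) {
  stopifnot(all(c("time_s", "count") %in% names(traj)))
  final <- traj$count[nrow(traj)]
  if (final == min(traj$count)) {      # flat trajectory: rate 0 by convention
    return(list(rate = 0, se = 0, n_points = nrow(traj), window = c(lower, upper)))
  }
  keep <- traj$count >= lower * final & traj$count <= upper * final
  sub <- traj[keep, , drop = FALSE]
  if (nrow(sub) < 3) stop("fewer than 3 trajectory points in the growth phase")
  fit <- stats::lm(count ~ time_s, data = sub)
  # a perfect linear trajectory is legitimate here; silence the exact-fit note
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(sm) >= 2 && !is.nan(sm["time_s", "Std. Error"]))
    sm["time_s", "Std. Error"] else 0
  list(rate = unname(stats::coef(fit)["time_s"]), se = unname(se),
       n_points = nrow(sub), window = c(lower, upper))
}

#' Predicted encapsulation completion time
#'
#' Time to assemble a full coat at a constant rate: `total_count / rate`,
#' reported in minutes.
#'
#' @param total_count Molecules in the complete coat.
#' @param rate Assembly rate, molecules/sec.
#' @return Minutes.
#' @export
completion_time <- function(total_count, rate) {
  if (!(total_count > 0 && rate > 0)) stop("total_count and rate must be positive")
  total_count / rate / 60
}

#' Four-parameter Hill model
#'
#' Sigmoidal dose-response: `bottom + (top - bottom) * conc^h / (km^h + conc^h)`.
#' `km` is the half-maximal concentration and `h` the Hill slope
#' (cooperativity exponent); h > 1 indicates positive cooperativity.
#'
#' @param conc Concentration(s), nM.
#' @param km Half-maximal concentration, nM.
#' @param hill_slope Hill exponent.
#' @param bottom,top Lower/upper asymptotes (fractions for coating curves).
#' @return Predicted response.
#' @export
hill_model <- function(conc, km, hill_slope, bottom = 0, top = 1) {
  stopifnot(km > 0)
  bottom + (top - bottom) / (1 + (km / conc)^hill_slope)
}

#' Fit the cooperative coating curve
#'
#' Nonlinear least-squares fit of the four-parameter Hill model to a coating
#' titration (fraction of bacteria coated vs protein concentration), yielding
#' the half-maximal coating concentration ("coat Km") and Hill slope.
#' Levenberg-Marquardt with box constraints is started from a deterministic
#' grid of initial values (km0 = geometric mean of the concentrations scaled
#' by 1/4..4, crossed with shallow and steep slope starts) because steep
#' cooperative curves make single-start fits fragile; the best converged
#' start by residual sum of squares is returned. Replicates are fitted
#' pointwise, not on means.
#'
#' @param titration data.frame with columns `conc_nM` and `fraction`
#'   (replicates as repeated rows), e.g. from [gen_titration()].
#' @param constrain_range Logical; fix bottom = 0 and top = 1 instead of
#'   fitting them (default `FALSE`).
#' @return A `hill_fit` object with elements `km`, `hill_slope`, `bottom`,
#'   `top`, `rss`, `converged`, `data`, plus coef/print/summary/predict/
#'   residuals methods.
#' @export
fit_hill <- function(titration, constrain_range = FALSE) {
  stopifnot(all(c("conc_nM", "fraction") %in% names(titration)))
  conc <- titration$conc_nM
  y <- titration$fraction
  stopifnot(all(conc > 0), length(unique(conc)) >= 4)
  if (diff(range(y)) <= 0.3)
    warning("fraction dynamic range <= 0.3; Hill fit may be poorly determined")

  km0 <- exp(mean(log(conc)))
  starts <- expand.grid(km = km0 * c(0.25, 0.5, 1, 2, 4), h = c(1, 4))
  dat <- data.frame(conc = conc, y = y)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- if (constrain_range) {
      try(minpack.lm::nlsLM(
        y ~ 1 / (1 + (km / conc)^h), data = dat,
        start = list(km = starts$km[i], h = starts$h[i]),
        lower = c(km = 1e-6, h = 1e-3), upper = c(km = 1e6, h = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + (km / conc)^h), data = dat,
        start = list(km = starts$km[i], h = starts$h[i],
                     bottom = min(y), top = max(y)),
        lower = c(km = 1e-6, h = 1e-3, bottom = -0.5, top = 0),
        upper = c(km = 1e6, h = 20, bottom = 1, top = 1.5),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    out <- list(km = NA_real_, hill_slope = NA_real_,
                bottom = if (constrain_range) 0 else NA_real_,
                top = if (constrain_range) 1 else NA_real_,
                rss = Inf, converged = FALSE, constrained = constrain_range,
                data = dat, nls = NULL)
  } else {
    p <- stats::coef(best$fit)
    out <- list(km = unname(p["km"]), hill_slope = unname(p["h"]),
                bottom = if (constrain_range) 0 else unname(p["bottom"]),
                top = if (constrain_range) 1 else unname(p["top"]),
                rss = best$rss, converged = TRUE, constrained = constrain_range,
                data = dat, nls = best$fit)
  }
  class(out) <- "hill_fit"
  out
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(km = object$km, hill_slope = object$hill_slope,
    bottom = object$bottom, top = object$top)
}

#' @export
predict.hill_fit <- function(object, conc = NULL, ...) {
  if (is.null(conc)) conc <- object$data$conc
  hill_model(conc, object$km, object$hill_slope, object$bottom, object$top)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hill_fit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("<hill_fit> coat Km = %.4g nM, Hill slope = %.4g (bottom %.3g, top %.3g)\n",
              x$km, x$hill_slope, x$bottom, x$top))
  cat(sprintf("  RSS = %.4g over %d points%s\n", x$rss, nrow(x$data),
              if (x$constrained) " [bottom/top fixed 0/1]" else ""))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$nls)) {
    cat("\nParameter table (asymptotic):\n")
    print(summary(object$nls)$coefficients)
  }
  invisible(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  plot(x$data$conc, x$data$y, log = "x", xlab = "concentration (nM)",
       ylab = "coating fraction", ...)
  cg <- exp(seq(log(min(x$data$conc)), log(max(x$data$conc)), length.out = 200))
  graphics::lines(cg, predict(x, conc = cg))
  graphics::abline(v = x$km, lty = 3)
  invisible(x)
}
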