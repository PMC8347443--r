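#' Constraints on an in-cell refractive-index distribution
#'
#' Summary statistics that a compartment's RI distribution must reproduce:
#' the modal RI, hard support bounds, the fraction of voxels inside a stated
#' RI band, and the fraction strictly below the mode (the asymmetry of the
#' fingerprint curve).  For control cytoplasm the reported values are a mode
#' near 1.3725, support 1.365-1.395, 99.5% of voxels in 1.365-1.39, and 34%
#' of voxels below the mode.
#'
#' @param mode_ri target modal RI value.
#' @param support_lo,support_hi hard truncation bounds (RI units).
#' @param band_lo,band_hi band over which `frac_in_band` is evaluated.
#' @param frac_in_band fraction of probability mass in `[band_lo, band_hi]`.
#' @param frac_below_mode fraction of mass strictly below `mode_ri`.
#' @return An object of class `ri_constraints`.
#' @export
ri_constraints <- function(mode_ri, support_lo, support_hi,
                           band_lo, band_hi, frac_in_band, frac_below_mode) {
  stopifnot(support_lo < mode_ri, mode_ri < support_hi,
            frac_in_band > 0, frac_in_band <= 1,
            frac_below_mode > 0, frac_below_mode < 1,
            band_lo < band_hi)
  structure(list(mode_ri = mode_ri, support_lo = support_lo,
                 support_hi = support_hi, band_lo = band_lo,
                 band_hi = band_hi, frac_in_band = frac_in_band,
                 frac_below_mode = frac_below_mode),
            class = "ri_constraints")
}

# Skew-normal density (location xi, scale omega, shape alpha), unnormalized
# over a truncated support.
dsn <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

#' Truncated skew-normal RI distribution
#'
#' A minimal unimodal family with controllable asymmetry, truncated to a hard
#' RI support.  The cumulative distribution is tabulated on a dense grid at
#' construction time; sampling uses inverse-CDF interpolation, so truncation
#' is exact (no sample can fall outside the support).
#'
#' @param location,scale,shape skew-normal parameters (location/scale in RI
#'   units, shape dimensionless; shape 0 is symmetric).
#' @param support_lo,support_hi truncation bounds (RI units).
#' @param grid_n grid resolution for the tabulated CDF.
#' @return An object of class `ri_dist`.
#' @export
ri_dist <- function(location, scale, shape, support_lo, support_hi,
                    grid_n = 4096) {
  stopifnot(scale > 0, support_lo < support_hi)
  x <- seq(support_lo, support_hi, length.out = grid_n)
  f <- dsn(x, location, scale, shape)
  dx <- x[2] - x[1]
  # trapezoid cumulative integral, renormalized to the truncated support
  cdf <- c(0, cumsum((f[-1] + f[-grid_n]) / 2 * dx))
  z <- cdf[grid_n]
  if (!is.finite(z) || z <= 0) stop("degenerate density on support")
  structure(list(family = "truncated_skew_normal",
                 location = location, scale = scale, shape = shape,
                 support_lo = support_lo, support_hi = support_hi,
                 norm = z, grid_x = x, grid_pdf = f / z, grid_cdf = cdf / z),
            class = "ri_dist")
}

#' @export
print.ri_dist <- function(x, ...) {
  cat(sprintf(
    "Truncated skew-normal RI distribution\n  location %.5f  scale %.5f  shape %.3f\n  support [%.4f, %.4f]  mode %.5f\n",
    x$location, x$scale, x$shape, x$support_lo, x$support_hi, ri_dist_mode(x)))
  invisible(x)
}

#' Density of a truncated RI distribution
#' @param d an `ri_dist`.
#' @param x RI values.
#' @return density values (0 outside the support).
#' @export
ri_dist_density <- function(d, x) {
  out <- dsn(x, d$location, d$scale, d$shape) / d$norm
  out[x < d$support_lo | x > d$support_hi] <- 0
  out
}

#' CDF of a truncated RI distribution (interpolated from the dense grid)
#' @param d an `ri_dist`.
#' @param q RI values.
#' @return cumulative probabilities.
#' @export
ri_dist_cdf <- function(d, q) {
  p <- stats::approx(d$grid_x, d$grid_cdf, xout = q, rule = 2)$y
  p[q <= d$support_lo] <- 0
  p[q >= d$support_hi] <- 1
  p
}

#' Mode of a truncated RI distribution
#' @param d an `ri_dist`.
#' @return RI value maximizing the density.
#' @export
ri_dist_mode <- function(d) {
  # grid argmax refined by golden-section search on the continuous density
  i <- which.max(d$grid_pdf)
  lo <- d$grid_x[max(1, i - 2)]
  hi <- d$grid_x[min(length(d$grid_x), i + 2)]
  if (lo >= hi) return(d$grid_x[i])
  stats::optimize(function(x) ri_dist_density(d, x), c(lo, hi),
                  maximum = TRUE, tol = 1e-9)$maximum
}

#' Probability mass of a closed RI band, by numerical integration
#' @param d an `ri_dist`.
#' @param lo,hi band bounds (RI units).
#' @return probability in `[lo, hi]`.
#' @export
ri_dist_frac_in_band <- function(d, lo, hi) {
  ri_dist_cdf(d, hi) - ri_dist_cdf(d, lo)
}

#' Probability mass strictly below an RI value
#' @param d an `ri_dist`.
#' @param x RI value.
#' @return probability below `x`.
#' @export
ri_dist_frac_below <- function(d, x) ri_dist_cdf(d, x)

#' Sample RI values by inverse-CDF interpolation
#'
#' Draws are exact with respect to truncation: every value lies in
#' `[support_lo, support_hi]`.  Uses the current R RNG stream.
#'
#' @param d an `ri_dist`.
#' @param n number of draws.
#' @return numeric vector of RI values.
#' @export
ri_dist_sample <- function(d, n) {
  if (n == 0) return(numeric(0))
  u <- stats::runif(n)
  # grid_cdf is strictly increasing wherever pdf > 0; approx inverts it
  stats::approx(d$grid_cdf, d$grid_x, xout = u, ties = "ordered", rule = 2)$y
}

#' Calibrate a truncated skew-normal to fingerprint constraints
#'
#' Fits location, scale and shape so that the distribution's mode, band mass
#' and below-mode mass reproduce the constraints; agreement is verified by
#' numerical integration on the tabulated density, never by sampling.  This
#' is how the phantom's cytoplasm and nucleus RI models are anchored to the
#' published control-cell fingerprint statistics.
#'
#' @param constraints an [ri_constraints] object.
#' @param tol maximum absolute error tolerated on `frac_in_band` and
#'   `frac_below_mode`; the mode must match within `tol` RI units as well.
#' @param max_restarts number of Nelder-Mead restarts before giving up.
#' @return A calibrated [ri_dist].
#' @export
calibrate_ri_distribution <- function(constraints, tol = 0.002,
                                      max_restarts = 8) {
  stopifnot(inherits(constraints, "ri_constraints"), tol > 0)
  cs <- constraints
  width <- cs$support_hi - cs$support_lo
  ri_scale <- width / 4  # natural length scale for mode residuals

  make_dist <- function(par) {
    ri_dist(par[1], exp(par[2]), par[3], cs$support_lo, cs$support_hi,
            grid_n = 2048)
  }
  resid <- function(par) {
    d <- tryCatch(make_dist(par), error = function(e) NULL)
    if (is.null(d)) return(c(10, 10, 10))
    c((ri_dist_mode(d) - cs$mode_ri) / ri_scale,
      ri_dist_frac_in_band(d, cs$band_lo, cs$band_hi) - cs$frac_in_band,
      ri_dist_frac_below(d, cs$mode_ri) - cs$frac_below_mode)
  }
  obj <- function(par) sum(resid(par)^2)

  # start symmetric at the target mode, then progressively skewed restarts
  starts <- list(c(cs$mode_ri, log(width / 4), 0))
  for (a in c(2, -2, 5, -5, 8, 1, 3)) {
    starts[[length(starts) + 1]] <- c(cs$mode_ri, log(width / 3), a)
  }
  best <- NULL
  for (k in seq_len(min(max_restarts, length(starts)))) {
    fit <- stats::optim(starts[[k]], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < (tol / 4)^2) break
  }

  d <- ri_dist(best$par[1], exp(best$par[2]), best$par[3],
               cs$support_lo, cs$support_hi)
  err <- c(mode = abs(ri_dist_mode(d) - cs$mode_ri),
           frac_in_band = abs(ri_dist_frac_in_band(d, cs$band_lo, cs$band_hi) -
                                cs$frac_in_band),
           frac_below_mode = abs(ri_dist_frac_below(d, cs$mode_ri) -
                                   cs$frac_below_mode))
  lim <- c(mode = tol, frac_in_band = tol, frac_below_mode = tol)
  if (any(err > lim)) {
    worst <- names(err)[which.max(err / lim)]
    stop(sprintf(
      "RI distribution calibration failed: constraint '%s' unmet (error %.3g > tol %.3g)",
      worst, err[[worst]], lim[[worst]]), call. = FALSE)
  }
  d
}
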