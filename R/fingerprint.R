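# Per-cell RI fingerprints: the "graph of pixels for each refractive index"
# that characterizes a cell, expressed as percent of in-cell voxels per RI
# bin so that cells of different sizes are comparable.  Bins are half-open
# [lo, lo + w), on a grid anchored at RI 1.3000 with default width 0.0025
# (the grid implied by the printed statistics 1.365 / 1.3725 / 1.390).

.fp_anchor <- 1.3

bin_index <- function(v, bin_width, anchor = .fp_anchor) {
  # epsilon guards values that sit exactly on a bin edge against FP error
  as.integer(floor((v - anchor) / bin_width + 1e-9))
}

#' Compute a per-cell RI fingerprint
#'
#' Histogram of in-mask voxel RI values on contiguous half-open bins
#' `[lo, lo + w)`, normalized to percent of in-mask voxels (interior bins
#' with zero count are kept so the bin grid is gap-free).
#'
#' @param stack an [ri_stack].
#' @param mask a [cell_mask] on the same grid.
#' @param bin_width bin width in RI units.
#' @param dose optional dose annotation carried into outputs.
#' @return object of class `ri_fingerprint`: a data frame with columns
#'   `bin_lo`, `percent` plus attributes `bin_width`, `cell_id`, `dose`,
#'   `n_voxels`.
#' @export
compute_fingerprint <- function(stack, mask, bin_width = 0.0025,
                                dose = NA_real_) {
  stopifnot(inherits(stack, "ri_stack"), inherits(mask, "cell_mask"),
            bin_width > 0)
  if (!identical(dim(stack$voxels), dim(mask$mask))) {
    stop("stack grid does not match mask grid")
  }
  v <- stack$voxels[mask$mask]
  if (length(v) == 0) stop("empty mask: fingerprint undefined")
  k <- bin_index(v, bin_width)
  rng <- range(k)
  counts <- tabulate(k - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  fp <- data.frame(bin_lo = .fp_anchor + (rng[1]:rng[2]) * bin_width,
                   percent = 100 * counts / length(v))
  structure(fp, class = c("ri_fingerprint", "data.frame"),
            bin_width = bin_width, cell_id = mask$cell_id, dose = dose,
            n_voxels = length(v), anchor = .fp_anchor)
}

#' @export
print.ri_fingerprint <- function(x, ...) {
  cat(sprintf(
    "RI fingerprint '%s' (dose %s): %d bins of width %g, %d voxels\n",
    attr(x, "cell_id"), format(attr(x, "dose")), nrow(x),
    attr(x, "bin_width"), attr(x, "n_voxels")))
  invisible(x)
}

same_binning <- function(a, b) {
  isTRUE(all.equal(attr(a, "bin_width"), attr(b, "bin_width"))) &&
    isTRUE(all.equal(attr(a, "anchor"), attr(b, "anchor")))
}

#' Average fingerprints across a cohort
#'
#' Equal weight per cell (each cell's fingerprint already sums to 100, so
#' cell size does not leak into the cohort curve).  Bin grids are aligned
#' on their common anchor; bins absent from a cell count as 0.
#'
#' @param fps list of `ri_fingerprint` objects with identical binning.
#' @param dose optional dose annotation for the result.
#' @return an `ri_fingerprint` holding the cohort-mean curve.
#' @export
mean_fingerprint <- function(fps, dose = NA_real_) {
  stopifnot(length(fps) >= 1)
  w <- attr(fps[[1]], "bin_width")
  for (fp in fps) {
    if (!same_binning(fps[[1]], fp)) {
      stop("fingerprints have mismatched binning; cannot average")
    }
  }
  k_all <- lapply(fps, function(fp) bin_index(fp$bin_lo + w / 2, w))
  rng <- range(unlist(k_all))
  acc <- numeric(rng[2] - rng[1] + 1L)
  for (i in seq_along(fps)) {
    acc[k_all[[i]] - rng[1] + 1L] <- acc[k_all[[i]] - rng[1] + 1L] +
      fps[[i]]$percent
  }
  fp <- data.frame(bin_lo = .fp_anchor + (rng[1]:rng[2]) * w,
                   percent = acc / length(fps))
  structure(fp, class = c("ri_fingerprint", "data.frame"),
            bin_width = w, cell_id = sprintf("mean_of_%d", length(fps)),
            dose = dose, n_voxels = sum(vapply(fps, attr, 0L, "n_voxels")),
            anchor = .fp_anchor)
}

#' Summary statistics of an RI fingerprint
#'
#' @param fp an `ri_fingerprint`.
#' @param band RI band `(lo, hi)` for the in-band percentage; a bin counts
#'   as in-band when its center lies in `[lo, hi]`.
#' @param high_cut bins with center above this RI contribute to
#'   `high_ri_frac` (the nanoparticle-sensitive tail).
#' @return object of class `fingerprint_stats`: `mode_ri` (modal bin
#'   center, ties to the lower bin), `peak_height` (% in modal bin),
#'   `ri_min`/`ri_max` (lower bin edges of the extreme nonzero bins),
#'   `frac_in_band`, `frac_below_mode` (% strictly below the modal bin) and
#'   `high_ri_frac`, all in percent of in-cell voxels.
#' @export
fingerprint_stats <- function(fp, band = c(1.365, 1.39), high_cut = 1.39) {
  stopifnot(inherits(fp, "ri_fingerprint"))
  w <- attr(fp, "bin_width")
  centers <- fp$bin_lo + w / 2
  imode <- which.max(fp$percent)  # which.max takes the first (lowest) tie
  nz <- which(fp$percent > 0)
  eps <- w * 1e-6
  structure(list(
    mode_ri = centers[imode],
    peak_height = fp$percent[imode],
    ri_min = fp$bin_lo[min(nz)],
    ri_max = fp$bin_lo[max(nz)],
    frac_in_band = sum(fp$percent[centers >= band[1] - eps &
                                    centers <= band[2] + eps]),
    frac_below_mode = sum(fp$percent[seq_len(imode - 1L)]),
    high_ri_frac = sum(fp$percent[centers > high_cut + eps]),
    band = band, high_cut = high_cut
  ), class = "fingerprint_stats")
}

#' @export
print.fingerprint_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Fingerprint stats: mode %.4f (peak %.2f%%), band [%.4f, %.4f] ",
           "= %.2f%%, below mode %.2f%%, above %.3f = %.3f%%\n"),
    x$mode_ri, x$peak_height, x$band[1], x$band[2], x$frac_in_band,
    x$frac_below_mode, x$high_cut, x$high_ri_frac))
  invisible(x)
}

#' Compare a treated cohort fingerprint against control
#'
#' Quantifies the dose-dependent right shift of the RI curve: every delta is
#' treated minus control, computed on cohort-mean fingerprints.
#'
#' @param control,treated `ri_fingerprint` objects on identical binning
#'   (cohort means).
#' @param transition_band RI band whose mass shift attests nanoparticle
#'   presence (default 1.38-1.39).
#' @param high_cut threshold for the high-RI tail (default 1.39).
#' @return object of class `shift_report`: `delta_peak_height`,
#'   `delta_transition_band`, `delta_high_ri_frac`,
#'   `signed_area_right_of_mode` (percentage points).
#' @export
compare_fingerprints <- function(control, treated,
                                 transition_band = c(1.38, 1.39),
                                 high_cut = 1.39) {
  stopifnot(inherits(control, "ri_fingerprint"),
            inherits(treated, "ri_fingerprint"))
  if (!same_binning(control, treated)) {
    stop("fingerprint binning mismatch between control and treated")
  }
  sc <- fingerprint_stats(control, band = transition_band,
                          high_cut = high_cut)
  st <- fingerprint_stats(treated, band = transition_band,
                          high_cut = high_cut)
  # signed area right of the control modal bin, on the aligned union grid
  w <- attr(control, "bin_width")
  u <- merge(data.frame(bin_lo = control$bin_lo, pc = control$percent),
             data.frame(bin_lo = treated$bin_lo, pt = treated$percent),
             by = "bin_lo", all = TRUE)
  u[is.na(u)] <- 0
  right <- u$bin_lo > sc$mode_ri  # bins fully right of the control mode
  structure(list(
    delta_peak_height = st$peak_height - sc$peak_height,
    delta_transition_band = st$frac_in_band - sc$frac_in_band,
    delta_high_ri_frac = st$high_ri_frac - sc$high_ri_frac,
    signed_area_right_of_mode = sum(u$pt[right] - u$pc[right]),
    transition_band = transition_band, high_cut = high_cut
  ), class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf(
    paste0("Fingerprint shift (treated - control):\n",
           "  peak height       %+.3f pp\n",
           "  %.3f-%.3f band    %+.3f pp\n",
           "  high-RI (>%.3f)   %+.3f pp\n",
           "  area right of mode %+.3f pp\n"),
    x$delta_peak_height, x$transition_band[1], x$transition_band[2],
    x$delta_transition_band, x$high_cut, x$delta_high_ri_frac,
    x$signed_area_right_of_mode))
  invisible(x)
}

#' Plot cohort fingerprints (percent of voxels vs RI)
#'
#' @param fps named list of `ri_fingerprint` objects (names become legend
#'   labels, e.g. doses).
#' @param file optional PNG path; when given the plot is written there.
#' @param main plot title.
#' @return invisibly, `file` (or NULL when plotting to the active device).
#' @export
plot_fingerprints <- function(fps, file = NULL,
                              main = "RI fingerprint by condition") {
  stopifnot(length(fps) >= 1)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off())
  }
  xr <- range(unlist(lapply(fps, function(f) range(f$bin_lo))))
  yr <- c(0, max(unlist(lapply(fps, function(f) max(f$percent)))))
  cols <- grDevices::hcl.colors(max(3, length(fps)), "Dark 2")
  graphics::plot(NA, xlim = xr + c(0, attr(fps[[1]], "bin_width")),
                 ylim = yr * 1.05, xlab = "Refractive index",
                 ylab = "% of in-cell voxels", main = main)
  w <- attr(fps[[1]], "bin_width")
  for (i in seq_along(fps)) {
    graphics::lines(fps[[i]]$bin_lo + w / 2, fps[[i]]$percent,
                    col = cols[i], lwd = 2)
  }
  lbl <- names(fps)
  if (is.null(lbl)) lbl <- paste("cohort", seq_along(fps))
  graphics::legend("topright", legend = lbl, col = cols[seq_along(fps)],
                   lwd = 2, bty = "n")
  invisible(file)
}
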