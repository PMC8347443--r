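# Fluorescence validation of RI-based detections.  Nanodiamonds are
# intrinsically fluorescent, so true nanoparticle accumulations are
# fluorescence-positive while chromatin (which can also exceed RI 1.39) is
# not; overlap statistics (Manders M1, Dice) and per-dose group tests
# reproduce the published validation logic.

#' Otsu threshold of a numeric sample
#'
#' Classic maximization of between-class variance on a fixed-resolution
#' histogram.  Returns the threshold plus `eta2`, the fraction of total
#' variance explained by the two-class split (1 = perfectly bimodal,
#' ~0.6-0.7 for a featureless unimodal Gaussian).
#'
#' @param values numeric vector.
#' @param n_bins histogram resolution.
#' @return list `(threshold, eta2)`.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  rng <- range(values)
  if (!is.finite(rng[1]) || rng[2] <= rng[1]) {
    stop("degenerate threshold: intensities are constant", call. = FALSE)
  }
  h <- tabulate(pmin(n_bins,
                     1L + floor((values - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  sb2 <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)
  total_var <- sum(p * (mids - mu_t)^2)
  list(threshold = mids[k] + diff(rng) / n_bins / 2,
       eta2 = if (total_var > 0) sb2[k] / total_var else 0)
}

#' Binarize a fluorescence channel inside the cell
#'
#' Otsu-thresholds the in-mask intensities, but only accepts the split when
#' it explains at least `min_eta2` of the intensity variance; an
#' effectively unimodal channel (e.g. an unexposed cell showing pure
#' background noise) yields zero positives instead of an arbitrary split of
#' the noise.
#'
#' @param fl a [fluor_stack].
#' @param mask a [cell_mask] on the same grid.
#' @param min_eta2 bimodality acceptance level for the Otsu split.
#' @return logical array of fluorescence-positive voxels (subset of the
#'   mask) with attributes `threshold` and `eta2`.
#' @export
binarize_fluorescence <- function(fl, mask, min_eta2 = 0.8) {
  stopifnot(inherits(fl, "fluor_stack"), inherits(mask, "cell_mask"))
  if (!identical(dim(fl$voxels), dim(mask$mask))) {
    stop("fluorescence grid does not match mask grid")
  }
  v <- fl$voxels[mask$mask]
  ot <- otsu_threshold(v)
  pos <- array(FALSE, dim = dim(fl$voxels))
  if (ot$eta2 >= min_eta2) {
    pos <- mask$mask & fl$voxels > ot$threshold
  }
  attr(pos, "threshold") <- ot$threshold
  attr(pos, "eta2") <- ot$eta2
  pos
}

#' Overlap statistics between two binary masks
#'
#' @param band_mask logical array (RI-band detections).
#' @param fluor_mask logical array (fluorescence positives), same grid.
#' @return object of class `coloc_stats`: `M1` (fraction of band voxels
#'   that are fluorescence-positive; 0 when the band is empty), `dice`
#'   (`2|A.B| / (|A| + |B|)`; 0 when both empty), `n_band`, `n_fluor`.
#' @export
coloc_stats <- function(band_mask, fluor_mask) {
  stopifnot(is.logical(band_mask), is.logical(fluor_mask))
  if (!identical(dim(band_mask), dim(fluor_mask))) {
    stop("mask grids do not match")
  }
  n_band <- sum(band_mask)
  n_fluor <- sum(fluor_mask)
  inter <- sum(band_mask & fluor_mask)
  structure(list(
    M1 = if (n_band > 0) inter / n_band else 0,
    dice = if (n_band + n_fluor > 0) 2 * inter / (n_band + n_fluor) else 0,
    n_band = n_band, n_fluor = n_fluor, n_intersect = inter
  ), class = "coloc_stats")
}

#' @export
print.coloc_stats <- function(x, ...) {
  cat(sprintf("Co-localization: M1 = %.3f, Dice = %.3f (band %d, fluor %d voxels)\n",
              x$M1, x$dice, x$n_band, x$n_fluor))
  invisible(x)
}

#' Classify band components as nanoparticle or not via fluorescence
#'
#' A component is a nanoparticle accumulation iff at least `min_overlap` of
#' its voxels are fluorescence-positive (boundary inclusive); chromatin
#' components in the nucleus fail this and are labelled non-NP.
#'
#' @param detection a `detection_result` from [detect_band()].
#' @param fluor_mask logical array of fluorescence positives.
#' @param min_overlap overlap fraction at or above which a component is NP.
#' @return the detection's `components` data frame with extra columns
#'   `fluor_overlap` and `label` ("NP" / "non-NP").
#' @export
classify_components <- function(detection, fluor_mask, min_overlap = 0.5) {
  stopifnot(inherits(detection, "detection_result"), is.logical(fluor_mask))
  comps <- detection$components
  if (nrow(comps) == 0) {
    comps$fluor_overlap <- numeric(0)
    comps$label <- character(0)
    return(comps)
  }
  ov <- vapply(comps$id, function(id) {
    sel <- detection$labels == id
    mean(fluor_mask[sel])
  }, numeric(1))
  comps$fluor_overlap <- ov
  comps$label <- ifelse(ov >= min_overlap, "NP", "non-NP")
  comps
}

#' Per-cell mean fluorescence
#'
#' Arithmetic mean of in-mask intensities in AU; the per-cell summary whose
#' dose response (5.1 / 10.1 / 15.1 AU for 0 / 0.25 / 0.5 mg/mL) validates
#' the uptake estimate.
#'
#' @param fl a [fluor_stack].
#' @param mask a [cell_mask] on the same grid.
#' @return mean intensity (AU).
#' @export
per_cell_fluorescence <- function(fl, mask) {
  stopifnot(inherits(fl, "fluor_stack"), inherits(mask, "cell_mask"))
  if (!identical(dim(fl$voxels), dim(mask$mask))) {
    stop("fluorescence grid does not match mask grid")
  }
  if (mask$voxel_count == 0) stop("empty mask")
  mean(fl$voxels[mask$mask])
}

#' Per-dose group comparison: t-tests, one-way ANOVA, Fisher's PLSD
#'
#' Two-sided pooled-variance Student t-tests of each treated dose against
#' the control (lowest dose), a one-way ANOVA omnibus F, and Fisher's
#' protected-LSD pairwise tests built on the ANOVA pooled mean-square error
#' with N - k error degrees of freedom.
#'
#' @param values numeric vector (one value per cell, e.g. per-cell mean
#'   fluorescence).
#' @param doses vector of the same length assigning each value to a dose.
#' @return object of class `group_stats`: `summary` (dose, n, mean, sem),
#'   `t_tests` (treated dose vs control: t, df, p), `anova` (F, df1, df2,
#'   p), `plsd` (all pairs: diff, t, p).
#' @export
group_compare <- function(values, doses) {
  stopifnot(length(values) == length(doses))
  lev <- sort(unique(doses))
  if (length(lev) < 2) stop("need at least 2 dose groups")
  groups <- lapply(lev, function(d) values[doses == d])
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2)) stop("every dose group needs at least 2 values")
  if (all(vapply(groups, function(g) stats::var(g) == 0, TRUE))) {
    stop("degenerate test: zero within-group variance in every group",
         call. = FALSE)
  }
  summ <- data.frame(dose = lev, n = ns,
                     mean = vapply(groups, mean, 0),
                     sem = vapply(groups, function(g)
                       stats::sd(g) / sqrt(length(g)), 0))

  pooled_t <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    list(t = t, df = na + nb - 2, p = 2 * stats::pt(-abs(t), na + nb - 2))
  }
  tt <- do.call(rbind, lapply(seq_along(lev)[-1], function(i) {
    r <- pooled_t(groups[[i]], groups[[1]])
    data.frame(dose = lev[i], control = lev[1], t = r$t, df = r$df, p = r$p)
  }))

  # one-way ANOVA from group sums of squares
  grand <- mean(values)
  ss_between <- sum(ns * (summ$mean - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(lev) - 1
  df2 <- length(values) - length(lev)
  mse <- ss_within / df2
  f <- (ss_between / df1) / mse
  an <- list(F = f, df1 = df1, df2 = df2,
             p = stats::pf(f, df1, df2, lower.tail = FALSE))

  pairs <- utils::combn(seq_along(lev), 2)
  plsd <- do.call(rbind, apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    diff <- summ$mean[j] - summ$mean[i]
    t <- diff / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    data.frame(dose_a = lev[i], dose_b = lev[j], diff = diff, t = t,
               df = df2, p = 2 * stats::pt(-abs(t), df2))
  }))
  rownames(plsd) <- NULL

  structure(list(summary = summ, t_tests = tt, anova = an, plsd = plsd),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("Per-dose summary:\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  cat("Fisher PLSD pairwise tests:\n")
  print(x$plsd, row.names = FALSE)
  invisible(x)
}
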