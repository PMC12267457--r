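#' Spectral preprocessing configuration
#'
#' Parameters of the processing chain applied to each raw MALDI profile, in
#' this fixed order: baseline correction, Savitzky-Golay smoothing, local
#' noise estimation, S/N-thresholded peak picking. Defaults are the settings
#' used for collagen fingerprint screening of archaeological bone:
#' baseline \code{precision = 15} segments with \code{relative offset = 25},
#' Savitzky-Golay smoothing with a 0.3 Da window run for 2 cycles, and peak
#' picking at S/N 3.0 with the centroid taken at 75\% of peak height.
#'
#' @param baseline_precision integer >= 2; number of equal-width m/z segments
#'   whose minima anchor the baseline.
#' @param baseline_relative_offset percent by which each anchor is lifted
#'   above the segment minimum, relative to the segment's robust intensity
#'   spread (median minus minimum).
#' @param smooth_window smoothing window width in Da (converted to an odd
#'   number of sample points from the local m/z spacing; polynomial order 2).
#' @param smooth_cycles number of smoothing passes, >= 1.
#' @param snr_threshold minimum apex signal-to-noise ratio for a peak.
#' @param picking_height fraction of apex height (strictly between 0 and 1)
#'   at which the two profile crossings defining the centroid are taken.
#' @param noise_window width in Da of the sliding windows used for the
#'   robust local noise estimate.
#' @return A list of class \code{zooms_preprocess_config}.
#' @export
preprocess_config <- function(baseline_precision = 15L,
                              baseline_relative_offset = 25,
                              smooth_window = 0.3,
                              smooth_cycles = 2L,
                              snr_threshold = 3.0,
                              picking_height = 0.75,
                              noise_window = 100) {
  stopifnot(baseline_precision >= 2L, baseline_relative_offset >= 0,
            smooth_window > 0, smooth_cycles >= 1L, snr_threshold > 0,
            picking_height > 0, picking_height < 1, noise_window > 0)
  structure(list(baseline_precision = as.integer(baseline_precision),
                 baseline_relative_offset = baseline_relative_offset,
                 smooth_window = smooth_window,
                 smooth_cycles = as.integer(smooth_cycles),
                 snr_threshold = snr_threshold,
                 picking_height = picking_height,
                 noise_window = noise_window),
            class = "zooms_preprocess_config")
}

.stage_flag <- function(s, flag) isTRUE(attr(s, flag))

#' Baseline correction by segment minima
#'
#' The m/z axis is split into \code{baseline_precision} equal-width segments.
#' Each segment contributes one anchor point: its intensity minimum, lifted
#' by \code{baseline_relative_offset} percent of the segment's robust
#' intensity spread (median minus minimum, so that sparse tall peaks do not
#' inflate the offset). The baseline is the piecewise-linear interpolation
#' through the anchors (constant beyond the outermost anchors); it is
#' subtracted and negative residuals are clipped to zero. A constant
#' spectrum therefore maps to all zeros, and peak apexes sit on a locally
#' flat background.
#'
#' @param s a \code{zooms_spectrum}.
#' @param cfg a [preprocess_config()].
#' @return The corrected \code{zooms_spectrum} (same length), flagged so that
#'   downstream stages know the baseline has been removed.
#' @export
correct_baseline <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "zooms_spectrum"))
  n <- length(s$mz)
  k <- cfg$baseline_precision
  if (n < 2L * k) {
    warning("spectrum shorter than baseline segments; using a single segment")
    k <- 1L
  }
  edges <- seq(min(s$mz), max(s$mz), length.out = k + 1L)
  seg <- findInterval(s$mz, edges, rightmost.closed = TRUE)
  ax <- numeric(k); ay <- numeric(k); keep <- logical(k)
  for (i in seq_len(k)) {
    idx <- which(seg == i)
    if (length(idx) == 0L) next
    ymin <- min(s$intensity[idx])
    spread <- stats::median(s$intensity[idx]) - ymin
    ax[i] <- s$mz[idx[which.min(s$intensity[idx])]]
    ay[i] <- ymin + cfg$baseline_relative_offset / 100 * spread
    keep[i] <- TRUE
  }
  ax <- ax[keep]; ay <- ay[keep]
  if (length(ax) >= 2L) {
    # extrapolate linearly to the axis ends so a ramp-shaped background is
    # removed at the edges too (constant extension would leave a residual)
    m1 <- (ay[2L] - ay[1L]) / (ax[2L] - ax[1L])
    m2 <- (ay[length(ay)] - ay[length(ay) - 1L]) /
          (ax[length(ax)] - ax[length(ax) - 1L])
    ax <- c(min(s$mz), ax, max(s$mz))
    ay <- c(ay[1L] + m1 * (min(s$mz) - ax[2L]), ay,
            ay[length(ay)] + m2 * (max(s$mz) - ax[length(ax) - 1L]))
    dup <- duplicated(ax)
    ax <- ax[!dup]; ay <- ay[!dup]
  }
  base <- if (length(ax) == 1L) rep(ay, n)
          else stats::approx(ax, ay, xout = s$mz, rule = 2)$y
  out <- s
  out$intensity <- pmax(s$intensity - base, 0)
  attr(out, "baseline_corrected") <- TRUE
  attr(out, "smoothed") <- attr(s, "smoothed")
  out
}

#' Savitzky-Golay smoothing
#'
#' Applies an order-2 Savitzky-Golay filter \code{smooth_cycles} times. The
#' window is \code{smooth_window} Da converted to an odd number of points
#' using the median m/z spacing; windows narrower than 5 points are widened
#' to 5 (the filter needs more points than its polynomial order), and a
#' window that cannot fit the spectrum makes the call a warning no-op.
#' Order-2 Savitzky-Golay reproduces quadratic signals exactly.
#'
#' @inheritParams correct_baseline
#' @return The smoothed \code{zooms_spectrum}, flagged as smoothed.
#' @export
smooth_spectrum <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "zooms_spectrum"))
  dmz <- stats::median(diff(s$mz))
  np <- max(5L, as.integer(round(cfg$smooth_window / dmz)))
  if (np %% 2L == 0L) np <- np + 1L
  if (np < 3L || np >= length(s$mz)) {
    warning("smoothing window does not fit the spectrum; skipping")
    return(s)
  }
  out <- s
  for (i in seq_len(cfg$smooth_cycles))
    out$intensity <- signal::sgolayfilt(out$intensity, p = 2, n = np)
  out$intensity <- pmax(out$intensity, 0)
  attr(out, "baseline_corrected") <- attr(s, "baseline_corrected")
  attr(out, "smoothed") <- TRUE
  out
}

# Windowed robust statistics: running median (residual local background)
# and MAD noise, linearly interpolated to every sample point.
.noise_background <- function(s, window = 100) {
  n <- length(s$mz)
  span <- max(s$mz) - min(s$mz)
  k <- max(1L, as.integer(ceiling(span / window)))
  edges <- seq(min(s$mz), max(s$mz), length.out = k + 1L)
  seg <- findInterval(s$mz, edges, rightmost.closed = TRUE)
  cx <- numeric(0); cy <- numeric(0); cb <- numeric(0)
  for (i in seq_len(k)) {
    idx <- which(seg == i)
    if (length(idx) < 2L) next
    cx <- c(cx, mean(range(s$mz[idx])))
    cy <- c(cy, stats::mad(s$intensity[idx]))  # mad() already scales by 1.4826
    cb <- c(cb, stats::median(s$intensity[idx]))
  }
  floor_val <- max(.Machine$double.eps, 1e-12 * max(1, max(s$intensity)))
  if (length(cx) == 0L)
    return(list(noise = rep(floor_val, n), background = rep(0, n)))
  interp <- function(v) {
    if (length(cx) == 1L) rep(v, n)
    else stats::approx(cx, v, xout = s$mz, rule = 2)$y
  }
  list(noise = pmax(interp(cy), floor_val), background = interp(cb))
}

#' Robust local noise estimate
#'
#' Median absolute deviation (scaled by 1.4826 for consistency with the
#' Gaussian standard deviation) of the intensities in sliding windows of
#' \code{window} Da, linearly interpolated to every sample point. The
#' estimate is robust: sparse tall peaks barely move it. An all-zero
#' spectrum yields a machine-epsilon floor rather than zero so that S/N
#' ratios stay finite.
#'
#' @param s a baseline-corrected \code{zooms_spectrum}.
#' @param window window width in Da (default 100).
#' @return Numeric vector of strictly positive per-point noise levels.
#' @export
estimate_noise <- function(s, window = 100) {
  stopifnot(inherits(s, "zooms_spectrum"), window > 0)
  .noise_background(s, window)$noise
}

#' S/N-thresholded peak picking with fractional-height centroiding
#'
#' Local intensity maxima whose apex height meets \code{snr_threshold}
#' times the local noise level become peaks. Apex height and S/N are
#' measured above the residual local background (the running median of the
#' corrected profile): after ideal baseline removal the background is zero
#' and this is simply apex over noise, but measuring above the running
#' median keeps the threshold meaningful when a small baseline pedestal
#' survives correction. Each peak's centroid m/z is the midpoint of the two
#' linearly interpolated crossings of the profile at \code{picking_height}
#' of the apex height, searched outward from the apex; the reported
#' intensity is the apex height and the S/N is recorded. The function
#' expects a baseline-corrected, smoothed profile and warns (but proceeds)
#' when the pipeline order was not respected.
#'
#' @param s a \code{zooms_spectrum}, baseline-corrected and smoothed.
#' @param cfg a [preprocess_config()].
#' @param noise optional precomputed per-point noise vector, typically
#'   estimated on the baseline-corrected profile before smoothing (what
#'   [preprocess_spectrum()] does); default [estimate_noise()] on \code{s}
#'   itself with \code{cfg$noise_window}.
#' @return A \code{zooms_peaklist} (possibly with zero peaks).
#' @export
pick_peaks <- function(s, cfg = preprocess_config(), noise = NULL) {
  stopifnot(inherits(s, "zooms_spectrum"))
  if (!.stage_flag(s, "baseline_corrected") || !.stage_flag(s, "smoothed"))
    warning("pick_peaks called on a spectrum that was not baseline-corrected",
            " and smoothed; pipeline order is baseline -> smooth -> pick")
  nb <- .noise_background(s, cfg$noise_window)
  noise <- if (is.null(noise)) nb$noise else noise
  bg <- nb$background
  y <- s$intensity; x <- s$mz; n <- length(y)
  if (n < 3L) return(zooms_peaklist(
    data.frame(mz = numeric(0), intensity = numeric(0), snr = numeric(0)),
    s$sample_id, s$replicate_index))

  d <- diff(y)
  apex <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  height <- y[apex] - bg[apex]
  keep <- height > 0 & height / noise[apex] >= cfg$snr_threshold
  apex <- apex[keep]
  # an apex must dominate its neighbourhood (+/- the smoothing window):
  # noise ripples on the flank of a strong peak otherwise pass the S/N
  # threshold by inheriting the peak's height
  if (length(apex) > 0L) {
    w <- cfg$smooth_window
    apex <- apex[vapply(apex, function(i) {
      nb <- which(x >= x[i] - w & x <= x[i] + w)
      y[i] >= max(y[nb])
    }, logical(1))]
  }

  # Walk outward from the apex until the profile crosses the fractional
  # height level; linearly interpolate the crossing. If the profile starts
  # rising again before crossing (overlapping neighbour), truncate at the
  # valley.
  cross <- function(i, dir) {
    h <- bg[i] + cfg$picking_height * (y[i] - bg[i])
    j <- i
    repeat {
      k <- j + dir
      if (k < 1L || k > n) return(x[j])
      if (y[k] < h) {
        if (y[k] == y[j]) return(x[j])
        return(x[j] + (h - y[j]) * (x[k] - x[j]) / (y[k] - y[j]))
      }
      if (y[k] > y[j] && j != i) return(x[j])
      j <- k
    }
  }

  res <- lapply(apex, function(i) {
    left <- cross(i, -1L)
    right <- cross(i, +1L)
    c(mz = (left + right) / 2, intensity = y[i] - bg[i],
      snr = (y[i] - bg[i]) / noise[i])
  })
  peaks <- if (length(res) == 0L)
    data.frame(mz = numeric(0), intensity = numeric(0), snr = numeric(0))
  else as.data.frame(do.call(rbind, res))
  zooms_peaklist(peaks, s$sample_id, s$replicate_index)
}

#' Full preprocessing chain for one spectrum
#'
#' Baseline correction, noise estimation, smoothing and peak picking, in
#' that order. The noise level is estimated on the baseline-corrected
#' profile \emph{before} smoothing: smoothing attenuates the noise it is
#' meant to cosmetically suppress, and thresholding at S/N 3 against the
#' smoothed (attenuated) noise scale would re-admit pure noise maxima as
#' peaks. Calibrating S/N to the raw-noise scale keeps the threshold's
#' meaning independent of the smoothing window.
#'
#' @inheritParams pick_peaks
#' @return A \code{zooms_peaklist}.
#' @export
preprocess_spectrum <- function(s, cfg = preprocess_config()) {
  b <- correct_baseline(s, cfg)
  noise <- estimate_noise(b, cfg$noise_window)
  pick_peaks(smooth_spectrum(b, cfg), cfg, noise = noise)
}
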