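# Small in-code fixtures shared across test files.

# A minimal 3-leaf, 2-marker library: marker M1 separates A from {B, C},
# marker M2 separates C from {A, B}. Category "BC" groups B and C.
tiny_library <- function() {
  panel <- data.frame(
    marker_id = c("M1", "M2"), letter_code = c("X", "Y"),
    window_min = c(1000, 2000), window_max = c(1100, 2100))
  values <- data.frame(
    leaf = c("A", "B", "C", "A", "B", "C"),
    marker_id = c("M1", "M1", "M1", "M2", "M2", "M2"),
    mz = c(1010, 1050, 1050, 2010, 2010, 2050),
    provenance = "literature")
  reference_library(panel, values,
                    list(root = c("A", "B", "C"), A = "A", B = "B", C = "C",
                         BC = c("B", "C")))
}

# Independent brute-force oracle for minimal_category: scan every category,
# keep covers, order by (size, name).
brute_minimal_category <- function(lib, taxa) {
  best_name <- NULL
  best_size <- Inf
  for (nm in names(lib$categories)) {
    m <- lib$categories[[nm]]
    if (!all(taxa %in% m)) next
    if (length(m) < best_size ||
        (length(m) == best_size && nm < best_name)) {
      best_name <- nm
      best_size <- length(m)
    }
  }
  best_name
}

# Spectrum of Gaussian peaks on a regular grid plus optional baseline/noise.
planted_spectrum <- function(centers, amplitudes, sigma = 0.08,
                             mz_min = min(centers) - 30,
                             mz_max = max(centers) + 30, step = 0.02,
                             baseline = function(mz) 0, noise_sd = 0,
                             sample_id = "planted") {
  mz <- seq(mz_min, mz_max, by = step)
  y <- baseline(mz)
  if (noise_sd > 0) y <- y + stats::rnorm(length(mz), 0, noise_sd)
  for (i in seq_along(centers))
    y <- y + amplitudes[i] * exp(-(mz - centers[i])^2 / (2 * sigma^2))
  zooms_spectrum(mz, pmax(y, 0), sample_id)
}

# Mark a spectrum as already baseline-corrected and smoothed (for tests that
# target pick_peaks in isolation).
mark_processed <- function(s) {
  attr(s, "baseline_corrected") <- TRUE
  attr(s, "smoothed") <- TRUE
  s
}

# Full-survival flags for the default library's panel.
full_survival <- function(lib = default_library()) {
  stats::setNames(rep(TRUE, nrow(lib$panel)), lib$panel$marker_id)
}
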