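#' Construct a MALDI-TOF spectrum
#'
#' A continuous m/z-intensity profile from one MALDI acquisition (one spot).
#' The m/z axis must be strictly increasing and intensities nonnegative;
#' inputs violating either are repaired (re-sorted, clipped at zero) with a
#' warning rather than silently accepted.
#'
#' @param mz numeric vector of m/z values (Da), length >= 2.
#' @param intensity numeric vector, same length.
#' @param sample_id sample label (e.g. "CLC476").
#' @param replicate_index spot replicate number, >= 1.
#' @return An object of class \code{zooms_spectrum} with elements \code{mz},
#'   \code{intensity}, \code{sample_id}, \code{replicate_index}.
#' @export
zooms_spectrum <- function(mz, intensity, sample_id = "", replicate_index = 1L) {
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity), length(mz) >= 2L,
            replicate_index >= 1L)
  if (anyNA(mz) || anyNA(intensity)) stop("NA values in spectrum arrays")
  if (is.unsorted(mz, strictly = TRUE)) {
    warning("m/z axis not strictly increasing; re-sorting")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    keep <- c(TRUE, diff(mz) > 0)
    mz <- mz[keep]; intensity <- intensity[keep]
  }
  if (any(intensity < 0)) {
    warning("negative intensities clipped to 0")
    intensity <- pmax(intensity, 0)
  }
  structure(list(mz = mz, intensity = intensity,
                 sample_id = as.character(sample_id),
                 replicate_index = as.integer(replicate_index)),
            class = "zooms_spectrum")
}

#' @export
print.zooms_spectrum <- function(x, ...) {
  cat(sprintf("ZooMS spectrum '%s' (replicate %d): %d points, m/z %.1f-%.1f\n",
              x$sample_id, x$replicate_index, length(x$mz),
              min(x$mz), max(x$mz)))
  invisible(x)
}

#' Read a spectrum from mzML or two-column text
#'
#' Text input is whitespace- or comma-separated \code{m/z intensity} pairs,
#' one per line; lines starting with \code{#} are ignored. mzML input is read
#' through the \pkg{mzR} Bioconductor parser; by default the first spectrum
#' in the file is used.
#'
#' @param path input file.
#' @param format "xy_text", "mzml", or "auto" (from the extension).
#' @param scan 1-based spectrum index for mzML input.
#' @param sample_id,replicate_index labels attached to the returned spectrum;
#'   defaults derive the sample id from the file name.
#' @return A \code{zooms_spectrum}.
#' @export
read_spectrum <- function(path, format = c("auto", "xy_text", "mzml"),
                          scan = 1L, sample_id = NULL, replicate_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "xy_text"
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))

  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the 'mzR' package")
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, scan)
    return(zooms_spectrum(pk[, 1], pk[, 2], sample_id, replicate_index))
  }

  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty spectrum file: ", path)
  parts <- strsplit(trimws(lines), "[,;[:space:]]+")
  n <- lengths(parts)
  bad <- which(n < 2L)
  if (length(bad) > 0L)
    stop(sprintf("cannot parse line %d of '%s': need two columns", bad[1L], path))
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(mz) | is.na(it))
  if (length(bad) > 0L)
    stop(sprintf("non-numeric value on line %d of '%s'", bad[1L], path))
  zooms_spectrum(mz, it, sample_id, replicate_index)
}

#' Write a spectrum to two-column text or mzML
#'
#' @param s a \code{zooms_spectrum}.
#' @param path output file.
#' @param format "xy_text", "mzml", or "auto" (from the extension).
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("auto", "xy_text", "mzml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "xy_text"
  if (format == "xy_text") {
    utils::write.table(data.frame(s$mz, s$intensity), path,
                       sep = " ", row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the 'mzR' package")
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = length(s$mz), totIonCurrent = sum(s$intensity),
    retentionTime = 0, basePeakMZ = s$mz[which.max(s$intensity)],
    basePeakIntensity = max(s$intensity), collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = min(s$mz), highMZ = max(s$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(list(cbind(s$mz, s$intensity)), file = path, header = hdr)
  invisible(path)
}

#' Construct a peak list
#'
#' Picked centroids for one spectrum, sorted by m/z, with apex intensity and
#' signal-to-noise ratio per peak.
#'
#' @param peaks data.frame with numeric columns \code{mz}, \code{intensity},
#'   \code{snr}; zero rows allowed.
#' @param sample_id,replicate_index labels.
#' @return An object of class \code{zooms_peaklist}.
#' @export
zooms_peaklist <- function(peaks, sample_id = "", replicate_index = 1L) {
  peaks <- as.data.frame(peaks)
  need <- c("mz", "intensity", "snr")
  miss <- setdiff(need, names(peaks))
  if (length(miss) > 0L)
    stop("peak list missing column(s): ", paste(miss, collapse = ", "))
  peaks <- peaks[need]
  if (nrow(peaks) > 0L) {
    if (any(peaks$snr < 0)) stop("negative S/N in peak list")
    if (is.unsorted(peaks$mz)) peaks <- peaks[order(peaks$mz), ]
  }
  rownames(peaks) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 replicate_index = as.integer(replicate_index),
                 peaks = peaks),
            class = "zooms_peaklist")
}

#' @export
print.zooms_peaklist <- function(x, ...) {
  cat(sprintf("ZooMS peak list '%s' (replicate %d): %d peaks\n",
              x$sample_id, x$replicate_index, nrow(x$peaks)))
  if (nrow(x$peaks) > 0L) print(utils::head(x$peaks, 10L))
  invisible(x)
}

#' Write / read a peak list as CSV
#'
#' CSV with columns \code{mz,intensity,snr}; the sample id and replicate
#' index are carried in a \code{# sample_id=...; replicate=...} comment line
#' so the round trip is lossless.
#'
#' @param pl a \code{zooms_peaklist}.
#' @param path CSV file path.
#' @return For \code{write_peaklist}, \code{path} invisibly; for
#'   \code{read_peaklist}, a \code{zooms_peaklist}.
#' @export
write_peaklist <- function(pl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s; replicate=%d",
                     pl$sample_id, pl$replicate_index), con)
  utils::write.csv(pl$peaks, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sample_id <- ""
  replicate <- 1L
  if (grepl("^# sample_id=", first)) {
    sample_id <- sub("^# sample_id=([^;]*);.*$", "\\1", first)
    replicate <- as.integer(sub("^.*replicate=([0-9]+).*$", "\\1", first))
  }
  tab <- tryCatch(utils::read.csv(path, comment.char = "#"),
                  error = function(e) stop("cannot parse peak-list CSV '",
                                           path, "': ", conditionMessage(e)))
  miss <- setdiff(c("mz", "intensity", "snr"), names(tab))
  if (length(miss) > 0L)
    stop("peak-list CSV missing column(s): ", paste(miss, collapse = ", "))
  zooms_peaklist(tab, sample_id, replicate)
}

#' Default stratigraphic layer to cultural complex mapping
#'
#' The packaged stratigraphy: Mousterian layers \code{cgr}, \code{gar} and
#' (lower) \code{rsi}; Uluzzian layers \code{rsi} (upper), \code{pie},
#' \code{rpi}, \code{rsa''}; Protoaurignacian \code{rsa'}. Records from
#' \code{rsi} default to Uluzzian, matching the sampled portion of that
#' layer; the mapping is a plain data.frame and can be replaced or a
#' per-record \code{complex} column can override it.
#'
#' @return data.frame with columns \code{layer}, \code{complex}.
#' @export
default_layer_complex <- function() {
  data.frame(
    layer = c("cgr", "gar", "rsi", "pie", "rpi", "rsa''", "rsa'"),
    complex = c("Mousterian", "Mousterian", "Uluzzian", "Uluzzian",
                "Uluzzian", "Uluzzian", "Protoaurignacian"),
    stringsAsFactors = FALSE)
}

#' Read sample metadata
#'
#' CSV with required columns \code{sample_id} and \code{layer}; optional
#' \code{square} (grid label such as "H13"), \code{spit} and \code{complex}.
#' When \code{complex} is absent or empty it is inferred from the layer via
#' the mapping table; unknown layer labels are a validation error listing the
#' offending rows.
#'
#' @param path CSV file.
#' @param layer_complex mapping data.frame, default [default_layer_complex()].
#' @return data.frame with columns \code{sample_id}, \code{square},
#'   \code{spit}, \code{layer}, \code{complex} (square/spit may be NA).
#' @export
read_metadata <- function(path, layer_complex = default_layer_complex()) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "layer"), names(tab))
  if (length(miss) > 0L)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("square", "spit", "complex"))
    if (is.null(tab[[col]])) tab[[col]] <- NA_character_
  tab$square[!is.na(tab$square) & !nzchar(trimws(tab$square))] <- NA
  tab$square[!is.na(tab$square) & trimws(tab$square) %in% c("-", "—")] <- NA

  bad <- which(!tab$layer %in% layer_complex$layer)
  if (length(bad) > 0L)
    stop("unknown layer label(s) in rows ",
         paste(utils::head(bad, 10L), collapse = ", "), ": ",
         paste(unique(tab$layer[bad]), collapse = ", "))
  infer <- is.na(tab$complex) | !nzchar(trimws(tab$complex))
  tab$complex[infer] <-
    layer_complex$complex[match(tab$layer[infer], layer_complex$layer)]
  known <- unique(layer_complex$complex)
  bad <- which(!tab$complex %in% known)
  if (length(bad) > 0L)
    stop("unknown complex label(s) in rows ",
         paste(utils::head(bad, 10L), collapse = ", "))
  tab[c("sample_id", "square", "spit", "layer", "complex")]
}
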