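#' Read a reference library from TSV or JSON
#'
#' Two on-disk layouts are supported. \strong{JSON}: a single document with
#' keys \code{panel} (records with \code{marker_id}, \code{letter_code},
#' \code{window_min}, \code{window_max}), \code{leaves} (records with
#' \code{leaf}, \code{marker_id}, \code{mz}, \code{provenance}) and
#' \code{categories} (object mapping category name to member array).
#' \strong{TSV}: one row per (leaf, marker) expected value with columns
#' \code{leaf}, \code{marker_id}, \code{letter_code}, \code{mz},
#' \code{provenance}; the category lattice lives in a companion JSON file
#' (default: the TSV path with extension replaced by
#' \code{.categories.json}) which may also carry a \code{panel} key with the
#' marker windows. When no panel windows are declared, each marker's window
#' is inferred as the value range padded by 5 Da and clipped to 800--3600.
#'
#' @param path file path; UTF-8, dot decimal separator.
#' @param format "tsv", "json", or "auto" (from the extension).
#' @param categories_path companion categories JSON for TSV input; ignored
#'   for JSON input.
#' @return A validated \code{zooms_library}.
#' @export
load_library <- function(path, format = c("auto", "tsv", "json"),
                         categories_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"

  if (format == "json") {
    doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      stop("cannot parse JSON library '", path, "': ",
                           conditionMessage(e)))
    for (k in c("panel", "leaves", "categories"))
      if (is.null(doc[[k]]))
        stop("JSON library missing required key '", k, "'")
    cats <- lapply(doc$categories, as.character)
    return(reference_library(doc$panel, doc$leaves, cats))
  }

  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse TSV library '", path, "': ",
                             conditionMessage(e)))
  need <- c("leaf", "marker_id", "letter_code", "mz", "provenance")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("TSV library missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(tab$mz))
    stop("TSV library column 'mz' is not numeric (check decimal separator)")

  if (is.null(categories_path))
    categories_path <- sub("\\.[^.]+$", ".categories.json", path)
  if (!file.exists(categories_path))
    stop("companion categories file not found: ", categories_path)
  cdoc <- jsonlite::read_json(categories_path, simplifyVector = TRUE)
  if (!is.null(cdoc$categories)) {
    cats <- lapply(cdoc$categories, as.character)
    pan <- cdoc$panel
  } else {
    cats <- lapply(cdoc, as.character)
    pan <- NULL
  }

  if (is.null(pan)) {
    ids <- unique(tab$marker_id)
    pan <- data.frame(
      marker_id = ids,
      letter_code = tab$letter_code[match(ids, tab$marker_id)],
      window_min = vapply(ids, function(m)
        max(800, min(tab$mz[tab$marker_id == m]) - 5), numeric(1)),
      window_max = vapply(ids, function(m)
        min(3600, max(tab$mz[tab$marker_id == m]) + 5), numeric(1)),
      stringsAsFactors = FALSE)
  }
  values <- tab[c("leaf", "marker_id", "mz", "provenance")]
  reference_library(pan, values, cats)
}

#' Write a reference library to TSV or JSON
#'
#' Inverse of [load_library()]: \code{load_library(write_library(lib, p))}
#' reproduces an equal library in either format. TSV output also writes the
#' companion \code{.categories.json} with the panel windows included, so the
#' round trip preserves declared windows.
#'
#' @param lib a \code{zooms_library}.
#' @param path output path.
#' @param format "tsv", "json", or "auto" (from the extension).
#' @return \code{path}, invisibly.
#' @export
write_library <- function(lib, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    jsonlite::write_json(
      list(panel = lib$panel, leaves = lib$values,
           categories = lib$categories),
      path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  tab <- lib$values
  tab$letter_code <- lib$panel$letter_code[match(tab$marker_id,
                                                 lib$panel$marker_id)]
  tab <- tab[c("leaf", "marker_id", "letter_code", "mz", "provenance")]
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(panel = lib$panel, categories = lib$categories),
    sub("\\.[^.]+$", ".categories.json", path),
    auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Path to a packaged data file
#' @param file file name under the package's \code{extdata} directory; with
#'   no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
zoomsid_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "zoomsid")))
  p <- system.file("extdata", file, package = "zoomsid")
  if (p == "") stop("no packaged file named '", file, "'")
  p
}

.library_cache <- new.env(parent = emptyenv())

#' The packaged default ZooMS reference library
#'
#' A 9-marker panel over 25 medium/large mammal leaf taxa covering all the
#' groups reportable for a Late Pleistocene southern-European assemblage
#' (equids, cervids, caprines, large bovids, rhinoceros, suids, carnivores,
#' and \emph{Homo}), with the category lattice used for reporting
#' (e.g. "Cervid", "Cervid/Rupicapra", "Felis/Lynx/Ursus", "Canid").
#'
#' Expected masses flagged \code{provenance = "paper-anchor"} are the
#' diagnostic contrasts fixed from the study this package models: the
#' COL1a2 757-789 (G) values 3017/3033 for the red/fallow/giant deer group
#' against 3043/3059 for \emph{Capreolus capreolus}; the COL1a2 502-519 (C)
#' values 1550 (cervids) and 1580 (\emph{Rupicapra}); and the COL1a2 889-906
#' value 1576.8 present in \emph{Canis}/\emph{Cuon} but not in
#' \emph{Vulpes}. All other values are plausible reference data in the style
#' of published ZooMS marker compilations, flagged \code{"literature"}, and
#' are meant to be replaced wholesale by a user-curated library for real
#' analyses ([load_library()]).
#'
#' @return A validated \code{zooms_library} (cached after first load).
#' @export
default_library <- function() {
  if (is.null(.library_cache$default))
    .library_cache$default <-
      load_library(zoomsid_example("zooms_reference_library.json"))
  .library_cache$default
}
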