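#' Castelcivita ZNISP counts (packaged fixture)
#'
#' The ZooMS Number of Identified Specimens per category and cultural
#' complex for the Grotta di Castelcivita assemblage, transcribed from the
#' published assemblage table: 1263 sampled bone fragments across the
#' Mousterian (210), Uluzzian (840) and Protoaurignacian (213) complexes,
#' including the per-complex \code{Fail} counts (18/108/23). Only the ZNISP
#' columns are transcription-grade; the morphological NISP companion
#' ([castelcivita_morph()]) is best-effort because several printed cells
#' are typographically ambiguous, and is used solely for rank-association
#' comparisons.
#'
#' @return data.frame with columns \code{broad_category}, \code{zooms_id},
#'   \code{Mousterian}, \code{Uluzzian}, \code{Protoaurignacian}.
#' @export
castelcivita_znisp <- function() {
  utils::read.delim(zoomsid_example("castelcivita_znisp.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname castelcivita_znisp
#' @export
castelcivita_morph <- function() {
  utils::read.delim(zoomsid_example("castelcivita_morph_nisp.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}

#' Expand the Castelcivita ZNISP fixture into per-specimen identifications
#'
#' Reconstructs one identification record per counted specimen from the
#' printed ZNISP table (category calls for identified specimens, \code{fail}
#' status for the Fail rows), together with matching metadata records
#' carrying the cultural complex. Feeding the result to [tabulate_znisp()]
#' reproduces the printed table exactly, which is how the package's
#' assemblage arithmetic is validated.
#'
#' @return List with \code{ids} (data.frame: sample_id, status, category)
#'   and \code{records} (data.frame: sample_id, square, spit, layer,
#'   complex; square/spit/layer are NA -- the printed table does not carry
#'   them).
#' @export
znisp_fixture_identifications <- function() {
  tab <- castelcivita_znisp()
  strata <- c("Mousterian", "Uluzzian", "Protoaurignacian")
  ids <- list()
  for (s in strata) for (i in seq_len(nrow(tab))) {
    n <- tab[[s]][i]
    if (n == 0L) next
    fail <- tab$zooms_id[i] == "Fail"
    ids[[length(ids) + 1L]] <- data.frame(
      status = rep(if (fail) "fail" else "identified", n),
      category = rep(if (fail) NA_character_ else tab$zooms_id[i], n),
      complex = rep(s, n), stringsAsFactors = FALSE)
  }
  ids <- do.call(rbind, ids)
  ids$sample_id <- sprintf("CLCF%04d", seq_len(nrow(ids)))
  list(
    ids = ids[c("sample_id", "status", "category")],
    records = data.frame(sample_id = ids$sample_id, square = NA_character_,
                         spit = NA_character_, layer = NA_character_,
                         complex = ids$complex, stringsAsFactors = FALSE))
}
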