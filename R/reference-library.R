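#' Construct a ZooMS peptide-marker reference library
#'
#' A reference library holds (i) an ordered panel of collagen peptide markers,
#' each with a single-letter code and a nominal m/z window; (ii) expected
#' monoisotopic \eqn{[M+H]^+} m/z values per leaf taxon and marker; and
#' (iii) a lattice of named taxonomic categories (from single taxa up to a
#' root containing every leaf) within which identifications are reported.
#'
#' Masses are treated throughout as singly protonated monoisotopic values in
#' Daltons, the MALDI-TOF ZooMS convention. Deamidation shifts (~+0.984 Da)
#' are not expanded into extra expected values; the matching tolerance absorbs
#' sub-Dalton shifts.
#'
#' @param panel data.frame with columns \code{marker_id}, \code{letter_code},
#'   \code{window_min}, \code{window_max} (Da). One row per marker, in panel
#'   order.
#' @param values data.frame with columns \code{leaf}, \code{marker_id},
#'   \code{mz}, \code{provenance} ("paper-anchor" or "literature"). A leaf may
#'   carry several values for one marker and may lack a marker entirely
#'   (marker uninformative for that taxon).
#' @param categories named list; each element a character vector of leaf
#'   names. Exactly one category must contain every leaf (the root).
#' @param validate logical; run [validate_library()] and stop on violations.
#' @return An object of class \code{zooms_library}.
#' @seealso [load_library()], [default_library()], [candidate_taxa()],
#'   [minimal_category()]
#' @export
reference_library <- function(panel, values, categories, validate = TRUE) {
  panel <- as.data.frame(panel, stringsAsFactors = FALSE)
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "letter_code", "window_min", "window_max") %in%
                  names(panel)),
            all(c("leaf", "marker_id", "mz", "provenance") %in% names(values)),
            is.list(categories), length(names(categories)) == length(categories))
  categories <- lapply(categories, function(m) sort(unique(as.character(m))))
  lib <- structure(
    list(panel = panel, values = values, categories = categories),
    class = "zooms_library")
  if (validate) {
    rep <- validate_library(lib)
    if (nrow(rep) > 0L)
      stop("invalid reference library:\n",
           paste(sprintf("  [%s] %s: %s", rep$check, rep$where, rep$problem),
                 collapse = "\n"))
  }
  lib
}

#' Leaf taxa of a reference library
#' @param lib a \code{zooms_library}.
#' @return Character vector of leaf taxon names, sorted.
#' @export
library_leaves <- function(lib) sort(unique(lib$values$leaf))

#' Root category name of a reference library
#' @param lib a \code{zooms_library}.
#' @return Name of the (first) category containing every leaf.
#' @export
library_root <- function(lib) {
  leaves <- library_leaves(lib)
  covers <- vapply(lib$categories, function(m) all(leaves %in% m), logical(1))
  if (!any(covers)) return(NA_character_)
  sort(names(lib$categories)[covers])[1L]
}

#' @export
print.zooms_library <- function(x, ...) {
  cat("ZooMS reference library\n")
  cat(sprintf("  panel:      %d markers (%s)\n", nrow(x$panel),
              paste(x$panel$letter_code, collapse = "")))
  cat(sprintf("  leaves:     %d taxa, %d expected m/z values\n",
              length(library_leaves(x)), nrow(x$values)))
  cat(sprintf("  categories: %d named (root: %s)\n",
              length(x$categories), library_root(x)))
  invisible(x)
}

#' Validate a reference library
#'
#' Checks every structural invariant of the library and reports all
#' violations rather than stopping at the first: marker windows inside the
#' MALDI reflector range 800--3600 Da, unique letter codes, expected values
#' inside their marker's window, values referring to known markers, nonempty
#' categories over known leaves, presence of a root category, and pairwise
#' leaf separability (each pair either differs on at least one marker's value
#' set or shares a named category).
#'
#' @param lib a \code{zooms_library} (possibly not yet validated).
#' @return data.frame with columns \code{check}, \code{where}, \code{problem};
#'   zero rows iff the library is valid.
#' @export
validate_library <- function(lib) {
  bad <- list()
  note <- function(check, where, problem)
    bad[[length(bad) + 1L]] <<- data.frame(check = check, where = where,
                                           problem = problem)
  p <- lib$panel
  for (i in seq_len(nrow(p))) {
    if (!(p$window_min[i] > 0 && p$window_max[i] > p$window_min[i] &&
          p$window_min[i] >= 800 && p$window_max[i] <= 3600))
      note("marker_window", p$marker_id[i],
           sprintf("window [%g, %g] not inside [800, 3600] Da",
                   p$window_min[i], p$window_max[i]))
  }
  dup <- p$letter_code[duplicated(p$letter_code)]
  for (d in unique(dup))
    note("letter_code", d, "letter code used by more than one marker")

  v <- lib$values
  unknown <- setdiff(unique(v$marker_id), p$marker_id)
  for (m in unknown)
    note("value_marker", m, "expected value for marker not in panel")
  ok <- v$marker_id %in% p$marker_id
  idx <- which(ok)
  wmin <- p$window_min[match(v$marker_id[idx], p$marker_id)]
  wmax <- p$window_max[match(v$marker_id[idx], p$marker_id)]
  for (j in which(v$mz[idx] < wmin | v$mz[idx] > wmax))
    note("value_window", sprintf("%s / %s", v$leaf[idx[j]], v$marker_id[idx[j]]),
         sprintf("m/z %g outside marker window [%g, %g]",
                 v$mz[idx[j]], wmin[j], wmax[j]))

  leaves <- sort(unique(v$leaf))
  cats <- lib$categories
  if (length(cats) == 0L) note("categories", "<library>", "no categories")
  for (nm in names(cats)) {
    if (length(cats[[nm]]) == 0L) note("category_empty", nm, "empty category")
    miss <- setdiff(cats[[nm]], leaves)
    for (m in miss)
      note("category_member", nm, sprintf("unknown leaf '%s'", m))
  }
  if (length(cats) > 0L &&
      !any(vapply(cats, function(m) all(leaves %in% m), logical(1))))
    note("root", "<library>", "no category contains all leaves")

  # pairwise separability: value sets differ on some marker, or shared category
  vsets <- split(v[c("marker_id", "mz")], v$leaf)
  key <- function(df) {
    df <- df[order(df$marker_id, df$mz), ]
    paste(df$marker_id, round(df$mz, 4), sep = "@", collapse = ";")
  }
  keys <- vapply(vsets, key, character(1))
  if (length(leaves) > 1L) {
    for (i in seq_len(length(leaves) - 1L)) for (j in seq(i + 1L, length(leaves))) {
      a <- leaves[i]; b <- leaves[j]
      if (identical(keys[[a]], keys[[b]])) {
        shared <- any(vapply(cats, function(m) all(c(a, b) %in% m), logical(1)))
        if (!shared)
          note("leaf_pair", sprintf("%s | %s", a, b),
               "indistinguishable leaves with no shared named category")
      }
    }
  }
  if (length(bad) == 0L)
    return(data.frame(check = character(), where = character(),
                      problem = character()))
  do.call(rbind, bad)
}

#' Leaf taxa compatible with an observed marker mass
#'
#' Returns exactly the leaves whose expected m/z for \code{marker_id} lies
#' within \code{tol} of \code{observed_mz}. With \code{tol = 0} only
#' exact-value leaves are returned; enlarging the tolerance never shrinks the
#' set. An empty result is legitimate (no taxon carries a compatible value).
#'
#' @param lib a \code{zooms_library}.
#' @param marker_id a marker in the library's panel.
#' @param observed_mz observed peak m/z (Da).
#' @param tol matching tolerance (Da), >= 0.
#' @return Character vector of leaf names (sorted, possibly empty).
#' @export
candidate_taxa <- function(lib, marker_id, observed_mz, tol = 0.5) {
  if (!marker_id %in% lib$panel$marker_id)
    stop(sprintf("unknown marker_id '%s'", marker_id))
  stopifnot(is.numeric(observed_mz), length(observed_mz) == 1L, tol >= 0)
  v <- lib$values[lib$values$marker_id == marker_id, ]
  sort(unique(v$leaf[abs(v$mz - observed_mz) <= tol]))
}

#' Smallest named category covering a set of taxa
#'
#' The identification lattice query: among all named categories whose member
#' set contains \code{taxa}, return the one with the fewest members. Ties are
#' broken by lexicographic category name, so the result is deterministic.
#' When no smaller category covers the set, the root is returned.
#'
#' @param lib a \code{zooms_library}.
#' @param taxa nonempty character vector of leaf names known to the library.
#' @return A category name.
#' @export
minimal_category <- function(lib, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("empty taxa set")
  unknown <- setdiff(taxa, library_leaves(lib))
  if (length(unknown) > 0L)
    stop("unknown leaf taxa: ", paste(unknown, collapse = ", "))
  covers <- vapply(lib$categories, function(m) all(taxa %in% m), logical(1))
  if (!any(covers))
    stop("no category covers the given taxa (library has no root?)")
  nm <- names(lib$categories)[covers]
  sz <- vapply(lib$categories[covers], length, integer(1))
  nm[order(sz, nm)][1L]
}
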