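#' Marker-matching configuration
#'
#' @param mz_tolerance matching tolerance in Da (0 < tol <= 2). The default
#'   0.5 Da separates the sub-Dalton shifts a MALDI reflector shows from the
#'   multi-Dalton contrasts between taxa, and keeps the diagnostic pairs
#'   (1550/1580, 3017/3033/3043/3059) unambiguous.
#' @param min_markers minimum number of distinct matched markers for a
#'   successful identification (default 4).
#' @param max_markers panel size ceiling (default 9).
#' @param consensus_rule how replicate spots are combined:
#'   \code{"union-consistent"} (default) pools the marker matches of
#'   mutually consistent replicates before re-resolving;
#'   \code{"strict-intersection"} keeps only markers matched in every
#'   replicate that produced matches.
#' @return A list of class \code{zooms_match_config}.
#' @export
match_config <- function(mz_tolerance = 0.5, min_markers = 4L,
                         max_markers = 9L,
                         consensus_rule = c("union-consistent",
                                            "strict-intersection")) {
  consensus_rule <- match.arg(consensus_rule)
  stopifnot(mz_tolerance > 0, mz_tolerance <= 2,
            min_markers >= 1L, min_markers <= max_markers)
  structure(list(mz_tolerance = mz_tolerance,
                 min_markers = as.integer(min_markers),
                 max_markers = as.integer(max_markers),
                 consensus_rule = consensus_rule),
            class = "zooms_match_config")
}

#' Match picked peaks against the marker panel
#'
#' For each marker of the panel in order, the peaks falling inside the
#' marker's nominal m/z window are tested against every leaf's expected
#' values at \code{mz_tolerance}. At most one match per marker is kept: the
#' peak with the smallest absolute mass error wins, ties going to the more
#' intense peak. The match records every expected value within tolerance of
#' the winning peak and the union of their leaf taxa, so a peak compatible
#' with several value groups carries all of them.
#'
#' @param peaks a \code{zooms_peaklist}.
#' @param lib a \code{zooms_library}.
#' @param cfg a [match_config()].
#' @return data.frame with one row per matched marker: \code{marker_id},
#'   \code{observed_mz}, \code{intensity}, \code{best_delta}, \code{leaves}
#'   (list column of character vectors), \code{values} (list column of
#'   matched expected m/z). Zero rows when nothing matches.
#' @export
match_markers <- function(peaks, lib, cfg = match_config()) {
  stopifnot(inherits(peaks, "zooms_peaklist"), inherits(lib, "zooms_library"))
  pk <- peaks$peaks
  out <- list()
  for (i in seq_len(nrow(lib$panel))) {
    mid <- lib$panel$marker_id[i]
    v <- lib$values[lib$values$marker_id == mid, ]
    if (nrow(v) == 0L) next
    cand <- which(pk$mz >= lib$panel$window_min[i] - cfg$mz_tolerance &
                  pk$mz <= lib$panel$window_max[i] + cfg$mz_tolerance)
    if (length(cand) == 0L) next
    delta <- vapply(pk$mz[cand], function(m) min(abs(v$mz - m)), numeric(1))
    ok <- delta <= cfg$mz_tolerance
    if (!any(ok)) next
    cand <- cand[ok]; delta <- delta[ok]
    best <- cand[order(delta, -pk$intensity[cand])][1L]
    bd <- min(abs(v$mz - pk$mz[best]))
    hit <- abs(v$mz - pk$mz[best]) <= cfg$mz_tolerance
    out[[length(out) + 1L]] <- data.frame(
      marker_id = mid, observed_mz = pk$mz[best],
      intensity = pk$intensity[best], best_delta = bd,
      stringsAsFactors = FALSE)
    out[[length(out)]]$leaves <- list(sort(unique(v$leaf[hit])))
    out[[length(out)]]$values <- list(sort(unique(v$mz[hit])))
  }
  if (length(out) == 0L)
    return(data.frame(marker_id = character(), observed_mz = numeric(),
                      intensity = numeric(), best_delta = numeric(),
                      leaves = I(list()), values = I(list())))
  do.call(rbind, out)
}

#' Resolve the taxonomic category from marker matches
#'
#' The candidate leaf set is the intersection, over all matched markers, of
#' each match's leaf union; markers absent from the spectrum impose no
#' constraint, which is exactly how missing markers broaden the resulting
#' category. The reported category is the smallest named category covering
#' the candidates ([minimal_category()]). A sample is \code{identified} iff
#' at least \code{min_markers} distinct markers matched and the candidate
#' set is nonempty; a nonempty match set whose intersection is empty is a
#' \code{fail} flagged as a conflict, never a root-category identification.
#'
#' @param matches data.frame from [match_markers()] (one replicate).
#' @param lib a \code{zooms_library}.
#' @param cfg a [match_config()].
#' @param sample_id label carried into the result.
#' @return An object of class \code{zooms_id}: list with \code{sample_id},
#'   \code{status} ("identified"/"fail"), \code{category} (NA unless
#'   identified), \code{n_markers}, \code{candidates},
#'   \code{replicate_agreement}, \code{conflict}, \code{matches}.
#' @export
resolve_taxon <- function(matches, lib, cfg = match_config(),
                          sample_id = "") {
  n_markers <- length(unique(matches$marker_id))
  candidates <- if (nrow(matches) == 0L) character(0)
                else Reduce(intersect, matches$leaves)
  candidates <- sort(unique(candidates))
  conflict <- nrow(matches) > 0L && length(candidates) == 0L
  identified <- n_markers >= cfg$min_markers && length(candidates) > 0L
  structure(list(
    sample_id = sample_id,
    status = if (identified) "identified" else "fail",
    category = if (identified) minimal_category(lib, candidates)
               else NA_character_,
    n_markers = n_markers,
    candidates = candidates,
    replicate_agreement = "single",
    conflict = conflict,
    matches = matches), class = "zooms_id")
}

#' @export
print.zooms_id <- function(x, ...) {
  cat(sprintf("ZooMS identification '%s': %s%s, %d marker(s), agreement %s\n",
              x$sample_id, x$status,
              if (!is.na(x$category)) paste0(" as ", x$category) else "",
              x$n_markers, x$replicate_agreement))
  invisible(x)
}

# Two candidate sets are consistent when one contains the other or a named
# non-root category covers their union.
.sets_consistent <- function(lib, a, b) {
  if (length(a) == 0L || length(b) == 0L) return(TRUE)
  if (all(a %in% b) || all(b %in% a)) return(TRUE)
  root <- library_root(lib)
  u <- union(a, b)
  nm <- setdiff(names(lib$categories), root)
  any(vapply(lib$categories[nm], function(m) all(u %in% m), logical(1)))
}

.dedupe_matches <- function(matches) {
  if (nrow(matches) <= 1L) return(matches)
  o <- order(matches$marker_id, matches$best_delta, -matches$intensity)
  m <- matches[o, ]
  m <- m[!duplicated(m$marker_id), ]
  rownames(m) <- NULL
  m
}

#' Combine replicate spot identifications
#'
#' Spectra are acquired in (up to) triplicate spots per bone sample;
#' replicates are identified individually, checked against each other, and
#' combined. Under the default union-consistent rule, replicates whose
#' candidate sets are pairwise consistent (nested, or covered by a common
#' named category) pool their marker matches -- keeping the best match per
#' marker -- and the pooled matches are re-resolved, maximising marker
#' recovery. Disjoint candidate sets are a conflict: the strict-intersection
#' fallback is applied and the result flagged \code{conflict}. Under
#' \code{"strict-intersection"} only markers matched in every
#' match-producing replicate are kept, with the leaf sets intersected per
#' marker.
#'
#' Replicate agreement is reported as \code{"full"} (>= 2 replicates, all
#' identified with identical candidate sets), \code{"partial"} (consistent
#' but not identical, e.g. one replicate failed), \code{"single"} (one
#' usable replicate) or \code{"conflict"}.
#'
#' @param ids list of 1--3 \code{zooms_id} sharing one sample id.
#' @param lib a \code{zooms_library}.
#' @param cfg a [match_config()].
#' @return A combined \code{zooms_id}.
#' @export
combine_replicates <- function(ids, lib, cfg = match_config()) {
  stopifnot(length(ids) >= 1L,
            all(vapply(ids, inherits, logical(1), "zooms_id")))
  sid <- unique(vapply(ids, `[[`, "", "sample_id"))
  if (length(sid) != 1L)
    stop("replicates belong to different samples: ",
         paste(sid, collapse = ", "))
  if (length(ids) == 1L) {
    out <- ids[[1L]]
    out$replicate_agreement <- "single"
    return(out)
  }

  sets <- lapply(ids, `[[`, "candidates")
  nonempty <- which(lengths(sets) > 0L)
  pairs_ok <- TRUE
  if (length(nonempty) >= 2L) {
    for (i in nonempty) for (j in nonempty) {
      if (i < j && !.sets_consistent(lib, sets[[i]], sets[[j]]))
        pairs_ok <- FALSE
    }
  }

  all_matches <- do.call(rbind, lapply(ids, `[[`, "matches"))

  if (!pairs_ok || cfg$consensus_rule == "strict-intersection") {
    with_matches <- which(vapply(ids, function(x) nrow(x$matches) > 0L,
                                 logical(1)))
    shared <- Reduce(intersect,
                     lapply(ids[with_matches],
                            function(x) unique(x$matches$marker_id)))
    kept <- .dedupe_matches(
      all_matches[all_matches$marker_id %in% shared, , drop = FALSE])
    if (nrow(kept) > 0L) {
      for (r in seq_len(nrow(kept))) {
        mk <- kept$marker_id[r]
        per_rep <- lapply(ids[with_matches], function(x) {
          rows <- x$matches$marker_id == mk
          if (!any(rows)) NULL else Reduce(union, x$matches$leaves[rows])
        })
        per_rep <- per_rep[!vapply(per_rep, is.null, logical(1))]
        kept$leaves[[r]] <- sort(Reduce(intersect, per_rep))
      }
      kept <- kept[lengths(kept$leaves) > 0L, , drop = FALSE]
    }
    out <- resolve_taxon(kept, lib, cfg, sample_id = sid)
    out$replicate_agreement <- if (!pairs_ok) "conflict" else
      .agreement_label(ids, sets)
    if (!pairs_ok) {
      out$conflict <- TRUE
      out$status <- "fail"
      out$category <- NA_character_
    }
    return(out)
  }

  out <- resolve_taxon(.dedupe_matches(all_matches), lib, cfg,
                       sample_id = sid)
  out$replicate_agreement <- .agreement_label(ids, sets)
  out
}

.agreement_label <- function(ids, sets) {
  usable <- which(vapply(ids, function(x) nrow(x$matches) > 0L, logical(1)))
  if (length(usable) <= 1L) return("single")
  statuses <- vapply(ids[usable], `[[`, "", "status")
  same <- length(unique(lapply(ids[usable], `[[`, "candidates"))) == 1L
  if (all(statuses == "identified") && same) "full" else "partial"
}

#' Classify one bone sample from its replicate spectra
#'
#' The full chain per replicate -- baseline correction, smoothing, peak
#' picking, marker matching, category resolution -- followed by replicate
#' combination. Deterministic for fixed inputs and configurations.
#'
#' @param spectra a single \code{zooms_spectrum} or list of 1--3 replicates
#'   sharing a sample id.
#' @param lib a \code{zooms_library}.
#' @param pre_cfg a [preprocess_config()].
#' @param cfg a [match_config()].
#' @return A \code{zooms_id}.
#' @export
classify_sample <- function(spectra, lib, pre_cfg = preprocess_config(),
                            cfg = match_config()) {
  if (inherits(spectra, "zooms_spectrum")) spectra <- list(spectra)
  ids <- lapply(spectra, function(s) {
    pl <- preprocess_spectrum(s, pre_cfg)
    resolve_taxon(match_markers(pl, lib, cfg), lib, cfg,
                  sample_id = s$sample_id)
  })
  combine_replicates(ids, lib, cfg)
}
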