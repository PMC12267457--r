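# Rounding convention used in assemblage tables: half-up, as printed tables
# in the field do (banker's rounding would turn 8.65 into 8.6).
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Tabulate ZooMS identifications into a ZNISP table
#'
#' Counts of identified specimens (ZNISP) per taxonomic category and
#' stratum (cultural complex or stratigraphic layer), with a \code{Fail} row
#' for unidentified samples and percentages computed on the stratum total
#' \emph{including} fails, rounded half-up to one decimal -- the convention
#' of published assemblage tables (18 fails of 210 prints as 8.6\%).
#'
#' @param ids identifications: a list of \code{zooms_id} or a data.frame
#'   with columns \code{sample_id}, \code{status}, \code{category}.
#' @param records sample metadata (data.frame from [read_metadata()] or with
#'   at least \code{sample_id} plus the stratum column).
#' @param stratum "complex" or "layer".
#' @return Object of class \code{znisp_table}: list with \code{counts}
#'   (integer matrix, categories + "Fail" by strata), \code{percent}
#'   (same shape), \code{totals}, \code{fails}, \code{stratum}.
#' @export
tabulate_znisp <- function(ids, records, stratum = c("complex", "layer")) {
  stratum <- match.arg(stratum)
  ids <- .ids_as_df(ids)
  if (!stratum %in% names(records))
    stop("records lack a '", stratum, "' column")
  miss <- setdiff(ids$sample_id, records$sample_id)
  if (length(miss) > 0L)
    stop("identifications without a metadata record: ",
         paste(utils::head(miss, 10L), collapse = ", "))
  ids$stratum <- records[[stratum]][match(ids$sample_id, records$sample_id)]
  ids$row <- ifelse(ids$status == "identified", ids$category, "Fail")

  strata <- unique(ids$stratum)
  pref <- c("Mousterian", "Uluzzian", "Protoaurignacian",
            default_layer_complex()$layer)
  strata <- c(intersect(pref, strata), sort(setdiff(strata, pref)))
  cats <- sort(setdiff(unique(ids$row), "Fail"))
  rows <- c(cats, "Fail")

  counts <- matrix(0L, length(rows), length(strata),
                   dimnames = list(rows, strata))
  tb <- table(factor(ids$row, levels = rows),
              factor(ids$stratum, levels = strata))
  counts[] <- as.integer(tb)
  totals <- colSums(counts)
  percent <- counts
  for (j in seq_along(strata))
    percent[, j] <- if (totals[j] > 0)
      round_half_up(100 * counts[, j] / totals[j], 1L) else 0
  structure(list(counts = counts, percent = percent, totals = totals,
                 fails = stats::setNames(counts["Fail", ], colnames(counts)),
                 stratum = stratum),
            class = "znisp_table")
}

.ids_as_df <- function(ids) {
  if (is.data.frame(ids)) {
    stopifnot(all(c("sample_id", "status", "category") %in% names(ids)))
    return(ids[c("sample_id", "status", "category")])
  }
  stopifnot(all(vapply(ids, inherits, logical(1), "zooms_id")))
  data.frame(
    sample_id = vapply(ids, `[[`, "", "sample_id"),
    status = vapply(ids, `[[`, "", "status"),
    category = vapply(ids, `[[`, "", "category"),
    stringsAsFactors = FALSE)
}

#' @export
print.znisp_table <- function(x, ...) {
  cat(sprintf("ZNISP table by %s (%d categories, totals: %s)\n", x$stratum,
              nrow(x$counts) - 1L,
              paste(sprintf("%s=%d", colnames(x$counts), x$totals),
                    collapse = ", ")))
  print(x$counts)
  invisible(x)
}

#' Identification success rate of a stratum
#'
#' 100 x (total - fails) / total, rounded half-up to an integer -- the
#' headline rate convention (e.g. 192 of 210 prints as 91).
#'
#' @param tab a \code{znisp_table}.
#' @param stratum a stratum name present in the table, or \code{"overall"}
#'   for the pooled rate across strata.
#' @return Integer percentage.
#' @export
success_rate <- function(tab, stratum = "overall") {
  stopifnot(inherits(tab, "znisp_table"))
  if (identical(stratum, "overall")) {
    tot <- sum(tab$totals); fl <- sum(tab$fails)
  } else {
    if (!stratum %in% colnames(tab$counts))
      stop("no stratum '", stratum, "' in table")
    tot <- tab$totals[[stratum]]; fl <- tab$fails[[stratum]]
  }
  if (tot == 0) stop("empty stratum '", stratum, "'")
  as.integer(round_half_up(100 * (tot - fl) / tot))
}

#' Default mapping from ZooMS categories to broad faunal categories
#'
#' The simplification used to compare ZooMS identifications with
#' morphological NISP: equids to Equid, all cervid categories to Cervidae,
#' caprine categories to Caprine, carnivores to Carnivore, and so on.
#'
#' @return Named character vector: ZooMS category -> broad category.
#' @export
default_broad_map <- function() {
  c("Equus" = "Equid",
    "Cervid" = "Cervidae",
    "Capreolus capreolus" = "Cervidae",
    "Unidentified Cervid" = "Cervidae",
    "Cervid/Rupicapra" = "Artiodactyla",
    "Artiodactyla" = "Artiodactyla",
    "Bos/Bison" = "Bos/Bison",
    "Capra sp." = "Caprine",
    "Rupicapra" = "Caprine",
    "Unidentified Caprine" = "Caprine",
    "Ovis aries" = "Caprine",
    "Rhinoceros" = "Rhinoceros",
    "Sus sp." = "Sus sp.",
    "Ursus sp." = "Carnivore",
    "Canid" = "Carnivore",
    "Canidae" = "Carnivore",
    "Vulpes" = "Carnivore",
    "Felis/Lynx/Ursus" = "Carnivore",
    "Panthera/Crocuta" = "Carnivore",
    "Carnivora" = "Carnivore",
    "Meles meles" = "Carnivore",
    "Homo sapiens" = "Hominin",
    "Mammalia" = "Mammalia")
}

#' Collapse a ZNISP table to broad faunal categories
#'
#' Counts are summed per broad category; the total number of specimens is
#' conserved (no sample dropped or double-counted), which is asserted.
#' The \code{Fail} row is carried through unchanged.
#'
#' @param tab a \code{znisp_table}.
#' @param map named character vector ZooMS category -> broad category
#'   (default [default_broad_map()]). Every category in the table must be
#'   mapped.
#' @return A \code{znisp_table} over broad categories.
#' @export
map_broad <- function(tab, map = default_broad_map()) {
  stopifnot(inherits(tab, "znisp_table"))
  cats <- setdiff(rownames(tab$counts), "Fail")
  unmapped <- setdiff(cats, names(map))
  if (length(unmapped) > 0L)
    stop("unmapped ZooMS category: ", paste(unmapped, collapse = ", "))
  broad <- map[cats]
  rows <- c(unique(broad), "Fail")
  counts <- matrix(0L, length(rows), ncol(tab$counts),
                   dimnames = list(rows, colnames(tab$counts)))
  for (i in seq_along(cats))
    counts[broad[i], ] <- counts[broad[i], ] + tab$counts[cats[i], ]
  counts["Fail", ] <- tab$counts["Fail", ]
  stopifnot(sum(counts) == sum(tab$counts))  # conservation
  totals <- colSums(counts)
  percent <- counts
  for (j in seq_len(ncol(counts)))
    percent[, j] <- if (totals[j] > 0)
      round_half_up(100 * counts[, j] / totals[j], 1L) else 0
  structure(list(counts = counts, percent = percent, totals = totals,
                 fails = stats::setNames(counts["Fail", ], colnames(counts)),
                 stratum = tab$stratum),
            class = "znisp_table")
}

#' Compare ZooMS and morphological NISP per broad category
#'
#' Builds the combined table (ZNISP, morphological NISP, their sum, and the
#' three within-stratum percentage series over identified specimens) and,
#' per stratum, a Spearman rank correlation between the two count series
#' with a one-sided permutation p-value and the ordinary least-squares slope
#' of morphological NISP on ZNISP.
#'
#' @param tab a \code{znisp_table} (typically broad, from [map_broad()]).
#' @param morph data.frame or matrix of morphological NISP counts with
#'   categories as rows (rownames or a \code{category} column) and the same
#'   strata as columns.
#' @param n_perm number of permutations for the p-value (default 10000).
#' @param seed integer seed for the permutation draw.
#' @return List with \code{table} (long data.frame: stratum, category,
#'   znisp, morph_nisp, total, znisp_pct, morph_pct, total_pct) and
#'   \code{stats} (per stratum: spearman_rho, p_perm, ols_slope).
#' @export
compare_with_morph <- function(tab, morph, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(tab, "znisp_table"))
  if (is.data.frame(morph) && "category" %in% names(morph)) {
    rownames(morph) <- morph$category
    morph$category <- NULL
  }
  morph <- as.matrix(morph)
  cats <- setdiff(rownames(tab$counts), "Fail")
  strata <- colnames(tab$counts)
  miss <- setdiff(cats, rownames(morph))
  if (length(miss) > 0L)
    stop("morph table lacks categories: ", paste(miss, collapse = ", "))
  miss <- setdiff(strata, colnames(morph))
  if (length(miss) > 0L)
    stop("morph table lacks strata: ", paste(miss, collapse = ", "))
  z <- tab$counts[cats, strata, drop = FALSE]
  m <- morph[cats, strata, drop = FALSE]

  long <- do.call(rbind, lapply(strata, function(s) {
    zs <- z[, s]; ms <- m[, s]; tots <- zs + ms
    data.frame(stratum = s, category = cats, znisp = zs, morph_nisp = ms,
               total = tots,
               znisp_pct = round_half_up(100 * zs / max(1, sum(zs)), 1L),
               morph_pct = round_half_up(100 * ms / max(1, sum(ms)), 1L),
               total_pct = round_half_up(100 * tots / max(1, sum(tots)), 1L),
               row.names = NULL)
  }))

  set.seed(seed)
  stats <- do.call(rbind, lapply(strata, function(s) {
    zs <- z[, s]; ms <- m[, s]
    rho <- suppressWarnings(stats::cor(zs, ms, method = "spearman"))
    perm <- replicate(n_perm,
      suppressWarnings(stats::cor(zs, sample(ms), method = "spearman")))
    p <- (1 + sum(perm >= rho, na.rm = TRUE)) / (1 + n_perm)
    slope <- if (stats::var(zs) > 0)
      unname(stats::coef(stats::lm(ms ~ zs))[2L]) else NA_real_
    data.frame(stratum = s, spearman_rho = rho, p_perm = p,
               ols_slope = slope, row.names = NULL)
  }))
  list(table = long, stats = stats)
}

#' Spatial grid of ZooMS identification success
#'
#' Per excavation square (optionally per square and layer): number of
#' sampled bones, number identified, and the success percentage. Only
#' records with a square label enter the grid; samples without spatial data
#' are counted separately in the \code{unlocated} attribute. Cells never
#' sampled are simply absent from the result -- absence of data is
#' distinguished from a true 0\%.
#'
#' @param ids identifications (list of \code{zooms_id} or data.frame, as for
#'   [tabulate_znisp()]).
#' @param records metadata with \code{square} (NA allowed) and \code{layer}.
#' @param by_layer also split by stratigraphic layer.
#' @return data.frame with columns \code{square}, (\code{layer}),
#'   \code{n_sampled}, \code{n_identified}, \code{percent}; attribute
#'   \code{unlocated} = number of samples without square labels.
#' @export
spatial_success <- function(ids, records, by_layer = FALSE) {
  ids <- .ids_as_df(ids)
  rec <- records[match(ids$sample_id, records$sample_id), ]
  located <- !is.na(rec$square)
  ids <- ids[located, ]; rec <- rec[located, ]
  keys <- if (by_layer) list(square = rec$square, layer = rec$layer)
          else list(square = rec$square)
  agg <- stats::aggregate(
    cbind(n_sampled = rep(1L, nrow(ids)),
          n_identified = as.integer(ids$status == "identified")),
    by = keys, FUN = sum)
  agg$percent <- round_half_up(100 * agg$n_identified / agg$n_sampled, 1L)
  agg <- agg[do.call(order, agg[names(keys)]), ]
  rownames(agg) <- NULL
  attr(agg, "unlocated") <- sum(!located)
  agg
}

#' Plot a spatial success grid as a heatmap
#'
#' A plain image of the per-square success percentages, squares arranged by
#' their letter row and number column.
#'
#' @param grid data.frame from [spatial_success()] (without \code{by_layer}).
#' @param ... passed to [graphics::image()].
#' @return The percentage matrix, invisibly.
#' @export
plot_success_grid <- function(grid, ...) {
  rowlab <- sort(unique(gsub("[0-9]", "", grid$square)))
  collab <- sort(unique(as.integer(gsub("[^0-9]", "", grid$square))))
  m <- matrix(NA_real_, length(rowlab), length(collab),
              dimnames = list(rowlab, collab))
  for (i in seq_len(nrow(grid))) {
    r <- gsub("[0-9]", "", grid$square[i])
    c <- as.character(as.integer(gsub("[^0-9]", "", grid$square[i])))
    m[r, c] <- grid$percent[i]
  }
  graphics::image(seq_along(collab), seq_along(rowlab), t(m),
                  xlab = "square number", ylab = "square letter",
                  axes = FALSE, ...)
  graphics::axis(1, seq_along(collab), collab)
  graphics::axis(2, seq_along(rowlab), rowlab)
  invisible(m)
}
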