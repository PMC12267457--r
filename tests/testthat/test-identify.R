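peaklist_at <- function(mz, intensity = 50, sample_id = "S") {
  zooms_peaklist(data.frame(mz = mz,
                            intensity = rep_len(intensity, length(mz)),
                            snr = rep_len(40, length(mz))),
                 sample_id)
}

test_that("match_markers keeps at most one best match per marker", {
  lib <- default_library()
  pl <- peaklist_at(c(3033.1, 3033.4))   # two peaks in the G window
  m <- match_markers(pl, lib)
  expect_identical(nrow(m), 1L)
  expect_identical(m$marker_id, "COL1a2 757-789")
  expect_equal(m$observed_mz, 3033.1)    # smaller delta wins
  expect_setequal(m$leaves[[1]],
                  c("Cervus elaphus", "Dama dama", "Megaloceros giganteus"))

  empty <- peaklist_at(numeric(0))
  expect_identical(nrow(match_markers(empty, lib)), 0L)
})

test_that("a peak within tolerance of two value groups carries both leaf sets", {
  tl <- tiny_library()   # M1 values: A@1010, B/C@1050
  lib2 <- reference_library(
    tl$panel,
    within(tl$values, mz[leaf == "A" & marker_id == "M1"] <- 1047),
    tl$categories)
  pl <- peaklist_at(1048.5)   # 1.5 from both 1047 and 1050
  m <- match_markers(pl, lib2, match_config(mz_tolerance = 2))
  expect_identical(nrow(m), 1L)
  expect_setequal(m$leaves[[1]], c("A", "B", "C"))
  expect_setequal(unlist(m$values), c(1047, 1050))
})

test_that("ties on delta go to the more intense peak", {
  tl <- tiny_library()
  pl <- zooms_peaklist(data.frame(mz = c(1049, 1051),
                                  intensity = c(10, 90), snr = 40), "S")
  m <- match_markers(pl, tl, match_config(mz_tolerance = 1.5))
  expect_equal(m$observed_mz[m$marker_id == "M1"], 1051)
})

test_that("resolve_taxon intersects leaf sets and applies the marker minimum", {
  lib <- default_library()
  cfg <- match_config()
  equus_mz <- lib$values$mz[lib$values$leaf == "Equus"]

  id <- resolve_taxon(match_markers(peaklist_at(equus_mz), lib, cfg),
                      lib, cfg, "EQ")
  expect_identical(id$status, "identified")
  expect_identical(id$category, "Equus")
  expect_identical(id$n_markers, 9L)

  # three matched markers only: below the four-marker criterion
  id3 <- resolve_taxon(match_markers(peaklist_at(equus_mz[1:3]), lib, cfg),
                       lib, cfg, "EQ3")
  expect_identical(id3$status, "fail")
  expect_identical(id3$n_markers, 3L)
  expect_true(is.na(id3$category))

  # markers shared by cervids and Rupicapra, C absent: category broadens
  id4 <- resolve_taxon(
    match_markers(peaklist_at(c(1105.6, 2131.1, 2780.3, 2869.3)), lib, cfg),
    lib, cfg, "CR")
  expect_identical(id4$category, "Cervid/Rupicapra")

  # incompatible markers from different taxa: conflict, not root category
  idc <- resolve_taxon(
    match_markers(peaklist_at(c(1453.8, 1427.7, 2151.1, 2175.2)), lib, cfg),
    lib, cfg, "CF")
  expect_identical(idc$status, "fail")
  expect_true(idc$conflict)
})

test_that("adding marker matches never enlarges the candidate set", {
  lib <- default_library()
  cfg <- match_config(min_markers = 1L)
  set.seed(202)
  for (rep in 1:10) {
    leaf <- sample(library_leaves(lib), 1)
    vals <- lib$values$mz[lib$values$leaf == leaf]
    vals <- sample(vals, length(vals))
    prev <- NULL
    for (k in seq_along(vals)) {
      id <- resolve_taxon(match_markers(peaklist_at(vals[1:k]), lib, cfg),
                          lib, cfg)
      if (!is.null(prev)) expect_true(all(id$candidates %in% prev))
      prev <- id$candidates
      expect_true(leaf %in% id$candidates)
    }
  }
})

test_that("replicate combination distinguishes full, partial and conflicting agreement", {
  lib <- default_library()
  cfg <- match_config()
  equus_mz <- lib$values$mz[lib$values$leaf == "Equus"]
  capr_mz <- lib$values$mz[lib$values$leaf == "Capreolus capreolus"]
  mk <- function(mz, sid) resolve_taxon(
    match_markers(peaklist_at(mz, sample_id = sid), lib, cfg), lib, cfg, sid)

  full <- combine_replicates(list(mk(equus_mz, "S"), mk(equus_mz, "S"),
                                  mk(equus_mz, "S")), lib, cfg)
  expect_identical(full$category, "Equus")
  expect_identical(full$replicate_agreement, "full")

  partial <- combine_replicates(list(mk(equus_mz, "S"), mk(equus_mz, "S"),
                                     mk(equus_mz[1:2], "S")), lib, cfg)
  expect_identical(partial$category, "Equus")
  expect_identical(partial$status, "identified")
  expect_identical(partial$replicate_agreement, "partial")

  confl <- combine_replicates(list(mk(equus_mz, "S"), mk(capr_mz, "S")),
                              lib, cfg)
  expect_identical(confl$replicate_agreement, "conflict")
  expect_identical(confl$status, "fail")

  expect_error(combine_replicates(list(mk(equus_mz, "S1"),
                                       mk(equus_mz, "S2")), lib, cfg),
               "different samples")
})

test_that("union-consistent pooling recovers markers split across replicates", {
  lib <- default_library()
  cfg <- match_config()
  equus_mz <- sort(lib$values$mz[lib$values$leaf == "Equus"])
  mk <- function(mz) resolve_taxon(
    match_markers(peaklist_at(mz, sample_id = "S"), lib, cfg), lib, cfg, "S")
  # each replicate alone is below the marker minimum
  combined <- combine_replicates(list(mk(equus_mz[1:3]), mk(equus_mz[4:6]),
                                      mk(equus_mz[7:9])), lib, cfg)
  expect_identical(combined$status, "identified")
  expect_identical(combined$n_markers, 9L)
  expect_identical(combined$category, "Equus")

  strict <- combine_replicates(list(mk(equus_mz[1:5]), mk(equus_mz[1:5]),
                                    mk(equus_mz[3:9])),
                               lib, match_config(consensus_rule =
                                                   "strict-intersection"))
  expect_identical(sort(unique(strict$matches$marker_id)),
                   sort(unique(match_markers(peaklist_at(equus_mz[3:5]),
                                             lib, cfg)$marker_id)))
})

test_that("classify_sample runs the full chain on synthetic replicates", {
  lib <- default_library()
  cfg <- simulation_config(seed = 5, replicates = 3)
  surv <- full_survival(lib)
  set.seed(55)
  sp <- lapply(1:3, function(r)
    render_spectrum("Equus", surv, cfg, lib, "SYN1", r))
  id <- classify_sample(sp, lib)
  expect_identical(id$status, "identified")
  expect_identical(id$category, "Equus")
  expect_identical(id$replicate_agreement, "full")

  none <- surv & FALSE
  set.seed(56)
  sp0 <- render_spectrum("Equus", none, cfg, lib, "SYN0", 1)
  id0 <- classify_sample(sp0, lib)
  expect_identical(id0$status, "fail")
  expect_identical(id0$n_markers, 0L)

  # Capreolus with the G marker present resolves away from the Cervid group
  set.seed(57)
  spc <- render_spectrum("Capreolus capreolus", surv, cfg, lib, "SYNC", 1)
  idc <- classify_sample(spc, lib)
  expect_identical(idc$status, "identified")
  expect_false(any(c("Cervus elaphus", "Dama dama") %in%
                     lib$categories[[idc$category]]))
  expect_true("Capreolus capreolus" %in% lib$categories[[idc$category]])
})
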