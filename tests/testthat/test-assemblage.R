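test_that("the packaged assemblage fixture reproduces the printed table", {
  fx <- znisp_fixture_identifications()
  tab <- tabulate_znisp(fx$ids, fx$records, "complex")

  expect_equal(unname(tab$totals),
               c(210, 840, 213)[match(colnames(tab$counts),
                                      c("Mousterian", "Uluzzian",
                                        "Protoaurignacian"))])
  expect_identical(tab$counts["Equus", "Uluzzian"], 338L)
  expect_identical(tab$counts["Fail", "Mousterian"], 18L)
  expect_identical(sum(tab$counts), 1263L)
  expect_identical(sum(tab$counts) - sum(tab$fails), 1114L)

  expect_equal(tab$percent["Equus", "Uluzzian"], 40.2)
  expect_equal(tab$percent["Equus", "Protoaurignacian"], 50.2)
  expect_equal(tab$percent["Fail", "Uluzzian"], 12.9)
  expect_equal(tab$percent["Fail", "Mousterian"], 8.6)

  # percentages in any stratum sum to 100 within rounding slack
  expect_true(all(abs(colSums(tab$percent) - 100) <= 0.3))
})

test_that("headline success rates match the printed values", {
  fx <- znisp_fixture_identifications()
  tab <- tabulate_znisp(fx$ids, fx$records, "complex")
  expect_identical(success_rate(tab, "Mousterian"), 91L)
  expect_identical(success_rate(tab, "Uluzzian"), 87L)
  expect_identical(success_rate(tab, "Protoaurignacian"), 89L)
  expect_identical(success_rate(tab, "overall"), 88L)
  expect_error(success_rate(tab, "Aurignacian"), "no stratum")
})

test_that("broad-category mapping conserves counts and matches the reported totals", {
  fx <- znisp_fixture_identifications()
  tab <- tabulate_znisp(fx$ids, fx$records, "complex")
  broad <- map_broad(tab)
  expect_identical(sum(broad$counts), sum(tab$counts))
  expect_equal(unname(rowSums(broad$counts)["Equid"]), 448)
  expect_equal(unname(rowSums(broad$counts)["Cervidae"]), 367)
  expect_equal(unname(rowSums(broad$counts)["Bos/Bison"]), 156)
  expect_equal(unname(rowSums(broad$counts)["Caprine"]), 110)

  ident <- setNames(rownames(tab$counts), rownames(tab$counts))
  same <- map_broad(tab, ident)
  expect_equal(same$counts[rownames(tab$counts), ], tab$counts)

  expect_error(map_broad(tab, c(Equus = "Equid")), "unmapped")
})

test_that("degenerate tabulations behave", {
  ids1 <- data.frame(sample_id = "X1", status = "identified",
                     category = "Equus")
  rec1 <- data.frame(sample_id = "X1", complex = "Uluzzian")
  t1 <- tabulate_znisp(ids1, rec1, "complex")
  expect_equal(t1$percent["Equus", "Uluzzian"], 100.0)
  expect_identical(success_rate(t1, "Uluzzian"), 100L)

  expect_error(
    tabulate_znisp(ids1, data.frame(sample_id = "Y9", complex = "Uluzzian"),
                   "complex"),
    "X1")
})

test_that("ZooMS vs morphological NISP comparison computes association per complex", {
  fx <- znisp_fixture_identifications()
  broad <- map_broad(tabulate_znisp(fx$ids, fx$records, "complex"))
  cats <- setdiff(rownames(broad$counts), "Fail")

  # strictly proportional morph table: perfect rank agreement
  prop <- broad$counts[cats, ] * 3L
  cmp <- compare_with_morph(broad, prop, n_perm = 500, seed = 9)
  expect_true(all(cmp$stats$spearman_rho == 1))
  expect_equal(cmp$table$total, cmp$table$znisp + cmp$table$morph_nisp)

  # all-zero morph table: totals collapse onto the ZNISP counts
  zero <- prop * 0L
  cmp0 <- compare_with_morph(broad, zero, n_perm = 10, seed = 9)
  expect_equal(cmp0$table$total, cmp0$table$znisp)

  expect_error(compare_with_morph(broad, prop[-1, ]), "lacks categories")
})

test_that("transcribed morphological NISP associates positively with ZNISP in every complex", {
  fx <- znisp_fixture_identifications()
  broad <- map_broad(tabulate_znisp(fx$ids, fx$records, "complex"))
  morph <- castelcivita_morph()
  bm <- default_broad_map()
  morph$broad <- bm[morph$zooms_id]
  agg <- aggregate(morph[c("Mousterian", "Uluzzian", "Protoaurignacian")],
                   by = list(category = morph$broad), FUN = sum)
  cmp <- compare_with_morph(broad, agg, n_perm = 2000, seed = 17)
  expect_true(all(cmp$stats$spearman_rho > 0))
  expect_identical(nrow(cmp$stats), 3L)
})

test_that("spatial success grids distinguish absent cells from zero percent", {
  ids <- data.frame(
    sample_id = sprintf("S%02d", 1:7),
    status = c("identified", "identified", "fail", "identified",
               "fail", "fail", "identified"),
    category = c("Equus", "Equus", NA, "Cervid", NA, NA, "Equus"))
  rec <- data.frame(
    sample_id = sprintf("S%02d", 1:7),
    square = c("G12", "G12", "G12", "H13", "H13", NA, NA),
    layer = c("pie", "pie", "rpi", "pie", "pie", "pie", "pie"),
    complex = "Uluzzian")
  g <- spatial_success(ids, rec)
  expect_identical(nrow(g), 2L)   # only sampled squares appear
  expect_equal(g$percent[g$square == "G12"], round(100 * 2 / 3, 1))
  expect_equal(g$percent[g$square == "H13"], 50.0)
  expect_identical(attr(g, "unlocated"), 2L)

  gl <- spatial_success(ids, rec, by_layer = TRUE)
  expect_identical(nrow(gl), 3L)
  expect_equal(gl$percent[gl$square == "G12" & gl$layer == "rpi"], 0.0)
  expect_false(any(gl$square == "H13" & gl$layer == "rpi"))
})

test_that("fully identified squares report 100 percent", {
  ids <- data.frame(sample_id = c("A1", "A2"), status = "identified",
                    category = "Equus")
  rec <- data.frame(sample_id = c("A1", "A2"), square = "E12",
                    layer = "pie", complex = "Uluzzian")
  g <- spatial_success(ids, rec)
  expect_equal(g$percent, 100.0)
})
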