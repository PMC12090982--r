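test_that("worked reference compositions classify as expected", {
  r <- classify("Hex:8 HexNAc:8 dHex:2")
  expect_equal(r$type_class, "COMPLEX")
  expect_setequal(r$decorations, c("BISECTING", "MULTI_FUCOSYLATED",
                                   "POLYLACTOSAMINE", "TETRA_ANTENNARY"))
  expect_false(r$ambiguous)
  expect_equal(r$display_name,
               "complex bisecting-multifucose-polylactosamine-tetra antennary")

  r <- classify("Hex:6 HexNAc:6")
  expect_equal(r$type_class, "COMPLEX")
  expect_equal(r$decorations, "BISECTING_OR_TETRA_ANTENNARY")
  expect_true(r$ambiguous)

  r <- classify("Hex:7 HexNAc:2")
  expect_equal(r$type_class, "HIGH_MANNOSE")
  expect_length(r$decorations, 0)

  r <- classify("Hex:3 HexNAc:6")
  expect_equal(r$type_class, "COMPLEX")
  expect_equal(r$decorations, "TETRA_ANTENNARY")

  r <- classify("Hex:9 HexNAc:8 dHex:1")
  expect_equal(r$type_class, "COMPLEX")
  expect_setequal(r$decorations, c("FUCOSYLATED", "POLYLACTOSAMINE",
                                   "TETRA_ANTENNARY"))
  expect_equal(r$display_name,
               "complex fucosylated-polylactosamine-tetra antennary")

  # the intact core and a fucosylated truncation are pauci-mannose
  expect_equal(classify("Hex:3 HexNAc:2")$type_class, "PAUCI_MANNOSE")
  rf <- classify("Hex:2 HexNAc:2 dHex:1")
  expect_equal(rf$type_class, "PAUCI_MANNOSE")
  expect_equal(rf$fucosylation, "fucosylated")
  expect_equal(rf$display_name, "pauci-mannose")  # fucose stays out of the name
})

test_that("classifier agrees with an independent rule oracle on the full grid", {
  g <- grid_compositions()
  comps <- lapply(seq_len(nrow(g)), function(i)
    glycan_composition(c(Hex = g$H[i], HexNAc = g$N[i],
                         dHex = g$F[i], NeuAc = g$S[i])))
  got <- classify_compositions(comps)
  want <- lapply(seq_len(nrow(g)), function(i)
    oracle_classify(g$H[i], g$N[i], g$F[i], g$S[i]))

  got_deco <- vapply(strsplit(got$decorations, ";", fixed = TRUE),
                     function(d) paste(sort(d[nzchar(d)]), collapse = ";"),
                     character(1))
  want_deco <- vapply(want, function(w) paste(w$decorations, collapse = ";"),
                      character(1))
  mism <- which(got$type_class != vapply(want, `[[`, character(1), "type") |
                got_deco != want_deco |
                got$ambiguous != vapply(want, `[[`, logical(1), "ambiguous"))
  expect_identical(got$composition[mism], character(0),
                   label = "compositions disagreeing with the rule oracle")
})

test_that("rule-system invariants hold across the grid", {
  g <- grid_compositions()
  comps <- lapply(seq_len(nrow(g)), function(i)
    glycan_composition(c(Hex = g$H[i], HexNAc = g$N[i],
                         dHex = g$F[i], NeuAc = g$S[i])))
  tab <- classify_compositions(comps)
  deco <- strsplit(tab$decorations, ";", fixed = TRUE)

  # exactly one type class, from the closed vocabulary
  expect_true(all(tab$type_class %in%
    c("PAUCI_MANNOSE", "HIGH_MANNOSE", "HYBRID", "COMPLEX", "UNCLASSIFIED")))

  # fucosylated and multifucosylated never co-occur
  expect_false(any(vapply(deco, function(d)
    all(c("FUCOSYLATED", "MULTI_FUCOSYLATED") %in% d), logical(1))))

  # polylactosamine implies tetra-antennary under the implemented rules
  has <- function(d, x) vapply(d, function(v) x %in% v, logical(1))
  expect_true(all(!has(deco, "POLYLACTOSAMINE") | has(deco, "TETRA_ANTENNARY")))

  # ambiguous flag appears exactly with the combined branching label
  expect_identical(tab$ambiguous, has(deco, "BISECTING_OR_TETRA_ANTENNARY"))
})

test_that("classification is pure and unknown residues only warn", {
  a <- classify("Hex:5 HexNAc:4 dHex:1 NeuAc:1")
  b <- classify("Hex:5 HexNAc:4 dHex:1 NeuAc:1")
  expect_identical(a[setdiff(names(a), "composition")],
                   b[setdiff(names(b), "composition")])

  expect_warning(r <- classify("Hex:5 HexNAc:4 NeuGc:1"), "NeuGc")
  expect_equal(r$type_class, "COMPLEX")   # type set from known residues only
})

test_that("ontology terms and class counts follow from classification", {
  comps <- c(g1 = "Hex:7 HexNAc:2", g2 = "Hex:3 HexNAc:6")
  ont <- ontology_terms(comps)
  expect_equal(ont$terms$g1, "HIGH_MANNOSE")
  expect_setequal(ont$terms$g2, c("COMPLEX", "TETRA_ANTENNARY"))
  expect_equal(ont$index$HIGH_MANNOSE, "g1")
  expect_equal(ont$index$COMPLEX, "g2")
  expect_equal(ont$index$TETRA_ANTENNARY, "g2")

  cc <- class_counts(comps)
  expect_equal(cc$count[cc$term == "HIGH_MANNOSE"], 1L)
  expect_equal(cc$count[cc$term == "COMPLEX"], 1L)

  expect_error(ontology_terms(list()), "non-empty")

  # duplicates are separate occurrences; every glycan carries >= 1 term
  dup <- c("Hex:7 HexNAc:2", "Hex:7 HexNAc:2", "Hex:4 HexNAc:2 dHex:1")
  ont2 <- ontology_terms(dup)
  expect_length(ont2$terms, 3)
  expect_true(all(lengths(ont2$terms) >= 1))
  expect_length(ont2$index$HIGH_MANNOSE, 2)

  # counts are order-independent
  set.seed(5)
  perm <- sample(dup)
  c1 <- class_counts(dup); c2 <- class_counts(perm)
  expect_equal(c1[order(c1$term), ], c2[order(c2$term), ], ignore_attr = TRUE)
})
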