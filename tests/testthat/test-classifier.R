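test_that("the Dicer gate requires tandem RNase III plus an RNA-binding domain", {
  # {RNaseIII x2, DUF283} passes; {RNaseIII x2} alone and a single RNase III fail
  expect_true(dcr_gate(2L, TRUE))
  expect_false(dcr_gate(2L, FALSE))
  expect_false(dcr_gate(1L, TRUE))
  expect_equal(dcr_gate(c(2, 3, 1, 0), c(TRUE, FALSE, TRUE, TRUE)),
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("the unit rule table is mutually exclusive and exhaustive over all 16 patterns", {
  grid <- expand.grid(hel = c(TRUE, FALSE), duf = c(TRUE, FALSE),
                      paz = c(TRUE, FALSE), dsrbd = c(TRUE, FALSE))
  cats <- classify_units(grid$hel, grid$duf, grid$paz, grid$dsrbd)
  expect_true(all(cats %in% dcr_categories()))
  # the five named patterns appear exactly once each
  named <- function(h, d, p, r) cats[grid$hel == h & grid$duf == d &
                                       grid$paz == p & grid$dsrbd == r]
  expect_equal(named(TRUE, TRUE, TRUE, TRUE), "canonical")
  expect_equal(named(TRUE, TRUE, TRUE, FALSE), "nonA")   # missing dsRBD only
  expect_equal(named(TRUE, TRUE, FALSE, TRUE), "nonB")   # missing PAZ only
  expect_equal(named(FALSE, TRUE, TRUE, FALSE), "nonC")  # missing HEL + dsRBD
  expect_equal(named(TRUE, TRUE, FALSE, FALSE), "nonD")  # missing PAZ + dsRBD
  expect_equal(sum(cats == "nonE"), 16L - 5L)            # catch-all
  # e.g. DUF283 + tandem RNase III only: three units missing -> nonE
  expect_equal(named(FALSE, TRUE, FALSE, FALSE), "nonE")
})

test_that("classification is invariant to hit order and to removable decoys", {
  sim <- simulate_proteome(60, seed = 9)
  lengths <- sim$truth[, c("protein_id", "protein_length")]
  base <- sim$hits |>
    filter_hits() |>
    assemble_architectures(lengths) |>
    classify_architectures()
  shuffled <- sim$hits[sample.int(nrow(sim$hits)), ] |>
    filter_hits() |>
    assemble_architectures(lengths) |>
    classify_architectures()
  with_decoys <- sim$hits |>                      # no filter: decoys stay
    filter_hits(evalue_max = 1e-3) |>
    assemble_architectures(lengths) |>
    classify_architectures()
  expect_equal(base$category, shuffled$category)
  expect_equal(base$category, with_decoys$category)
})

test_that("planted categories are recovered end-to-end on a synthetic proteome", {
  sim <- simulate_proteome(200, seed = 21)
  rec <- sim$hits |>
    filter_hits() |>
    assemble_architectures(sim$truth[, c("protein_id", "protein_length")]) |>
    classify_architectures()
  joined <- dplyr::inner_join(sim$truth, rec, by = "protein_id")
  dcr <- joined$category.x != "non_dcr"
  expect_equal(joined$is_dcr, dcr)
  expect_equal(joined$category.y[dcr], joined$category.x[dcr])
})

test_that("terminal lengths are measured to the DUF283 and RNase IIIb anchors", {
  hits <- tibble::tibble(
    protein_id = "p",
    domain_label = c("DUF283", "RNaseIII", "RNaseIII"),
    start = c(300L, 500L, 650L), end = c(380L, 600L, 750L),
    evalue = 1e-10, score = 100
  )
  tl <- terminal_lengths(hits, 1000L)
  expect_equal(tl$n_term_len, 299L)
  expect_equal(tl$c_term_len, 250L)
  # boundary cases: DUF283 at residue 1; RNase IIIb ending at the C-terminus
  hits2 <- hits
  hits2$start[1] <- 1L
  hits2$end[3] <- 1000L
  tl2 <- terminal_lengths(hits2, 1000L)
  expect_equal(tl2$n_term_len, 0L)
  expect_equal(tl2$c_term_len, 0L)
  # undefined without the anchors
  expect_true(is.na(terminal_lengths(hits[2:3, ], 1000L)$n_term_len))
  expect_true(is.na(terminal_lengths(hits[1:2, ], 1000L)$c_term_len))
})

test_that("annotation duplicates collapse within species; isoforms and cross-species records survive", {
  rec <- tibble::tibble(
    protein_id = c("XP_2", "XP_1", "XP_3", "XP_4", "XP_5"),
    species = c("s1", "s1", "s1", "s2", "s1"),
    sequence = c("MAAA", "MAAA", "MAAAK", "MAAA", NA),
    uniprot_id = c("U1", "U1", "U2", "U1", "U3"),
    gene_id = c("g1", "g1", "g1", "g9", "g5"),
    locus = c("L1", "L1", "L1", "L9", "L5")
  )
  out <- deduplicate_records(rec)
  # XP_1/XP_2 are duplicates -> lexicographically smallest kept
  expect_true("XP_1" %in% out$protein_id)
  expect_false("XP_2" %in% out$protein_id)
  # same gene/locus but different sequence (isoform) kept
  expect_true("XP_3" %in% out$protein_id)
  # identical sequence in another species kept
  expect_true("XP_4" %in% out$protein_id)
  # missing metadata passes through
  expect_true("XP_5" %in% out$protein_id)
  # idempotent
  expect_equal(deduplicate_records(out), out)
  # singleton unchanged
  expect_equal(deduplicate_records(rec[4, ]), rec[4, ])
})

test_that("category summaries reproduce share arithmetic", {
  s <- summarize_categories(c(canonical = 10))
  expect_equal(s$categories$percent[s$categories$category == "canonical"], 100)
  s2 <- summarize_categories(c(nonB = 1, nonD = 1, nonE = 2))
  expect_equal(s2$cpaz_lacking_pct, 100)
  expect_equal(sum(s2$categories$n), s2$total)
})

test_that("dataset composition rounds half-up to one decimal", {
  comp <- dataset_composition(c(a = 1, b = 2), total = 3)
  expect_equal(comp$percent, c(33.3, 66.7))
})
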