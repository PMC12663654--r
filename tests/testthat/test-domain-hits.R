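# a hand-written domtblout fixture in the hmmscan layout (model as target):
# 22 data columns; envelope coordinates in columns 20-21, i-E-value in 13
domtbl_lines <- c(
  "# --- full sequence --- -------------- this domain -------------",
  "#target acc tlen query qacc qlen E score bias # of cE iE dscore dbias hf ht af at ef et acc desc",
  paste("RNase_III PF00636.23 120 protA - 1000 1e-12 80.1 0.1 1 2",
        "3e-11 2e-10 45.2 0.0 2 118 10 142 12 140 0.95 -"),
  paste("PAZ PF02170.12 110 protA - 1000 5e-9 60.0 0.0 1 1",
        "8e-8 6e-8 30.0 0.0 1 108 300 420 298 422 0.90 -"),
  paste("Unknown PF99999.1 50 protA - 1000 1e-5 20.0 0.0 1 1",
        "1e-4 1e-4 10.0 0.0 1 48 500 550 499 551 0.80 -")
)

test_that("domtblout parsing maps accessions, envelope coordinates and i-E-values", {
  hits <- suppressWarnings(read_domtblout(domtbl_lines))
  expect_equal(nrow(hits), 2L)
  r3 <- hits[hits$domain_label == "RNaseIII", ]
  expect_equal(r3$protein_id, "protA")
  expect_equal(c(r3$start, r3$end), c(12L, 140L))   # env, not ali (10-142)
  expect_equal(r3$evalue, 2e-10)                    # independent, not cond.
  expect_equal(r3$score, 45.2)
  expect_warning(read_domtblout(domtbl_lines), "PF99999")
})

test_that("comment-only input gives an empty table; short rows are reported with line numbers", {
  expect_equal(nrow(read_domtblout(c("# only", "# comments"))), 0L)
  bad <- c("# header", "too few columns here")
  expect_error(read_domtblout(bad), "line\\(s\\) 2")
})

test_that("hmmsearch layout (model as query) parses identically", {
  line <- paste("protB - 900 RNase_III PF00636.23 120 1e-12 80.1 0.1 1 1",
                "3e-11 2e-10 45.2 0.0 2 118 10 142 12 140 0.95 -")
  hits <- read_domtblout(line)
  expect_equal(hits$protein_id, "protB")
  expect_equal(hits$domain_label, "RNaseIII")
})

test_that("E-value filtering is inclusive at the threshold and idempotent", {
  hits <- tibble::tibble(
    protein_id = "p", domain_label = "PAZ",
    start = c(1L, 50L, 100L), end = c(40L, 90L, 140L),
    evalue = c(1e-3, 5e-2, 1e-10), score = c(10, 5, 90)
  )
  kept <- filter_hits(hits, evalue_max = 1e-3)
  expect_equal(kept$evalue, c(1e-3, 1e-10))          # 1e-3 retained, 5e-2 not
  expect_identical(filter_hits(kept, 1e-3), kept)    # idempotent
  expect_identical(filter_hits(hits, 1), hits)       # all below -> identity
})

test_that("overlap resolution keeps the lower-E-value hit and counts RNase III correctly", {
  mk_hits <- function(starts, ends, ev, sc = rev(seq_along(ev))) {
    tibble::tibble(protein_id = "p", domain_label = "RNaseIII",
                   start = as.integer(starts), end = as.integer(ends),
                   evalue = ev, score = as.numeric(sc))
  }
  lengths <- tibble::tibble(protein_id = "p", protein_length = 1000L)

  overl <- assemble_architectures(mk_hits(c(500, 550), c(600, 650),
                                          c(1e-20, 1e-5)), lengths)
  expect_equal(overl$rnase3_count, 1L)
  expect_equal(overl$hits[[1]]$evalue, 1e-20)

  disj <- assemble_architectures(mk_hits(c(500, 650), c(600, 750),
                                         c(1e-20, 1e-5)), lengths)
  expect_equal(disj$rnase3_count, 2L)

  none <- assemble_architectures(empty_hits <- mk_hits(integer(0), integer(0),
                                                       numeric(0)), lengths)
  expect_equal(none$rnase3_count, 0L)
  expect_false(any(c(none$has_paz, none$has_dsrbd, none$has_helicase)))
})

test_that("architectures reject hits extending beyond the protein length", {
  hits <- tibble::tibble(protein_id = "p", domain_label = "PAZ",
                         start = 10L, end = 200L, evalue = 1e-9, score = 50)
  expect_error(
    assemble_architectures(hits,
                           tibble::tibble(protein_id = "p",
                                          protein_length = 150L)),
    "beyond protein_length"
  )
})

test_that("greedy resolution attains the exhaustive optimum on mutually-overlapping hits and matches the rule's recursive form in general", {
  lengths <- tibble::tibble(protein_id = "p", protein_length = 2000L)
  for (seed in 1:25) {
    withr::with_seed(seed, {
      # clique instance: 2-3 hits all sharing residue 100
      k <- sample(2:3, 1)
      clique <- tibble::tibble(
        protein_id = "p", domain_label = "RNaseIII",
        start = as.integer(sample(50:100, k)),
        end = as.integer(sample(100:160, k)),
        evalue = 10^-runif(k, 3, 30), score = runif(k, 10, 100)
      )
      got <- assemble_architectures(clique, lengths)$hits[[1]]
      opt <- clique[max_subset_oracle(clique), ]
      expect_equal(got$start, sort(opt$start))
      expect_equal(sum(got$evalue), sum(opt$evalue))

      # general random instance: greedy rule restated as recursion
      n <- sample(3:6, 1)
      s <- sample(1:1500, n)
      rnd <- tibble::tibble(
        protein_id = "p", domain_label = "RNaseIII",
        start = as.integer(s), end = as.integer(s + sample(30:300, n)),
        evalue = 10^-runif(n, 3, 30), score = runif(n, 10, 100)
      )
      rnd$end <- pmin(rnd$end, 2000L)
      got2 <- assemble_architectures(rnd, lengths)$hits[[1]]
      expect_equal(sort(got2$start), sort(rnd$start[greedy_rule_oracle(rnd)]))
    })
  }
})

test_that("retained hits round-trip through the TSV dialect", {
  sim <- simulate_proteome(20, seed = 42)
  kept <- filter_hits(sim$hits)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(kept, path)
  back <- read_hits_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(kept))
})
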