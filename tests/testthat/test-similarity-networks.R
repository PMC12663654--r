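test_that("self-hits drop, reciprocal duplicates merge to max identity, thresholds are inclusive", {
  pairs <- tibble::tibble(
    id_a = c("x", "a", "b", "c", "d"),
    id_b = c("x", "b", "a", "d", "e"),
    identity = c(100, 55, 60, 50.0, 49.9),
    coverage_a = c(100, 90, 95, 80.0, 95),
    coverage_b = c(100, 92, 85, 81, 95)
  )
  g <- build_sequence_network(pairs)
  expect_equal(nrow(g$edges), 2L)
  ab <- g$edges[g$edges$id_a == "a", ]
  expect_equal(ab$weight, 60)                  # max of the reciprocal pair
  expect_true(any(g$edges$id_a == "c"))        # 50.0 / 80.0 retained (inclusive)
  expect_false(any(g$edges$id_b == "e"))       # 49.9 rejected
  expect_true("x" %in% g$nodes)                # node survives self-hit removal
})

test_that("coverage is enforced on both sequences", {
  pairs <- tibble::tibble(id_a = "a", id_b = "b", identity = 90,
                          coverage_a = 95, coverage_b = 60)
  expect_equal(nrow(build_sequence_network(pairs)$edges), 0L)
  expect_error(build_sequence_network(dplyr::mutate(pairs, identity = 130)),
               "\\[0, 100\\]")
})

test_that("structure network excludes low-pLDDT models first and averages asymmetric TM-scores", {
  tm <- tibble::tibble(
    id_a = c("a", "b", "a", "c"),
    id_b = c("b", "a", "c", "a"),
    tm_score = c(0.92, 0.90, 0.95, 0.95)
  )
  pl <- c(a = 80, b = 75, c = 69.9)
  g <- build_structure_network(tm, pl)
  expect_false("c" %in% g$nodes)               # 69.9 < 70 excluded
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 0.91)           # mean(0.92, 0.90) >= 0.9
  # all-low TM: edgeless, every node its own singleton cluster
  g2 <- build_structure_network(dplyr::mutate(tm, tm_score = 0.5), pl)
  cl2 <- cluster_components(g2)
  expect_equal(cl2$n_clusters, length(g2$nodes))
  expect_true(all(cl2$clusters$is_singleton))
})

test_that("clusters order by size then member, and hubs have maximal degree", {
  pairs <- tibble::tibble(
    id_a = c("a", "b", "c", "p", "q"),
    id_b = c("b", "c", "a", "q", "r"),
    identity = 90, coverage_a = 95, coverage_b = 95
  )
  g <- build_sequence_network(pairs, nodes = c("a", "b", "c", "p", "q", "r", "z"))
  cl <- cluster_components(g)
  expect_equal(cl$clusters$size, c(3L, 3L, 1L))
  # triangle: all degree 2, lexicographic hub; path p-q-r: hub is q (degree 2)
  expect_equal(cl$clusters$hub, c("a", "q", "z"))
  m <- tidy(cl)
  expect_true(all(vapply(split(m, m$cluster), function(d) {
    max(d$degree) == d$degree[d$is_hub]
  }, logical(1))))
})

test_that("components equal the transitive-closure oracle on random graphs", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- 50
      ids <- sprintf("n%02d", 1:n)
      m <- 60
      pairs <- tibble::tibble(
        id_a = sample(ids, m, replace = TRUE),
        id_b = sample(ids, m, replace = TRUE),
        identity = runif(m, 0, 100),
        coverage_a = runif(m, 0, 100),
        coverage_b = runif(m, 0, 100)
      )
      g <- build_sequence_network(pairs, nodes = ids)
      cl <- cluster_components(g)
      oracle <- closure_components(ids, g$edges)
      got <- split(cl$membership$id, cl$membership$cluster)
      expect_setequal(
        unname(vapply(got, function(s) paste(sort(s), collapse = ","),
                      character(1))),
        unname(vapply(oracle, function(s) paste(sort(s), collapse = ","),
                      character(1)))
      )
    })
  }
})

test_that("edge and component counts are invariant to row order; raising thresholds refines clusters", {
  withr::with_seed(99, {
    plan <- tibble::tibble(cluster_size = c(6, 5, 4),
                           within_identity = c(72, 66, 58),
                           between_identity = c(30, 25, 20))
    st <- simulate_similarity_table(plan, seed = 7)
    g1 <- build_sequence_network(st$pairs)
    g2 <- build_sequence_network(st$pairs[sample.int(nrow(st$pairs)), ])
    expect_equal(nrow(g1$edges), nrow(g2$edges))
    expect_equal(cluster_components(g1)$n_clusters,
                 cluster_components(g2)$n_clusters)
    base <- cluster_components(g1)$membership
    for (thr in c(55, 60, 65, 70, 80)) {
      finer <- cluster_components(build_sequence_network(st$pairs,
                                                         identity_min = thr))
      j <- dplyr::inner_join(base, finer$membership, by = "id",
                             suffix = c("_lo", "_hi"))
      # refinement: two nodes in one high-threshold cluster must share the
      # low-threshold cluster
      pairs_same_hi <- split(j$cluster_lo, j$cluster_hi)
      expect_true(all(vapply(pairs_same_hi,
                             function(x) length(unique(x)) == 1L, logical(1))))
    }
  })
})

test_that("planted clusters are recovered exactly when thresholds separate them", {
  plan <- tibble::tibble(cluster_size = c(8, 6, 5, 3),
                         within_identity = c(75, 68, 62, 55),
                         between_identity = c(30, 28, 22, 18))
  st <- simulate_similarity_table(plan, seed = 31)
  cl <- cluster_components(build_sequence_network(st$pairs))
  j <- dplyr::inner_join(tidy(cl), st$truth, by = "id",
                         suffix = c("_got", "_true"))
  # bijection between recovered and planted clusters
  tab <- table(j$cluster_got, j$cluster_true)
  expect_equal(sum(tab > 0), nrow(plan))
  expect_equal(unname(colSums(tab)), plan$cluster_size)
})
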