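#' Default category mix for simulated proteomes
#'
#' Probabilities over the six architecture categories plus a `non_dcr`
#' decoy class. The Dicer categories follow the composition observed in
#' the clade-wide survey (35 : 80 : 356 : 273 : 1825 : 342), scaled to
#' leave `non_dcr_frac` of proteins as RNase III-containing non-Dicers.
#'
#' @param non_dcr_frac Fraction of non-Dicer decoy proteins; default 0.2.
#' @return Named probability vector summing to 1.
#' @export
default_category_mix <- function(non_dcr_frac = 0.2) {
  counts <- c(canonical = 35, nonA = 80, nonB = 356,
              nonC = 273, nonD = 1825, nonE = 342)
  c(counts / sum(counts) * (1 - non_dcr_frac), non_dcr = non_dcr_frac)
}

# domain segment templates: typical envelope lengths in aa
.domain_lengths <- c(DEAD = 170L, ResIII = 150L, HeliC = 110L, DUF283 = 80L,
                     PAZ = 110L, RNaseIII = 100L, dsRBD = 70L)

# ordered domain layout per planted class
.category_layout <- list(
  canonical = c("DEAD", "ResIII", "HeliC", "DUF283", "PAZ",
                "RNaseIII", "RNaseIII", "dsRBD"),
  nonA = c("DEAD", "ResIII", "HeliC", "DUF283", "PAZ",
           "RNaseIII", "RNaseIII"),
  nonB = c("DEAD", "ResIII", "HeliC", "DUF283",
           "RNaseIII", "RNaseIII", "dsRBD"),
  nonC = c("DUF283", "PAZ", "RNaseIII", "RNaseIII"),
  nonD = c("DEAD", "ResIII", "HeliC", "DUF283", "RNaseIII", "RNaseIII"),
  nonE = c("DUF283", "RNaseIII", "RNaseIII")
)

#' Simulate a proteome with planted Dicer architectures
#'
#' Generates a domain-hit table in the package's tabular dialect together
#' with the planted ground truth, protein metadata, and i.i.d.-uniform
#' amino-acid sequences. Each protein is drawn from `category_mix` and
#' given a domain layout matching its category exactly: planted hits have
#' E-values far below the detection threshold, while decoy hits carry
#' E-values above `1e-3` and are placed so they never overlap planted
#' segments, so the gate/classifier ground truth is unambiguous.
#' Non-Dicer decoys fail the gate either by having a single RNase III
#' (plus PAZ) or two RNase III domains with no RNA-binding domain.
#'
#' @param n_proteins Number of proteins, `> 0`.
#' @param category_mix Named probability vector over
#'   `c(dcr_categories(), "non_dcr")`; see [default_category_mix()].
#' @param decoy_rate Mean number of above-threshold decoy hits per
#'   protein (Poisson); default 1.
#' @param n_species Number of species the proteins are spread over.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return An object of class `dcr_sim`: list with tibbles `hits`
#'   (protein_id, domain_label, start, end, evalue, score), `truth`
#'   (protein_id, category, protein_length), `meta` (species, phylum,
#'   proteome_id, gene_id, locus, uniprot_id per protein) and a named
#'   character vector `sequences`.
#' @export
simulate_proteome <- function(n_proteins = 500,
                              category_mix = default_category_mix(),
                              decoy_rate = 1,
                              n_species = max(1L, n_proteins %/% 2L),
                              seed = 1L) {
  if (n_proteins <= 0) stop("n_proteins must be positive", call. = FALSE)
  stopifnot(abs(sum(category_mix) - 1) < 1e-9,
            all(names(category_mix) %in% c(dcr_categories(), "non_dcr")))
  withr::with_seed(seed, {
    categories <- sample(names(category_mix), n_proteins, replace = TRUE,
                         prob = category_mix)
    ids <- sprintf("P%05d", seq_len(n_proteins))
    species_pool <- sprintf("Species_%03d", seq_len(n_species))
    phyla <- c("Ascomycota", "Basidiomycota", "Mucoromycota",
               "Chytridiomycota", "Zoopagomycota")
    species <- sample(species_pool, n_proteins, replace = TRUE)
    sp_phylum <- stats::setNames(
      sample(phyla, n_species, replace = TRUE,
             prob = c(0.55, 0.25, 0.1, 0.05, 0.05)),
      species_pool
    )
    per_protein <- purrr::map2(ids, categories, function(id, cat) {
      plant_protein(id, cat, decoy_rate)
    })
    hits <- dplyr::bind_rows(purrr::map(per_protein, "hits"))
    truth <- tibble::tibble(
      protein_id = ids,
      category = categories,
      protein_length = purrr::map_int(per_protein, "protein_length")
    )
    meta <- tibble::tibble(
      protein_id = ids,
      species = species,
      phylum = unname(sp_phylum[species]),
      proteome_id = paste0("GCF_", species),
      gene_id = sprintf("gene_%05d", seq_len(n_proteins)),
      locus = sprintf("LOC%05d", seq_len(n_proteins)),
      uniprot_id = sprintf("U%05d", seq_len(n_proteins))
    )
    sequences <- stats::setNames(
      vapply(truth$protein_length, random_protein, character(1)),
      ids
    )
    structure(list(hits = hits, truth = truth, meta = meta,
                   sequences = sequences, seed = seed),
              class = "dcr_sim")
  })
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# lay out one protein's planted segments + decoys
plant_protein <- function(id, category, decoy_rate) {
  layout <- if (category == "non_dcr") {
    if (stats::runif(1) < 0.5) c("PAZ", "RNaseIII") else c("RNaseIII", "RNaseIII")
  } else {
    .category_layout[[category]]
  }
  n <- length(layout)
  gaps <- sample(20:120, n, replace = TRUE)
  lens <- .domain_lengths[layout]
  # start_i = lead + sum_{j<i}(len_j + gap_j)
  lead <- sample(10:100, 1L)
  start <- lead + c(0L, cumsum(unname(lens[-n]) + gaps[seq_len(n - 1L)]))
  end <- start + unname(lens) - 1L
  tail_len <- sample(10:150, 1L)
  protein_length <- end[n] + tail_len
  planted <- tibble::tibble(
    protein_id = id,
    domain_label = layout,
    start = as.integer(start),
    end = as.integer(end),
    evalue = 10^-stats::runif(n, 5, 50),
    score = stats::runif(n, 80, 500)
  )
  n_decoy <- stats::rpois(1L, decoy_rate)
  decoys <- plant_decoys(id, n_decoy, planted, protein_length)
  list(hits = dplyr::bind_rows(planted, decoys),
       protein_length = as.integer(protein_length))
}

# decoys live in the free gaps between planted segments, never overlapping
# them, and always carry E-values above the 1e-3 detection threshold
plant_decoys <- function(id, n_decoy, planted, protein_length) {
  if (n_decoy == 0L) return(NULL)
  occupied <- planted[order(planted$start), c("start", "end")]
  free <- free_intervals(occupied, protein_length)
  free <- free[free$end - free$start + 1L >= 15L, ]
  if (nrow(free) == 0L) return(NULL)
  pick1 <- function(x) x[sample.int(length(x), 1L)]  # safe for length-1 x
  rows <- purrr::map(seq_len(n_decoy), function(i) {
    g <- free[sample.int(nrow(free), 1L), ]
    len <- pick1(10:min(30L, g$end - g$start + 1L))
    s <- pick1(g$start:(g$end - len + 1L))
    tibble::tibble(
      protein_id = id,
      domain_label = sample(dcr_domains(), 1L),
      start = as.integer(s),
      end = as.integer(s + len - 1L),
      evalue = stats::runif(1L, 2e-3, 10),
      score = stats::runif(1L, 1, 20)
    )
  })
  dplyr::bind_rows(rows)
}

free_intervals <- function(occupied, protein_length) {
  bounds <- c(0L, occupied$end, protein_length + 1L)
  starts <- utils::head(bounds, -1) + 1L
  ends <- c(occupied$start - 1L, protein_length)
  keep <- starts <= ends
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' @export
print.dcr_sim <- function(x, ...) {
  cat(sprintf("<dcr_sim> %d proteins (%d hits), seed %s\n",
              nrow(x$truth), nrow(x$hits), format(x$seed)))
  print(table(x$truth$category))
  invisible(x)
}

#' Simulate a random rooted tree
#'
#' Seed-deterministic wrapper around [ape::rtree()] (uniform branch
#' lengths in (0, 1)).
#'
#' @param n_tips Number of tips.
#' @param seed Integer seed.
#' @return A rooted `phylo` tree.
#' @export
simulate_tree <- function(n_tips, seed = 1L) {
  withr::with_seed(seed, ape::rtree(n_tips))
}

#' Simulate a binary character on a tree under the ER-Mk model
#'
#' The root state is drawn from a uniform prior and each branch of length
#' `t` flips the state with probability `(1 - exp(-2 q t)) / 2` — the
#' exact two-state equal-rates transition probability, so simulated data
#' match the model fitted by [fit_mk_er()].
#'
#' @param tree Rooted `phylo` tree with branch lengths `>= 0`.
#' @param q ER rate, `>= 0`.
#' @param seed Integer seed.
#' @return Tibble with `id` (tip label) and `state` (0/1). The full
#'   node-state vector (ape node numbering) is attached as attribute
#'   `node_states`.
#' @export
simulate_binary_character <- function(tree, q, seed = 1L) {
  check_tree(tree)
  if (q < 0) stop("q must be non-negative", call. = FALSE)
  withr::with_seed(seed, {
    nt <- length(tree$tip.label)
    nn <- tree$Nnode
    state <- integer(nt + nn)
    root <- nt + 1L
    state[root] <- sample(0:1, 1L)
    tr <- ape::reorder.phylo(tree, "postorder")
    E <- tr$edge
    el <- tr$edge.length
    for (i in rev(seq_len(nrow(E)))) {  # preorder: parents before children
      p_flip <- (1 - exp(-2 * q * el[i])) / 2
      flip <- stats::runif(1L) < p_flip
      state[E[i, 2L]] <- if (flip) 1L - state[E[i, 1L]] else state[E[i, 1L]]
    }
    out <- tibble::tibble(id = tree$tip.label, state = state[seq_len(nt)])
    attr(out, "node_states") <- state
    out
  })
}

#' Simulate a pairwise-similarity table with planted clusters
#'
#' Builds `(id_a, id_b, identity, coverage_a, coverage_b)` rows directly
#' (no alignment is simulated). All within-cluster pairs receive identity
#' near `within_identity` with high coverage; a sample of between-cluster
#' pairs receives identity near `between_identity`. Self-hits and
#' reciprocal duplicates are included deliberately so network cleaning is
#' exercised.
#'
#' @param cluster_plan Tibble with columns `cluster_size`,
#'   `within_identity`, `between_identity` (one row per planted cluster).
#' @param seed Integer seed.
#' @return List with `pairs` (the similarity tibble) and `truth`
#'   (tibble `id`, `cluster`).
#' @export
simulate_similarity_table <- function(cluster_plan, seed = 1L) {
  stopifnot(all(c("cluster_size", "within_identity", "between_identity")
                %in% names(cluster_plan)))
  withr::with_seed(seed, {
    members <- purrr::imap(cluster_plan$cluster_size, function(sz, k) {
      sprintf("c%02d_m%02d", k, seq_len(sz))
    })
    truth <- tibble::tibble(
      id = unlist(members),
      cluster = rep(seq_along(members), cluster_plan$cluster_size)
    )
    jitter_id <- function(center, n) {
      pmin(100, pmax(0, center + stats::runif(n, -1.5, 1.5)))
    }
    within <- purrr::imap(members, function(m, k) {
      if (length(m) < 2L) return(NULL)
      pr <- t(utils::combn(m, 2L))
      n <- nrow(pr)
      tibble::tibble(
        id_a = pr[, 1L], id_b = pr[, 2L],
        identity = jitter_id(cluster_plan$within_identity[k], n),
        coverage_a = stats::runif(n, 85, 100),
        coverage_b = stats::runif(n, 85, 100)
      )
    })
    ids <- truth$id
    n_between <- 3L * nrow(truth)
    a <- sample(ids, n_between, replace = TRUE)
    b <- sample(ids, n_between, replace = TRUE)
    ka <- truth$cluster[match(a, ids)]
    kb <- truth$cluster[match(b, ids)]
    keep <- ka != kb
    between <- tibble::tibble(
      id_a = a[keep], id_b = b[keep],
      identity = jitter_id(
        (cluster_plan$between_identity[ka[keep]] +
           cluster_plan$between_identity[kb[keep]]) / 2,
        sum(keep)
      ),
      coverage_a = stats::runif(sum(keep), 40, 100),
      coverage_b = stats::runif(sum(keep), 40, 100)
    )
    selfhits <- tibble::tibble(id_a = ids, id_b = ids, identity = 100,
                               coverage_a = 100, coverage_b = 100)
    # reciprocal duplicates for a sample of within-cluster rows
    wtab <- dplyr::bind_rows(within)
    recip <- wtab[sample.int(nrow(wtab), min(20L, nrow(wtab))), ]
    recip <- dplyr::rename(recip, id_a = "id_b", id_b = "id_a")
    pairs <- dplyr::bind_rows(wtab, recip, between, selfhits)
    pairs <- pairs[sample.int(nrow(pairs)), ]
    list(pairs = pairs, truth = truth)
  })
}

#' Write a toy C-alpha structure with planted anchors
#'
#' Emits valid PDB `ATOM` records, one C-alpha per residue of each named
#' segment. The first residue of each segment sits exactly on the
#' segment's anchor coordinate (so planted inter-segment distances are
#' exact); later residues extend from it in 1.5-Angstrom steps. The
#' B-factor column carries the planted per-segment pLDDT.
#'
#' @param segment_plan Tibble with columns `segment`, `start`, `end`
#'   (residue numbers), `x`, `y`, `z` (anchor, Angstrom) and `plddt`.
#' @param path Optional output path; when `NULL` the lines are returned
#'   only.
#' @return Character vector of PDB lines, invisibly when written.
#' @export
#' @examples
#' plan <- tibble::tibble(segment = c("PAZ", "RNaseIIIa"),
#'                        start = c(1, 50), end = c(10, 60),
#'                        x = c(0, 3), y = c(0, 4), z = c(0, 0), plddt = 80)
#' head(write_toy_structure(plan), 3)
write_toy_structure <- function(segment_plan, path = NULL) {
  needed <- c("segment", "start", "end", "x", "y", "z", "plddt")
  if (!all(needed %in% names(segment_plan))) {
    stop("segment_plan must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(segment_plan$start > segment_plan$end)) {
    stop("segment start must be <= end", call. = FALSE)
  }
  res <- segment_plan |>
    dplyr::rowwise() |>
    dplyr::reframe(
      residue = .data$start:.data$end,
      x = .data$x + 1.5 * (.data$residue - .data$start),
      y = .data$y,
      z = .data$z,
      plddt = .data$plddt
    ) |>
    dplyr::arrange(.data$residue)
  if (anyDuplicated(res$residue)) {
    stop("segments overlap in residue numbering", call. = FALSE)
  }
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(res)), res$residue, res$x, res$y, res$z, 1.00, res$plddt, "C"
  )
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write full-length protein sequences as FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return The written lines, invisibly.
#' @export
write_protein_fasta <- function(sequences, path) {
  lines <- as.vector(rbind(paste0(">", names(sequences)),
                           unname(sequences)))
  writeLines(lines, path)
  invisible(lines)
}
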