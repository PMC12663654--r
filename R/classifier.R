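#' The Dicer gate
#'
#' A protein qualifies as a putative Dicer when it carries (1) two tandem
#' RNase III domains — implemented as at least two retained, non-overlapping
#' RNase III hits, the 5'-most being IIIa — and (2) at least one RNA-binding
#' domain among the helicase subdomains (DEAD, ResIII, HeliC), DUF283, PAZ
#' or dsRBD.
#'
#' @param rnase3_count Integer vector: retained RNase III hits per protein.
#' @param has_binding Logical vector: any RNA-binding domain present.
#' @return Logical vector.
#' @export
#' @examples
#' dcr_gate(rnase3_count = c(2, 2, 1), has_binding = c(TRUE, FALSE, TRUE))
dcr_gate <- function(rnase3_count, has_binding) {
  rnase3_count >= 2L & has_binding
}

#' Six-category architecture classification
#'
#' Gate-passing Dicers are classified by which of four domain *units* are
#' missing: the helicase unit `HEL` (present iff any of DEAD/ResIII/HeliC
#' is detected), `DUF283`, `PAZ` and `dsRBD`. The missing-set drives the
#' category:
#'
#' * none missing — `canonical`
#' * only dsRBD — `nonA`
#' * only PAZ — `nonB`
#' * HEL and dsRBD — `nonC`
#' * PAZ and dsRBD — `nonD`
#' * any other pattern (including three or more missing units or patterns
#'   involving DUF283) — `nonE`, the catch-all
#'
#' The five named patterns plus the catch-all partition all 16 unit
#' patterns, so classification is total on gate-passing architectures.
#' Helicase subdomain completeness does not affect the category.
#'
#' @param has_helicase,has_duf283,has_paz,has_dsrbd Logical vectors of
#'   unit presence.
#' @return Character vector of category labels (see [dcr_categories()]).
#' @export
classify_units <- function(has_helicase, has_duf283, has_paz, has_dsrbd) {
  dplyr::case_when(
    has_helicase & has_duf283 & has_paz & has_dsrbd ~ "canonical",
    has_helicase & has_duf283 & has_paz & !has_dsrbd ~ "nonA",
    has_helicase & has_duf283 & !has_paz & has_dsrbd ~ "nonB",
    !has_helicase & has_duf283 & has_paz & !has_dsrbd ~ "nonC",
    has_helicase & has_duf283 & !has_paz & !has_dsrbd ~ "nonD",
    .default = "nonE"
  )
}

#' Classify assembled architectures
#'
#' Applies the Dicer gate and, for gate-passing proteins, the six-category
#' unit classifier and the terminal-length measurements. Terminal lengths
#' are measured to the nearest highly conserved anchors: the N-terminal
#' length runs up to the DUF283 start (`DUF283.start - 1`), the C-terminal
#' length from the end of the second RNase III hit (IIIb, by start order)
#' to the end of the protein. They are `NA` when the anchor is absent.
#'
#' @param arch Architecture tibble from [assemble_architectures()].
#' @return `arch` with added columns `is_dcr` (gate verdict), `category`
#'   (`NA` for non-Dicers), `helicase_complete` (all three subdomains
#'   detected; metadata only), `n_term_len` and `c_term_len`.
#' @export
classify_architectures <- function(arch) {
  binding <- arch$has_dead | arch$has_resiii | arch$has_helic |
    arch$has_duf283 | arch$has_paz | arch$has_dsrbd
  term <- purrr::map2(arch$hits, arch$protein_length, terminal_lengths)
  arch |>
    dplyr::mutate(
      is_dcr = dcr_gate(.data$rnase3_count, binding),
      category = dplyr::if_else(
        .data$is_dcr,
        classify_units(.data$has_helicase, .data$has_duf283,
                       .data$has_paz, .data$has_dsrbd),
        NA_character_
      ),
      helicase_complete = .data$has_dead & .data$has_resiii & .data$has_helic,
      n_term_len = purrr::map_int(term, "n_term_len"),
      c_term_len = purrr::map_int(term, "c_term_len")
    )
}

#' Terminal lengths for one protein
#'
#' @param hits Retained hits for one protein (sorted by `start`).
#' @param protein_length Protein length in amino acids.
#' @return List with integer `n_term_len` and `c_term_len` (`NA` when the
#'   respective anchor — DUF283, or a second RNase III hit — is absent).
#' @export
terminal_lengths <- function(hits, protein_length) {
  n_term <- NA_integer_
  c_term <- NA_integer_
  if (!is.null(hits) && nrow(hits) > 0L) {
    duf <- hits[hits$domain_label == "DUF283", ]
    if (nrow(duf) > 0L) {
      n_term <- as.integer(min(duf$start) - 1L)
    }
    r3 <- hits[hits$domain_label == "RNaseIII", ]
    if (nrow(r3) >= 2L) {
      r3 <- r3[order(r3$start), ]
      c_term <- as.integer(protein_length - r3$end[2L])
    }
  }
  list(n_term_len = n_term, c_term_len = c_term)
}

#' Collapse annotation duplicates
#'
#' Entries of the same species with a 100% identical amino-acid sequence
#' and the same UniProt accession are annotation duplicates: one
#' representative (the lexicographically smallest `protein_id`) is kept.
#' Entries sharing `gene_id` and `locus` but differing in sequence are
#' potential isoforms and are all retained. Records with missing species,
#' sequence or UniProt metadata pass through untouched.
#'
#' @param records Tibble with `protein_id` and (optionally) `species`,
#'   `sequence`, `uniprot_id` columns.
#' @return The deduplicated tibble; idempotent, never collapses across
#'   species.
#' @export
deduplicate_records <- function(records) {
  needed <- c("species", "sequence", "uniprot_id")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    message("deduplicate_records: no ", paste(missing_cols, collapse = "/"),
            " metadata; records passed through unchanged")
    return(records)
  }
  complete <- !is.na(records$species) & !is.na(records$sequence) &
    !is.na(records$uniprot_id)
  dup_part <- records[complete, ] |>
    dplyr::group_by(.data$species, .data$sequence, .data$uniprot_id) |>
    dplyr::slice_min(.data$protein_id, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- dplyr::bind_rows(dup_part, records[!complete, ])
  out[order(match(out$protein_id, records$protein_id)), ]
}

#' Summarise classified Dicer records
#'
#' Computes the per-category counts and one-decimal percentages (rounded
#' half-up), the share of Dicers lacking a recognizable canonical PAZ
#' (categories nonB + nonD + nonE), and — when the metadata are present —
#' a per-phylum cross-tabulation and a per-proteome copy-number histogram.
#'
#' @param records Classified records (rows with `is_dcr == TRUE` are used),
#'   or a named numeric vector of per-category counts.
#' @return An object of class `dcr_summary`: a list with `categories`
#'   (tibble of count/percent per category), `total`, `cpaz_lacking_pct`,
#'   and optionally `by_phylum` and `copy_number`.
#' @export
#' @examples
#' summarize_categories(c(canonical = 35, nonA = 80, nonB = 356,
#'                        nonC = 273, nonD = 1825, nonE = 342))
summarize_categories <- function(records) {
  if (is.numeric(records)) {
    stopifnot(!is.null(names(records)),
              all(names(records) %in% dcr_categories()))
    counts <- tibble::tibble(
      category = factor(names(records), levels = dcr_categories()),
      n = as.integer(records)
    ) |>
      tidyr::complete(.data$category, fill = list(n = 0L)) |>
      dplyr::arrange(.data$category)
    by_phylum <- NULL
    copy_number <- NULL
  } else {
    dcrs <- dplyr::filter(records, .data$is_dcr)
    counts <- dcrs |>
      dplyr::count(category = factor(.data$category, levels = dcr_categories())) |>
      tidyr::complete(.data$category, fill = list(n = 0L))
    by_phylum <- if ("phylum" %in% names(dcrs)) {
      dplyr::count(dcrs, .data$phylum, .data$category)
    }
    copy_number <- if ("proteome_id" %in% names(records)) {
      records |>
        dplyr::group_by(.data$proteome_id) |>
        dplyr::summarise(n_dcr = sum(.data$is_dcr), .groups = "drop") |>
        dplyr::count(.data$n_dcr, name = "n_proteomes")
    }
  }
  total <- sum(counts$n)
  counts$percent <- round_half_up(100 * counts$n / total, 1)
  lacking <- sum(counts$n[counts$category %in% c("nonB", "nonD", "nonE")])
  structure(
    list(
      categories = counts,
      total = total,
      cpaz_lacking_pct = round_half_up(100 * lacking / total, 1),
      by_phylum = by_phylum,
      copy_number = copy_number
    ),
    class = "dcr_summary"
  )
}

#' @export
print.dcr_summary <- function(x, ...) {
  cat("Dicer category summary —", x$total, "proteins\n")
  print(x$categories)
  cat(sprintf("cPAZ-lacking (nonB + nonD + nonE): %.1f%%\n", x$cpaz_lacking_pct))
  invisible(x)
}

#' Dataset composition percentages
#'
#' Shares of a whole as one-decimal percentages (rounded half-up), e.g.
#' unique species per phylum out of the total surveyed, or Dicer-less
#' proteomes out of all proteomes.
#'
#' @param counts Named numeric vector of group counts.
#' @param total Denominator; defaults to `sum(counts)`.
#' @return Tibble with `group`, `n`, `percent`.
#' @export
#' @examples
#' dataset_composition(c(Ascomycota = 910, Basidiomycota = 333,
#'                       Mucoromycota = 95), total = 1418)
dataset_composition <- function(counts, total = sum(counts)) {
  tibble::tibble(
    group = names(counts),
    n = as.numeric(counts),
    percent = round_half_up(100 * as.numeric(counts) / total, 1)
  )
}

#' Suggested structural-cluster-based names
#'
#' Implements the `Dcf` (Dicer fungi) naming scheme: each Dicer is named
#' `Dcf<k>` after the structural cluster `k` it belongs to.
#'
#' @param records Classified records with `protein_id`.
#' @param clusters Tibble with `id` and `cluster` (e.g. from
#'   [cluster_components()]).
#' @return `records` with an added `dcf_name` column (`NA` where the
#'   protein is not in the clustering).
#' @export
suggest_dcf_names <- function(records, clusters) {
  records |>
    dplyr::left_join(
      dplyr::transmute(clusters, protein_id = .data$id,
                       dcf_name = paste0("Dcf", .data$cluster)),
      by = "protein_id"
    )
}
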