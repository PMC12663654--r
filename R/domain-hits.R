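#' Read a HMMER per-domain hit table (domtblout dialect)
#'
#' Parses the whitespace-delimited per-domain tabular output of
#' `hmmscan`/`hmmsearch` into a tidy hit table. One row is produced per
#' domain match, carrying the envelope (`env`) coordinates, the independent
#' (`i-Evalue`) per-domain E-value and the per-domain bit score. The domain
#' model is recognised through its Pfam/InterPro accession (or name) on
#' either side of the table, so both `hmmscan` (model as target) and
#' `hmmsearch` (model as query) layouts are accepted. Rows whose accession
#' is outside the seven-domain Dicer vocabulary are dropped with a warning.
#'
#' @param path Path to a domtblout file, or a character vector of lines.
#' @return A tibble with columns `protein_id`, `domain_label`, `start`,
#'   `end`, `evalue`, `score`. Coordinates are 1-based inclusive amino-acid
#'   positions on the protein.
#' @seealso [read_hits_tsv()] for the minimal 6-column dialect,
#'   [filter_hits()], [assemble_architectures()]
#' @export
read_domtblout <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- nf < 22L
  if (any(bad)) {
    stop(sprintf(
      "malformed domtblout row(s) at line(s) %s: expected >= 22 columns",
      paste(line_no[bad], collapse = ", ")
    ), call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  target_name <- col(1); target_acc <- col(2)
  query_name <- col(4); query_acc <- col(5)
  # model side: whichever accession (or name) maps into the vocabulary
  lab_t <- map_domain_accession(target_acc)
  lab_t[is.na(lab_t)] <- map_domain_accession(target_name)[is.na(lab_t)]
  lab_q <- map_domain_accession(query_acc)
  lab_q[is.na(lab_q)] <- map_domain_accession(query_name)[is.na(lab_q)]
  model_is_target <- !is.na(lab_t)
  domain_label <- ifelse(model_is_target, lab_t, lab_q)
  protein_id <- ifelse(model_is_target, query_name, target_name)

  hits <- tibble::tibble(
    protein_id = protein_id,
    domain_label = domain_label,
    start = as.integer(col(20)),
    end = as.integer(col(21)),
    evalue = as.numeric(col(13)),
    score = as.numeric(col(14))
  )
  unknown <- is.na(hits$domain_label)
  if (any(unknown)) {
    shown <- ifelse(target_acc != "-", target_acc, query_acc)
    dropped <- unique(shown[unknown])
    warning(sprintf(
      "dropped %d hit(s) with accession(s) outside the Dicer domain vocabulary: %s",
      sum(unknown), paste(dropped, collapse = ", ")
    ), call. = FALSE)
    hits <- hits[!unknown, ]
  }
  hits
}

empty_hits <- function() {
  tibble::tibble(
    protein_id = character(), domain_label = character(),
    start = integer(), end = integer(),
    evalue = numeric(), score = numeric()
  )
}

#' Read/write the minimal 6-column hit table
#'
#' A plain TSV with columns `protein_id`, `domain_label`, `start`, `end`,
#' `evalue`, `score` — the package's interchange format for filtered hits.
#'
#' @param path File path.
#' @param hits A hit tibble as returned by [read_domtblout()].
#' @return `read_hits_tsv()` returns the hit tibble; `write_hits_tsv()`
#'   returns `hits` invisibly.
#' @export
read_hits_tsv <- function(path) {
  hits <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      domain_label = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      evalue = readr::col_double(),
      score = readr::col_double()
    )
  )
  bad <- !hits$domain_label %in% dcr_domains()
  if (any(bad)) {
    warning(sprintf("dropped %d hit(s) with unknown domain_label", sum(bad)),
            call. = FALSE)
    hits <- hits[!bad, ]
  }
  hits
}

#' @rdname read_hits_tsv
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(hits)
}

#' Filter domain hits by per-domain E-value
#'
#' Retains hits with `evalue <= evalue_max` (the threshold is inclusive).
#' Input order is preserved and the operation is idempotent.
#'
#' @param hits A hit tibble.
#' @param evalue_max Maximum independent E-value; default `1e-3`, the
#'   detection threshold used for the clade-wide survey.
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, evalue_max = 1e-3) {
  stopifnot(is.numeric(evalue_max), evalue_max > 0)
  dplyr::filter(hits, .data$evalue <= evalue_max)
}

# greedy overlap resolution for one protein's hits: ascending E-value,
# ties by higher score then smaller start; overlap = any shared residue
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1L) {
    return(dplyr::arrange(hits, .data$start))
  }
  ord <- order(hits$evalue, -hits$score, hits$start)
  kept_start <- integer(0)
  kept_end <- integer(0)
  keep <- logical(nrow(hits))
  for (i in ord) {
    s <- hits$start[i]; e <- hits$end[i]
    if (!any(s <= kept_end & e >= kept_start)) {
      keep[i] <- TRUE
      kept_start <- c(kept_start, s)
      kept_end <- c(kept_end, e)
    }
  }
  dplyr::arrange(hits[keep, ], .data$start)
}

#' Assemble per-protein domain architectures
#'
#' Groups filtered hits by protein, resolves overlapping same-protein hits
#' greedily (ascending E-value; ties broken by higher bit score, then
#' smaller start; overlap means any shared residue), and computes the
#' unit-presence flags consumed by the Dicer gate and classifier.
#'
#' @param hits A (filtered) hit tibble.
#' @param protein_lengths A tibble with columns `protein_id` and
#'   `protein_length` (amino acids). Proteins listed here but absent from
#'   `hits` yield hit-less architectures (all flags `FALSE`).
#' @return A tibble with one row per protein: `protein_id`,
#'   `protein_length`, logical presence flags `has_dead`, `has_resiii`,
#'   `has_helic`, `has_duf283`, `has_paz`, `has_dsrbd`, the derived
#'   `has_helicase` (any helicase subdomain), `rnase3_count`, and a `hits`
#'   list-column with each protein's retained hits sorted by `start`.
#' @export
assemble_architectures <- function(hits, protein_lengths) {
  stopifnot(all(c("protein_id", "protein_length") %in% names(protein_lengths)))
  over <- dplyr::anti_join(
    dplyr::distinct(hits, .data$protein_id),
    protein_lengths, by = "protein_id"
  )
  if (nrow(over) > 0L) {
    stop("hits reference protein_id(s) missing from protein_lengths: ",
         paste(utils::head(over$protein_id, 5), collapse = ", "), call. = FALSE)
  }
  resolved <- hits |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(~ resolve_overlaps(.x)) |>
    dplyr::ungroup()

  if (nrow(resolved) > 0L) {
    bad_len <- resolved |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::summarise(max_end = max(.data$end), .groups = "drop") |>
      dplyr::inner_join(protein_lengths, by = "protein_id") |>
      dplyr::filter(.data$max_end > .data$protein_length)
    if (nrow(bad_len) > 0L) {
      stop("hit envelope(s) extend beyond protein_length for: ",
           paste(bad_len$protein_id, collapse = ", "), call. = FALSE)
    }
  }

  flags <- resolved |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      has_dead = any(.data$domain_label == "DEAD"),
      has_resiii = any(.data$domain_label == "ResIII"),
      has_helic = any(.data$domain_label == "HeliC"),
      has_duf283 = any(.data$domain_label == "DUF283"),
      has_paz = any(.data$domain_label == "PAZ"),
      has_dsrbd = any(.data$domain_label == "dsRBD"),
      rnase3_count = sum(.data$domain_label == "RNaseIII"),
      .groups = "drop"
    )
  nested <- resolved |>
    tidyr::nest(hits = -"protein_id")

  protein_lengths |>
    dplyr::select("protein_id", "protein_length") |>
    dplyr::left_join(flags, by = "protein_id") |>
    dplyr::left_join(nested, by = "protein_id") |>
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("has_"), ~ tidyr::replace_na(.x, FALSE)),
      rnase3_count = tidyr::replace_na(.data$rnase3_count, 0L),
      has_helicase = .data$has_dead | .data$has_resiii | .data$has_helic,
      hits = purrr::map(.data$hits, ~ .x %||% empty_hits()[-1])
    ) |>
    dplyr::relocate("has_helicase", .after = "has_helic")
}
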