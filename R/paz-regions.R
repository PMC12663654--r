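#' Extract canonical and inferred fungal PAZ regions
#'
#' For each gate-passing Dicer, returns the PAZ region used for downstream
#' alignment and profile building:
#'
#' * when a PAZ hit is present, the canonical PAZ (`cPAZ`) with the hit's
#'   envelope coordinates;
#' * otherwise, when both DUF283 and at least one RNase III hit are
#'   present, the inferred fungal PAZ (`fPAZ`) — the inter-domain region
#'   between the DUF283 envelope and the first (5'-most) RNase III
#'   envelope, i.e. `(DUF283.end + 1)` to `(RNaseIII.start - 1)`;
#' * nothing when neither applies or when the inter-domain span is empty
#'   (adjacent or overlapping anchors).
#'
#' @param arch Classified architecture tibble (see
#'   [classify_architectures()]); non-Dicer rows are ignored.
#' @return Tibble with `protein_id`, `kind` (`"cPAZ"` or `"fPAZ"`),
#'   `start`, `end` (1-based inclusive). At most one region per protein.
#' @export
extract_paz_regions <- function(arch) {
  dcrs <- if ("is_dcr" %in% names(arch)) {
    dplyr::filter(arch, .data$is_dcr)
  } else {
    arch
  }
  rows <- purrr::pmap(
    list(dcrs$protein_id, dcrs$hits),
    function(protein_id, hits) {
      if (is.null(hits) || nrow(hits) == 0L) return(NULL)
      paz <- hits[hits$domain_label == "PAZ", ]
      if (nrow(paz) > 0L) {
        paz <- paz[order(paz$evalue), ]
        return(tibble::tibble(protein_id = protein_id, kind = "cPAZ",
                              start = paz$start[1L], end = paz$end[1L]))
      }
      duf <- hits[hits$domain_label == "DUF283", ]
      r3 <- hits[hits$domain_label == "RNaseIII", ]
      if (nrow(duf) == 0L || nrow(r3) == 0L) return(NULL)
      s <- max(duf$end) + 1L
      e <- min(r3$start) - 1L
      if (s > e) {
        message("empty fPAZ span for ", protein_id, "; skipped")
        return(NULL)
      }
      tibble::tibble(protein_id = protein_id, kind = "fPAZ",
                     start = as.integer(s), end = as.integer(e))
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(protein_id = character(), kind = character(),
                          start = integer(), end = integer())
  }
  out
}

#' Write PAZ regions as FASTA
#'
#' Subsequences are cut from the full-length protein sequences at the
#' region coordinates; headers follow `>protein_id|kind|start-end` so a
#' round-trip parse recovers the coordinates.
#'
#' @param regions Region tibble from [extract_paz_regions()].
#' @param sequences Named character vector (or tibble with `protein_id`,
#'   `sequence`) of full-length protein sequences.
#' @param path Output FASTA path.
#' @return The written lines, invisibly.
#' @export
write_region_fasta <- function(regions, sequences, path) {
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$protein_id)
  }
  if (nrow(regions) == 0L) {
    writeLines(character(0), path)
    return(invisible(character(0)))
  }
  missing_seq <- setdiff(regions$protein_id, names(sequences))
  if (length(missing_seq) > 0L) {
    stop("no sequence for: ", paste(missing_seq, collapse = ", "), call. = FALSE)
  }
  seq_len_ok <- nchar(sequences[regions$protein_id]) >= regions$end
  if (!all(seq_len_ok)) {
    stop("region extends beyond sequence for: ",
         paste(regions$protein_id[!seq_len_ok], collapse = ", "), call. = FALSE)
  }
  lines <- purrr::pmap(regions, function(protein_id, kind, start, end, ...) {
    c(sprintf(">%s|%s|%d-%d", protein_id, kind, start, end),
      substr(sequences[[protein_id]], start, end))
  })
  lines <- unlist(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Parse a region FASTA written by [write_region_fasta()]
#'
#' @param path FASTA path.
#' @return Tibble with `protein_id`, `kind`, `start`, `end`, `sequence`.
#' @export
read_region_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble::tibble(protein_id = character(), kind = character(),
                          start = integer(), end = integer(),
                          sequence = character()))
  }
  hdr_idx <- grep("^>", lines)
  parts <- stringr::str_match(lines[hdr_idx],
                              "^>([^|]+)\\|([^|]+)\\|(\\d+)-(\\d+)$")
  seq_end <- c(hdr_idx[-1] - 1L, length(lines))
  seqs <- purrr::map2_chr(hdr_idx + 1L, seq_end,
                          ~ paste(lines[.x:.y], collapse = ""))
  tibble::tibble(
    protein_id = parts[, 2], kind = parts[, 3],
    start = as.integer(parts[, 4]), end = as.integer(parts[, 5]),
    sequence = seqs
  )
}
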