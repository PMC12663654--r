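#' Dicer domain vocabulary
#'
#' The seven conserved Dicer-associated domains used throughout the package,
#' together with the Pfam/InterPro accessions they are mapped from when
#' parsing HMMER output. `DEAD`, `ResIII` and `HeliC` are the three helicase
#' subdomains; `DUF283` is the Dicer dimerization domain; `PAZ` binds the
#' 3' overhang of the dsRNA substrate; `RNaseIII` is the catalytic domain
#' (two tandem copies form the cleavage dimer); `dsRBD` is the
#' double-stranded RNA-binding domain.
#'
#' @return A character vector of the seven domain labels.
#' @export
#' @examples
#' dcr_domains()
dcr_domains <- function() {
  c("DEAD", "ResIII", "HeliC", "DUF283", "PAZ", "RNaseIII", "dsRBD")
}

# Pfam and InterPro accessions -> domain label
.accession_map <- c(
  PF00270 = "DEAD",     IPR011545 = "DEAD",
  PF04851 = "ResIII",   IPR006935 = "ResIII",
  PF00271 = "HeliC",    IPR001650 = "HeliC",
  PF03368 = "DUF283",   IPR005034 = "DUF283",
  PF02170 = "PAZ",      IPR003100 = "PAZ",
  PF00636 = "RNaseIII", IPR000999 = "RNaseIII",
  PF00035 = "dsRBD",    IPR014720 = "dsRBD"
)

#' Map Pfam/InterPro accessions to domain labels
#'
#' Version suffixes (e.g. `PF00636.23`) are stripped before lookup. Labels
#' already in the vocabulary pass through unchanged; anything else maps to
#' `NA`.
#'
#' @param accession Character vector of accessions or domain labels.
#' @return Character vector of domain labels (`NA` where unknown).
#' @export
#' @examples
#' map_domain_accession(c("PF00636.23", "IPR003100", "PAZ", "PF99999"))
map_domain_accession <- function(accession) {
  acc <- sub("\\.\\d+$", "", accession)
  out <- unname(.accession_map[acc])
  passthrough <- is.na(out) & acc %in% dcr_domains()
  out[passthrough] <- acc[passthrough]
  out
}

#' Dicer architecture categories
#'
#' Category labels in display order: `canonical` plus the five non-canonical
#' groups `A`-`E` defined by which domain units are missing.
#'
#' @return Character vector of the six category labels.
#' @export
dcr_categories <- function() {
  c("canonical", "nonA", "nonB", "nonC", "nonD", "nonE")
}

# round half-up at `digits` decimals; base round() is round-half-even
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
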