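#' Read a structure model's alpha carbons
#'
#' Reads a PDB file (via bio3d) and returns the C-alpha trace of the first
#' chain, with the B-factor column interpreted as the per-residue pLDDT —
#' the convention used by AlphaFold-style model files. Multi-chain or
#' multi-model files are reduced to chain A / the first chain.
#'
#' @param path PDB file path.
#' @return Tibble with `residue` (residue number), `x`, `y`, `z`
#'   (Angstrom) and `plddt`.
#' @export
read_ca_model <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  chain <- if ("A" %in% atoms$chain) "A" else atoms$chain[1L]
  ca <- atoms[atoms$elety == "CA" & atoms$chain == chain, ]
  if (nrow(ca) == 0L) stop("no CA atoms in ", path, call. = FALSE)
  tibble::tibble(
    residue = as.integer(ca$resno),
    x = ca$x, y = ca$y, z = ca$z,
    plddt = ca$b
  )
}

#' Mean per-residue pLDDT of a model
#'
#' Arithmetic mean of the C-alpha B-factors; models are kept for the
#' structural network when this is `>= 70` (inclusive).
#'
#' @param model CA tibble from [read_ca_model()].
#' @return Mean pLDDT (0-100 scale).
#' @export
mean_plddt <- function(model) {
  if (nrow(model) == 0L) stop("empty model", call. = FALSE)
  mean(model$plddt)
}

#' PAZ-to-RNase IIIa molecular-ruler distance
#'
#' The Euclidean distance, in Angstroms, between the C-alpha of the first
#' (N-terminal) residue of the PAZ/fPAZ segment and the C-alpha of the
#' first residue of the RNase IIIa segment. This spacing acts as the
#' molecular ruler that sets small-RNA product length (about 50-55 A in
#' Dicer models).
#'
#' @param model CA tibble from [read_ca_model()].
#' @param paz_interval,rnase3a_interval Integer vectors `c(start, end)`
#'   (1-based residue numbers); only the start residue is used.
#' @return Distance in Angstrom.
#' @export
#' @examples
#' m <- tibble::tibble(residue = c(1, 50), x = c(0, 3), y = c(0, 4),
#'                     z = c(0, 0), plddt = 90)
#' ruler_distance(m, c(1, 10), c(50, 60))  # 5
ruler_distance <- function(model, paz_interval, rnase3a_interval) {
  a <- ca_coords(model, paz_interval[1L])
  b <- ca_coords(model, rnase3a_interval[1L])
  sqrt(sum((a - b)^2))
}

ca_coords <- function(model, residue) {
  row <- model[model$residue == residue, ]
  if (nrow(row) == 0L) {
    stop("no CA atom for residue ", residue, call. = FALSE)
  }
  c(row$x[1L], row$y[1L], row$z[1L])
}

#' Mean pLDDT per model file
#'
#' Convenience wrapper for filtering a set of model files before the
#' structural network: reads each file and reports its mean pLDDT and
#' whether it passes the inclusive `>= plddt_min` filter.
#'
#' @param paths Named character vector of PDB paths (names become model
#'   ids; unnamed paths use the base filename).
#' @param plddt_min Inclusive threshold, default 70.
#' @return Tibble with `id`, `plddt`, `pass`.
#' @export
score_models <- function(paths, plddt_min = 70) {
  ids <- names(paths) %||% tools::file_path_sans_ext(basename(paths))
  pl <- vapply(paths, function(p) mean_plddt(read_ca_model(p)), numeric(1))
  tibble::tibble(id = ids, plddt = unname(pl), pass = unname(pl) >= plddt_min)
}
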