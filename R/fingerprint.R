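#' Canonicalize a SMILES string
#'
#' Canonical SMILES via Open Babel; returns `NA` for unparseable input
#' (used by the dataset curation step to reject invalid molecules).
#'
#' @param smiles SMILES string
#' @return canonical SMILES, or `NA_character_` if not parseable
#' @export
canonicalSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    return(NA_character_)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  out <- sub("\t.*$", "", sub("\n$", "", out))
  out <- trimws(out)
  if (!nzchar(out)) NA_character_ else out
}

#' Circular (Morgan-type) molecule fingerprint
#'
#' Hashed extended-connectivity fingerprint of the canonicalized
#' structure, folded to a fixed bit length (default 1024 bits, circular
#' radius 2, i.e. ECFP4-equivalent). Equivalent SMILES spellings of the
#' same molecule give identical fingerprints.
#'
#' @param smiles SMILES string
#' @param nBits fingerprint length (bits)
#' @param radius circular radius (2 -> ECFP4, 3 -> ECFP6)
#' @return list with `bits` (integer 0/1 vector of length `nBits`),
#'   `radius`, `smiles_canonical`
#' @examples
#' fp <- moleculeFingerprint("CCO")
#' sum(fp$bits)
#' @export
moleculeFingerprint <- function(smiles, nBits = 1024L, radius = 2L) {
  can <- canonicalSmiles(smiles)
  if (is.na(can))
    stop("unparseable SMILES: ", smiles)
  fpName <- switch(as.character(radius), "1" = "ECFP2", "2" = "ECFP4",
                   "3" = "ECFP6", stop("unsupported radius"))
  raw <- ChemmineOB::forEachMol("SMILES", can, function(mol)
    ChemmineOB::fingerprint_OB(list(mol), fpName))[[1]]
  raw <- as.integer(raw)
  nBits <- as.integer(nBits)
  bits <- integer(nBits)
  on <- which(raw == 1L)
  if (length(on)) bits[unique((on - 1L) %% nBits) + 1L] <- 1L
  list(bits = bits, radius = as.integer(radius), smiles_canonical = can)
}
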