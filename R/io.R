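#' Read RNA sequences from a FASTA file
#'
#' DNA-style records are accepted; `T` is converted to `U`.
#'
#' @param path FASTA file
#' @param kind sequence kind assigned to every record
#' @return named list of [RnaSequence-class]
#' @export
readFastaRna <- function(path, kind = "mRNA") {
  set <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(set), function(q)
    rnaSequence(as.character(set[[q]]), id = names(set)[q], kind = kind))
  names(out) <- names(set)
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs list of [RnaSequence-class]
#' @param path output file
#' @export
writeFastaRna <- function(seqs, path) {
  set <- Biostrings::BStringSet(vapply(seqs, seqBases, character(1)))
  names(set) <- vapply(seqs, seqId, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read structures in dot-bracket text format
#'
#' The conventional two-line dialect: an optional `>id` header, a
#' sequence line, then a structure line with an optional trailing
#' `(energy)` suffix.
#'
#' @param path text file
#' @return list of [SecondaryStructure-class]
#' @export
readDotBracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  q <- 1L
  while (q <= length(lines)) {
    if (startsWith(lines[q], ">")) q <- q + 1L
    if (q + 1L > length(lines)) break
    seqLine <- trimws(lines[q])
    stLine <- trimws(lines[q + 1L])
    energy <- NA_real_
    m <- regmatches(stLine, regexec("^([.()]+)\\s*\\((\\s*-?[0-9.]+)\\)$",
                                    stLine))[[1]]
    if (length(m)) {
      energy <- as.numeric(m[3])
      stLine <- m[2]
    }
    out[[length(out) + 1L]] <- parseDotBracket(stLine, sequence = seqLine,
                                               energy = energy)
    q <- q + 2L
  }
  out
}

#' Write a structure in dot-bracket text format
#'
#' @param structure a [SecondaryStructure-class]
#' @param path output file
#' @param id header identifier
#' @export
writeDotBracket <- function(structure, path, id = "structure") {
  lines <- c(paste0(">", id))
  if (nzchar(structure@sequence)) lines <- c(lines, structure@sequence)
  st <- structure@dotBracket
  if (!is.na(structure@energy))
    st <- sprintf("%s (%.2f)", st, structure@energy)
  writeLines(c(lines, st), path)
  invisible(path)
}
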