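#' Read protein sequences from FASTA into a records tibble
#'
#' Headers may be UniProt-style (`>sp|ACC|NAME ... OS=Organism ...`) or bare.
#' The organism is taken from an `OS=` tag when present and the kingdom from a
#' `KD=` tag (as written by [write_protein_fasta()]); both default to missing.
#' Residues are uppercased and `*` stop characters stripped. Records whose
#' sequence contains letters outside the 20-residue alphabet plus X are kept
#' but flagged `BAD_ALPHABET` in the `flag` column.
#'
#' @param file path to a FASTA file, or a character scalar of FASTA text.
#' @return A tibble with columns `accession`, `organism`, `kingdom`,
#'   `sequence`, `description`, `flag`.
#' @export
read_protein_fasta <- function(file) {
  if (length(file) == 1 && (grepl("\n", file) || startsWith(file, ">"))) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(file, tmp)
    file <- tmp
  }
  set <- Biostrings::readBStringSet(file)
  if (length(set) == 0) {
    warning("empty FASTA input")
    return(tibble::tibble(accession = character(), organism = character(),
                          kingdom = character(), sequence = character(),
                          description = character(), flag = character()))
  }
  headers <- names(set)
  seqs <- gsub("*", "", toupper(as.character(set)), fixed = TRUE)
  parsed <- purrr::map(headers, parse_fasta_header)
  out <- dplyr::bind_rows(parsed)
  out$sequence <- unname(seqs)
  out$flag <- ifelse(grepl(AA_ALPHABET_RE, out$sequence), NA_character_, "BAD_ALPHABET")
  dplyr::relocate(out, "accession", "organism", "kingdom", "sequence",
                  "description", "flag")
}

parse_fasta_header <- function(header) {
  first <- sub("\\s.*$", "", header)
  rest <- sub("^\\S+\\s*", "", header)
  acc <- if (grepl("^(sp|tr)\\|[^|]+\\|", first)) {
    strsplit(first, "|", fixed = TRUE)[[1]][2]
  } else first
  os <- stringr::str_match(header, "OS=(.*?)(?:\\s+[A-Z]{2}=|$)")[, 2]
  kd <- stringr::str_match(header, "KD=(\\S+)")[, 2]
  kingdom <- if (!is.na(kd) && kd %in% c("Bacteria", "Archaea", "Eucarya")) kd else "unknown"
  tibble::tibble(accession = acc,
                 organism = if (is.na(os)) NA_character_ else trimws(os),
                 kingdom = kingdom,
                 description = rest)
}

#' Write a records tibble to FASTA
#'
#' Organism and kingdom are serialized as `OS=` / `KD=` header tags so that
#' [read_protein_fasta()] round-trips them.
#'
#' @param records records tibble.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_protein_fasta <- function(records, file) {
  records <- as_records(records)
  hdr <- paste0(
    records$accession,
    ifelse(nzchar(records$description %||% ""), paste0(" ", records$description), ""),
    ifelse(is.na(records$organism), "", paste0(" OS=", records$organism)),
    ifelse(records$kingdom %in% c("Bacteria", "Archaea", "Eucarya"),
           paste0(" KD=", records$kingdom), "")
  )
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(set, file, width = 60)
  invisible(file)
}

#' Read / write an aligned FASTA file
#'
#' @param file path to aligned FASTA (gap character `-`).
#' @return `read_msa`: a named character vector of equal-length rows.
#' @export
read_msa <- function(file) {
  set <- Biostrings::readBStringSet(file)
  msa <- stats::setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
  as_msa(msa)
}

#' @rdname read_msa
#' @param msa named character vector of aligned rows.
#' @export
write_msa <- function(msa, file) {
  msa <- as_msa(msa)
  set <- Biostrings::BStringSet(msa)
  Biostrings::writeXStringSet(set, file, width = 60)
  invisible(file)
}
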