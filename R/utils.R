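# Internal helpers shared across modules.

# The twenty standard residues; X is tolerated on input but never generated.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_ALPHABET_RE <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

# Clustal strong similarity groups; used both for the STRONG_SIMILAR column
# class and for the generator's within-group residue resampling.
STRONG_GROUPS <- list(
  c("S", "T", "A"),
  c("N", "E", "Q", "K"),
  c("N", "H", "Q", "K"),
  c("N", "D", "E", "Q"),
  c("Q", "H", "R", "K"),
  c("M", "I", "L", "V"),
  c("M", "I", "L", "F"),
  c("H", "Y"),
  c("F", "Y", "W")
)

.gh13_env <- new.env(parent = emptyenv())

# BLOSUM62 as shipped with Biostrings (includes X and *).
blosum62 <- function() {
  if (is.null(.gh13_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .gh13_env$BLOSUM62 <- e$BLOSUM62
  }
  .gh13_env$BLOSUM62
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste(x, collapse = "")

# Ungapped BLOSUM62 score of two equal-length character vectors.
window_score <- function(a, b) {
  B <- blosum62()
  sum(B[cbind(a, b)])
}

# Residues chemically similar to `res` (union of strong groups), excluding
# `res` itself; falls back to all other residues for group-less ones (C, G, P).
similar_residues <- function(res) {
  hits <- unlist(STRONG_GROUPS[vapply(STRONG_GROUPS, function(g) res %in% g, logical(1))])
  out <- setdiff(unique(hits), res)
  if (length(out) == 0) out <- setdiff(AA20, res)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Coerce the accepted record containers to a records tibble.
as_records <- function(records) {
  if (inherits(records, "data.frame")) {
    if (!all(c("accession", "sequence") %in% names(records))) {
      stopf("records must have at least 'accession' and 'sequence' columns")
    }
    rec <- tibble::as_tibble(records)
    if (is.null(rec[["organism"]])) rec$organism <- NA_character_
    if (is.null(rec[["kingdom"]])) rec$kingdom <- "unknown"
    if (is.null(rec[["description"]])) rec$description <- ""
    return(rec)
  }
  if (is.character(records)) {
    acc <- names(records) %||% paste0("SEQ", seq_along(records))
    return(tibble::tibble(accession = acc, organism = NA_character_,
                          kingdom = "unknown", sequence = unname(records),
                          description = ""))
  }
  stopf("unsupported records container: %s", paste(class(records), collapse = "/"))
}

# MSA container: named character vector of equal-length aligned strings.
as_msa <- function(msa) {
  if (inherits(msa, "data.frame")) {
    col <- intersect(c("aligned", "sequence"), names(msa))[1]
    if (is.na(col)) stopf("msa data frame needs an 'aligned' or 'sequence' column")
    msa <- stats::setNames(msa[[col]], msa$accession)
  }
  if (!is.character(msa)) stopf("msa must be a character vector or data frame")
  if (length(unique(nchar(msa))) > 1) stopf("alignment rows have unequal lengths")
  if (is.null(names(msa))) names(msa) <- paste0("SEQ", seq_along(msa))
  msa
}

msa_matrix <- function(msa) {
  msa <- as_msa(msa)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}
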