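#' Synthetic surrogate reference sequence
#'
#' A deterministic, fully synthetic 602-residue stand-in for a
#' cyclomaltodextrinase query sequence: the GH13_46 profile skeleton of the
#' bundled generator (signal peptide, N-domain, the eight conserved windows,
#' C-terminal tail) with zero mutation. It anchors CSR localisation and the
#' N-domain membership filter when no user reference is supplied. It is not a
#' database sequence.
#'
#' @return A one-row records tibble.
#' @seealso [csr_anchors()] for its window coordinates.
#' @export
#' @examples
#' nchar(gh13_reference()$sequence)
gh13_reference <- function() {
  if (is.null(.gh13_env$reference)) {
    skel <- build_profile_skeleton("GH13_46", 602L)
    .gh13_env$reference <- tibble::tibble(
      accession = "SYNREF01",
      organism = "Synthetica flavobacterii",
      kingdom = "Bacteria",
      sequence = skel$sequence,
      description = "synthetic surrogate cyclomaltodextrinase reference (GH13_46 profile)"
    )
  }
  .gh13_env$reference
}

# N-domain span of the bundled reference (1-based inclusive), i.e. the region
# the membership filter aligns candidate N-termini against.
reference_ndomain_range <- function() {
  c(SIGNAL_LENGTH + 1L, SIGNAL_LENGTH + NDOMAIN_LENGTH)
}

#' Conserved-window anchor table
#'
#' Reads an anchor table giving the eight window coordinates (name, start,
#' end; 1-based inclusive) on a reference sequence. The default is the table
#' shipped for the bundled synthetic reference; supply your own TSV to anchor
#' on a different reference.
#'
#' @param file path to a TSV with columns `name`, `start`, `end`; `NULL` for
#'   the shipped default.
#' @return A tibble with one row per window, ordered along the sequence.
#' @export
csr_anchors <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "synthetic_reference_anchors.tsv",
                        package = "gh13sub", mustWork = TRUE)
  }
  anchors <- readr::read_tsv(file, show_col_types = FALSE,
                             col_types = readr::cols(
                               name = readr::col_character(),
                               start = readr::col_integer(),
                               end = readr::col_integer()
                             ))
  if (!setequal(anchors$name, CSR_ORDER)) {
    stopf("anchor table must contain exactly the windows %s",
          paste(CSR_ORDER, collapse = ", "))
  }
  anchors[match(CSR_ORDER, anchors$name), ]
}
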