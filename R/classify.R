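#' Classify the fifth-region pentapeptide
#'
#' The pentapeptide in the fifth conserved region separates the classical
#' GH13 groupings: `Q-P-D-x-N` marks the oligo-1,6-glucosidase group,
#' `M-P-K-x-N` the neopullulanase group, and `M-P-D-x-N` the intermediary
#' group that contains GH13_36 and GH13_46. Patterns are tested in that
#' order; anything else is `OTHER`.
#'
#' @param penta character vector of 5-residue strings.
#' @return A factor with levels `OLIGO16_GROUP`, `NEOPUL_GROUP`,
#'   `INTERMEDIARY`, `OTHER`.
#' @export
#' @examples
#' classify_csr5(c("QPDLN", "MPKLN", "MPDLN", "APDLN"))
classify_csr5 <- function(penta) {
  if (any(nchar(penta) != 5, na.rm = TRUE)) stopf("fifth-region strings must have length 5")
  out <- dplyr::case_when(
    grepl("^QPD.N$", penta) ~ "OLIGO16_GROUP",
    grepl("^MPK.N$", penta) ~ "NEOPUL_GROUP",
    grepl("^MPD.N$", penta) ~ "INTERMEDIARY",
    TRUE ~ "OTHER"
  )
  factor(out, levels = c("OLIGO16_GROUP", "NEOPUL_GROUP", "INTERMEDIARY", "OTHER"))
}

#' Aromatic end of the second conserved region
#'
#' `TRUE` when in-window positions 7-9 read tyrosine, one of Gly/Ser/Pro,
#' tyrosine -- the Y-x-Y end diagnostic for the GH13_46 group.
#'
#' @param csr2 character vector of 9-residue strings.
#' @return Logical vector.
#' @export
csr2_aromatic_end <- function(csr2) {
  if (any(nchar(csr2) != 9, na.rm = TRUE)) stopf("second-region strings must have length 9")
  grepl("^.{6}Y[GSP]Y$", csr2)
}

#' Glutamate following the proton donor in the third conserved region
#'
#' `TRUE` when in-window position 6 (the residue after the catalytic proton
#' donor at position 5) is glutamate. Independent of triad validity: the
#' donor itself need not be glutamate for this flag.
#'
#' @param csr3 character vector of 8-residue strings.
#' @return Logical vector.
#' @export
csr3_glu_after_donor <- function(csr3) {
  if (any(nchar(csr3) != 8, na.rm = TRUE)) stopf("third-region strings must have length 8")
  substr(csr3, 6, 6) == "E"
}

#' Score the GH13_46 diagnostic signature
#'
#' Turns located windows into per-sequence feature flags and a subfamily
#' call. The four scored features are: intermediary fifth-region class
#' (`M-P-D-x-N`), the aromatic Y-x-Y end of region II, the glutamate after
#' the proton donor in region III, and the WW stretch. The GH13_46 call
#' requires a valid Asp/Glu/Asp triad, the intermediary fifth region, and at
#' least `min_score` of the four features -- the default 3 tolerates the
#' documented single-sequence FW variant of the WW stretch.
#'
#' @param csrs a `gh13_csrset` from [locate_csrs()].
#' @param min_score minimum feature score (of 4) for a GH13_46 call.
#' @return A tibble with one row per sequence: `csr5_class`,
#'   `csr2_aromatic_end`, `csr3_glu_after_donor`, `ww_motif`, `triad_valid`,
#'   `score` (0-4), `gh13_46_call`, and `missing_csr` for incomplete window
#'   sets (which are never called).
#' @export
classify_signatures <- function(csrs, min_score = 3) {
  wide <- csrs |>
    dplyr::select("accession", "complete", "window", "residues") |>
    tidyr::pivot_wider(names_from = "window", values_from = "residues")
  triad <- extract_triad(csrs) |>
    dplyr::select("accession", "triad_valid")
  out <- wide |>
    dplyr::left_join(triad, by = "accession") |>
    dplyr::mutate(
      missing_csr = !.data$complete,
      csr5_class = classify_csr5(ifelse(is.na(.data$CSR5), "XXXXX", .data$CSR5)),
      csr2_aromatic_end = !is.na(.data$CSR2) & csr2_aromatic_end(
        ifelse(is.na(.data$CSR2), strrep("X", 9), .data$CSR2)),
      csr3_glu_after_donor = !is.na(.data$CSR3) & csr3_glu_after_donor(
        ifelse(is.na(.data$CSR3), strrep("X", 8), .data$CSR3)),
      ww_motif = !is.na(.data$WW) & .data$WW == "WW",
      score = (.data$csr5_class == "INTERMEDIARY") + .data$csr2_aromatic_end +
        .data$csr3_glu_after_donor + .data$ww_motif,
      gh13_46_call = !.data$missing_csr &
        !is.na(.data$triad_valid) & .data$triad_valid &
        .data$csr5_class == "INTERMEDIARY" & .data$score >= min_score
    ) |>
    dplyr::select("accession", "csr5_class", "csr2_aromatic_end",
                  "csr3_glu_after_donor", "ww_motif", "triad_valid", "score",
                  "gh13_46_call", "missing_csr")
  out
}

#' @rdname classify_signatures
#' @export
gh13_46_verdict <- function(csrs, min_score = 3) {
  classify_signatures(csrs, min_score = min_score)
}
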