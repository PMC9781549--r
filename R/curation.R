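#' One representative sequence per species
#'
#' Keeps exactly one record per distinct organism string (after whitespace
#' normalization): the longest sequence, ties broken by the lexicographically
#' smallest accession. Records with a missing organism are never merged with
#' each other.
#'
#' @param records records tibble.
#' @return The input tibble with logical `kept` and a `reason` column
#'   (`DUPLICATE_SPECIES` or `NA`), in the input row order.
#' @export
dedupe_by_species <- function(records) {
  records <- as_records(records)
  org <- stringr::str_squish(dplyr::coalesce(records$organism, ""))
  key <- ifelse(org == "", paste0("\r__unknown__", seq_len(nrow(records))), org)
  out <- records |>
    dplyr::mutate(.row = dplyr::row_number(), .key = key,
                  .len = nchar(.data$sequence)) |>
    dplyr::group_by(.data$.key) |>
    dplyr::mutate(kept = dplyr::row_number() ==
                    order(-.data$.len, .data$accession)[1]) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::mutate(reason = ifelse(.data$kept, NA_character_, "DUPLICATE_SPECIES")) |>
    dplyr::select(-".row", -".key", -".len")
  out
}

#' Apply the three GH13 membership criteria
#'
#' A candidate is accepted when (i) its region upstream of the located CSR-VI
#' aligns locally (BLOSUM62, gap open 11 / extend 1) to the reference
#' N-domain with a score of at least `ndomain_ratio` times the reference
#' N-domain self-score; (ii) all seven CSRs are located with confidence at
#' or above the threshold (the WW stretch is a signature feature, not a
#' membership criterion); and (iii) the catalytic triad reads Asp/Glu/Asp.
#' The first failing criterion is reported.
#'
#' @param records records tibble.
#' @param reference one-row records tibble used for both the N-domain and the
#'   window templates.
#' @param templates window templates (default: built from `reference`).
#' @param ndomain_range 1-based inclusive span of the N-domain on the
#'   reference.
#' @param ndomain_ratio acceptance threshold as a fraction of the reference
#'   N-domain self-score.
#' @param slack,conf_threshold passed to [locate_csrs()].
#' @return A tibble with `accession`, `accepted`, `reason`
#'   (`NO_NDOMAIN`, `CSR_INCOMPLETE`, `TRIAD_BROKEN` or `NA`) and the
#'   N-domain score ratio. The located windows are attached as attribute
#'   `"csrs"`.
#' @export
apply_membership_filters <- function(records,
                                     reference = gh13_reference(),
                                     templates = build_csr_templates(reference),
                                     ndomain_range = reference_ndomain_range(),
                                     ndomain_ratio = 0.25,
                                     slack = 40,
                                     conf_threshold = 0.35) {
  records <- as_records(records)
  reference <- as_records(reference)
  if (nchar(reference$sequence[1]) < ndomain_range[2]) {
    stopf("reference sequence is shorter than its N-domain definition (%d-%d)",
          ndomain_range[1], ndomain_range[2])
  }
  ref_ndom <- substr(reference$sequence[1], ndomain_range[1], ndomain_range[2])
  B <- blosum62()
  self_score <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref_ndom), Biostrings::AAString(ref_ndom),
    type = "local", substitutionMatrix = B,
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)

  csrs <- locate_csrs(records, templates, slack = slack,
                      conf_threshold = conf_threshold)
  # membership criterion (ii) concerns the seven CSRs; the WW stretch is a
  # logo/signature feature, not a membership filter
  comp7 <- csrs |>
    dplyr::filter(.data$window != "WW") |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(complete = all(.data$confidence >= conf_threshold),
                     .groups = "drop")
  csr6 <- csrs |>
    dplyr::filter(.data$window == "CSR6") |>
    dplyr::select("accession", csr6_start = "start")
  info <- records |>
    dplyr::left_join(csr6, by = "accession") |>
    dplyr::left_join(comp7, by = "accession")

  pre <- substr(info$sequence, 1,
                pmax(0L, dplyr::coalesce(info$csr6_start,
                                         templates$start[1]) - 1L))
  scores <- rep(NA_real_, length(pre))
  nonempty <- nzchar(pre)
  if (any(nonempty)) {
    scores[nonempty] <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pre[nonempty]), Biostrings::AAString(ref_ndom),
      type = "local", substitutionMatrix = B,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  }
  ratio <- dplyr::coalesce(scores / self_score, 0)

  triad <- suppressWarnings(extract_triad(csrs)) |>
    dplyr::select("accession", "triad_valid")
  out <- info |>
    dplyr::left_join(triad, by = "accession") |>
    dplyr::mutate(
      ndom_score_ratio = ratio,
      reason = dplyr::case_when(
        ndom_score_ratio < ndomain_ratio ~ "NO_NDOMAIN",
        !.data$complete ~ "CSR_INCOMPLETE",
        !dplyr::coalesce(.data$triad_valid, FALSE) ~ "TRIAD_BROKEN",
        TRUE ~ NA_character_
      ),
      accepted = is.na(.data$reason)
    ) |>
    dplyr::select("accession", "accepted", "reason", "ndom_score_ratio")
  attr(out, "csrs") <- csrs
  out
}

#' Curate a candidate sequence set
#'
#' Full curation pass in the order: alphabet check (non-standard letters),
#' one-per-species deduplication, then the three membership criteria of
#' [apply_membership_filters()]. Every input record ends up accepted or
#' rejected with a single (first-failing) reason.
#'
#' @inheritParams apply_membership_filters
#' @param ... passed to [apply_membership_filters()].
#' @return The records tibble with `status` (`"accepted"`/`"rejected"`) and
#'   `reason` columns; class `gh13_curation`.
#' @export
curate_sequences <- function(records, reference = gh13_reference(), ...) {
  records <- as_records(records)
  if (nrow(records) == 0) stopf("no input records")
  flag <- records[["flag"]] %||% ifelse(grepl(AA_ALPHABET_RE, records$sequence),
                                        NA_character_, "BAD_ALPHABET")
  reason <- ifelse(!grepl(AA_ALPHABET_RE, records$sequence) |
                     !is.na(flag) & flag == "BAD_ALPHABET",
                   "BAD_ALPHABET", NA_character_)
  ok <- is.na(reason)
  if (any(ok)) {
    dd <- dedupe_by_species(records[ok, , drop = FALSE])
    reason[ok][!dd$kept] <- "DUPLICATE_SPECIES"
    ok <- is.na(reason)
  }
  if (any(ok)) {
    mf <- apply_membership_filters(records[ok, , drop = FALSE],
                                   reference = reference, ...)
    reason[ok] <- mf$reason[match(records$accession[ok], mf$accession)]
  }
  out <- records |>
    dplyr::mutate(reason = reason,
                  status = ifelse(is.na(reason), "accepted", "rejected"))
  class(out) <- c("gh13_curation", class(out))
  out
}

#' Summarise a curation result
#'
#' @param curation result of [curate_sequences()].
#' @return A tibble of counts per outcome (accepted plus each rejection
#'   reason).
#' @export
curation_summary <- function(curation) {
  curation |>
    tibble::as_tibble() |>
    dplyr::count(outcome = dplyr::coalesce(.data$reason, "accepted"),
                 name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Sequence length statistics
#'
#' Lengths of the stored sequences (signal peptides included as stored).
#'
#' @param records records tibble.
#' @return A one-row tibble with `n`, `min`, `max`, `mean`.
#' @export
length_stats <- function(records) {
  records <- as_records(records)
  if (nrow(records) == 0) stopf("length_stats on an empty record set")
  len <- nchar(records$sequence)
  tibble::tibble(n = length(len), min = min(len), max = max(len),
                 mean = mean(len))
}
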