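#' Build conserved-window templates from a reference sequence
#'
#' Extracts the eight window strings (seven CSRs plus the WW stretch) from a
#' reference sequence at the anchor coordinates and records the inter-window
#' spacing used to project window positions onto candidate sequences.
#'
#' @param reference one-row records tibble (default: the bundled synthetic
#'   surrogate reference).
#' @param anchors anchor tibble from [csr_anchors()].
#' @return A template tibble with columns `name`, `start`, `end`, `length`,
#'   `window`, `gap_before` (residues between the previous window and this
#'   one), and `self_score` (ungapped BLOSUM62 score of the window against
#'   itself).
#' @export
build_csr_templates <- function(reference = gh13_reference(),
                                anchors = csr_anchors()) {
  reference <- as_records(reference)
  if (nrow(reference) != 1) stopf("reference must be a single record")
  anchors <- anchors[match(CSR_ORDER, anchors$name), ]
  if (anyNA(anchors$start)) stopf("anchor table is missing windows")
  len <- anchors$end - anchors$start + 1L
  if (!all(len == unname(CSR_LENGTHS[anchors$name]))) {
    stopf("anchor window lengths must be (%s)",
          paste(CSR_LENGTHS[CSR_ORDER], collapse = ", "))
  }
  if (any(diff(anchors$start) <= 0) ||
      any(anchors$start[-1] <= anchors$end[-nrow(anchors)])) {
    stopf("anchor windows must be ordered and non-overlapping (CSR-VI, I, V, WW, II, III, IV, VII)")
  }
  if (max(anchors$end) > nchar(reference$sequence)) {
    stopf("reference sequence (%d aa) shorter than its anchor table",
          nchar(reference$sequence))
  }
  win <- substring(reference$sequence, anchors$start, anchors$end)
  self <- vapply(win, function(w) {
    ch <- seq_chars(w)
    window_score(ch, ch)
  }, numeric(1))
  tibble::tibble(
    name = anchors$name,
    start = anchors$start,
    end = anchors$end,
    length = len,
    window = unname(win),
    gap_before = anchors$start - c(0L, anchors$end[-nrow(anchors)]) - 1L,
    self_score = unname(self)
  )
}

#' Locate the conserved windows in candidate sequences
#'
#' For each template in barrel order, the best-scoring ungapped window
#' (BLOSUM62 sum against the reference window) is selected within a slack
#' band around the position projected from the previous window and the
#' reference inter-window spacing. Located windows never overlap and keep
#' their order; equal-scoring windows resolve to the start closest to the
#' projected position, then the smallest. Confidence is the window score
#' divided by the template self-score; a sequence is `complete` when all
#' eight windows reach the confidence threshold.
#'
#' @param records records tibble (or named character vector of sequences).
#' @param templates template tibble from [build_csr_templates()].
#' @param slack search slack (residues) around the projected start.
#' @param conf_threshold minimum confidence for a window to count as found.
#' @return A tibble of class `gh13_csrset`: one row per sequence and window
#'   with `accession`, `window`, `start`, `end`, `residues`, `score`,
#'   `confidence` and the per-sequence `complete` flag. Coordinates are
#'   1-based inclusive.
#' @export
locate_csrs <- function(records, templates = build_csr_templates(),
                        slack = 40, conf_threshold = 0.35) {
  records <- as_records(records)
  B <- blosum62()
  tpl_chars <- lapply(templates$window, seq_chars)
  ww_i <- which(templates$name == "WW")

  scan_window <- function(chars, i, lo, hi, proj) {
    # best ungapped BLOSUM62 window for template i in start range [lo, hi];
    # ties go to the start closest to the projected position, then smallest
    len <- templates$length[i]
    L <- length(chars)
    lo <- max(lo, 1L)
    hi <- min(hi, L - len + 1L)
    if (lo > hi) {
      return(tibble::tibble(window = templates$name[i],
                            start = NA_integer_, end = NA_integer_,
                            residues = NA_character_, score = NA_real_,
                            confidence = 0))
    }
    starts <- lo:hi
    sc <- numeric(length(starts))
    tc <- tpl_chars[[i]]
    for (j in seq_len(len)) {
      sc <- sc + B[cbind(tc[j], chars[starts + j - 1L])]
    }
    tied <- starts[sc == max(sc)]
    best <- tied[order(abs(tied - proj), tied)][1]
    tibble::tibble(
      window = templates$name[i],
      start = best, end = best + len - 1L,
      residues = chars_to_seq(chars[best:(best + len - 1L)]),
      score = max(sc),
      confidence = max(sc) / templates$self_score[i]
    )
  }

  rows <- purrr::map(seq_len(nrow(records)), function(r) {
    chars <- seq_chars(records$sequence[r])
    out <- vector("list", nrow(templates))
    # chain pass over the seven CSRs; the WW stretch does not anchor the
    # chain (it is located afterwards inside the CSR-V .. CSR-II gap)
    prev_end <- 0L
    for (i in setdiff(seq_len(nrow(templates)), ww_i)) {
      gap <- templates$gap_before[i] +
        if (i - 1L == ww_i) templates$gap_before[ww_i] + templates$length[ww_i] else 0L
      proj <- prev_end + gap + 1L
      out[[i]] <- scan_window(chars, i, max(prev_end + 1L, proj - slack),
                              proj + slack, proj)
      prev_end <- if (is.na(out[[i]]$start)) proj + templates$length[i] - 1L
                  else out[[i]]$end
    }
    lo <- out[[ww_i - 1L]]$end
    hi <- out[[ww_i + 1L]]$start
    if (is.na(lo)) lo <- 0L
    if (is.na(hi)) hi <- length(chars) + 1L
    out[[ww_i]] <- scan_window(chars, ww_i, lo + 1L,
                               hi - templates$length[ww_i],
                               lo + templates$gap_before[ww_i] + 1L)
    res <- dplyr::bind_rows(out)
    res$accession <- records$accession[r]
    res$complete <- all(res$confidence >= conf_threshold)
    res
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::relocate("accession")
  class(out) <- c("gh13_csrset", class(out))
  attr(out, "templates") <- templates
  attr(out, "conf_threshold") <- conf_threshold
  out
}

#' Extract the catalytic triad from located windows
#'
#' Reads the catalytic nucleophile (CSR-II position 5), proton donor
#' (CSR-III position 5) and transition-state stabilizer (CSR-IV position 6)
#' from a located window set. The triad is valid when the residues are
#' exactly Asp, Glu, Asp. Sequences for which any of the three windows could
#' not be located get `NA` with a warning.
#'
#' @param csrs a `gh13_csrset` from [locate_csrs()].
#' @return A tibble with one row per sequence: residues, absolute 1-based
#'   positions, and `triad_valid`.
#' @export
extract_triad <- function(csrs) {
  wide <- csrs |>
    dplyr::filter(.data$window %in% c("CSR2", "CSR3", "CSR4")) |>
    dplyr::select("accession", "window", "start", "residues") |>
    tidyr::pivot_wider(names_from = "window",
                       values_from = c("start", "residues"))
  located <- !is.na(wide$residues_CSR2) & !is.na(wide$residues_CSR3) &
    !is.na(wide$residues_CSR4)
  if (any(!located)) {
    warning("unlocated triad windows: triad reported as NA for ",
            sum(!located), " sequence(s)")
  }
  pick <- function(res, off) ifelse(is.na(res), NA_character_, substr(res, off, off))
  out <- tibble::tibble(
    accession = wide$accession,
    nucleophile = pick(wide$residues_CSR2, 5L),
    nucleophile_pos = wide$start_CSR2 + 4L,
    proton_donor = pick(wide$residues_CSR3, 5L),
    proton_donor_pos = wide$start_CSR3 + 4L,
    stabilizer = pick(wide$residues_CSR4, 6L),
    stabilizer_pos = wide$start_CSR4 + 5L,
    triad_valid = pick(wide$residues_CSR2, 5L) == "D" &
      pick(wide$residues_CSR3, 5L) == "E" &
      pick(wide$residues_CSR4, 6L) == "D"
  )
  out$triad_valid[!located] <- NA
  out
}

#' Concatenate located windows into the 54-position logo string
#'
#' Windows are concatenated in barrel order (CSR-VI, I, V, WW, II, III, IV,
#' VII), giving the 54-character string used for the subfamily sequence logo;
#' positions 16-20 hold the fifth-region pentapeptide and positions 27, 36
#' and 45 the catalytic triad.
#'
#' @param csrs a `gh13_csrset` from [locate_csrs()].
#' @return A tibble with `accession` and `logo` (NA for incomplete sets, with
#'   a warning).
#' @export
concat_logo_string <- function(csrs) {
  out <- csrs |>
    dplyr::mutate(window = factor(.data$window, levels = CSR_ORDER)) |>
    dplyr::arrange(.data$accession, .data$window) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      logo = if (any(is.na(.data$residues)) || !all(.data$complete)) NA_character_
             else paste(.data$residues, collapse = ""),
      .groups = "drop"
    )
  if (anyNA(out$logo)) {
    warning("incomplete CSR sets: logo string NA for ", sum(is.na(out$logo)),
            " sequence(s)")
  }
  out
}
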