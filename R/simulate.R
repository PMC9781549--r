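#' Generate a labelled synthetic GH13-like sequence set
#'
#' Emits protein sequences with the architecture the downstream analysis
#' assumes: an N-terminal signal peptide, an immunoglobulin-like N-domain,
#' the eight ordered conserved windows (CSR-VI, I, V, WW, II, III, IV, VII)
#' embedded in variable linkers, an Asp/Glu/Asp catalytic triad, and a
#' C-terminal tail filling the sequence to its sampled length. Sequences of
#' one profile are mutated copies of a fixed profile skeleton, so sets behave
#' like a star phylogeny around the subfamily consensus.
#'
#' Subfamily-diagnostic window positions (the MPDxN/QPDxN/MPKxN anchor of the
#' fifth region, the WW pair, the terminal tyrosines of region II, the
#' glutamate after the proton donor, and the triad itself) are invariant in
#' the profile; `csr_mutation_rate` resamples only the remaining window
#' positions, within the consensus residue's Clustal strong group. Linker,
#' N-domain, signal and tail positions mutate to a uniformly drawn different
#' residue at `linker_mutation_rate`. Deliberate defects are introduced with
#' `corruption`, applied to the first `corruption_n` records.
#'
#' @param n_sequences number of sequences to generate.
#' @param profile one of `"GH13_46"`, `"OLIGO16"`, `"NEOPUL"`, `"RANDOM"`.
#' @param csr_mutation_rate per-site resampling probability inside the
#'   conserved windows (diagnostic positions exempt).
#' @param linker_mutation_rate per-site substitution probability outside the
#'   conserved windows.
#' @param length_range integer vector `c(min, max)` of total sequence lengths,
#'   sampled uniformly per sequence (defaults to the 588-616 residue span of
#'   the subfamily the package models).
#' @param include_ndomain,include_signal_peptide include the N-terminal
#'   domain / signal peptide in the emitted sequences.
#' @param corruption character vector of deliberate defects:
#'   `"BREAK_TRIAD"` (proton donor Glu -> Gln), `"WW_TO_FW"` (first Trp of the
#'   WW stretch -> Phe), `"DROP_NDOMAIN"` (delete signal peptide + N-domain),
#'   or `"DROP_CSR:<name>"` (delete that window's residues).
#' @param corruption_n apply the corruption to the first `corruption_n`
#'   records only (default: all).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param accession_prefix prefix for the generated accessions.
#'
#' @return A list of class `gh13_sim` with elements `records` (a tibble with
#'   columns `accession`, `organism`, `kingdom`, `sequence`, `description`)
#'   and `truth` (a tibble with the generating label, triad status, applied
#'   corruptions, and 1-based inclusive window coordinates, `NA` for deleted
#'   windows).
#' @export
#' @examples
#' sim <- simulate_gh13_set(5, seed = 1)
#' sim$truth
simulate_gh13_set <- function(n_sequences = 108,
                              profile = c("GH13_46", "OLIGO16", "NEOPUL", "RANDOM"),
                              csr_mutation_rate = 0.03,
                              linker_mutation_rate = 0.10,
                              length_range = c(588L, 616L),
                              include_ndomain = TRUE,
                              include_signal_peptide = TRUE,
                              corruption = character(),
                              corruption_n = Inf,
                              seed = 1L,
                              accession_prefix = "SYN") {
  profile <- match.arg(profile)
  stopifnot(n_sequences >= 1, length(length_range) == 2,
            length_range[1] <= length_range[2],
            csr_mutation_rate >= 0, csr_mutation_rate <= 1,
            linker_mutation_rate >= 0, linker_mutation_rate <= 1)
  corruption <- unique(corruption)
  dropped <- sub("^DROP_CSR:", "", grep("^DROP_CSR:", corruption, value = TRUE))
  bad <- setdiff(corruption,
                 c("BREAK_TRIAD", "WW_TO_FW", "DROP_NDOMAIN",
                   paste0("DROP_CSR:", CSR_ORDER)))
  if (length(bad)) stopf("unknown corruption(s): %s", paste(bad, collapse = ", "))
  if ("BREAK_TRIAD" %in% corruption &&
      any(dropped %in% c("CSR2", "CSR3", "CSR4"))) {
    stopf("contradictory corruption: BREAK_TRIAD targets a window dropped by DROP_CSR")
  }
  if ("DROP_NDOMAIN" %in% corruption && !include_ndomain) {
    stopf("contradictory corruption: DROP_NDOMAIN with include_ndomain = FALSE")
  }

  skel <- build_profile_skeleton(profile, max(length_range),
                                 include_ndomain = include_ndomain,
                                 include_signal_peptide = include_signal_peptide)
  skel_chars <- seq_chars(skel$sequence)
  win <- skel$windows
  win_pos <- unlist(Map(seq.int, win$start, win$end))
  # window-site metadata for csr mutation
  site_tab <- do.call(rbind, lapply(seq_len(nrow(win)), function(i) {
    w <- win$name[i]
    off <- seq_len(CSR_LENGTHS[[w]])
    data.frame(window = w, offset = off, pos = win$start[i] + off - 1L,
               stringsAsFactors = FALSE)
  }))
  inv <- skel$invariant
  site_tab$invariant <- mapply(function(w, o) o %in% (inv[[w]] %||% integer(0)),
                               site_tab$window, site_tab$offset)
  mutable_sites <- site_tab[!site_tab$invariant, , drop = FALSE]

  records <- vector("list", n_sequences)
  truth <- vector("list", n_sequences)

  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_sequences)) {
      total <- if (length_range[1] == length_range[2]) length_range[1] else
        sample(seq.int(length_range[1], length_range[2]), 1)
      chars <- skel_chars[seq_len(total)]
      coords <- stats::setNames(win$start, win$name)

      # linker / background mutation
      linker_idx <- setdiff(seq_len(total), win_pos)
      hit <- linker_idx[stats::runif(length(linker_idx)) < linker_mutation_rate]
      if (length(hit)) {
        chars[hit] <- vapply(chars[hit], function(r) sample(setdiff(AA20, r), 1),
                             character(1))
      }

      # window mutation: resample non-diagnostic sites within the consensus
      # residue's similarity group (or the site's restricted alphabet)
      hit <- mutable_sites[stats::runif(nrow(mutable_sites)) < csr_mutation_rate, ,
                           drop = FALSE]
      for (j in seq_len(nrow(hit))) {
        w <- hit$window[j]; p <- hit$pos[j]
        allowed <- skel$site_sets[[w]][[as.character(hit$offset[j])]]
        cons_res <- substr(skel$consensus[[w]], hit$offset[j], hit$offset[j])
        if (is.null(allowed)) allowed <- similar_residues(cons_res)
        allowed <- setdiff(allowed, chars[p])
        if (length(allowed)) chars[p] <- sample(allowed, 1)
      }

      corrupted <- if (i <= corruption_n) corruption else character(0)
      triad_ok <- TRUE
      if ("BREAK_TRIAD" %in% corrupted) {
        chars[coords[["CSR3"]] + 4L] <- "Q"
        triad_ok <- FALSE
      }
      if ("WW_TO_FW" %in% corrupted) chars[coords[["WW"]]] <- "F"

      ends <- coords + CSR_LENGTHS[CSR_ORDER] - 1L
      # deletions last; shift downstream coordinates
      drop_spans <- list()
      for (w in corrupted_window_names(corrupted)) {
        drop_spans[[w]] <- c(coords[[w]], ends[[w]])
      }
      if ("DROP_NDOMAIN" %in% corrupted) {
        drop_spans[["__NDOM__"]] <- c(1L, skel$ndomain[2])
      }
      if (length(drop_spans)) {
        del <- unlist(lapply(drop_spans, function(s) seq.int(s[1], s[2])))
        keep <- setdiff(seq_along(chars), del)
        shift <- function(p) {
          vapply(p, function(q) {
            if (is.na(q) || q %in% del) NA_integer_ else q - sum(del < q)
          }, integer(1))
        }
        coords <- shift(coords)
        ends <- shift(ends)
        for (w in names(drop_spans)) {
          if (w %in% names(coords)) { coords[[w]] <- NA_integer_; ends[[w]] <- NA_integer_ }
        }
        chars <- chars[keep]
      }

      acc <- sprintf("%s%05d", accession_prefix, i)
      records[[i]] <- tibble::tibble(
        accession = acc,
        organism = sprintf("Synthetica sp. %s-%05d", accession_prefix, i),
        kingdom = "Bacteria",
        sequence = chars_to_seq(chars),
        description = sprintf("synthetic %s-profile GH13-like protein", profile)
      )
      tr <- tibble::tibble(accession = acc, label = profile, triad_ok = triad_ok,
                           corrupted = paste(corrupted, collapse = ";"))
      for (w in CSR_ORDER) {
        tr[[paste0(tolower(w), "_start")]] <- coords[[w]]
        tr[[paste0(tolower(w), "_end")]] <- ends[[w]]
      }
      truth[[i]] <- tr
    }
  })

  out <- list(records = dplyr::bind_rows(records), truth = dplyr::bind_rows(truth))
  class(out) <- c("gh13_sim", class(out))
  out
}

# which window names a corruption vector drops
corrupted_window_names <- function(corrupted) {
  sub("^DROP_CSR:", "", grep("^DROP_CSR:", corrupted, value = TRUE))
}

#' Generate a mixture of subfamily profiles with truth labels
#'
#' Convenience wrapper around [simulate_gh13_set()] producing one labelled
#' set per profile, with unique accessions.
#'
#' @param n_per_profile sequences per profile.
#' @param profiles profiles to include.
#' @param seed integer seed (each profile derives its own stream from it).
#' @param ... passed on to [simulate_gh13_set()].
#' @return A `gh13_sim` list with combined `records` and `truth`.
#' @export
simulate_gh13_mixture <- function(n_per_profile = 30,
                                  profiles = c("GH13_46", "OLIGO16", "NEOPUL", "RANDOM"),
                                  seed = 1L, ...) {
  tags <- c(GH13_46 = "SYNA", OLIGO16 = "SYNB", NEOPUL = "SYNC", RANDOM = "SYND")
  sims <- purrr::imap(stats::setNames(profiles, profiles), function(p, nm) {
    simulate_gh13_set(n_sequences = n_per_profile, profile = p,
                      seed = as.integer(seed) + match(p, SIM_PROFILES),
                      accession_prefix = tags[[p]] %||% paste0("SYN", p), ...)
  })
  out <- list(records = dplyr::bind_rows(purrr::map(sims, "records")),
              truth = dplyr::bind_rows(purrr::map(sims, "truth")))
  class(out) <- c("gh13_sim", class(out))
  out
}

#' Write / read a generator truth table
#'
#' Plain TSV serialization of the `truth` tibble emitted by
#' [simulate_gh13_set()]; `read_truth(write_truth(x))` round-trips.
#'
#' @param truth truth tibble.
#' @param file path to write to / read from.
#' @return `write_truth` returns `file` invisibly; `read_truth` a tibble.
#' @export
write_truth <- function(truth, file) {
  readr::write_tsv(truth, file)
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  readr::read_tsv(file, show_col_types = FALSE,
                  col_types = readr::cols(
                    accession = readr::col_character(),
                    label = readr::col_character(),
                    triad_ok = readr::col_logical(),
                    corrupted = readr::col_character(),
                    .default = readr::col_integer()
                  )) |>
    dplyr::mutate(corrupted = dplyr::coalesce(.data$corrupted, ""))
}
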