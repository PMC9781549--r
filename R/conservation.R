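#' Per-column conservation profile of an alignment
#'
#' Classifies every alignment column and computes residue frequencies and
#' information content. A gap-free column with a single residue is
#' `IDENTICAL`; gap-free with all residues inside one Clustal strong
#' similarity group (STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW) is
#' `STRONG_SIMILAR`; any column containing a gap is `GAPPED`; the rest are
#' `OTHER`. Percent identity/similarity are the respective column counts
#' over the consensus length (the number of alignment columns). Information
#' content per column is `log2(20) - H` with `H` the Shannon entropy of the
#' observed residue frequencies (no pseudocounts or small-sample
#' correction); frequencies are over non-gap standard residues.
#'
#' @param msa named character vector of aligned rows (gap `-`), or a data
#'   frame with `accession` and `aligned` columns.
#' @return An object of class `gh13_profile`; see [tidy.gh13_profile()] for
#'   the per-column tibble and [glance.gh13_profile()] for the summary row.
#' @export
profile_from_msa <- function(msa) {
  m <- msa_matrix(msa)
  new_profile(m, allow_gaps = TRUE)
}

#' Position-frequency and information-content matrix of motif strings
#'
#' Same statistics as [profile_from_msa()] for ungapped equal-length strings
#' (e.g. the 54-character concatenated window strings used for the subfamily
#' logo).
#'
#' @param strings character vector (or tibble with a `logo` column) of
#'   equal-length, gap-free residue strings.
#' @return A `gh13_profile` object.
#' @export
logo_matrix <- function(strings) {
  if (inherits(strings, "data.frame")) {
    strings <- stats::setNames(strings$logo, strings$accession)
  }
  strings <- strings[!is.na(strings)]
  if (length(strings) == 0) stopf("no logo strings")
  if (length(unique(nchar(strings))) > 1) stopf("logo strings have unequal lengths")
  if (any(grepl("-", strings, fixed = TRUE))) stopf("logo strings must be gap-free")
  m <- msa_matrix(strings)
  new_profile(m, allow_gaps = FALSE)
}

new_profile <- function(m, allow_gaps) {
  n <- nrow(m)
  L <- ncol(m)
  gap <- m == "-"
  freq <- matrix(0, nrow = L, ncol = length(AA20),
                 dimnames = list(NULL, AA20))
  ic <- numeric(L)
  class_v <- character(L)
  top_res <- character(L)
  top_freq <- numeric(L)
  for (j in seq_len(L)) {
    col <- m[!gap[, j], j]
    col20 <- col[col %in% AA20]
    if (length(col20)) {
      f <- tabulate(factor(col20, levels = AA20), nbins = length(AA20))
      p <- f / sum(f)
      freq[j, ] <- p
      h <- -sum(p[p > 0] * log2(p[p > 0]))
      ic[j] <- log2(20) - h
      top_res[j] <- AA20[which.max(p)]
      top_freq[j] <- max(p)
    } else {
      ic[j] <- NA_real_
      top_res[j] <- NA_character_
      top_freq[j] <- NA_real_
    }
    u <- unique(col)
    class_v[j] <- if (any(gap[, j])) "GAPPED"
      else if (length(u) == 1) "IDENTICAL"
      else if (any(vapply(STRONG_GROUPS, function(g) all(u %in% g), logical(1))))
        "STRONG_SIMILAR"
      else "OTHER"
  }
  n_ident <- sum(class_v == "IDENTICAL")
  n_sim <- sum(class_v == "STRONG_SIMILAR")
  out <- list(
    n_sequences = n,
    n_columns = L,
    columns = tibble::tibble(
      position = seq_len(L),
      class = factor(class_v,
                     levels = c("IDENTICAL", "STRONG_SIMILAR", "OTHER", "GAPPED")),
      ic = ic,
      top_residue = top_res,
      top_freq = top_freq,
      gap_frac = colMeans(gap)
    ),
    freq = freq,
    pct_identity = 100 * n_ident / L,
    pct_similarity = 100 * (n_ident + n_sim) / L
  )
  class(out) <- "gh13_profile"
  out
}

#' @export
print.gh13_profile <- function(x, ...) {
  cat(sprintf(
    "<gh13_profile> %d sequences x %d columns | identity %.2f%% | similarity %.2f%%\n",
    x$n_sequences, x$n_columns, x$pct_identity, x$pct_similarity))
  invisible(x)
}

#' Tidy / summarise a conservation profile
#'
#' `tidy()` returns the per-column statistics (position, class, information
#' content in bits, modal residue and its frequency, gap fraction);
#' `glance()` a one-row summary with the consensus length and the percent
#' identical / strongly-similar columns.
#'
#' @param x a `gh13_profile`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.gh13_profile <- function(x, ...) x$columns

#' @rdname tidy.gh13_profile
#' @export
glance.gh13_profile <- function(x, ...) {
  tibble::tibble(n_sequences = x$n_sequences, n_columns = x$n_columns,
                 pct_identity = x$pct_identity, pct_similarity = x$pct_similarity,
                 mean_ic = mean(x$columns$ic, na.rm = TRUE))
}

#' Plot a conservation profile
#'
#' Information content per column, coloured by column class -- a numeric
#' stand-in for a sequence logo.
#'
#' @param object a `gh13_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gh13_profile <- function(object, ...) {
  dat <- object$columns
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$ic,
                                    fill = .data$class)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = c(
      IDENTICAL = "#1b9e77", STRONG_SIMILAR = "#7570b3",
      OTHER = "grey60", GAPPED = "grey85"), drop = FALSE) +
    ggplot2::labs(x = "alignment position", y = "information content (bits)",
                  fill = "column class") +
    ggplot2::theme_minimal()
}

#' Count sequences whose window equals a motif
#'
#' @param csrs a `gh13_csrset` from [locate_csrs()].
#' @param window_name one of the eight window names (e.g. `"WW"`, `"CSR5"`).
#' @param motif exact residue string to count.
#' @return Integer count.
#' @export
count_motif <- function(csrs, window_name, motif) {
  if (!window_name %in% CSR_ORDER) {
    stopf("unknown window '%s' (expected one of %s)", window_name,
          paste(CSR_ORDER, collapse = ", "))
  }
  if (nrow(csrs) == 0) return(0L)
  sum(csrs$residues[csrs$window == window_name] == motif, na.rm = TRUE)
}

#' Pairwise percent identity over mutually ungapped columns
#'
#' @param msa named character vector of aligned rows.
#' @return A symmetric matrix of percent identities (diagonal 100); pairs
#'   with no overlapping non-gap columns are `NA`.
#' @export
pairwise_identity <- function(msa) {
  m <- msa_matrix(msa)
  m[m == "-"] <- NA
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      out[i, j] <- out[j, i] <-
        if (!any(ok)) NA_real_ else 100 * mean(m[i, ok] == m[j, ok])
    }
  }
  out
}
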