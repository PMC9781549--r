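#' Multiple sequence alignment
#'
#' `align_sequences()` aligns a record set either with the bundled
#' deterministic center-star aligner (default; no external software) or by
#' shelling out to an external progressive aligner such as `mafft`
#' (`method = "external"`).
#'
#' When every sequence carries a located set of the seven CSRs (see
#' [locate_csrs()]), the bundled aligner anchors on them: CSR columns are
#' aligned residue-to-residue across the whole set and the inter-window
#' segments (including the N-terminal region and C-terminal tail) are
#' left-justified and padded to the widest segment -- the same
#' window-pinning idea used when curating family-wide GH13 alignments by
#' hand. When windows cannot be located for every sequence it falls back to
#' a center-star: the center is picked by shared 4-mer counts, every other
#' sequence is globally aligned to it (BLOSUM62, gap opening 15 /
#' extension 2), and the pairwise alignments are merged under the
#' once-a-gap-always-a-gap rule with insertions left-aligned. Both paths
#' are deterministic for fixed input.
#'
#' @param records records tibble or named character vector of sequences.
#' @param method `"center_star"` or `"external"`.
#' @param command external aligner command (used when `method = "external"`).
#' @param args arguments for the external command; `%s` is replaced by the
#'   input FASTA path.
#' @param anchor attempt CSR-anchored alignment (center-star only).
#' @param templates window templates used for anchoring.
#' @return A named character vector of equal-length aligned rows.
#' @export
align_sequences <- function(records, method = c("center_star", "external"),
                            command = "mafft", args = c("--auto", "%s"),
                            anchor = TRUE, templates = build_csr_templates()) {
  method <- match.arg(method)
  records <- as_records(records)
  if (method == "center_star") {
    return(align_center_star(records, anchor = anchor, templates = templates))
  }
  fa <- tempfile(fileext = ".fasta")
  on.exit(unlink(fa), add = TRUE)
  write_protein_fasta(records, fa)
  out <- system2(command, sub("%s", fa, args, fixed = TRUE), stdout = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status != 0) stopf("external aligner '%s' failed (status %d)", command, status)
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(out, tmp)
  read_msa(tmp)
}

#' @rdname align_sequences
#' @export
align_center_star <- function(records, anchor = TRUE,
                              templates = build_csr_templates()) {
  records <- as_records(records)
  seqs <- stats::setNames(records$sequence, records$accession)
  n <- length(seqs)
  if (n == 0) stopf("no sequences to align")
  if (n == 1) return(seqs)

  anchors <- NULL
  if (anchor) {
    csrs <- locate_csrs(records, templates)
    core <- dplyr::filter(csrs, .data$window != "WW")
    if (!anyNA(core$start)) anchors <- core
  }
  if (!is.null(anchors)) return(align_anchored_blocks(seqs, anchors))

  ci <- center_index(seqs)
  pw <- star_pairwise_plain(seqs, ci)
  merge_star(seqs, ci, pw$pat, pw$subj)
}

# Anchored block alignment: the seven CSR windows are fixed columns; each
# inter-window segment is left-justified and right-padded to its widest
# occurrence across the set.
align_anchored_blocks <- function(seqs, anchors) {
  acc <- names(seqs)
  win <- anchors |>
    dplyr::arrange(match(.data$accession, acc), .data$start)
  wnames <- unique(win$window)
  starts <- matrix(win$start, nrow = length(acc), byrow = TRUE,
                   dimnames = list(acc, wnames))
  ends <- matrix(win$end, nrow = length(acc), byrow = TRUE,
                 dimnames = list(acc, wnames))
  lens <- nchar(seqs)
  nseg <- length(wnames) + 1L
  parts <- matrix("", nrow = length(acc), ncol = 2L * nseg - 1L)
  for (k in seq_len(nseg)) {
    lo <- if (k == 1) rep(1L, length(acc)) else ends[, k - 1L] + 1L
    hi <- if (k == nseg) lens else starts[, k] - 1L
    segs <- substr(unname(seqs), lo, hi)
    width <- max(nchar(segs))
    parts[, 2L * k - 1L] <- paste0(segs, strrep("-", width - nchar(segs)))
    if (k < nseg) parts[, 2L * k] <- substr(unname(seqs), starts[, k], ends[, k])
  }
  stats::setNames(apply(parts, 1, paste, collapse = ""), acc)
}

# Plain global pairwise alignment of all non-center sequences to the center.
star_pairwise_plain <- function(seqs, ci) {
  B <- blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(seqs[-ci])),
    Biostrings::AAString(seqs[[ci]]),
    type = "global", substitutionMatrix = B,
    gapOpening = 15, gapExtension = 2)
  list(pat = as.character(Biostrings::alignedPattern(aln)),
       subj = as.character(Biostrings::alignedSubject(aln)))
}

# Merge pairwise (pattern, center) alignments under once-a-gap-always-a-gap.
merge_star <- function(seqs, ci, pat, subj) {
  n <- length(seqs)
  center <- seqs[[ci]]
  L <- nchar(center)
  ins <- matrix(0L, nrow = n - 1, ncol = L + 1L)
  seg <- vector("list", n - 1)
  for (a in seq_len(n - 1)) {
    sc <- seq_chars(subj[a])
    pc <- seq_chars(pat[a])
    pos <- which(sc != "-")
    ins[a, ] <- diff(c(0L, pos, length(sc) + 1L)) - 1L
    seg[[a]] <- list(pc = pc, pos = pos)
  }
  master <- apply(ins, 2, max)

  build_row <- function(chars_by_slot, residue_chars) {
    pieces <- character(2L * L + 1L)
    for (k in seq_len(L + 1L)) {
      insert <- chars_by_slot[[k]]
      pieces[2L * k - 1L] <- paste0(paste(insert, collapse = ""),
                                    strrep("-", master[k] - length(insert)))
      if (k <= L) pieces[2L * k] <- residue_chars[k]
    }
    paste(pieces, collapse = "")
  }

  rows <- character(n)
  rows[ci] <- build_row(rep(list(character(0)), L + 1L), seq_chars(center))
  oi <- setdiff(seq_len(n), ci)
  for (a in seq_len(n - 1)) {
    pc <- seg[[a]]$pc
    pos <- seg[[a]]$pos
    bounds <- c(0L, pos, length(pc) + 1L)
    slots <- lapply(seq_len(L + 1L), function(k) {
      lo <- bounds[k] + 1L
      hi <- bounds[k + 1L] - 1L
      if (lo > hi) character(0) else pc[lo:hi]
    })
    rows[oi[a]] <- build_row(slots, pc[pos])
  }
  stats::setNames(rows, names(seqs))
}

# Deterministic center choice: the sequence sharing the most 4-mers
# (by unique-kmer incidence) with the rest; ties to the first.
center_index <- function(seqs) {
  if (length(seqs) == 2) return(1L)
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < 4) return(character(0))
    unique(substring(s, 1:(nchar(s) - 3L), 4:nchar(s)))
  })
  vocab <- unique(unlist(kmers))
  M <- vapply(kmers, function(k) vocab %in% k, logical(length(vocab)))
  sim <- crossprod(M + 0)        # shared unique kmers between pairs
  diag(sim) <- 0
  which.max(colSums(sim))
}
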