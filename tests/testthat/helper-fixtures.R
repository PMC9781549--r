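# Shared helpers: tiny fixtures are built in code, never stored.

toy_fasta <- function() {
  paste(
    ">sp|Q11111|AMY1_TEST Test amylase OS=Testus primus OX=1234 GN=amy1",
    "MKLVINHTTE",
    ">A22222 hypothetical protein OS=Testus secundus KD=Bacteria",
    "mklvinhaaa",
    ">B33333 odd residues",
    "MKLBINH",
    sep = "\n")
}

# all-vs-all permutations of 1..k (k small)
perms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(perms(v[-i]), function(p) c(v[i], p))
  }))
}

# best label-matching accuracy of a clustering against truth labels
cluster_accuracy <- function(clusters, truth) {
  tab <- table(truth$label[match(clusters$accession, truth$accession)],
               clusters$cluster)
  k <- nrow(tab)
  stopifnot(ncol(tab) == k)
  max(vapply(perms(seq_len(k)), function(p) sum(tab[cbind(seq_len(k), p)]),
             numeric(1))) / sum(tab)
}

# random additive distance matrix from a random tree with its tree
random_additive <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::rexp(length(tr$edge.length), rate = 2) + 0.05
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}

# four-point condition: for every quadruple the two largest of the three
# pairings agree (within tol)
four_point_ok <- function(d, tol = 1e-9) {
  n <- nrow(d)
  for (q in utils::combn(n, 4, simplify = FALSE)) {
    i <- q[1]; j <- q[2]; k <- q[3]; l <- q[4]
    s <- sort(c(d[i, j] + d[k, l], d[i, k] + d[j, l], d[i, l] + d[j, k]))
    if (s[3] - s[2] > tol) return(FALSE)
  }
  TRUE
}

CSR_WINDOW_NAMES <- c("CSR6", "CSR1", "CSR5", "WW", "CSR2", "CSR3", "CSR4", "CSR7")

truth_coord_matrix <- function(truth, what = "start") {
  as.matrix(truth[, paste0(tolower(CSR_WINDOW_NAMES), "_", what)])
}
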