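POISSON_MAX <- -log(1e-6)  # distance cap when pairwise p reaches 1

#' Pairwise distance matrix from an alignment
#'
#' `p_distance` is the fraction of mismatching residues over the mutually
#' ungapped columns of each pair; `poisson` applies the Poisson correction
#' `-ln(1 - p)`, capped at `-ln(1e-6)` when `p` reaches 1.
#'
#' @param msa named character vector of aligned rows.
#' @param model `"p_distance"` or `"poisson"`.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
msa_distance <- function(msa, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  m <- msa_matrix(msa)
  if (nrow(m) < 3) stopf("need at least 3 sequences for a distance matrix")
  m[m == "-"] <- NA
  n <- nrow(m)
  L <- ncol(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    sub <- m[js, , drop = FALSE]
    Ai <- matrix(m[i, ], nrow = length(js), ncol = L, byrow = TRUE)
    ok <- !is.na(sub) & !is.na(Ai)
    overlap <- rowSums(ok)
    if (any(overlap == 0)) {
      bad <- js[which(overlap == 0)[1]]
      stopf("no overlapping non-gap columns for pair %s / %s",
            rownames(m)[i], rownames(m)[bad])
    }
    mism <- rowSums((sub != Ai) & ok)
    p <- mism / overlap
    d <- if (model == "p_distance") p else
      ifelse(p >= 1 - 1e-6, POISSON_MAX, -log(1 - p))
    D[i, js] <- D[js, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration on a symmetric distance matrix.
#' Equal-scoring joins are broken deterministically by the smallest
#' taxon-index pair; negative branch lengths are clamped to zero with the
#' deficit moved to the sibling edge. NJ is exact on additive matrices: the
#' tree's path lengths reproduce the input distances.
#'
#' @param d symmetric distance matrix (zero diagonal, `n >= 3`) with taxa as
#'   dimnames, or a [stats::dist].
#' @return An object of class `gh13_tree` wrapping an unrooted `ape::phylo`
#'   tree (`$tree`), the input matrix (`$distances`) and, after
#'   [bootstrap_support()], a `$supports` tibble.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(n) || n < 3) stopf("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) stopf("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stopf("distance matrix must have a zero diagonal")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  nw <- labels
  D <- unname(d)
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    merged <- sprintf("(%s:%s,%s:%s)", nw[i], fmt(li), nw[j], fmt(lj))
    dn <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn), c(dn, 0))
    nw <- c(nw[keep], merged)
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    nw[1], fmt(l1), nw[2], fmt(l2), nw[3], fmt(l3))
  phy <- ape::read.tree(text = newick)
  out <- list(tree = phy, distances = d, supports = NULL)
  class(out) <- "gh13_tree"
  out
}

# Canonical non-trivial bipartition keys of an unrooted phylo, named by the
# internal node defining each split.
tree_bipartitions <- function(phy) {
  tips <- phy$tip.label
  n <- length(tips)
  ref <- min(tips)  # fixed reference taxon so keys agree across trees
  pp <- ape::prop.part(phy)
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(pp)) {
    side <- tips[pp[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
      nodes <- c(nodes, n + k)
    }
  }
  stats::setNames(keys, nodes)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' fraction of replicate trees containing the same bipartition. A fixed seed
#' gives identical output. Supports are also attached as node labels so they
#' serialize into Newick.
#'
#' @param msa named character vector of aligned rows.
#' @param n_replicates number of bootstrap replicates (`>= 1`).
#' @param seed integer seed for the column resampling.
#' @param model distance model, see [msa_distance()].
#' @param tree optional precomputed `gh13_tree` of `msa` (recomputed when
#'   omitted).
#' @return The `gh13_tree` with a `$supports` tibble (node, bipartition key,
#'   support fraction) and node labels set on `$tree`.
#' @export
bootstrap_support <- function(msa, n_replicates = 100, seed = 1L,
                              model = c("p_distance", "poisson"), tree = NULL) {
  model <- match.arg(model)
  stopifnot(n_replicates >= 1)
  msa <- as_msa(msa)
  if (is.null(tree)) tree <- nj_tree(msa_distance(msa, model))
  phy <- tree$tree
  keys <- tree_bipartitions(phy)
  counts <- stats::setNames(numeric(length(keys)), keys)
  m <- msa_matrix(msa)
  L <- ncol(m)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_msa <- stats::setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                                 rownames(m))
      rep_tree <- nj_tree(msa_distance(rep_msa, model))
      rep_keys <- tree_bipartitions(rep_tree$tree)
      hitk <- intersect(keys, rep_keys)
      counts[hitk] <- counts[hitk] + 1
    }
  })
  support <- counts / n_replicates
  n <- length(phy$tip.label)
  labels <- rep("", phy$Nnode)
  node_ids <- as.integer(names(keys))
  labels[node_ids - n] <- sprintf("%.4g", support)
  phy$node.label <- labels
  tree$tree <- phy
  tree$supports <- tibble::tibble(node = node_ids,
                                  bipartition = unname(keys),
                                  support = unname(support))
  tree
}

#' Cut a tree into k clusters
#'
#' Removes edges in order of decreasing branch length (ties broken by edge
#' index) until the taxa fall into `k` connected groups.
#'
#' @param tree a `gh13_tree` or `ape::phylo`.
#' @param k number of clusters, `2 <= k <=` number of taxa.
#' @return A tibble with `accession` and integer `cluster` (numbered by
#'   first appearance in tip order).
#' @export
cut_clusters <- function(tree, k) {
  phy <- if (inherits(tree, "gh13_tree")) tree$tree else tree
  n <- length(phy$tip.label)
  if (k < 2 || k > n) stopf("k must be between 2 and the number of taxa (%d)", n)
  edges <- phy$edge
  len <- phy$edge.length
  ord <- order(-len, seq_along(len))
  n_nodes <- n + phy$Nnode
  removed <- logical(nrow(edges))
  comp <- node_components(n_nodes, edges[!removed, , drop = FALSE])
  for (e in ord) {
    if (n_taxa_clusters(comp, n) >= k) break
    removed[e] <- TRUE
    comp <- node_components(n_nodes, edges[!removed, , drop = FALSE])
  }
  tip_comp <- comp[seq_len(n)]
  cluster <- match(tip_comp, unique(tip_comp))
  tibble::tibble(accession = phy$tip.label, cluster = cluster)
}

n_taxa_clusters <- function(comp, n) length(unique(comp[seq_len(n)]))

node_components <- function(n_nodes, edges) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

#' Serialize a tree to Newick
#'
#' Branch lengths and (when present) bootstrap supports as internal node
#' labels, either as fractions or integer percents.
#'
#' @param tree a `gh13_tree`.
#' @param file output path; `NULL` returns the Newick string.
#' @param percent write supports as integer percents instead of fractions.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_tree_newick <- function(tree, file = NULL, percent = FALSE) {
  phy <- if (inherits(tree, "gh13_tree")) tree$tree else tree
  if (percent && !is.null(phy$node.label)) {
    num <- suppressWarnings(as.numeric(phy$node.label))
    phy$node.label <- ifelse(is.na(num), phy$node.label,
                             as.character(round(100 * num)))
  }
  s <- ape::write.tree(phy)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' @export
print.gh13_tree <- function(x, ...) {
  cat(sprintf("<gh13_tree> %d taxa, %d internal nodes%s\n",
              length(x$tree$tip.label), x$tree$Nnode,
              if (is.null(x$supports)) "" else
                sprintf(", %d bootstrapped splits", nrow(x$supports))))
  invisible(x)
}

#' Tidy / summarise a tree
#'
#' `tidy()` returns one row per edge (parent and child node, branch length,
#' tip label and bootstrap support where defined); `glance()` a one-row
#' summary.
#'
#' @param x a `gh13_tree`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.gh13_tree <- function(x, ...) {
  phy <- x$tree
  n <- length(phy$tip.label)
  child <- phy$edge[, 2]
  sup <- rep(NA_real_, nrow(phy$edge))
  if (!is.null(x$supports)) {
    hit <- match(child, x$supports$node)
    sup <- x$supports$support[hit]
  }
  tibble::tibble(
    parent = phy$edge[, 1],
    node = child,
    branch_length = phy$edge.length,
    is_tip = child <= n,
    label = ifelse(child <= n, phy$tip.label[child], NA_character_),
    support = sup
  )
}

#' @rdname tidy.gh13_tree
#' @export
glance.gh13_tree <- function(x, ...) {
  phy <- x$tree
  tibble::tibble(
    n_taxa = length(phy$tip.label),
    n_internal = phy$Nnode,
    total_branch_length = sum(phy$edge.length),
    mean_support = if (is.null(x$supports)) NA_real_ else mean(x$supports$support)
  )
}

#' Plot a tree as a rectangular cladogram
#'
#' @param object a `gh13_tree`.
#' @param show_support annotate internal edges with bootstrap support.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gh13_tree <- function(object, show_support = TRUE, ...) {
  phy <- object$tree
  n <- length(phy$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  x <- numeric(n + phy$Nnode)
  y <- numeric(n + phy$Nnode)
  tip_counter <- 0L
  assign_xy <- function(node, depth) {
    x[node] <<- depth
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) {
      tip_counter <<- tip_counter + 1L
      y[node] <<- tip_counter
      return(invisible())
    }
    for (r in rows) assign_xy(phy$edge[r, 2], depth + phy$edge.length[r])
    y[node] <<- mean(y[phy$edge[rows, 2]])
  }
  assign_xy(root, 0)
  ed <- tidy(object)
  seg <- tibble::tibble(
    x = x[ed$parent], xend = x[ed$node],
    y = y[ed$node], yend = y[ed$node],
    vy = y[ed$parent], vx = x[ed$parent]
  )
  tips <- tibble::tibble(x = x[seq_len(n)], y = y[seq_len(n)],
                         label = phy$tip.label)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$vx, xend = .data$vx,
                                       y = .data$vy, yend = .data$y)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       hjust = -0.05, size = 2.8) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.25))) +
    ggplot2::labs(x = "distance", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
  if (show_support && !is.null(object$supports)) {
    supdat <- ed[!is.na(ed$support), ]
    if (nrow(supdat)) {
      supdat$xend <- x[supdat$node]
      supdat$yv <- y[supdat$node]
      p <- p + ggplot2::geom_text(
        data = supdat,
        ggplot2::aes(x = .data$xend, y = .data$yv,
                     label = sprintf("%.0f", 100 * .data$support)),
        vjust = -0.4, size = 2.5, colour = "grey40")
    }
  }
  p
}
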