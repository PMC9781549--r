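test_that("distance models follow their closed forms", {
  msa <- c(a = "AAAA", b = "AAAA", c = "AACC", d = "CCCC")
  p <- msa_distance(msa, "p_distance")
  expect_equal(p["a", "b"], 0)
  expect_equal(p["a", "c"], 0.5)
  expect_equal(p["a", "d"], 1)
  expect_equal(p, t(p))
  expect_equal(unname(diag(p)), rep(0, 4))

  ps <- msa_distance(msa, "poisson")
  expect_equal(ps["a", "b"], 0)
  expect_equal(ps["a", "c"], -log(0.5))      # 0.6931...
  expect_equal(ps["a", "d"], -log(1e-6))     # documented cap at p = 1

  # gap-excluded pairwise overlap; zero overlap names the pair
  gappy <- c(a = "AA--", b = "--AA", c = "AAAA")
  expect_error(msa_distance(gappy), "a / b")

  # independent oracle: hamming proportion from phangorn on a gap-free toy
  skip_if_not_installed("phangorn")
  mat <- do.call(rbind, strsplit(unname(msa), ""))
  rownames(mat) <- names(msa)
  pd <- phangorn::phyDat(mat, type = "AA")
  expect_equal(as.matrix(phangorn::dist.hamming(pd)), p, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("three-taxon neighbor joining matches the three-point formulas", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr$tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # branch lengths are (2, 3, 7) up to tip order
  expect_equal(sort(tr$tree$edge.length), c(2, 3, 7))
})

test_that("neighbor joining is exact on additive matrices", {
  d <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  # additive for ((A:2,B:3):1,(C:4,D:5))
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr$tree)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-9)
  # recovered split is AB|CD
  splits <- gh13sub:::tree_bipartitions(tr$tree)
  expect_true("C|D" %in% splits || "A|B" %in% splits)

  for (s in 1:10) {
    ra <- random_additive(7, seed = 100 + s)
    tr2 <- nj_tree(ra$d)
    expect_equal(ape::cophenetic.phylo(tr2$tree)[rownames(ra$d), colnames(ra$d)],
                 ra$d, tolerance = 1e-9)
    skip_if_not_installed("phangorn")
    expect_equal(phangorn::RF.dist(tr2$tree, ape::unroot(ra$tree)), 0)
  }
})

test_that("branch lengths never go negative and ties resolve deterministically", {
  withr::with_seed(9, {
    for (i in 1:10) {
      n <- 6
      m <- matrix(stats::runif(n * n, 0.1, 1), n, n)
      d <- (m + t(m)) / 2
      diag(d) <- 0
      dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
      tr <- nj_tree(d)
      expect_true(all(tr$tree$edge.length >= 0))
      expect_identical(write_tree_newick(tr), write_tree_newick(nj_tree(d)))
    }
  })
  eq <- matrix(1, 4, 4) - diag(4)
  dimnames(eq) <- list(letters[1:4], letters[1:4])
  tre <- nj_tree(eq)
  cp <- ape::cophenetic.phylo(tre$tree)
  expect_equal(unname(cp[upper.tri(cp)]), rep(1, 6), tolerance = 1e-12)
})

test_that("newick serialization round-trips byte-stably", {
  ra <- random_additive(6, seed = 5)
  tr <- nj_tree(ra$d)
  s1 <- write_tree_newick(tr)
  re <- ape::read.tree(text = s1)
  s2 <- ape::write.tree(re)
  expect_identical(s1, s2)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, f)
  expect_identical(readLines(f), s1)
})

test_that("bootstrap supports saturate for clean splits and are reproducible", {
  msa <- c(A1 = strrep("A", 30), A2 = strrep("A", 30),
           B1 = strrep("W", 30), B2 = strrep("W", 30),
           C1 = paste0(strrep("A", 15), strrep("W", 15)))
  bt <- bootstrap_support(msa, n_replicates = 25, seed = 3)
  expect_true(all(bt$supports$support >= 0 & bt$supports$support <= 1))
  # both non-trivial splits (the A pair and the B pair) are clean
  expect_equal(nrow(bt$supports), 2L)
  expect_true(all(bt$supports$support == 1))

  bt2 <- bootstrap_support(msa, n_replicates = 25, seed = 3)
  expect_identical(bt$supports, bt2$supports)

  one <- bootstrap_support(msa, n_replicates = 1, seed = 4)
  expect_true(all(one$supports$support %in% c(0, 1)))

  # supports serialize as node labels
  nwk <- write_tree_newick(bt, percent = TRUE)
  expect_match(nwk, "100")
})

test_that("taxon order does not change bipartitions", {
  ra <- random_additive(6, seed = 6)
  tr1 <- nj_tree(ra$d)
  perm <- c(3, 1, 6, 2, 5, 4)
  tr2 <- nj_tree(ra$d[perm, perm])
  expect_setequal(unname(gh13sub:::tree_bipartitions(tr1$tree)),
                  unname(gh13sub:::tree_bipartitions(tr2$tree)))
})

test_that("tree cutting recovers block structure and degenerate cuts", {
  block <- matrix(0.9, 6, 6)
  block[1:3, 1:3] <- 0.05
  block[4:6, 4:6] <- 0.05
  diag(block) <- 0
  dimnames(block) <- list(paste0("t", 1:6), paste0("t", 1:6))
  tr <- nj_tree(block)
  cl <- cut_clusters(tr, 2)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(length(unique(cl$cluster[cl$accession %in% paste0("t", 1:3)])), 1L)
  expect_equal(length(unique(cl$cluster[cl$accession %in% paste0("t", 4:6)])), 1L)

  singletons <- cut_clusters(tr, 6)
  expect_equal(sort(unique(singletons$cluster)), 1:6)
  expect_error(cut_clusters(tr, 1), "between 2")
  expect_error(cut_clusters(tr, 7), "between 2")
})

test_that("tree objects expose broom-style methods and a plot", {
  ra <- random_additive(6, seed = 8)
  tr <- nj_tree(ra$d)
  td <- tidy(tr)
  expect_equal(nrow(td), nrow(tr$tree$edge))
  expect_equal(sum(td$is_tip), 6L)
  gl <- glance(tr)
  expect_equal(gl$n_taxa, 6L)
  expect_s3_class(autoplot(tr), "ggplot")
})
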