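test_that("column classes and percent identity/similarity follow the Clustal convention", {
  msa <- c(a = "MKLVAAAAGV", b = "MKLVAAAAGV", c = "MKLVAAAAGV")
  p <- profile_from_msa(msa)
  expect_equal(p$pct_identity, 100)
  expect_equal(p$pct_similarity, 100)

  # exactly 2 invariant columns out of 10, no similar columns (brute-force
  # verified layout: columns 1,2 identical; the rest mix dissimilar residues)
  msa2 <- c(a = "MKGWAGWAGW", b = "MKWGWAGWAG", c = "MKAWGWAGWA")
  p2 <- profile_from_msa(msa2)
  expect_equal(p2$pct_identity, 20)

  # strong-group column (I/L/V) counts as similar, not identical
  msa3 <- c(a = "MI", b = "ML", c = "MV")
  p3 <- profile_from_msa(msa3)
  expect_equal(as.character(tidy(p3)$class), c("IDENTICAL", "STRONG_SIMILAR"))
  expect_equal(p3$pct_identity, 50)
  expect_equal(p3$pct_similarity, 100)

  # gapped columns never count as identical or similar
  msa4 <- c(a = "M-A", b = "M-A", c = "MAA")
  p4 <- profile_from_msa(msa4)
  expect_equal(as.character(tidy(p4)$class), c("IDENTICAL", "GAPPED", "IDENTICAL"))

  expect_error(profile_from_msa(c(a = "MK", b = "MKL")), "unequal")
})

test_that("information content matches the analytic values", {
  # invariant column: IC = log2(20); uniform over 20: IC = 0; 50/50: log2(20)-1
  inv <- logo_matrix(rep("A", 10))
  expect_equal(inv$columns$ic, log2(20), tolerance = 1e-12)

  unif <- logo_matrix(c("A","C","D","E","F","G","H","I","K","L",
                        "M","N","P","Q","R","S","T","V","W","Y"))
  expect_equal(unif$columns$ic, 0, tolerance = 1e-12)

  half <- logo_matrix(c(rep("A", 5), rep("W", 5)))
  expect_equal(half$columns$ic, log2(20) - 1, tolerance = 1e-12)

  expect_error(logo_matrix(c("AA", "A")), "unequal")
  expect_error(logo_matrix(c("A-", "AA")), "gap")
})

test_that("logo frequencies sum to one and statistics ignore sequence order", {
  sim <- simulate_gh13_set(20, seed = 15)
  csr <- locate_csrs(sim$records)
  logo <- concat_logo_string(csr)
  lp <- logo_matrix(logo)
  expect_equal(unname(rowSums(lp$freq)), rep(1, 54), tolerance = 1e-9)
  expect_true(all(lp$columns$ic >= 0 & lp$columns$ic <= log2(20) + 1e-12))
  # modal fifth-region positions spell MPDLN (positions 16-20)
  expect_equal(paste(lp$columns$top_residue[16:20], collapse = ""), "MPDLN")

  msa <- align_sequences(sim$records)
  p1 <- profile_from_msa(msa)
  p2 <- profile_from_msa(msa[sample(length(msa))])
  expect_equal(p1$pct_identity, p2$pct_identity)
  expect_equal(p1$pct_similarity, p2$pct_similarity)
  expect_true(p1$pct_identity <= p1$pct_similarity)
})

test_that("motif counting is exact over named windows", {
  sim <- simulate_gh13_set(12, csr_mutation_rate = 0, seed = 16)
  csr <- locate_csrs(sim$records)
  expect_equal(count_motif(csr, "WW", "WW"), 12L)
  expect_equal(count_motif(csr, "CSR5", "MPDLN"), 12L)
  expect_equal(count_motif(csr[0, ], "WW", "WW"), 0L)
  expect_error(count_motif(csr, "CSR9", "WW"), "unknown window")
})

test_that("pairwise identity is symmetric with a 100 diagonal and NA on no overlap", {
  msa <- c(a = "MKLVMKLVMK", b = "MKLVMKLVMA", c = "M---MKLVMK")
  m <- pairwise_identity(msa)
  expect_equal(diag(m), c(a = 100, b = 100, c = 100))
  expect_equal(m, t(m))
  expect_equal(m["a", "b"], 90)          # 1 mismatch over 10 overlap columns
  expect_equal(m["a", "c"], 100)         # overlap columns all match

  disjoint <- c(a = "AA--", b = "--AA", c = "AAAA")
  expect_true(is.na(pairwise_identity(disjoint)["a", "b"]))
})

test_that("profile objects expose broom-style methods and a plot", {
  sim <- simulate_gh13_set(6, seed = 17)
  p <- profile_from_msa(align_sequences(sim$records))
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("position", "class", "ic") %in% names(td)))
  gl <- glance(p)
  expect_equal(gl$n_sequences, 6L)
  expect_equal(gl$n_columns, p$n_columns)
  expect_s3_class(autoplot(p), "ggplot")
})
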