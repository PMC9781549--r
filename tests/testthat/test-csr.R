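test_that("templates carry the eight windows with the family lengths", {
  tpl <- build_csr_templates()
  expect_equal(tpl$name, c("CSR6", "CSR1", "CSR5", "WW", "CSR2", "CSR3", "CSR4", "CSR7"))
  expect_equal(tpl$length, c(9L, 6L, 5L, 2L, 9L, 8L, 6L, 9L))
  expect_equal(sum(tpl$length), 54L)
  expect_true(all(tpl$self_score > 0))
})

test_that("disordered or overlapping anchors are a configuration error", {
  a <- csr_anchors()
  disordered <- a
  # move CSR5 (length preserved) downstream of CSR2
  disordered[disordered$name == "CSR5", c("start", "end")] <- list(300L, 304L)
  expect_error(build_csr_templates(anchors = disordered), "ordered")

  overlap <- a
  overlap$start[2] <- a$end[1] - 2L
  overlap$end[2] <- overlap$start[2] + 5L
  expect_error(build_csr_templates(anchors = overlap), "ordered|non-overlap")
})

test_that("the reference reproduces its own anchor table with confidence 1", {
  csr <- locate_csrs(gh13_reference())
  a <- csr_anchors()
  expect_equal(csr$start, a$start)
  expect_equal(csr$end, a$end)
  expect_equal(csr$confidence, rep(1, 8))
  expect_true(all(csr$complete))
})

test_that("window starts are strictly increasing for located sets", {
  sim <- simulate_gh13_set(20, seed = 55)
  csr <- locate_csrs(sim$records)
  for (acc in unique(csr$accession)) {
    s <- csr$start[csr$accession == acc]
    expect_true(all(diff(s) > 0))
  }
})

test_that("embedded windows are recovered exactly under linker mutation", {
  # >= 100 sequences, 10% linker mutation, 0% window mutation
  sim <- simulate_gh13_set(108, csr_mutation_rate = 0,
                           linker_mutation_rate = 0.10, seed = 77)
  csr <- locate_csrs(sim$records)
  got <- matrix(csr$start, ncol = 8, byrow = TRUE)
  expect_equal(unname(got), unname(truth_coord_matrix(sim$truth, "start")))
  expect_true(all(csr$complete))
})

test_that("a deleted window leaves the set incomplete at a strict threshold", {
  sim <- simulate_gh13_set(5, corruption = "DROP_CSR:CSR4", seed = 78)
  csr <- locate_csrs(sim$records, conf_threshold = 0.5)
  c4 <- csr[csr$window == "CSR4", ]
  expect_true(all(c4$confidence < 0.5))
  expect_true(all(!csr$complete))
})

test_that("the catalytic triad reads D/E/D at the fixed in-window offsets", {
  csr <- locate_csrs(gh13_reference())
  tri <- extract_triad(csr)
  expect_equal(tri$nucleophile, "D")
  expect_equal(tri$proton_donor, "E")
  expect_equal(tri$stabilizer, "D")
  expect_true(tri$triad_valid)

  sim <- simulate_gh13_set(4, corruption = "BREAK_TRIAD", seed = 79)
  tri2 <- extract_triad(locate_csrs(sim$records))
  expect_equal(tri2$proton_donor, rep("Q", 4))
  expect_false(any(tri2$triad_valid))
})

test_that("the concatenated logo string has 54 positions with triad at 27/36/45", {
  csr <- locate_csrs(gh13_reference())
  logo <- concat_logo_string(csr)$logo
  expect_equal(nchar(logo), 54L)
  expect_equal(substr(logo, 16, 20), "MPDLN")
  expect_equal(substr(logo, 21, 22), "WW")
  expect_equal(substr(logo, 27, 27), "D")
  expect_equal(substr(logo, 36, 36), "E")
  expect_equal(substr(logo, 45, 45), "D")

  # generator ground truth: concatenation of the embedded windows
  sim <- simulate_gh13_set(3, csr_mutation_rate = 0, linker_mutation_rate = 0,
                           seed = 80)
  csr2 <- locate_csrs(sim$records)
  logos <- concat_logo_string(csr2)
  expected <- vapply(seq_len(3), function(i) {
    s <- sim$records$sequence[i]
    paste(substring(s, truth_coord_matrix(sim$truth, "start")[i, ],
                    truth_coord_matrix(sim$truth, "end")[i, ]), collapse = "")
  }, character(1))
  expect_equal(logos$logo[match(sim$records$accession, logos$accession)],
               expected)
})
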