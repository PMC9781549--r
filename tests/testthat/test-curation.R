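rec <- function(acc, org, seq) {
  tibble::tibble(accession = acc, organism = org, kingdom = "Bacteria",
                 sequence = seq, description = "")
}

test_that("species deduplication keeps the longest sequence, ties by accession", {
  r <- rec(c("X1", "X2"), c("Same sp.", "Same sp."),
           c(strrep("A", 600), strrep("A", 590)))
  dd <- dedupe_by_species(r)
  expect_equal(dd$kept, c(TRUE, FALSE))
  expect_equal(dd$reason, c(NA, "DUPLICATE_SPECIES"))

  r2 <- rec(c("A1", "A0"), c("Same sp.", "Same sp."),
            c(strrep("A", 10), strrep("A", 10)))
  dd2 <- dedupe_by_species(r2)
  expect_equal(dd2$kept, c(FALSE, TRUE))

  # distinct organisms: nothing merged
  sim <- simulate_gh13_set(12, seed = 3)
  expect_true(all(dedupe_by_species(sim$records)$kept))

  # unknown organisms never merge with each other
  r3 <- rec(c("U1", "U2"), c(NA, NA), c("MKLV", "MKLV"))
  expect_true(all(dedupe_by_species(r3)$kept))
})

test_that("deduplication is idempotent", {
  r <- rec(c("X1", "X2", "X3"), c("A sp.", "A sp.", "B sp."),
           c(strrep("M", 50), strrep("M", 60), strrep("M", 40)))
  once <- dedupe_by_species(r)
  kept <- once[once$kept, names(r)]
  twice <- dedupe_by_species(kept)
  expect_true(all(twice$kept))
  expect_equal(kept$accession, twice$accession)
})

test_that("membership filters accept intact synthetic members and report first failures", {
  sim <- simulate_gh13_set(8, seed = 21)
  mf <- apply_membership_filters(sim$records)
  expect_true(all(mf$accepted))

  broken <- simulate_gh13_set(8, corruption = "BREAK_TRIAD", seed = 22)
  mfb <- apply_membership_filters(broken$records)
  expect_true(all(!mfb$accepted))
  expect_true(all(mfb$reason == "TRIAD_BROKEN"))

  headless <- simulate_gh13_set(8, corruption = "DROP_NDOMAIN", seed = 23)
  mfh <- apply_membership_filters(headless$records)
  expect_true(all(mfh$reason == "NO_NDOMAIN"))

  # deleted window: undetectable at the permissive default, caught with the
  # stricter exposed confidence threshold
  noc4 <- simulate_gh13_set(8, corruption = "DROP_CSR:CSR4", seed = 24)
  mfc <- apply_membership_filters(noc4$records, conf_threshold = 0.5)
  expect_true(all(mfc$reason == "CSR_INCOMPLETE"))
})

test_that("filtering is order-independent and covers every record exactly once", {
  sim <- simulate_gh13_set(6, seed = 31)
  bad <- simulate_gh13_set(3, corruption = "BREAK_TRIAD", seed = 32,
                           accession_prefix = "BRK")
  records <- dplyr::bind_rows(sim$records, bad$records)
  records$sequence[5] <- sub("M", "B", records$sequence[5])  # alphabet reject

  cur <- curate_sequences(records)
  expect_equal(nrow(cur), nrow(records))
  expect_true(all(cur$status %in% c("accepted", "rejected")))
  expect_equal(sum(curation_summary(cur)$n), nrow(records))

  perm <- sample(nrow(records))
  cur2 <- curate_sequences(records[perm, ])
  acc1 <- sort(cur$accession[cur$status == "accepted"])
  acc2 <- sort(cur2$accession[cur2$status == "accepted"])
  expect_equal(acc1, acc2)
})

test_that("reference shorter than its N-domain definition is a configuration error", {
  short_ref <- tibble::tibble(accession = "R", organism = "r", kingdom = "Bacteria",
                              sequence = strrep("M", 50), description = "")
  sim <- simulate_gh13_set(2, seed = 41)
  expect_error(apply_membership_filters(sim$records, reference = short_ref,
                                        templates = build_csr_templates()),
               "N-domain")
})

test_that("length statistics are exact and reject empty input", {
  r <- rec(c("a", "b", "c"), c("x", "y", "z"),
           c(strrep("M", 5), strrep("M", 7), strrep("M", 9)))
  ls <- length_stats(r)
  expect_equal(unlist(ls), c(n = 3, min = 5, max = 9, mean = 7))
  one <- length_stats(r[1, ])
  expect_equal(one$min, one$max)
  expect_equal(one$mean, 5)
  expect_error(length_stats(r[0, ]), "empty")
})

test_that("generated sets span the configured length range as stored", {
  sim <- simulate_gh13_set(108, seed = 7)
  ls <- length_stats(sim$records)
  expect_equal(ls$min, 588)
  expect_equal(ls$max, 616)
})
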