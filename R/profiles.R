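# Subfamily sequence profiles used by the generator and the reference.
#
# Window order along the catalytic barrel and the concatenated-logo layout:
# CSR-VI (9), CSR-I (6), CSR-V (5), WW (2), CSR-II (9), CSR-III (8),
# CSR-IV (6), CSR-VII (9); 54 positions in total. Within-window 1-based
# offsets of the catalytic triad: nucleophile Asp at CSR-II position 5,
# proton donor Glu at CSR-III position 5, transition-state stabilizer Asp at
# CSR-IV position 6 (concatenated-logo positions 27, 36 and 45).

CSR_ORDER <- c("CSR6", "CSR1", "CSR5", "WW", "CSR2", "CSR3", "CSR4", "CSR7")

CSR_LENGTHS <- c(CSR6 = 9L, CSR1 = 6L, CSR5 = 5L, WW = 2L,
                 CSR2 = 9L, CSR3 = 8L, CSR4 = 6L, CSR7 = 9L)

# window, 1-based in-window offset
TRIAD_SITES <- data.frame(
  role   = c("nucleophile", "proton_donor", "stabilizer"),
  window = c("CSR2", "CSR3", "CSR4"),
  offset = c(5L, 5L, 6L),
  residue = c("D", "E", "D"),
  stringsAsFactors = FALSE
)

SIM_PROFILES <- c("GH13_46", "OLIGO16", "NEOPUL", "RANDOM")

# Internal, fixed seeds: profile skeletons must be identical across calls and
# independent of the user's simulation seed.
PROFILE_SEEDS <- c(GH13_46 = 101L, OLIGO16 = 202L, NEOPUL = 303L, RANDOM = 404L)
SIGNAL_SEED <- 7L
NDOMAIN_SEED <- 11L

SIGNAL_LENGTH <- 20L
NDOMAIN_LENGTH <- 100L
# Linker lengths preceding each window (after the N-domain for the first one).
BASE_GAPS <- c(CSR6 = 30L, CSR1 = 35L, CSR5 = 55L, WW = 10L,
               CSR2 = 12L, CSR3 = 28L, CSR4 = 55L, CSR7 = 25L)

profile_consensus <- function(profile) {
  profile <- match.arg(profile, SIM_PROFILES)
  fixed <- list(
    GH13_46 = c(CSR6 = "GITAIWISP", CSR1 = "DAVINH", CSR5 = "MPDLN", WW = "WW",
                CSR2 = "GFRIDAYGY", CSR3 = "VLLGEEWD", CSR4 = "FIDNHD",
                CSR7 = "GIPVIYYGD"),
    OLIGO16 = c(CSR6 = "GVTALWLSP", CSR1 = "DLVINH", CSR5 = "QPDLN", WW = "YL",
                CSR2 = "GFRLDVAKH", CSR3 = "ILMGEAWN", CSR4 = "WIDNHD",
                CSR7 = "GTPAIYFGE"),
    NEOPUL  = c(CSR6 = "GVDALWISP", CSR1 = "DGVFNH", CSR5 = "MPKLN", WW = "FL",
                CSR2 = "GWRLDVAGH", CSR3 = "FLLGEVWH", CSR4 = "MWNNHD",
                CSR7 = "GLPLIYYGE")
  )
  if (profile %in% names(fixed)) return(fixed[[profile]])
  # RANDOM: a divergent family member with no subfamily signature -- the
  # fifth-region pattern matches none of the three groups and the WW stretch
  # is absent, but the windows stay locatable (valid triad, family-level
  # residues retained).
  c(CSR6 = "GLTHIWLTP", CSR1 = "DVVANH", CSR5 = "MADLN", WW = "WF",
    CSR2 = "GIRFDVVGH", CSR3 = "VVLGEVWD", CSR4 = "LVDNHD",
    CSR7 = "GVPSLYWGE")
}

# Positions (1-based, per window) that the profile treats as invariant: the
# catalytic triad plus the subfamily-diagnostic sites the study describes as
# (nearly) invariant. csr_mutation never touches these; explicit corruptions do.
profile_invariant_sites <- function(profile) {
  profile <- match.arg(profile, SIM_PROFILES)
  inv <- list(CSR2 = 5L, CSR3 = 5L, CSR4 = 6L)          # triad
  inv$CSR5 <- c(1L, 2L, 3L, 5L)                         # MPDxN / QPDxN / MPKxN anchor
  if (profile == "GH13_46") {
    inv$WW <- c(1L, 2L)
    inv$CSR2 <- c(inv$CSR2, 7L, 9L)                     # terminal Y-x-Y tyrosines
    inv$CSR3 <- c(inv$CSR3, 6L)                         # Glu after the proton donor
  }
  if (profile == "RANDOM") inv$CSR5 <- NULL
  inv
}

# Site-specific restricted alphabets (GH13_46: the middle of the aromatic end
# varies over G/S/P only).
profile_site_sets <- function(profile) {
  if (profile == "GH13_46") list(CSR2 = list(`8` = c("G", "S", "P"))) else list()
}

fixed_signal_peptide <- function() {
  if (is.null(.gh13_env$signal)) {
    .gh13_env$signal <- withr::with_seed(SIGNAL_SEED, {
      paste0("M", chars_to_seq(sample(c("A", "L", "V", "I", "F", "S", "T", "G", "W", "C"),
                                      SIGNAL_LENGTH - 1L, replace = TRUE)))
    })
  }
  .gh13_env$signal
}

fixed_ndomain <- function() {
  if (is.null(.gh13_env$ndomain)) {
    .gh13_env$ndomain <- withr::with_seed(NDOMAIN_SEED, {
      chars_to_seq(sample(AA20, NDOMAIN_LENGTH, replace = TRUE))
    })
  }
  .gh13_env$ndomain
}

# Deterministic profile skeleton: signal + N-domain + linkers + the eight
# windows + C-terminal tail filled to `total_length`. Window coordinates are
# 1-based inclusive on the emitted skeleton.
build_profile_skeleton <- function(profile, total_length,
                                   include_ndomain = TRUE,
                                   include_signal_peptide = TRUE) {
  profile <- match.arg(profile, SIM_PROFILES)
  cons <- profile_consensus(profile)
  withr::with_seed(PROFILE_SEEDS[[profile]], {
    gaps <- BASE_GAPS
    if (profile != "GH13_46") {
      gaps <- gaps + sample(-8:8, length(gaps), replace = TRUE)
    }
    parts <- character(0)
    if (include_signal_peptide) parts <- c(parts, fixed_signal_peptide())
    ndom_start <- NA_integer_
    if (include_ndomain) {
      ndom_start <- sum(nchar(parts)) + 1L
      parts <- c(parts, fixed_ndomain())
    }
    starts <- integer(length(CSR_ORDER))
    names(starts) <- CSR_ORDER
    for (w in CSR_ORDER) {
      linker <- chars_to_seq(sample(AA20, gaps[[w]], replace = TRUE))
      parts <- c(parts, linker)
      starts[[w]] <- sum(nchar(parts)) + 1L
      parts <- c(parts, cons[[w]])
    }
    core <- paste(parts, collapse = "")
    core_len <- nchar(core)
    if (total_length < core_len) {
      stopf("total_length %d shorter than the skeleton core (%d residues)",
            total_length, core_len)
    }
    tail <- chars_to_seq(sample(AA20, total_length - core_len, replace = TRUE))
    list(
      profile = profile,
      sequence = paste0(core, tail),
      core_length = core_len,
      windows = tibble::tibble(
        name = CSR_ORDER,
        start = unname(starts),
        end = unname(starts) + unname(CSR_LENGTHS[CSR_ORDER]) - 1L
      ),
      ndomain = if (include_ndomain) c(ndom_start, ndom_start + NDOMAIN_LENGTH - 1L) else c(NA_integer_, NA_integer_),
      consensus = cons,
      invariant = profile_invariant_sites(profile),
      site_sets = profile_site_sets(profile)
    )
  })
}
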