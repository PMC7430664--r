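motif14 <- paste0(strrep("AUA", 4), "AU")

# deterministic non-repetitive filler; distinct offsets give distinct spacers
# so no accidental repeated k-mer links two regions
filler <- function(n, offset = 1) {
  substring(strrep("ACGUCGAUGCAGUCAGCUAGCGUACUGAGCCGGAUUCGGCAUCCGAUAGGC", 10),
            offset, offset + n - 1)
}

test_that("candidate enumeration finds repeated k-mers with merged loci", {
  m <- "AUGCAUGGCCAUAG" # fixed 14-mer
  ref <- tibble::tibble(id = "ref", residues = paste0(m, filler(30), m))
  cand <- enumerate_candidates(ref, k = 14, min_loci = 2)
  expect_true(m %in% cand$motif)
  expect_equal(cand$n_ref_loci[cand$motif == m], 2L)

  # no repeated 14-mer -> empty candidate list
  none <- tibble::tibble(id = "r", residues = filler(60))
  expect_equal(nrow(enumerate_candidates(none, k = 14, min_loci = 2)), 0L)

  expect_error(enumerate_candidates(none, k = 100), "exceeds reference length")
})

test_that("a twice-embedded repeat tract yields phase-staggered candidates", {
  tract <- strrep("AUA", 7)
  ref <- tibble::tibble(id = "r",
                        residues = paste0(filler(25), tract, filler(25, 30), tract))
  cand <- enumerate_candidates(ref, k = 14, min_loci = 2)
  # every 14-mer inside a 21-nt tract recurs in the second copy: the three
  # distinct phase k-mers all qualify with 2 loci
  phases <- unique(substring(paste0(tract, tract), 1:8, 14:21))
  expect_true(all(phases %in% cand$motif))
  expect_true(all(cand$n_ref_loci[cand$motif %in% phases] == 2L))
})

test_that("the screen recovers exactly the planted motif on synthetic panels", {
  for (seed in 1:20) {
    panel <- gen_panel(seed = seed)
    res <- run_screen(panel$manifest, panel$seqs, k = 14, min_loci = 2)
    expect_equal(res$motif[res$verdict == "pass"], motif14)
  }
})

test_that("a single spurious copy in a required_absent species empties the pass set", {
  panel <- gen_panel(seed = 3)
  seqs <- panel$seqs
  i <- match("incompat_1", seqs$id)
  seqs$residues[i] <- paste0(seqs$residues[i], motif14)
  res <- run_screen(panel$manifest, seqs)
  expect_equal(sum(res$verdict == "pass"), 0L)
  expect_true(all(res$verdict[res$motif == motif14] == "fail_absent"))
})

test_that("species shorter than k are excluded with a warning", {
  panel <- gen_panel(seed = 5)
  seqs <- panel$seqs
  seqs$residues[match("compat_1", seqs$id)] <- "AUGGC" # incomplete sequence
  seqs$length <- nchar(seqs$residues)
  expect_warning(res <- run_screen(panel$manifest, seqs), "shorter than k")
  expect_equal(res$motif[res$verdict == "pass"], motif14)
  expect_false("present_compat_1" %in% names(res))
})

test_that("screen equals the brute-force per-k-mer oracle on small panels", {
  for (seed in c(11, 12, 13, 14, 15)) {
    panel <- gen_panel(seed = seed, length = 250)
    res <- run_screen(panel$manifest, panel$seqs, k = 14, min_loci = 2)
    expect_equal(
      sort(res$motif[res$verdict == "pass"]),
      oracle_screen_pass(panel$manifest, panel$seqs, k = 14, min_loci = 2)
    )
    # failing candidates stay in the output for audit
    expect_true(all(res$verdict %in% c("pass", "fail_present", "fail_absent")))
  }
})

test_that("adding constraints never enlarges the pass set", {
  panel <- gen_panel(seed = 8)
  base <- run_screen(panel$manifest, panel$seqs)
  base_pass <- base$motif[base$verdict == "pass"]

  # an extra required_absent species
  extra_a <- dplyr::bind_rows(
    panel$manifest,
    tibble::tibble(species = "extra_abs", sequence_ref = "extra_abs",
                   compat_class = "required_absent")
  )
  seqs_a <- dplyr::bind_rows(
    panel$seqs,
    gen_sequence(300, seed = 999, id = "extra_abs")
  )
  pass_a <- with(run_screen(extra_a, seqs_a), motif[verdict == "pass"])
  expect_true(all(pass_a %in% base_pass))

  # an extra required_present species
  extra_p <- dplyr::bind_rows(
    panel$manifest,
    tibble::tibble(species = "extra_pres", sequence_ref = "extra_pres",
                   compat_class = "required_present")
  )
  seqs_p <- dplyr::bind_rows(
    panel$seqs,
    gen_sequence(300, seed = 998, id = "extra_pres")
  )
  pass_p <- with(run_screen(extra_p, seqs_p), motif[verdict == "pass"])
  expect_true(all(pass_p %in% base_pass))
})

test_that("passing motifs group into span-merged reference regions", {
  tract <- strrep("AUA", 7)
  ref <- tibble::tibble(id = "r",
                        residues = paste0(filler(25), tract, filler(25, 30), tract))
  cand <- enumerate_candidates(ref, k = 14, min_loci = 2)
  regions <- group_into_regions(cand)
  # the overlapping phase 14-mers inside each tract merge into one region each
  expect_equal(nrow(regions), 2L)
  expect_true(all(regions$n_motifs >= 3L))

  empty <- cand[0, ]
  empty$verdict <- character(0)
  expect_equal(nrow(group_into_regions(empty)), 0L)
})

test_that("a missing panel sequence is an error", {
  panel <- gen_panel(seed = 2)
  expect_error(
    run_screen(panel$manifest, panel$seqs[-2, ]),
    "no sequence for manifest species"
  )
})
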