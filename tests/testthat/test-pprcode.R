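make_array <- function(residue_rows, protein_id = "p") {
  tibble::tibble(
    protein_id = protein_id,
    motif_index = seq_along(residue_rows),
    residues = residue_rows
  )
}

test_that("array tables are validated on read", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  arr <- gen_ppr_array(3, seed = 1)
  write_tsv_table(arr, tsv)
  expect_equal(read_ppr_array(tsv), arr)

  bad <- arr
  bad$residues[2] <- substr(bad$residues[2], 1, 34)
  write_tsv_table(bad, tsv)
  expect_error(read_ppr_array(tsv), "exactly 35 residues")

  bad <- arr
  bad$motif_index <- c(1L, 3L, 4L)
  write_tsv_table(bad, tsv)
  expect_error(read_ppr_array(tsv), "consecutive")

  expect_error(validate_ppr_array(arr[1, ]), "at least 2 motifs")
})

test_that("information content hits its analytic bounds", {
  # six identical motifs: every position has zero entropy, IC = log2(20)
  arr <- make_array(rep(strrep("ADNLK", 7), 6))
  prof <- phase_profiles(arr)
  expect_true(all(abs(prof$info$ic - log2(20)) < 1e-12))

  # a 50/50 split at one position gives IC = log2(20) - 1
  res <- rep(strrep("A", 35), 6)
  substr(res[1], 10, 10) <- "W" # phase A (motifs 1 and 4) splits 1/1 at position 10
  arr <- make_array(res)
  prof <- phase_profiles(arr)
  icA10 <- prof$info$ic[prof$info$phase == "A" & prof$info$position == 10]
  expect_equal(icA10, log2(20) - 1)

  # bounds hold on random arrays
  for (seed in 1:5) {
    p <- phase_profiles(gen_ppr_array(12, seed = seed))
    expect_true(all(p$info$ic >= -1e-12 & p$info$ic <= log2(20) + 1e-12))
    # column counts sum to the phase size
    expect_true(all(vapply(p$counts, function(m) all(rowSums(m) == 4L),
                           logical(1))))
  }
})

test_that("gap residues are excluded from profile columns", {
  res <- rep(strrep("A", 35), 6)
  substr(res[1], 5, 5) <- "X"
  prof <- phase_profiles(make_array(res))
  expect_equal(prof$info$n_obs[prof$info$phase == "A" &
                                 prof$info$position == 5], 1L)
})

test_that("signature detection applies an inclusive frequency threshold", {
  arr <- gen_ppr_array(
    15,
    planted = tibble::tibble(phase = "A", position = c(1, 6),
                             residue = c("D", "N"), freq = 1),
    seed = 42
  )
  sig <- detect_signature(phase_profiles(arr))
  expect_true(all(c("D", "N") %in%
                    sig$residue[sig$phase == "A" & sig$position %in% c(1, 6)]))

  # frequency 0.75 misses a 0.8 threshold, meets an inclusive 0.75 one
  res <- rep(strrep("A", 35), 12) # phase A has 4 motifs
  substr(res[1], 2, 2) <- "W" # position 2 in phase A: 3/4 = 0.75 "A"
  prof <- phase_profiles(make_array(res))
  s8 <- detect_signature(prof, min_freq = 0.8)
  expect_false(any(s8$phase == "A" & s8$position == 2))
  s75 <- detect_signature(prof, min_freq = 0.75)
  expect_true(any(s75$phase == "A" & s75$position == 2 & s75$residue == "A"))
})

test_that("planted signatures are recovered with zero false negatives", {
  for (seed in 1:20) {
    planted <- tibble::tibble(
      phase = c("A", "A", "B"), position = c(1, 6, 12),
      residue = c("D", "N", "K"), freq = c(1, 1, 0.9)
    )
    arr <- gen_ppr_array(21, planted = planted, seed = seed)
    sig <- detect_signature(phase_profiles(arr), min_freq = 0.85)
    for (i in seq_len(nrow(planted))) {
      expect_true(any(sig$phase == planted$phase[i] &
                        sig$position == planted$position[i] &
                        sig$residue == planted$residue[i]))
    }
  }
})

test_that("binding profiles follow the N-1 rule and the intersection code", {
  # N6 on one motif and D1 on the next concentrate the position on U
  res <- rep(strrep("L", 35), 4)
  substr(res[2], 6, 6) <- "N"
  substr(res[3], 1, 1) <- "D"
  bp <- binding_profile(make_array(res))
  expect_equal(nrow(bp$weights), 3L) # N - 1
  expect_equal(unname(bp$weights[2, "U"]), 1)
  expect_equal(bp$provenance[2], "six*one")
  # positions with no rule fall back to uniform
  expect_equal(unname(bp$weights[1, ]), rep(0.25, 4))
  expect_equal(bp$provenance[1], "uniform")
  # rows always sum to 1
  expect_true(all(abs(rowSums(bp$weights) - 1) < 1e-12))
})

test_that("single-residue rules fire alone when only one side matches", {
  res <- rep(strrep("L", 35), 3)
  substr(res[1], 6, 6) <- "N" # pyrimidine preference, no D1 on motif 2
  bp <- binding_profile(make_array(res))
  expect_equal(unname(bp$weights[1, ]), c(0, 0.5, 0, 0.5))
  expect_equal(bp$provenance[1], "six")
})

test_that("pair rules from a loaded code table take precedence", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(tibble::tibble(
    rule_type = c("pair", "six", "one"),
    aa6 = c("N", "N", NA),
    aa1_next = c("D", NA, "D"),
    A = c(1, 0, 0), C = c(0, 0.5, 0), G = c(0, 0, 0.5), U = c(0, 0.5, 0.5)
  ), tsv)
  code <- read_code_table(tsv)
  res <- rep(strrep("L", 35), 3)
  substr(res[1], 6, 6) <- "N"
  substr(res[2], 1, 1) <- "D"
  bp <- binding_profile(make_array(res), code)
  expect_equal(unname(bp$weights[1, "A"]), 1)
  expect_equal(bp$provenance[1], "pair")

  # weight vectors must be simplex rows
  write_tsv_table(tibble::tibble(
    rule_type = "six", aa6 = "N", aa1_next = NA,
    A = 0.5, C = 0.5, G = 0.5, U = 0.5
  ), tsv)
  expect_error(read_code_table(tsv), "sum to 1")
})

test_that("log-odds scanning scores windows independently of context", {
  arr <- gen_ppr_array(
    15,
    planted = tibble::tibble(phase = c("A", "B"), position = c(6, 1),
                             residue = c("N", "D"), freq = 1),
    seed = 11
  )
  bp <- binding_profile(arr)
  m <- nrow(bp$weights)
  target <- strrep("AUA", 7)
  sc1 <- scan_rna(bp, tibble::tibble(id = "a", residues = target))
  sc2 <- scan_rna(bp, tibble::tibble(
    id = "b", residues = paste0("GGCC", target, "CCGG")
  ))
  # the same window scores identically regardless of flanking context
  expect_equal(sc2$score[sc2$start == 5], sc1$score[sc1$start == 1])

  # a perfect-match profile scores 2 bits per position on uniform background
  w <- matrix(0, nrow = 4, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "U")))
  w[cbind(1:4, match(c("A", "U", "G", "C"), colnames(w)))] <- 1
  perfect <- structure(
    list(protein_id = "perfect", weights = w, provenance = rep("pair", 4)),
    class = "ppr_binding_profile"
  )
  sc <- scan_rna(perfect, tibble::tibble(id = "t", residues = "AUGC"))
  expect_equal(sc$score, 8) # 2 * profile length

  # zero-weight bases stay finite through the floor
  sc0 <- scan_rna(perfect, tibble::tibble(id = "t", residues = "GGGG"))
  expect_true(all(is.finite(sc0$score)))
})

test_that("a U-every-third profile prefers triplet repeats over dinucleotide repeats", {
  arr <- gen_ppr_array(
    15,
    planted = tibble::tibble(phase = c("A", "B"), position = c(6, 1),
                             residue = c("N", "D"), freq = 1),
    seed = 2
  )
  bp <- binding_profile(arr)
  aua <- tibble::tibble(id = "aua", residues = strrep("AUA", 7))
  ua <- tibble::tibble(id = "ua", residues = paste0(strrep("UA", 10), "A"))
  best_aua <- max(scan_rna(bp, aua)$score)
  best_ua <- max(scan_rna(bp, ua)$score)
  expect_gt(best_aua, best_ua)
})

test_that("profile tidiers expose positions, weights and provenance", {
  arr <- gen_ppr_array(6, seed = 3)
  bp <- binding_profile(arr)
  td <- generics::tidy(bp)
  expect_equal(nrow(td), 5L * 4L)
  expect_true(all(c("position", "base", "weight", "provenance") %in% names(td)))
  gl <- generics::glance(bp)
  expect_equal(gl$n_positions, 5L)

  prof <- phase_profiles(gen_ppr_array(9, seed = 4))
  tp <- generics::tidy(prof)
  expect_true(all(c("phase", "position", "residue", "freq", "ic") %in% names(tp)))
  expect_equal(nrow(generics::glance(prof)), 3L)
})
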