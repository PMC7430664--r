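# Sub-seed derivation: a documented counter scheme off one root seed, so each
# species/array gets an independent, reproducible stream and adding an entry
# does not perturb the others. Kept within 32-bit integer range.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + counter) %% 2147483647)
}

#' Generate a synthetic AU-rich RNA sequence with planted motifs
#'
#' Draws an i.i.d. background with per-base probabilities matching the target
#' A+U composition (A = U = `au_fraction`/2, C = G = (1 - `au_fraction`)/2 —
#' the default 0.85 mimics the strongly AT-rich yeast mitochondrial genome),
#' then overwrites the planted motifs at their positions. A post-check redraws
#' the background when it spuriously creates a copy of any planted motif
#' outside its site, or any `forbid` motif outside the planted intervals;
#' the redraw budget fails loudly when exhausted.
#'
#' @param length Sequence length in nt.
#' @param plant Optional data frame with columns `motif` and `start` (1-based)
#'   of motifs to plant; planted motifs must fit and must not overlap.
#' @param au_fraction Target A+U composition in (0, 1) (default 0.85).
#' @param seed Integer seed; the same (seed, arguments) always reproduces the
#'   same sequence.
#' @param id Record id (default `"synthetic"`).
#' @param forbid Character vector of motifs that must not occur anywhere
#'   outside the planted intervals.
#' @param max_redraws Redraw budget (default 100).
#' @return A one-row sequence tibble with columns `id`, `residues`, `length`.
#' @export
gen_sequence <- function(length, plant = NULL, au_fraction = 0.85, seed = 1,
                         id = "synthetic", forbid = character(),
                         max_redraws = 100) {
  stopifnot(length >= 1, au_fraction > 0, au_fraction < 1)
  if (!is.null(plant) && nrow(plant)) {
    plant <- as_tibble(plant)
    stopifnot(all(c("motif", "start") %in% names(plant)))
    plant$motif <- vapply(plant$motif, normalize_rna, character(1))
    plant$end <- plant$start + nchar(plant$motif) - 1L
    if (any(plant$start < 1) || any(plant$end > length)) {
      abort("planted motif does not fit in sequence", class = "pprmotif_validation_error")
    }
    p <- arrange(plant, .data$start)
    if (nrow(p) > 1 && any(p$start[-1] <= p$end[-nrow(p)])) {
      abort("planted motifs overlap", class = "pprmotif_validation_error")
    }
  } else {
    plant <- tibble(motif = character(), start = integer(), end = integer())
  }
  forbid <- vapply(forbid, normalize_rna, character(1), USE.NAMES = FALSE)
  probs <- c(au_fraction / 2, (1 - au_fraction) / 2,
             (1 - au_fraction) / 2, au_fraction / 2)
  set.seed(seed)
  for (attempt in seq_len(max_redraws + 1L)) {
    ch <- sample(.rna_bases, length, replace = TRUE, prob = probs)
    for (i in seq_len(nrow(plant))) {
      ch[plant$start[i]:plant$end[i]] <- strsplit(plant$motif[i], "")[[1]]
    }
    s <- paste(ch, collapse = "")
    if (.plant_clean(s, plant, forbid)) {
      return(tibble(id = id, residues = s, length = nchar(s)))
    }
  }
  abort(
    paste0("redraw budget (", max_redraws, ") exhausted without a clean background"),
    class = "pprmotif_generation_error"
  )
}

# TRUE when every planted motif occurs only at its planted start and every
# forbidden motif occurs only inside planted intervals
#' @keywords internal
#' @noRd
.plant_clean <- function(s, plant, forbid) {
  seqs <- tibble(id = "q", residues = s)
  for (m in unique(plant$motif)) {
    hits <- find_matches(seqs, m)
    want <- sort(as.integer(plant$start[plant$motif == m]))
    if (!identical(sort(as.integer(hits$start)), want)) {
      return(FALSE)
    }
  }
  for (f in forbid) {
    if (nchar(f) > nchar(s)) next
    hits <- find_matches(seqs, f)
    inside <- rep(FALSE, nrow(hits))
    for (i in seq_len(nrow(plant))) {
      inside <- inside | (hits$start >= plant$start[i] & hits$end <= plant$end[i])
    }
    if (any(!inside)) return(FALSE)
  }
  TRUE
}

#' Default synthetic panel plan
#'
#' One reference, three compatible (`required_present`) and six incompatible
#' (`required_absent`) species, echoing the presence/absence structure of a
#' yeast compatibility panel.
#'
#' @return A tibble with columns `species`, `compat_class`, `plant`.
#' @export
default_panel_plan <- function() {
  tibble(
    species = c("ref_sp", paste0("compat_", 1:3), paste0("incompat_", 1:6)),
    compat_class = c("reference", rep("required_present", 3),
                     rep("required_absent", 6)),
    plant = c(rep(TRUE, 4), rep(FALSE, 6))
  )
}

#' Generate a synthetic species panel with planted motifs
#'
#' Builds, from independent per-species sub-seeds, a panel of AU-rich
#' sequences in which each planted motif occurs at `min_loci` well-separated
#' sites in the reference, at one site in every `required_present` species
#' that plants it, and nowhere in any `required_absent` species (enforced by
#' the generator's reject-and-redraw check and verified again by exact search
#' after generation). Planting a motif in a `required_absent` species is
#' refused.
#'
#' @param plan A data frame with columns `species`, `compat_class`, `plant`
#'   (default [default_panel_plan()]).
#' @param motifs Character vector of motifs to plant (default the 14-nt
#'   4x-AUA + AU repeat motif).
#' @param length Per-species sequence length in nt (default 300).
#' @param au_fraction Background A+U composition (default 0.85).
#' @param min_loci Number of distinct reference loci per motif (default 2).
#' @param seed Root integer seed.
#' @return A list with `manifest` (panel manifest tibble) and `seqs`
#'   (sequence tibble, ids equal to species names).
#' @export
gen_panel <- function(plan = default_panel_plan(),
                      motifs = paste0(strrep("AUA", 4), "AU"),
                      length = 300, au_fraction = 0.85, min_loci = 2,
                      seed = 1) {
  plan <- as_tibble(plan)
  stopifnot(all(c("species", "compat_class", "plant") %in% names(plan)))
  if (sum(plan$compat_class == "reference") != 1) {
    abort("plan must contain exactly one reference", class = "pprmotif_validation_error")
  }
  if (any(plan$plant & plan$compat_class == "required_absent")) {
    abort("refusing to plant a motif in a required_absent species",
          class = "pprmotif_validation_error")
  }
  motifs <- vapply(motifs, normalize_rna, character(1), USE.NAMES = FALSE)
  mlen <- nchar(motifs)
  # deterministic, well-separated planting grid
  site_grid <- function(n_sites) {
    round(seq(0.15, 0.8, length.out = max(n_sites, 2))[seq_len(n_sites)] * length)
  }
  # site-specific non-A/U guards flank each planted copy: they keep planted
  # repeat tracts maximal and, because the guards differ between reference
  # sites, no frame-shifted k-mer overlapping a planted motif can recur at
  # min_loci reference loci
  guard_l <- c("G", "C")
  guard_r <- c("C", "G")
  seqs <- purrr::imap(seq_len(nrow(plan)), function(i, ...) {
    cls <- plan$compat_class[i]
    n_sites <- if (!plan$plant[i]) 0L else if (cls == "reference") min_loci else 1L
    plant <- NULL
    if (n_sites > 0) {
      rows <- purrr::imap(motifs, function(m, j) {
        site <- seq_len(n_sites)
        gl <- guard_l[(site - 1L) %% 2L + 1L]
        gr <- guard_r[(site - 1L) %% 2L + 1L]
        tibble(
          motif = paste0(gl, m, gr),
          start = site_grid(n_sites) + (j - 1L) * (max(mlen) + 9L) - 1L
        )
      })
      plant <- bind_rows(rows)
      if (any(plant$start + nchar(plant$motif) - 1L > length) ||
          any(plant$start < 1)) {
        abort("panel length too short for the requested planting",
              class = "pprmotif_validation_error")
      }
    }
    gen_sequence(
      length = length, plant = plant, au_fraction = au_fraction,
      seed = derive_seed(seed, i), id = plan$species[i], forbid = motifs
    )
  })
  seqs <- bind_rows(seqs)
  manifest <- tibble(
    species = plan$species,
    sequence_ref = plan$species,
    compat_class = plan$compat_class
  )
  # verify the advertised presence/absence contract by exact search
  for (m in motifs) {
    for (i in seq_len(nrow(plan))) {
      n_hits <- nrow(find_matches(seqs[i, ], m))
      cls <- plan$compat_class[i]
      ok <- if (cls == "required_absent") n_hits == 0
            else if (plan$plant[i] && cls == "reference") n_hits >= min_loci
            else if (plan$plant[i]) n_hits >= 1
            else TRUE
      if (!ok) {
        abort("generated panel violates its presence/absence contract",
              class = "pprmotif_generation_error")
      }
    }
  }
  list(manifest = validate_panel_manifest(manifest), seqs = seqs)
}

#' Generate a synthetic PPR motif array with planted phase signatures
#'
#' Draws 35-residue motifs with residues uniform over the 20 amino acids, then
#' plants the requested residues at the stated frequency in the stated phase
#' and position (phase A = motifs 1, 4, 7, ...; the number of carriers is
#' `ceiling(freq * phase size)`, chosen at random within the phase).
#'
#' @param n_motifs Number of motifs (at least 3).
#' @param planted Optional data frame with columns `phase` (`"A"`, `"B"` or
#'   `"C"`), `position` (1-35), `residue` (one-letter amino acid), `freq`
#'   in (0, 1].
#' @param seed Integer seed.
#' @param protein_id Protein id for the array (default `"synthetic_ppr"`).
#' @return A PPR array tibble with columns `protein_id`, `motif_index`,
#'   `residues`.
#' @export
gen_ppr_array <- function(n_motifs, planted = NULL, seed = 1,
                          protein_id = "synthetic_ppr") {
  if (n_motifs < 3) {
    abort("n_motifs must be at least 3", class = "pprmotif_validation_error")
  }
  set.seed(derive_seed(seed, 0L))
  mat <- matrix(sample(.aa20, n_motifs * .ppr_motif_len, replace = TRUE),
                nrow = n_motifs)
  if (!is.null(planted) && nrow(planted)) {
    planted <- as_tibble(planted)
    stopifnot(all(c("phase", "position", "residue", "freq") %in% names(planted)))
    if (any(planted$freq <= 0 | planted$freq > 1)) {
      abort("planted freq must be in (0, 1]", class = "pprmotif_validation_error")
    }
    phase_of <- c("C", "A", "B")[(seq_len(n_motifs) %% 3L) + 1L]
    for (i in seq_len(nrow(planted))) {
      members <- which(phase_of == planted$phase[i])
      n_carry <- ceiling(planted$freq[i] * length(members) - 1e-9)
      carriers <- if (n_carry >= length(members)) members
                  else sort(sample(members, n_carry))
      mat[carriers, planted$position[i]] <- planted$residue[i]
    }
  }
  tibble(
    protein_id = protein_id,
    motif_index = seq_len(n_motifs),
    residues = apply(mat, 1, paste, collapse = "")
  )
}

#' Generate a synthetic 15S-scale study sequence
#'
#' A labelled-synthetic surrogate for a mature small-subunit mitochondrial
#' rRNA: 1600 nt at 85% A+U, with a 21-nt (AUA)7 tract planted so its first
#' nucleotide is position 457 and a 14-nt (AUA)4AU motif planted at position
#' 761 — the two recognition loci of the yeast 15S rRNA. Single non-A/U guard
#' bases (distinct between the two sites) flank the planted tracts so they
#' stay maximal, and the 14-nt motif is
#' forbidden elsewhere, so the motif maps to exactly two loci.
#'
#' @param seed Integer seed.
#' @param length Sequence length (default 1600 nt, which an 80/20 tiling
#'   covers with 27 probes).
#' @return A one-row sequence tibble (`id` = `"synthetic_15s"`).
#' @export
gen_study_sequence <- function(seed = 1, length = 1600) {
  motif14 <- paste0(strrep("AUA", 4), "AU")
  gen_sequence(
    length = length,
    plant = tibble(
      motif = c(paste0("G", strrep("AUA", 7), "C"),
                paste0("C", motif14, "G")),
      start = c(456L, 760L)
    ),
    au_fraction = 0.85,
    seed = seed,
    id = "synthetic_15s",
    forbid = motif14
  )
}
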