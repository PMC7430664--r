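#' Enumerate repeated k-mer candidates in a reference sequence
#'
#' Enumerates every distinct k-mer of the reference, merges its (possibly
#' overlapping) occurrences into loci with [collapse_to_loci()] semantics, and
#' retains the k-mers occurring in at least `min_loci` distinct (non-
#' overlapping) regions. Screening at a fixed k is complete for the "at least
#' k nt long" question because any longer conserved motif contains a conserved
#' k-mer. K-mers containing `N` are never candidates.
#'
#' @param ref A one-row data frame with columns `id` and `residues` (the
#'   reference sequence).
#' @param k Candidate length in nt (default 14).
#' @param min_loci Minimum number of distinct merged loci in the reference
#'   (default 2).
#' @return A tibble in lexicographic motif order with columns `motif`,
#'   `n_ref_loci`, `ref_starts` (comma-joined 1-based locus starts) and
#'   `ref_loci` (list column of per-motif locus tibbles).
#' @export
enumerate_candidates <- function(ref, k = 14, min_loci = 2) {
  stopifnot(all(c("id", "residues") %in% names(ref)), nrow(ref) == 1)
  stopifnot(k >= 1, min_loci >= 1)
  s <- ref$residues[[1]]
  len <- nchar(s)
  if (k > len) {
    abort("k exceeds reference length", class = "pprmotif_validation_error")
  }
  starts <- seq_len(len - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  kmers <- kmers[ok]
  starts <- starts[ok]
  # a k-mer needs >= min_loci raw occurrences to reach min_loci loci
  tab <- table(kmers)
  repeated <- names(tab)[tab >= min_loci]
  if (!length(repeated)) {
    return(tibble(
      motif = character(), n_ref_loci = integer(),
      ref_starts = character(), ref_loci = list()
    ))
  }
  cand <- purrr::map(sort(repeated), function(m) {
    pos <- sort(starts[kmers == m])
    loci <- collapse_to_loci(tibble(
      seq_id = ref$id[[1]], start = pos, end = pos + k - 1L, motif = m
    ))
    tibble(
      motif = m,
      n_ref_loci = nrow(loci),
      ref_starts = paste(loci$start, collapse = ","),
      ref_loci = list(select(loci, "start", "end", "n_matches"))
    )
  }) |> bind_rows()
  filter(cand, .data$n_ref_loci >= min_loci)
}

#' Cross-species presence/absence screen of candidate motifs
#'
#' Runs the comparative screen: candidate k-mers from the reference (at least
#' `min_loci` distinct loci) are tested for exact presence in every
#' `required_present` species (orthologs at least partially compatible with
#' the reference mitochondrial genome) and exact absence from every
#' `required_absent` species (completely incompatible orthologs). Presence
#' means one or more exact occurrences anywhere in that species' sequence —
#' a single conserved copy suffices, matching the compatible single-motif
#' species. All candidates are retained in the output with their verdicts for
#' auditability.
#'
#' Species whose sequence is shorter than `k` (incomplete sequences) are
#' excluded from the constraints with a warning rather than failing the
#' screen.
#'
#' @param panel A panel manifest tibble (see [read_panel_manifest()]).
#' @param seqs A data frame of sequences with columns `id`, `residues`; ids
#'   are matched against the manifest's `sequence_ref`, falling back to
#'   `species`.
#' @param k Candidate length in nt (default 14).
#' @param min_loci Minimum distinct reference loci (default 2).
#' @return A tibble with one row per candidate: `motif`, `n_ref_loci`,
#'   `ref_starts`, `ref_loci` (list column), one logical presence column per
#'   constrained species (named `present_<species>`), and `verdict`
#'   (`pass`, `fail_present`, `fail_absent`).
#' @export
run_screen <- function(panel, seqs, k = 14, min_loci = 2) {
  panel <- validate_panel_manifest(panel)
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  resolve <- function(ref, species) {
    i <- match(ref, seqs$id)
    if (is.na(i)) i <- match(species, seqs$id)
    i
  }
  idx <- purrr::map2_int(
    panel$sequence_ref, panel$species,
    function(r, sp) {
      i <- resolve(r, sp)
      if (is.na(i)) NA_integer_ else i
    }
  )
  active <- panel$compat_class != "ignore"
  if (any(active & is.na(idx))) {
    abort(
      paste0(
        "no sequence for manifest species: ",
        paste(panel$species[active & is.na(idx)], collapse = ", ")
      ),
      class = "pprmotif_validation_error"
    )
  }
  ref_row <- which(panel$compat_class == "reference")
  ref <- seqs[idx[ref_row], ]
  cand <- enumerate_candidates(ref, k = k, min_loci = min_loci)

  constrained <- which(panel$compat_class %in%
                         c("required_present", "required_absent"))
  too_short <- constrained[nchar(seqs$residues[idx[constrained]]) < k]
  if (length(too_short)) {
    warn(paste0(
      "species with sequence shorter than k excluded from screen: ",
      paste(panel$species[too_short], collapse = ", ")
    ))
    constrained <- setdiff(constrained, too_short)
  }
  if (!nrow(cand)) {
    cand$verdict <- character(0)
    return(cand)
  }
  pres <- purrr::map(constrained, function(i) {
    stringr::str_detect(
      seqs$residues[idx[i]],
      stringr::fixed(cand$motif)
    )
  })
  names(pres) <- paste0("present_", panel$species[constrained])
  out <- bind_cols(cand, as_tibble(pres))
  need_present <- constrained[panel$compat_class[constrained] == "required_present"]
  need_absent <- constrained[panel$compat_class[constrained] == "required_absent"]
  ok_present <- if (length(need_present)) {
    Reduce(`&`, pres[paste0("present_", panel$species[need_present])])
  } else {
    rep(TRUE, nrow(cand))
  }
  ok_absent <- if (length(need_absent)) {
    !Reduce(`|`, pres[paste0("present_", panel$species[need_absent])])
  } else {
    rep(TRUE, nrow(cand))
  }
  out$verdict <- dplyr::case_when(
    ok_present & ok_absent ~ "pass",
    !ok_present ~ "fail_present",
    .default = "fail_absent"
  )
  out
}

#' Merge passing motifs' reference loci into regions
#'
#' Collapses the reference loci of all passing candidates into maximal
#' regions by span overlap, so the screen's answer is reported as regions of
#' the reference rather than individual k-mers (staggered k-mers inside one
#' repetitive tract form one region).
#'
#' @param results A screen result tibble from [run_screen()] (or a candidate
#'   tibble from [enumerate_candidates()], in which case all rows are treated
#'   as passing).
#' @return A tibble with columns `region`, `start`, `end`, `n_motifs` and
#'   `motifs` (comma-joined passing motifs overlapping the region).
#' @export
group_into_regions <- function(results) {
  if ("verdict" %in% names(results)) {
    results <- filter(results, .data$verdict == "pass")
  }
  if (!nrow(results)) {
    return(tibble(
      region = integer(), start = integer(), end = integer(),
      n_motifs = integer(), motifs = character()
    ))
  }
  spans <- purrr::map2(results$motif, results$ref_loci, function(m, loci) {
    tibble(motif = m, start = loci$start, end = loci$end)
  }) |> bind_rows() |> arrange(.data$start, .data$end)
  spans$region <- cumsum(spans$start > cummax_lag_end(spans$end))
  spans |>
    group_by(.data$region) |>
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_motifs = dplyr::n_distinct(.data$motif),
      motifs = paste(sort(unique(.data$motif)), collapse = ","),
      .groups = "drop"
    )
}
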