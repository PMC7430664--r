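#' Find all exact motif matches
#'
#' Reports every (possibly overlapping) exact occurrence of a motif in each
#' sequence. Matching is literal over the normalised RNA alphabet; `N` in a
#' sequence never matches any motif symbol.
#'
#' @param seqs A data frame of sequences with columns `id` and `residues`.
#' @param motif Motif string over `A`,`C`,`G`,`U` (DNA input is normalised).
#' @param both_strands Also scan the reverse complement (for mtDNA surveys);
#'   matches are reported in the coordinates of the given strand with
#'   `strand = "-"`.
#' @return A tibble with columns `seq_id`, `start`, `end` (1-based inclusive),
#'   `strand`, `motif`, sorted by `seq_id` then `start`.
#' @examples
#' seqs <- tibble::tibble(id = "t", residues = strrep("AUA", 7))
#' find_matches(seqs, strrep("AUA", 4) |> paste0("AU")) # starts 1, 4, 7
#' @export
find_matches <- function(seqs, motif, both_strands = FALSE) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  motif <- normalize_rna(motif)
  if (grepl("N", motif, fixed = TRUE)) {
    abort("motif must not contain N", class = "pprmotif_validation_error")
  }
  if (nchar(motif) < 1) {
    abort("motif must be non-empty", class = "pprmotif_validation_error")
  }
  if (any(nchar(seqs$residues) < nchar(motif))) {
    abort("motif longer than sequence", class = "pprmotif_validation_error")
  }
  scan_one <- function(id, s, pat, strand) {
    hits <- Biostrings::matchPattern(pat, Biostrings::BString(s))
    tibble(
      seq_id = id,
      start = Biostrings::start(hits),
      end = Biostrings::end(hits),
      strand = strand,
      motif = motif
    )
  }
  out <- purrr::map2(seqs$id, seqs$residues, scan_one, pat = motif, strand = "+")
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::RNAString(motif))
    )
    out <- c(
      out,
      purrr::map2(seqs$id, seqs$residues, scan_one, pat = rc, strand = "-")
    )
  }
  arrange(bind_rows(out), .data$seq_id, .data$start)
}

#' Merge overlapping motif matches into loci
#'
#' Matches whose spans overlap by at least one nucleotide are merged into a
#' single locus; a locus therefore counts a repetitive tract once even when it
#' contains several staggered copies of the motif (three overlapping 14-mers
#' inside a 21-nt (AUA)7 tract form one locus).
#'
#' @param matches A tibble of raw matches as returned by [find_matches()].
#' @return A tibble with columns `seq_id`, `start`, `end` (span union),
#'   `n_matches`, `motif`; loci for one motif on one sequence are disjoint and
#'   sorted.
#' @export
collapse_to_loci <- function(matches) {
  need <- c("seq_id", "start", "end", "motif")
  stopifnot(all(need %in% names(matches)))
  if (!nrow(matches)) {
    return(tibble(
      seq_id = character(), start = integer(), end = integer(),
      n_matches = integer(), motif = character()
    ))
  }
  matches |>
    group_by(.data$seq_id, .data$motif) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(new_locus = .data$start > cummax_lag_end(.data$end)) |>
    mutate(locus = cumsum(.data$new_locus)) |>
    group_by(.data$seq_id, .data$motif, .data$locus) |>
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_matches = n(),
      .groups = "drop"
    ) |>
    select("seq_id", "start", "end", "n_matches", "motif") |>
    arrange(.data$seq_id, .data$start)
}

# running maximum of previous ends, -Inf before the first row, so a match
# starting at or before cummax(end) + 1 - 1 overlaps the open locus
#' @keywords internal
#' @noRd
cummax_lag_end <- function(end) {
  c(-Inf, cummax(end)[-length(end)])
}

#' Map motif loci in sequences
#'
#' Convenience composition of [find_matches()] and [collapse_to_loci()].
#'
#' @inheritParams find_matches
#' @return A tibble of merged loci (see [collapse_to_loci()]).
#' @export
find_motif_loci <- function(seqs, motif, both_strands = FALSE) {
  collapse_to_loci(find_matches(seqs, motif, both_strands = both_strands))
}

#' Annotate loci against interval features
#'
#' Pairs each locus with the labels of every interval it overlaps by at least
#' one nucleotide (union semantics: a locus straddling two features gets both
#' labels). Loci overlapping nothing are labelled `"unannotated"`.
#'
#' @param loci A tibble of loci with columns `seq_id`, `start`, `end`.
#' @param intervals A tibble of features with columns `seq_id`, `start`, `end`,
#'   `label` (1-based inclusive; see [read_bed()]).
#' @param seqs Optional sequence tibble used to check that intervals lie within
#'   sequence bounds.
#' @return A tibble with one row per (locus, label) pair: the locus columns
#'   plus `label`.
#' @export
annotate_loci <- function(loci, intervals, seqs = NULL) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(loci)))
  stopifnot(all(c("seq_id", "start", "end", "label") %in% names(intervals)))
  if (!is.null(seqs)) {
    lens <- stats::setNames(nchar(seqs$residues), seqs$id)
    known <- intervals$seq_id %in% names(lens)
    if (any(known &
            (intervals$start < 1 | intervals$end > lens[intervals$seq_id]))) {
      abort("interval out of sequence bounds", class = "pprmotif_validation_error")
    }
  }
  if (!nrow(loci)) {
    return(mutate(loci, label = character(0)))
  }
  hits <- purrr::pmap(
    list(loci$seq_id, loci$start, loci$end, seq_len(nrow(loci))),
    function(sid, s, e, i) {
      ov <- intervals$seq_id == sid & intervals$start <= e & intervals$end >= s
      labs <- unique(intervals$label[ov])
      if (!length(labs)) labs <- "unannotated"
      tibble(row = i, label = labs)
    }
  ) |> bind_rows()
  out <- loci
  out$row <- seq_len(nrow(out))
  out <- left_join(out, hits, by = "row")
  select(out, -"row")
}

#' Design an overlapping tiling of fixed-length probes
#'
#' Tiles `[1, seq_len]` with probes of fixed length stepping by
#' `probe_len - overlap`. The final probe is anchored at the sequence end
#' (shifted left when the last regular start would overrun), so all probes are
#' full length; a shifted final probe is flagged `truncated_overlap`. With the
#' defaults (80-nt probes, 20-nt overlap) a sequence of mature 15S rRNA scale
#' (~1.6 kb) is covered by 27 probes.
#'
#' @param seq_len Sequence length in nt.
#' @param probe_len Probe length in nt (default 80).
#' @param overlap Nominal overlap between consecutive probes in nt (default 20).
#' @param number_from_3prime Number probes descending from the 3' end instead
#'   of ascending from the 5' end (slot-blot convention in which probe #1 is
#'   the 3'-most).
#' @return A tibble with columns `index`, `start`, `end` (1-based inclusive)
#'   and `truncated_overlap`.
#' @examples
#' design_tiling_probes(200) # 3 probes at starts 1, 61, 121
#' @export
design_tiling_probes <- function(seq_len, probe_len = 80, overlap = 20,
                                 number_from_3prime = FALSE) {
  stopifnot(overlap > 0, probe_len > overlap)
  if (seq_len < probe_len) {
    abort("sequence shorter than probe length", class = "pprmotif_validation_error")
  }
  step <- probe_len - overlap
  n <- max(1L, as.integer(ceiling((seq_len - probe_len) / step)) + 1L)
  starts0 <- (seq_len(n) - 1L) * step # 0-based regular grid
  last_regular <- starts0[n]
  starts0[n] <- seq_len - probe_len # anchor the final probe at the end
  idx <- if (number_from_3prime) rev(seq_len(n)) else seq_len(n)
  tibble(
    index = idx,
    start = starts0 + 1L,
    end = starts0 + probe_len,
    truncated_overlap = c(rep(FALSE, n - 1L), starts0[n] != last_regular)
  )
}

#' Tile sequences with probes and extract probe sequences
#'
#' Applies [design_tiling_probes()] to every sequence in `seqs` and attaches
#' the probe subsequence of each window.
#'
#' @param seqs A data frame of sequences with columns `id` and `residues`.
#' @inheritParams design_tiling_probes
#' @return A tibble with columns `seq_id`, `index`, `start`, `end`,
#'   `truncated_overlap`, `probe_seq`.
#' @export
tile_probes <- function(seqs, probe_len = 80, overlap = 20,
                        number_from_3prime = FALSE) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  purrr::map2(seqs$id, seqs$residues, function(id, s) {
    tiles <- design_tiling_probes(
      nchar(s), probe_len, overlap,
      number_from_3prime = number_from_3prime
    )
    tiles$seq_id <- id
    tiles$probe_seq <- substring(s, tiles$start, tiles$end)
    tiles
  }) |>
    bind_rows() |>
    select("seq_id", "index", "start", "end", "truncated_overlap", "probe_seq")
}
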