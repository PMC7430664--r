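#' @keywords internal
#' @noRd
check_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1 || nchar(unit) != 3) {
    abort("unit must be a single trinucleotide", class = "pprmotif_validation_error")
  }
  unit <- normalize_rna(unit)
  if (grepl("N", unit, fixed = TRUE)) {
    abort("unit must not contain N", class = "pprmotif_validation_error")
  }
  rot <- unit_rotations(unit)
  if (length(unique(rot)) != 3) {
    abort(
      "homopolymer units are not supported (rotations must be distinct)",
      class = "pprmotif_validation_error"
    )
  }
  unit
}

#' @keywords internal
#' @noRd
unit_rotations <- function(unit) {
  c(
    unit,
    paste0(substr(unit, 2, 3), substr(unit, 1, 1)),
    paste0(substr(unit, 3, 3), substr(unit, 1, 2))
  )
}

# Decompose a string as prefix + unit^n + suffix. Returns NULL when the string
# is not decomposable with n >= 1. Tie-break: maximal n, then minimal prefix.
#' @keywords internal
#' @noRd
decompose_tract <- function(x, unit) {
  len <- nchar(x)
  best <- NULL
  for (p in 0:2) {
    if (p + 3 > len) next
    # prefix must be a proper suffix of the unit
    if (p > 0 && substr(x, 1, p) != substr(unit, 3 - p + 1, 3)) next
    n <- 0L
    at <- p + 1L
    while (at + 2L <= len && substr(x, at, at + 2L) == unit) {
      n <- n + 1L
      at <- at + 3L
    }
    if (n < 1L) next
    suffix <- substr(x, at, len)
    # suffix must be a proper prefix of the unit
    if (nchar(suffix) >= 3 || (nchar(suffix) > 0 &&
                               suffix != substr(unit, 1, nchar(suffix)))) next
    # full decomposition must cover the string
    if (p + 3L * n + nchar(suffix) != len) next
    cand <- list(prefix = substr(x, 1, p), n_full = n, suffix = suffix)
    if (is.null(best) || cand$n_full > best$n_full ||
        (cand$n_full == best$n_full && nchar(cand$prefix) < nchar(best$prefix))) {
      best <- cand
    }
  }
  best
}

#' Classify a repeat-tract string into its canonical label
#'
#' Decomposes a string as `prefix + unit^n + suffix` (prefix a proper suffix of
#' the unit, suffix a proper prefix) and renders the canonical nomenclature
#' used for AUA tracts, e.g. `"UA(AUA)3"` or `"(AUA)2A"`. When several
#' decompositions exist the one with maximal `n` and then minimal prefix is
#' chosen, which makes labels unique.
#'
#' @param tract_string The tract substring.
#' @param unit The canonical trinucleotide unit, e.g. `"AUA"`.
#' @return The canonical label string.
#' @examples
#' classify_tract("AUAAUAA", "AUA") # "(AUA)2A"
#' @export
classify_tract <- function(tract_string, unit) {
  unit <- check_unit(unit)
  tract_string <- normalize_rna(tract_string)
  d <- decompose_tract(tract_string, unit)
  if (is.null(d)) {
    abort(
      paste0("not decomposable as prefix+", unit, "^n+suffix: ", tract_string),
      class = "pprmotif_validation_error"
    )
  }
  paste0(d$prefix, "(", unit, ")", d$n_full, d$suffix)
}

# Maximal period-3 tracts in one residue string; 1-based inclusive coordinates.
#' @keywords internal
#' @noRd
scan_tracts_one <- function(residues, unit, min_full) {
  len <- nchar(residues)
  if (len < 6) {
    return(tibble(
      start = integer(), end = integer(), tract = character(),
      prefix = character(), n_full = integer(), suffix = character(),
      label = character()
    ))
  }
  ch <- strsplit(residues, "")[[1]]
  rot <- unit_rotations(unit)
  # period-3 self-match; N never matches anything, terminating tracts
  m <- ch[1:(len - 3)] == ch[4:len] & ch[1:(len - 3)] != "N"
  r <- rle(m)
  ends_m <- cumsum(r$lengths)
  starts_m <- ends_m - r$lengths + 1L
  keep <- which(r$values)
  rows <- list()
  for (j in keep) {
    s <- starts_m[j]
    e <- ends_m[j] + 3L # inclusive end of the periodic interval
    # under period 3 every aligned window is a rotation of the first one,
    # so one membership check decides the whole run
    if (!(substr(residues, s, s + 2L) %in% rot)) next
    tract <- substr(residues, s, e)
    d <- decompose_tract(tract, unit)
    if (is.null(d) || d$n_full < min_full) next
    rows[[length(rows) + 1L]] <- tibble(
      start = s, end = e, tract = tract,
      prefix = d$prefix, n_full = d$n_full, suffix = d$suffix,
      label = paste0(d$prefix, "(", unit, ")", d$n_full, d$suffix)
    )
  }
  if (!length(rows)) {
    return(tibble(
      start = integer(), end = integer(), tract = character(),
      prefix = character(), n_full = integer(), suffix = character(),
      label = character()
    ))
  }
  arrange(bind_rows(rows), .data$start)
}

#' Find maximal trinucleotide repeat tracts
#'
#' Scans each sequence for maximal intervals with period 3 whose aligned
#' 3-windows are rotations of `unit`, and decomposes each interval canonically
#' as `prefix + unit^n + suffix`. Intervals are maximal (extending them by one
#' residue on either side breaks the periodicity or the rotation condition)
#' and sorted by start; two adjacent maximal tracts in different phases can
#' share at most a 2-residue partial flank, never a complete unit. Tracts with
#' fewer than `min_full`
#' complete units are discarded; the default of 2 reflects the smallest
#' category worth reporting for a 3-nt unit (6 nt).
#'
#' @param seqs A data frame of sequences with columns `id` and `residues`
#'   (as returned by [read_fasta()] or [gen_sequence()]).
#' @param unit Canonical trinucleotide unit (default `"AUA"`). Homopolymer
#'   units are rejected.
#' @param min_full Minimum number of complete units (default 2).
#' @return A tibble with columns `seq_id`, `start`, `end` (1-based inclusive),
#'   `length`, `tract`, `prefix`, `n_full`, `suffix`, `label`.
#' @examples
#' seqs <- tibble::tibble(id = "x", residues = "UAAUAAUAAUA")
#' find_repeat_tracts(seqs) # one tract labelled UA(AUA)3
#' @export
find_repeat_tracts <- function(seqs, unit = "AUA", min_full = 2) {
  unit <- check_unit(unit)
  stopifnot(all(c("id", "residues") %in% names(seqs)), min_full >= 1)
  out <- purrr::map2(seqs$id, seqs$residues, function(id, s) {
    tr <- scan_tracts_one(s, unit, min_full)
    if (nrow(tr)) tr$seq_id <- id
    tr
  })
  out <- bind_rows(out)
  if (!nrow(out)) {
    return(tibble(
      seq_id = character(), start = integer(), end = integer(),
      length = integer(), tract = character(), prefix = character(),
      n_full = integer(), suffix = character(), label = character()
    ))
  }
  out$length <- out$end - out$start + 1L
  select(
    out, "seq_id", "start", "end", "length",
    "tract", "prefix", "n_full", "suffix", "label"
  )
}

#' Census of repeat tracts by canonical label
#'
#' Runs [find_repeat_tracts()] and tallies tracts by their canonical label.
#' On the mature yeast mitochondrial 15S rRNA this census reproduces the
#' catalogue of short AUA tracts surrounding the two long recognition motifs.
#'
#' @inheritParams find_repeat_tracts
#' @return A tibble with columns `label` and `n`, ordered by decreasing count
#'   then label; the counts sum to the number of tracts.
#' @export
repeat_census <- function(seqs, unit = "AUA", min_full = 2) {
  tr <- find_repeat_tracts(seqs, unit = unit, min_full = min_full)
  if (!nrow(tr)) {
    return(tibble(label = character(), n = integer()))
  }
  arrange(count(tr, .data$label), dplyr::desc(.data$n), .data$label)
}
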