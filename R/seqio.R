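#' Read nucleotide sequences from a FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file and normalises every
#' record to the uppercase RNA alphabet: `T` is mapped to `U`, and any IUPAC
#' ambiguity letter other than `N` (e.g. `R`, `Y`, `W`) is mapped to `N` with a
#' warning. Record order is preserved.
#'
#' DNA input is accepted silently because organellar data sets routinely mix
#' mtDNA (T) and mature rRNA (U) alphabets; after normalisation all downstream
#' operations work in RNA space. `N` never matches any motif symbol and
#' terminates repeat tracts, so exact-match counts stay well defined.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `id` (first whitespace
#'   token of the header), `residues` (normalised sequence string over
#'   `A`,`C`,`G`,`U`,`N`) and `length`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "auat"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "pprmotif_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort("FASTA file contains no records", class = "pprmotif_io_error")
  }
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1)
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("FASTA record with empty id", class = "pprmotif_io_error")
  }
  if (anyDuplicated(ids)) {
    abort(
      paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]),
      class = "pprmotif_io_error"
    )
  }
  res <- vapply(as.character(set), normalize_rna, character(1), USE.NAMES = FALSE)
  if (any(nchar(res) == 0)) {
    abort(
      paste0("zero-length sequence for record: ", ids[nchar(res) == 0][1]),
      class = "pprmotif_io_error"
    )
  }
  tibble(id = ids, residues = res, length = nchar(res))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A data frame with columns `id` and `residues`.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` writes one line per record.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  lines <- unlist(purrr::map2(seqs$id, seqs$residues, function(id, s) {
    body <- if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1, nchar(s)))
    } else {
      s
    }
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Uppercases, maps `T` to `U`, and maps ambiguity letters other than `N` to
#' `N` (with a warning). Idempotent.
#'
#' @param x A single sequence string.
#' @return The normalised string over `A`,`C`,`G`,`U`,`N`.
#' @export
normalize_rna <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  if (grepl("[^ACGUN]", x)) {
    bad <- unique(strsplit(gsub("[ACGUN]", "", x), "")[[1]])
    warn(paste0(
      "ambiguity symbol(s) ", paste(bad, collapse = ","),
      " mapped to N"
    ))
    x <- gsub("[^ACGUN]", "N", x)
  }
  x
}

#' Write a tibble as a TSV file
#'
#' Header plus one tab-separated line per row, UTF-8, no locale-dependent
#' number formatting. Zero rows produce a header-only file.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(rows, path) {
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Read a TSV file written by [write_tsv_table()]
#'
#' @param path Path to a TSV file with a header line.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

.compat_classes <- c("reference", "required_present", "required_absent", "ignore")

#' Read a species-panel manifest
#'
#' The manifest is a TSV with columns `species`, `sequence_ref` and
#' `compat_class` assigning each species a nucleo-mitochondrial compatibility
#' class: `reference` (exactly one; the sequence the screen enumerates),
#' `required_present` (orthologs at least partially compatible with the
#' reference mitochondrial genome; candidate motifs must occur in their
#' sequence), `required_absent` (completely incompatible orthologs; candidates
#' must be absent), or `ignore` (kept in the table but excluded from all
#' constraints).
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with columns `species`, `sequence_ref`, `compat_class`.
#' @export
read_panel_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("manifest not found: ", path), class = "pprmotif_io_error")
  }
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_panel_manifest(m)
}

#' Validate a species-panel manifest
#'
#' @param manifest A data frame with columns `species`, `sequence_ref`,
#'   `compat_class`.
#' @return The validated manifest as a tibble.
#' @export
validate_panel_manifest <- function(manifest) {
  need <- c("species", "sequence_ref", "compat_class")
  if (!all(need %in% names(manifest))) {
    abort(
      paste0(
        "manifest must have columns ",
        paste(need, collapse = ", ")
      ),
      class = "pprmotif_validation_error"
    )
  }
  bad <- setdiff(unique(manifest$compat_class), .compat_classes)
  if (length(bad)) {
    abort(
      paste0("unknown compat_class: ", paste(bad, collapse = ", ")),
      class = "pprmotif_validation_error"
    )
  }
  n_ref <- sum(manifest$compat_class == "reference")
  if (n_ref != 1) {
    abort(
      paste0("manifest must contain exactly one reference entry, found ", n_ref),
      class = "pprmotif_validation_error"
    )
  }
  if (anyDuplicated(manifest$species)) {
    abort(
      paste0(
        "duplicate species in manifest: ",
        manifest$species[duplicated(manifest$species)][1]
      ),
      class = "pprmotif_validation_error"
    )
  }
  as_tibble(manifest[, need])
}

#' Read BED3+label interval annotations
#'
#' BED uses 0-based half-open coordinates; the returned tibble uses the 1-based
#' inclusive convention of the rest of the package (conversion happens here, at
#' the format boundary).
#'
#' @param path Path to a BED file with at least 4 columns
#'   (chrom, chromStart, chromEnd, name) and optionally a 6th strand column.
#' @return A tibble with columns `seq_id`, `start`, `end` (1-based inclusive),
#'   `label`, `strand` (`+`, `-` or `*`).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BED file not found: ", path), class = "pprmotif_io_error")
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 4) {
    abort("BED3+label requires at least 4 columns", class = "pprmotif_io_error")
  }
  strand <- if (ncol(raw) >= 6) raw[[6]] else rep("*", nrow(raw))
  tibble(
    seq_id = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]]),
    label = as.character(raw[[4]]),
    strand = ifelse(strand %in% c("+", "-"), strand, "*")
  )
}

#' Write intervals as BED3+label
#'
#' Converts the package's 1-based inclusive `start`/`end` columns to BED's
#' 0-based half-open convention.
#'
#' @param intervals A data frame with columns `seq_id`, `start`, `end` and
#'   optionally `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(intervals)))
  label <- if ("label" %in% names(intervals)) intervals$label else "."
  out <- data.frame(
    chrom = intervals$seq_id,
    start = as.integer(intervals$start) - 1L,
    end = as.integer(intervals$end),
    name = label
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
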