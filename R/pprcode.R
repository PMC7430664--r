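.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.ppr_motif_len <- 35L

#' Read a PPR motif-array table
#'
#' PPR proteins are tandem arrays of ~35-residue helix-turn-helix motifs.
#' Motif boundaries are an input (taken from external motif-prediction or
#' structural analysis), supplied as a TSV with columns `protein_id`,
#' `motif_index` (1-based, consecutive, N-to-C order) and `residues`
#' (35 one-letter amino acids; gaps as `X`).
#'
#' @param path Path to the TSV file.
#' @return A validated tibble with columns `protein_id`, `motif_index`,
#'   `residues`.
#' @export
read_ppr_array <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("array table not found: ", path), class = "pprmotif_io_error")
  }
  arr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_ppr_array(arr)
}

#' Validate a PPR motif-array tibble
#'
#' @param array A data frame with columns `protein_id`, `motif_index`,
#'   `residues`.
#' @return The validated tibble, ordered by `motif_index`.
#' @export
validate_ppr_array <- function(array) {
  need <- c("protein_id", "motif_index", "residues")
  if (!all(need %in% names(array))) {
    abort(
      paste0("array must have columns ", paste(need, collapse = ", ")),
      class = "pprmotif_validation_error"
    )
  }
  array <- arrange(as_tibble(array[, need]), .data$motif_index)
  if (nrow(array) < 2) {
    abort("array must contain at least 2 motifs", class = "pprmotif_validation_error")
  }
  if (any(nchar(array$residues) != .ppr_motif_len)) {
    abort(
      paste0("every motif must have exactly ", .ppr_motif_len, " residues"),
      class = "pprmotif_validation_error"
    )
  }
  if (!identical(as.integer(array$motif_index), seq_len(nrow(array)))) {
    abort(
      "motif_index must be consecutive starting at 1",
      class = "pprmotif_validation_error"
    )
  }
  bad <- grepl(paste0("[^", paste(c(.aa20, "X"), collapse = ""), "]"),
               toupper(array$residues))
  if (any(bad)) {
    abort(
      "residues must be one-letter amino acids (gaps as X)",
      class = "pprmotif_validation_error"
    )
  }
  mutate(array, residues = toupper(.data$residues))
}

#' Phase-stratified conservation profiles of a PPR array
#'
#' Groups every third motif of the array into three phases — phase A starts
#' from the first motif (`motif_index` 1, 4, 7, ...), phase B from the second,
#' phase C from the third — mirroring the trinucleotide periodicity of the RNA
#' target. For each phase it computes the per-position amino-acid frequency
#' matrix (35 positions by 20 residues) and the information content
#' `IC_j = log2(20) + sum_a f_a log2 f_a` in bits, with `X`/gap residues
#' excluded from the column and no small-sample correction.
#'
#' @param array A validated PPR array tibble (see [read_ppr_array()]).
#' @return An object of class `ppr_phase_profiles`: a list with `counts`
#'   (named list of 35 x 20 count matrices per phase), `freq` (long tibble of
#'   per-position residue frequencies) and `info` (tibble of per-position
#'   information content with the phase size). Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @export
phase_profiles <- function(array) {
  array <- validate_ppr_array(array)
  if (nrow(array) < 3) {
    abort("phase analysis needs at least 3 motifs", class = "pprmotif_validation_error")
  }
  phase_of <- c("C", "A", "B")[(array$motif_index %% 3L) + 1L]
  counts <- lapply(c(A = "A", B = "B", C = "C"), function(ph) {
    res <- array$residues[phase_of == ph]
    mat <- matrix(0L, nrow = .ppr_motif_len, ncol = length(.aa20),
                  dimnames = list(position = NULL, residue = .aa20))
    for (r in res) {
      ch <- strsplit(r, "")[[1]]
      keep <- ch %in% .aa20
      idx <- cbind(which(keep), match(ch[keep], .aa20))
      for (row in seq_len(nrow(idx))) {
        mat[idx[row, 1], idx[row, 2]] <- mat[idx[row, 1], idx[row, 2]] + 1L
      }
    }
    mat
  })
  freq <- purrr::imap(counts, function(mat, ph) {
    tot <- rowSums(mat)
    f <- sweep(mat, 1, pmax(tot, 1L), "/")
    tibble(
      phase = ph,
      position = rep(seq_len(.ppr_motif_len), times = length(.aa20)),
      residue = rep(.aa20, each = .ppr_motif_len),
      count = as.integer(mat),
      freq = as.numeric(f)
    )
  }) |> bind_rows()
  info <- purrr::imap(counts, function(mat, ph) {
    tot <- rowSums(mat)
    f <- sweep(mat, 1, pmax(tot, 1L), "/")
    ent <- -rowSums(ifelse(f > 0, f * log2(f), 0))
    tibble(
      phase = ph,
      position = seq_len(.ppr_motif_len),
      n_obs = as.integer(tot),
      ic = ifelse(tot > 0, log2(length(.aa20)) - ent, NA_real_)
    )
  }) |> bind_rows()
  structure(
    list(
      protein_id = array$protein_id[[1]],
      n_motifs = nrow(array),
      counts = counts,
      freq = freq,
      info = info
    ),
    class = "ppr_phase_profiles"
  )
}

#' @exportS3Method generics::tidy
tidy.ppr_phase_profiles <- function(x, ...) {
  left_join(x$freq, x$info, by = c("phase", "position"))
}

#' @exportS3Method generics::glance
glance.ppr_phase_profiles <- function(x, ...) {
  x$info |>
    group_by(.data$phase) |>
    summarise(
      n_motifs = max(.data$n_obs),
      max_ic = max(.data$ic, na.rm = TRUE),
      argmax_position = .data$position[which.max(.data$ic)],
      .groups = "drop"
    )
}

#' @export
print.ppr_phase_profiles <- function(x, ...) {
  cat("Phase-stratified PPR conservation profiles for", x$protein_id,
      "(", x$n_motifs, "motifs )\n")
  print(glance(x))
  invisible(x)
}

#' Detect conserved phase/position signatures
#'
#' Reports every (phase, position, residue) triple where a single residue
#' reaches at least `min_freq` of the motifs in that phase — the pattern that
#' reveals, e.g., conserved aspartate at position 1 and asparagine at position
#' 6 of every third motif.
#'
#' @param profiles A `ppr_phase_profiles` object from [phase_profiles()].
#' @param min_freq Minimum within-phase frequency of the residue
#'   (default 0.8). The threshold is inclusive.
#' @return A tibble with columns `phase`, `position`, `residue`, `freq`.
#' @export
detect_signature <- function(profiles, min_freq = 0.8) {
  stopifnot(inherits(profiles, "ppr_phase_profiles"))
  profiles$freq |>
    filter(.data$count > 0, .data$freq >= min_freq) |>
    select("phase", "position", "residue", "freq") |>
    arrange(.data$phase, .data$position, .data$residue)
}

#' Default PPR code table
#'
#' Encodes only the two single-residue rules with direct support for yeast
#' PPR motifs: asparagine at position 6 of a motif indicates affinity for
#' pyrimidines (U or C), and aspartate at position 1 of the following motif
#' indicates affinity for keto-group nucleotides (U or G). Pair rules are
#' empty by default; the fuller plant pair code can be loaded from a TSV with
#' [read_code_table()]. All weight vectors are non-negative and sum to 1.
#'
#' @return A list of class `ppr_code_table` with elements `pair` (tibble with
#'   columns `aa6`, `aa1_next`, `A`, `C`, `G`, `U`), `six` and `one`
#'   (single-residue rule tibbles with columns `aa`, `A`, `C`, `G`, `U`).
#' @export
default_code_table <- function() {
  structure(
    list(
      pair = tibble(
        aa6 = character(), aa1_next = character(),
        A = numeric(), C = numeric(), G = numeric(), U = numeric()
      ),
      six = tibble(aa = "N", A = 0, C = 0.5, G = 0, U = 0.5),
      one = tibble(aa = "D", A = 0, C = 0, G = 0.5, U = 0.5)
    ),
    class = "ppr_code_table"
  )
}

#' Read a PPR code table from TSV
#'
#' The TSV has columns `rule_type` (`pair`, `six` or `one`), `aa6`,
#' `aa1_next` (used by `pair` rules; `six` rules read `aa6`, `one` rules read
#' `aa1_next`) and weight columns `A`, `C`, `G`, `U`. Each weight vector must
#' be non-negative and sum to 1.
#'
#' @param path Path to the TSV file.
#' @return A `ppr_code_table` list (see [default_code_table()]).
#' @export
read_code_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("rule_type", "A", "C", "G", "U")
  if (!all(need %in% names(tab))) {
    abort("code table must have columns rule_type, A, C, G, U",
          class = "pprmotif_validation_error")
  }
  w <- as.matrix(tab[, .rna_bases])
  if (any(w < 0) || any(abs(rowSums(w) - 1) > 1e-8)) {
    abort("each code weight vector must be non-negative and sum to 1",
          class = "pprmotif_validation_error")
  }
  pick <- function(type) tab[tab$rule_type == type, , drop = FALSE]
  pr <- pick("pair")
  sx <- pick("six")
  on <- pick("one")
  structure(
    list(
      pair = tibble(
        aa6 = as.character(pr$aa6), aa1_next = as.character(pr$aa1_next),
        A = pr$A, C = pr$C, G = pr$G, U = pr$U
      ),
      six = tibble(aa = as.character(sx$aa6), A = sx$A, C = sx$C,
                   G = sx$G, U = sx$U),
      one = tibble(aa = as.character(on$aa1_next), A = on$A, C = on$C,
                   G = on$G, U = on$U)
    ),
    class = "ppr_code_table"
  )
}

#' Derive a nucleotide-preference binding profile from a PPR array
#'
#' A protein of N PPR motifs is expected to recognise a sequence of N - 1
#' nucleotides: target position i is specified jointly by the residue at
#' position 6 of motif i and the residue at position 1 of motif i + 1. For
#' each target position the pair rule is looked up first; failing that, the
#' single-residue rules for the two positions are intersected by a
#' renormalised elementwise product (N6 pyrimidine preference intersected with
#' D1' keto preference concentrates on U); if no rule fires — or the
#' intersection is empty — the position falls back to uniform weights.
#'
#' @param array A validated PPR array tibble.
#' @param code A `ppr_code_table` (default [default_code_table()]).
#' @return An object of class `ppr_binding_profile`: list with `weights`
#'   ((N-1) x 4 matrix over A,C,G,U, rows summing to 1), `provenance`
#'   (which rule fired per position) and `protein_id`. Use [tidy()] /
#'   [glance()] / [autoplot()] on it.
#' @export
binding_profile <- function(array, code = default_code_table()) {
  array <- validate_ppr_array(array)
  stopifnot(inherits(code, "ppr_code_table"))
  n <- nrow(array)
  aa6 <- substr(array$residues, 6, 6)
  aa1 <- substr(array$residues, 1, 1)
  uniform <- stats::setNames(rep(0.25, 4), .rna_bases)
  rule_vec <- function(tab, key_col, key) {
    i <- match(key, tab[[key_col]])
    if (is.na(i)) return(NULL)
    unlist(tab[i, .rna_bases])
  }
  w <- matrix(NA_real_, nrow = n - 1L, ncol = 4,
              dimnames = list(NULL, .rna_bases))
  prov <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    key6 <- aa6[i]
    key1 <- aa1[i + 1L]
    pv <- NULL
    if (nrow(code$pair)) {
      j <- which(code$pair$aa6 == key6 & code$pair$aa1_next == key1)
      if (length(j)) pv <- unlist(code$pair[j[1], .rna_bases])
    }
    if (!is.null(pv)) {
      w[i, ] <- pv
      prov[i] <- "pair"
      next
    }
    v6 <- rule_vec(code$six, "aa", key6)
    v1 <- rule_vec(code$one, "aa", key1)
    if (!is.null(v6) && !is.null(v1)) {
      pr <- v6 * v1
      if (sum(pr) > 0) {
        w[i, ] <- pr / sum(pr)
        prov[i] <- "six*one"
      } else {
        w[i, ] <- uniform
        prov[i] <- "conflict_uniform"
      }
    } else if (!is.null(v6)) {
      w[i, ] <- v6
      prov[i] <- "six"
    } else if (!is.null(v1)) {
      w[i, ] <- v1
      prov[i] <- "one"
    } else {
      w[i, ] <- uniform
      prov[i] <- "uniform"
    }
  }
  structure(
    list(
      protein_id = array$protein_id[[1]],
      weights = w,
      provenance = prov
    ),
    class = "ppr_binding_profile"
  )
}

#' @exportS3Method generics::tidy
tidy.ppr_binding_profile <- function(x, ...) {
  n <- nrow(x$weights)
  tibble(
    position = rep(seq_len(n), times = 4),
    base = rep(.rna_bases, each = n),
    weight = as.numeric(x$weights),
    provenance = rep(x$provenance, times = 4)
  ) |> arrange(.data$position, .data$base)
}

#' @exportS3Method generics::glance
glance.ppr_binding_profile <- function(x, ...) {
  tibble(
    protein_id = x$protein_id,
    n_positions = nrow(x$weights),
    n_informative = sum(x$provenance != "uniform"),
    top_base_mode = names(which.max(table(
      .rna_bases[apply(x$weights, 1, which.max)]
    )))
  )
}

#' @export
print.ppr_binding_profile <- function(x, ...) {
  cat("PPR binding profile for", x$protein_id, "—",
      nrow(x$weights), "target positions\n")
  consensus <- apply(x$weights, 1, function(v) {
    if (max(v) <= 0.25 + 1e-9) "n" else .rna_bases[which.max(v)]
  })
  cat("consensus:", paste(consensus, collapse = ""), "\n")
  invisible(x)
}

#' Scan RNA with a binding profile by log-odds scoring
#'
#' Slides the profile along each sequence and scores every window as
#' `sum_i log2(max(w_i[base], eps) / background[base])` in bits. The floor
#' `eps` keeps scores finite at zero-weight bases (standard position-weight-
#' matrix practice); `N` in a window scores as a floored base. A window's
#' score depends only on the window itself.
#'
#' @param profile A `ppr_binding_profile`.
#' @param seqs A data frame of sequences with columns `id`, `residues`.
#' @param background Background base weights over A,C,G,U (default uniform).
#' @param eps Weight floor (default 1e-3).
#' @return A tibble with columns `seq_id`, `start`, `end`, `score` and
#'   `is_best` (the maximal-score window per sequence, leftmost on ties),
#'   sorted by `seq_id` then `start`.
#' @export
scan_rna <- function(profile, seqs, background = c(A = 0.25, C = 0.25,
                                                   G = 0.25, U = 0.25),
                     eps = 1e-3) {
  stopifnot(inherits(profile, "ppr_binding_profile"))
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  background <- background[.rna_bases]
  stopifnot(!anyNA(background), all(background > 0))
  m <- nrow(profile$weights)
  if (any(nchar(seqs$residues) < m)) {
    abort("profile longer than sequence", class = "pprmotif_validation_error")
  }
  # per-position log-odds, with an extra column for N (floored weight)
  lw <- log2(pmax(profile$weights, eps))
  lodds <- sweep(lw, 2, log2(background), "-")
  lodds <- cbind(lodds, N = log2(eps) - log2(min(background)))
  out <- purrr::map2(seqs$id, seqs$residues, function(id, s) {
    ch <- strsplit(s, "")[[1]]
    code <- match(ch, c(.rna_bases, "N"))
    code[is.na(code)] <- 5L
    nwin <- length(ch) - m + 1L
    scores <- vapply(seq_len(nwin), function(w) {
      sum(lodds[cbind(seq_len(m), code[w:(w + m - 1L)])])
    }, numeric(1))
    tibble(
      seq_id = id,
      start = seq_len(nwin),
      end = seq_len(nwin) + m - 1L,
      score = scores,
      is_best = seq_len(nwin) == which.max(scores)
    )
  })
  bind_rows(out)
}
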