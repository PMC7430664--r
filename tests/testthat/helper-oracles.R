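# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own scanning code paths: they test
# every substring/window directly.

# All maximal prefix+unit^n+suffix substrings of s, found by comparing every
# substring against the infinite repeat of the unit at each of the 3 phases,
# then keeping containment-maximal intervals. O(L^2) windows.
oracle_tracts <- function(s, unit = "AUA", min_full = 2) {
  len <- nchar(s)
  inf <- strrep(unit, ceiling(len / 3) + 2)
  keep <- list()
  for (i in seq_len(len)) {
    ends <- i:len
    subs <- substring(s, i, ends)
    for (r in 1:3) {
      ref <- substring(inf, r, r + (ends - i))
      hit <- subs == ref
      if (!any(hit)) next
      pre <- (3 - r + 1) %% 3
      for (j in ends[hit]) {
        n <- (j - i + 1 - pre) %/% 3
        if (n >= min_full) {
          keep[[length(keep) + 1]] <- c(start = i, end = j)
        }
      }
    }
  }
  if (!length(keep)) {
    return(data.frame(start = integer(), end = integer()))
  }
  iv <- unique(do.call(rbind, keep))
  maximal <- vapply(seq_len(nrow(iv)), function(a) {
    !any(iv[, "start"] <= iv[a, "start"] & iv[, "end"] >= iv[a, "end"] &
           (iv[, "start"] != iv[a, "start"] | iv[, "end"] != iv[a, "end"]))
  }, logical(1))
  iv <- iv[maximal, , drop = FALSE]
  iv <- iv[order(iv[, "start"]), , drop = FALSE]
  data.frame(start = as.integer(iv[, "start"]), end = as.integer(iv[, "end"]))
}

# naive double-loop exact matcher
oracle_matches <- function(s, motif) {
  len <- nchar(s)
  k <- nchar(motif)
  if (k > len) return(integer())
  starts <- seq_len(len - k + 1)
  starts[substring(s, starts, starts + k - 1) == motif]
}

# independent interval merging by pairwise sweep
oracle_merge <- function(starts, k) {
  if (!length(starts)) return(data.frame(start = integer(), end = integer()))
  starts <- sort(starts)
  ends <- starts + k - 1
  out <- list(c(starts[1], ends[1]))
  for (i in seq_along(starts)[-1]) {
    last <- out[[length(out)]]
    if (starts[i] <= last[2] + 0) { # >=1 nt overlap
      out[[length(out)]][2] <- max(last[2], ends[i])
    } else {
      out[[length(out) + 1]] <- c(starts[i], ends[i])
    }
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# per-k-mer brute-force screen: every k-mer of the reference tested
# independently against the panel constraints
oracle_screen_pass <- function(manifest, seqs, k = 14, min_loci = 2) {
  get_seq <- function(sp) seqs$residues[match(sp, seqs$id)]
  ref_sp <- manifest$species[manifest$compat_class == "reference"]
  ref <- get_seq(ref_sp)
  kmers <- unique(substring(ref, seq_len(nchar(ref) - k + 1),
                            seq_len(nchar(ref) - k + 1) + k - 1))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  need_p <- manifest$species[manifest$compat_class == "required_present"]
  need_a <- manifest$species[manifest$compat_class == "required_absent"]
  need_p <- need_p[nchar(vapply(need_p, get_seq, character(1))) >= k]
  need_a <- need_a[nchar(vapply(need_a, get_seq, character(1))) >= k]
  pass <- character()
  for (m in kmers) {
    loci <- oracle_merge(oracle_matches(ref, m), k)
    if (nrow(loci) < min_loci) next
    if (!all(vapply(need_p, function(sp) grepl(m, get_seq(sp), fixed = TRUE),
                    logical(1)))) next
    if (any(vapply(need_a, function(sp) grepl(m, get_seq(sp), fixed = TRUE),
                   logical(1)))) next
    pass <- c(pass, m)
  }
  sort(pass)
}

# seeded AU-rich random sequence for property tests (independent of synth)
random_au_seq <- function(len, au = 0.85) {
  paste(sample(c("A", "U", "C", "G"), len, replace = TRUE,
               prob = c(au / 2, au / 2, (1 - au) / 2, (1 - au) / 2)),
        collapse = "")
}
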