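# pprmotif

Tools for locating and characterising tandem trinucleotide-repeat motifs in
AU-rich organellar RNAs, and for relating them to the modular RNA-recognition
code of pentatricopeptide repeat (PPR) proteins.

## The problem

The yeast mitochondrial PPR protein Dmr1 (Ccm1) is essential for the
stability of the small-subunit ribosomal RNA (15S rRNA). Its recognition
site is a repetitive motif built from AUA triplets: a minimal 14-nt
(AUA)₄AU element, present twice in the mature 15S rRNA — once inside a
longer 21-nt (AUA)₇ tract — against a background of many shorter AUA
repeats. Presence of this motif in the 15S rRNA of related yeast species
tracks the compatibility of their Dmr1 orthologs with the *S. cerevisiae*
mitochondrial genome, and the protein's own motif array shows a matching
periodicity: conserved aspartate (position 1) and asparagine (position 6)
in every third 35-residue PPR motif, consistent with a rudimentary PPR code
specifying U at every third nucleotide.

`pprmotif` implements the computational side of this analysis as reusable,
tested components:

* **Repeat tracts** — maximal period-3 tracts whose aligned triplets are
  rotations of a unit (default `AUA`), decomposed canonically as
  `prefix (UNIT)n suffix` (e.g. `UA(AUA)3`, `(AUA)2A`), plus a census of
  tract categories (`find_repeat_tracts()`, `classify_tract()`,
  `repeat_census()`).
* **Motif mapping** — exact (overlapping) motif matches merged into loci by
  span union, interval annotation, and fixed-length overlapping
  oligonucleotide tilings (`find_matches()`, `find_motif_loci()`,
  `annotate_loci()`, `design_tiling_probes()`, `tile_probes()`).
* **Comparative screen** — enumerate every reference k-mer occurring in at
  least `min_loci` distinct regions, then filter by exact presence in all
  compatible species and absence from all incompatible species, reporting
  merged passing regions (`enumerate_candidates()`, `run_screen()`,
  `group_into_regions()`).
* **PPR code** — phase-stratified amino-acid frequency matrices and
  information content (`IC_j = log2 20 + Σ_a f_a log2 f_a` bits) over a
  motif array, conserved-signature detection, nucleotide-preference binding
  profiles from a configurable code (a protein of N motifs targets N − 1
  nucleotides), and log-odds scanning of RNA (`phase_profiles()`,
  `detect_signature()`, `binding_profile()`, `scan_rna()`).
* **Synthetic data** — seeded generators for AU-rich sequences with planted
  motifs, species panels with guaranteed presence/absence structure, and
  PPR arrays with planted phase signatures (`gen_sequence()`, `gen_panel()`,
  `gen_ppr_array()`, `gen_study_sequence()`).

All user-facing functions take a data frame first and return tibbles, so
analyses chain with the pipe; fitted profile objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(pprmotif)

# a 15S-scale synthetic sequence (1600 nt, 85% A+U) carrying the two
# recognition loci at their reported positions
study <- gen_study_sequence(seed = 1)
motif <- "AUAAUAAUAAUAAU"            # (AUA)4AU

find_motif_loci(study, motif)
#> # A tibble: 2 × 5
#>   seq_id        start   end n_matches motif
#>   <chr>         <int> <int>     <int> <chr>
#> 1 synthetic_15s   457   476         3 AUAAUAAUAAUAAU
#> 2 synthetic_15s   761   774         1 AUAAUAAUAAUAAU
```

The motif maps to exactly two merged loci: three staggered 14-mer matches
inside the 21-nt (AUA)₇ tract starting at position 457 count as one locus,
and the minimal 14-nt copy starts at position 761.

```r
tile_probes(study, probe_len = 80, overlap = 20) |> nrow()
#> [1] 27

panel <- gen_panel(seed = 1)          # 1 reference, 3 compatible, 6 incompatible
res   <- run_screen(panel$manifest, panel$seqs, k = 14, min_loci = 2)
res$motif[res$verdict == "pass"]
#> [1] "AUAAUAAUAAUAAU"
```

Eighty-nt probes overlapping by 20 nt tile the sequence with 27 probes, and
the cross-species screen recovers the planted motif — and nothing else — as
the only 14-mer repeated in the reference, present in every compatible
species and absent from every incompatible one.

```r
arr <- gen_ppr_array(21, planted = tibble::tibble(
  phase = c("A", "B"), position = c(6, 1), residue = c("N", "D"), freq = 1
), seed = 1)
binding_profile(arr)
#> PPR binding profile for synthetic_ppr — 20 target positions
#> consensus: UnnUnCUnnUnnUnnUnnUn
```

Asparagine at position 6 intersected with aspartate at position 1 of the
next motif concentrates the profile on U at every third target position —
the U-periodicity that distinguishes (AUA)ₙ targets from (UA)ₙ controls in
log-odds scans.

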