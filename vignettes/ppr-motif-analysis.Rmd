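---
title: "Trinucleotide repeat motifs and a rudimentary PPR code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trinucleotide repeat motifs and a rudimentary PPR code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprmotif)
library(tibble)
library(dplyr)
```

`pprmotif` implements the in-silico side of a motif-identification study of
the yeast mitochondrial PPR protein Dmr1 and its target in 15S rRNA: a
repeat-tract census, motif-locus mapping, oligonucleotide tiling design, a
cross-species presence/absence screen, and a phase-stratified analysis of
the protein's own motif array. This vignette describes the underlying
models and the design choices, their assumptions, and what the tests do and
do not establish.

## Maximal repeat tracts and their nomenclature

A repeat tract for a trinucleotide unit (default `AUA`) is a maximal
interval of the sequence with period 3 whose aligned 3-windows are
rotations of the unit. Maximality means that extending the interval by one
residue on either side breaks either the periodicity `s[i] == s[i+3]` or
the rotation condition. Each tract is decomposed canonically as
`prefix + unit^n + suffix`, where the prefix is a proper suffix of the unit
and the suffix a proper prefix; when several decompositions exist, the one
with maximal `n` and then minimal prefix is used, which makes labels such
as `UA(AUA)3`, `(AUA)2A` or `(AUA)4AU` unique. Choices worth noting:

* `min_full = 2` by default: the smallest category counted is a 6-nt
  `(AUA)2`; single units flanked by partials are background, not tracts.
* Homopolymer units are rejected — their rotations coincide, so the
  phase-unique decomposition that the nomenclature relies on does not
  exist.
* `N` (the only ambiguity symbol kept after normalisation) matches nothing
  and terminates tracts, keeping exact-match counts well defined.
* Two adjacent maximal tracts in *different* phases can share a one- or
  two-residue partial flank (e.g. `AUAAUA` and `UAAUA…` around a phase
  break). We report both maximal intervals rather than trimming one:
  trimming would break the equivalence with the containment-maximal
  brute-force definition that the property tests assert. Overlaps never
  reach a complete unit.
* Tracts are computed on the given strand only; the repeat is a property
  of the transcript.

```{r tracts}
seqs <- tibble(id = "demo", residues = "GGUAAUAAUAAUAGGAUAAUAGG")
find_repeat_tracts(seqs)
```

## Motif loci and tiling design

Exact matching reports every overlapping occurrence; loci are the span
unions of overlapping matches. This distinction matters for repetitive
motifs: a 21-nt `(AUA)7` tract contains three staggered copies of the
14-nt `(AUA)4AU` motif, yet is a single binding region, and all
region-level counts in the package (and the screen's `min_loci` rule) are
locus counts, not raw match counts.

Tiling design covers `[1, L]` with fixed-length probes (default 80 nt)
stepping by `probe_len - overlap` (default 20-nt overlap). The final probe
is anchored at the sequence end and flagged when shifted, so every probe is
full length — matching fixed-length oligonucleotide synthesis — at the cost
of a larger-than-nominal final overlap. Probes are numbered from the 5'
end; `number_from_3prime = TRUE` reproduces the slot-blot convention in
which probe #1 is 3'-most.

## The cross-species screen

The screen asks which k-mers of a reference sequence (k = 14 by default)
occur in at least `min_loci = 2` distinct (non-overlapping) merged loci,
are present in every species whose ortholog is at least partially
compatible with the reference mitochondrial genome, and absent from every
completely incompatible species. Presence means one or more exact
occurrences anywhere — a single conserved copy suffices, since species with
one motif copy can be fully compatible. Screening at exact k is complete
for the "at least k nt" question: any longer conserved motif contains a
conserved k-mer, so the merged passing *regions* are identical, even though
per-motif candidate lists could differ from an all-lengths enumeration.
Species with sequences shorter than k (incomplete records) are excluded
from the constraints with a warning rather than failing the screen. All
candidates are kept in the output with pass/fail verdicts for audit.

"Distinct regions" is deliberately the weakest rule consistent with
counting a twice-occurring motif as two: non-overlap of merged loci. The
two real loci are ~300 nt apart; no separation threshold beyond
non-overlap is imposed.

## Phase profiles, information content and the binding profile

A PPR array is an ordered table of 35-residue motifs (boundaries are an
input — sequence-based PPR motif detection in fungi is unreliable, so the
package does not attempt it). Motifs are stratified by index modulo 3 into
phases A (1, 4, 7, …), B and C, mirroring the trinucleotide periodicity of
the RNA target. Per phase and position the package computes amino-acid
frequencies and information content

\[ IC_j = \log_2 20 + \sum_a f_{a,j} \log_2 f_{a,j} \quad \text{(bits)}, \]

with `X`/gap residues excluded from the column and, by default, no
small-sample correction — the reference behaviour mirrors qualitative
sequence logos, and with ~7 motifs per phase a Schneider–Stephens
correction would shift all columns by a constant that the signature
detection threshold (a frequency, not an IC) does not depend on.
`detect_signature()` reports (phase, position, residue) triples where one
residue reaches `min_freq` (default 0.8, inclusive) of the phase.

The binding profile follows the one-motif-one-nucleotide model: a protein
of N motifs is expected to recognise N − 1 nucleotides, target position i
being specified by the residue at position 6 of motif i together with the
residue at position 1 of motif i + 1. The default code table encodes only
the two rules with direct support here — N6 → pyrimidine {U, C} and
D1′ → keto {U, G} — combined by a renormalised elementwise product, which
concentrates N6 + D1′ positions on U. The two positions are treated
symmetrically because which of them leads specificity is an open question.
An empty intersection or an unknown residue pair falls back to uniform
weights, and the rule that fired is recorded per position. The fuller plant
pair code can be loaded from a TSV (`read_code_table()`) but is not assumed
to transfer to yeast. Note that the conserved D1/N6 pattern observed within
one phase informs two *adjacent* target positions (keto at i − 1,
pyrimidine at i); the U-at-every-third profile arises from the N6/D1′
pairing across adjacent motifs, which is how the synthetic tests plant it.

Log-odds scanning scores each window as
`sum_i log2(max(w_i[base], eps) / background[base])` with a weight floor
`eps = 1e-3` — standard position-weight-matrix practice to keep scores
finite at zero-weight bases; at the default floor a forbidden base costs
~8 bits against a uniform background, dominating any plausible window
without producing infinities. A window's score is independent of flanking
context; ties for the best site resolve to the leftmost window.

## Synthetic data: what it emulates, and what it does not

The generators emulate the study conditions so every pipeline stage is
testable without downloads:

* Backgrounds are i.i.d. draws at 85% A+U (A = U = 0.425,
  C = G = 0.075), the composition regime of the strongly AT-rich yeast
  mitochondrial genome; sequence length defaults to the 15S scale
  (1600 nt, which an 80/20 tiling covers with exactly 27 probes).
* Planted motifs are overwritten at fixed positions; a reject-and-redraw
  loop (budget 100, failing loudly) guarantees that no planted motif
  recurs outside its site and that `forbid` motifs are absent outside
  planted intervals — rejection sampling keeps the background natural
  rather than post-hoc masked.
* `gen_panel()` plants each motif with single non-A/U guard bases on both
  flanks, alternating (G…C, C…G) between reference sites. The guards keep
  planted tracts maximal and make the immediate context of the two
  reference loci differ, so no frame-shifted k-mer overlapping a planted
  motif can recur at two reference loci. Without guards, a shifted k-mer
  whose random flanking base happens to coincide across all planted sites
  passes the screen legitimately, and exact planted-set recovery would not
  hold for every seed.
* `gen_study_sequence()` is a labelled synthetic surrogate for the mature
  15S rRNA: it plants the 21-nt `(AUA)7` tract at position 457 and the
  14-nt `(AUA)4AU` motif at position 761 — the reported loci — with the
  motif forbidden elsewhere. Sequence-level acceptance checks run against
  this surrogate; analyses of the real rRNA require the user to supply the
  GenBank sequence (a documented manual step).
* Sub-seeds derive from the root seed by a counter scheme
  (`(seed * 7919 + i) mod (2^31 - 1)`), so panels are reproducible and
  adding a species does not perturb the others' sequences.
* PPR arrays draw residues uniformly over the 20 amino acids and plant
  signature residues in `ceiling(freq × phase size)` randomly chosen
  motifs of the phase.

What passing tests therefore show: the algorithms are exact on sequences
with the study's composition, scale and planted structure, and agree with
independent brute-force oracles on hundreds of random instances. What they
do not show: behaviour on real rRNA features the generators omit —
secondary structure, local composition heterogeneity, phylogenetic
correlation between species (each synthetic species is an independent
background rather than a diverged relative), and annotation context.

## Numerical and interface conventions

* Coordinates are 1-based inclusive everywhere in tibbles (the R and
  IRanges convention, and the frame in which positions 457 and 761 are
  reported); BED export converts to 0-based half-open at the format
  boundary. Where a sequence has a 5' extension, positions upstream of the
  mature +1 site can be expressed by subtracting a user-held offset at
  reporting time; internal storage stays non-negative.
* DNA input (`T`) is silently normalised to RNA (`U`); mtDNA surveys can
  scan both strands via `both_strands = TRUE`, but the default is the
  transcript strand.
* The reference frame of the published position numbering relative to a
  user-fetched record cannot be verified offline; the synthetic surrogate
  fixes its own frame by construction.
* Problem sizes in the test suite — 200 random sequences up to 200 nt for
  the tract oracle, panels of 10 species at 250–300 nt for the screen
  oracle, 20 seeds for planted-recovery properties, 21-motif arrays —
  were chosen to exercise every code path with comfortable margins while
  keeping the default suite fast.

## Known limitations

Only period-3 units are supported; approximate or degenerate repeats,
PWM-based repeat scoring, alignment-based conservation and tree-aware
reconstruction are out of scope. The screen is exact-match by design —
mismatch tolerance belongs to the weighted scanning of `scan_rna()`. The
default code table is deliberately minimal; deriving code weights from
data is not attempted. The position-1/6 numbering within the 35-residue
motif follows the convention of counting from the motif's first residue;
mapping onto alternative plant-literature numbering schemes is left to the
user via the code-table configuration.
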