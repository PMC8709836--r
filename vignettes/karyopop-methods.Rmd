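---
title: "Methods: banding-sequence algebra and population cytogenetics in karyopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: banding-sequence algebra and population cytogenetics in karyopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyopop)
```

## The model

Polytene chromosomes carry a reproducible banding pattern that serves as a
physical map. Within a species, alternative *banding sequences* of one
chromosome arm are related by paracentric inversions — reversals of a
contiguous block of bands not containing the centromere — and are inherited
like alleles of a single locus: a larva carries two sequences per arm, and a
heterozygous arm is visible as an inversion loop in the paired homologues.
`karyopop` treats each arm as one multi-allelic locus and each banding
sequence as an allele. All rearrangements handled here are paracentric, so
the centromere is modelled as a fixed terminal marker and sequences are
plain linear orders of bands.

## Notation semantics

A listing line is an id (`p'agiB1`: geographic-distribution prefix, species
tag, arm letter, serial number), a series of band-run tokens, and the
terminal centromere marker `C`. Band coordinates are section numbers with
optional lowercase letter subdivisions. Three token forms occur:

* ranges, within a section (`22a-r`, descending `25s-q`) or across sections
  (`18n-16a`), which cover the whole canonical-order interval between their
  endpoints;
* fused two-letter tokens (`22ab`, `6hg`): exactly two adjacent bands, with
  direction given by the letter order;
* single bands (`3i`, or a bare atomic section).

The notation never declares the band universe of an arm, so it is inferred
from all listings jointly (`infer_catalogue`): per section, the lettered
subdivisions are assumed contiguous from `a` to the highest letter observed
in any token, and sections that are only ever covered inside cross-section
ranges — never split by a run endpoint — are treated as atomic units.
Whether unseen letters exist (say a `12w` beyond the observed `12v`) is
unverifiable from listings alone; the assumption affects band counts but
not permutation comparisons, which is why nothing downstream depends on it.

Two semantic points deserve spelling out, because they are the package's
reading of the notation rather than anything the notation states:

* **Explicit claims take precedence over range interiors.** In one derived
  arm-C sequence, a long range spans the canonical position of two bands
  that the same listing also routes through an explicit fused token
  elsewhere. Under naive interval expansion those bands would be covered
  twice. `expand_map` therefore excludes bands claimed by a singleton or
  fused token of the same map from the interpolated interior of its range
  runs (endpoints always stand). With this rule every packaged listing
  expands to exactly one copy of its arm's band set.
* **A lone band has no expressible orientation.** The notation cannot say
  which way a single-band run points. Its orientation is carried as
  *ambiguous* and resolved downstream by minimisation (below), which is the
  only reading under which the published "simple inversion" calls are
  reproducible.

Arm E has two published mapping versions (KV and GV) of its main sequence.
These are different coordinate systems, not different sequences: the package
stores GV as the default and keeps the KV listing as an alternate that is
never mixed with GV maps in one catalogue or comparison.

`format_sequence_line` inverts the parser exactly (fused tokens re-emit
fused), so `parse(format(m)) = m` on every packaged sequence.

## Reversal distances

`common_refinement` renders two sequences of one arm over a shared segment
alphabet: segments are maximal blocks of bands never split by a run
boundary of either map and traversed contiguously, co-oriented, in both.
The reference map becomes the identity `+1..+K`; the target becomes a
signed permutation of the same ids, with a free-sign mask for single-band
segments.

`reversal_distance` finds the exact minimal number of contiguous-segment
reversals by iterative deepening: depth 0, 1, 2, … up to `max_d` (default
3), pruning any branch whose breakpoint count `b` exceeds twice the
remaining depth (each reversal removes at most two breakpoints). The free
signs of ambiguous segments are decision variables: the search minimises
over all `2^a` assignments (`a` is at most 2 on the packaged data; a guard
refuses more than 12). Among minimal scenarios the search order makes the
witness deterministic (reversals tried in lexicographic interval order);
the returned scenario is oriented reference-to-target, so replaying it on
the identity reproduces the target. Beyond `max_d` the breakpoint lower
bound is reported with an `exact = FALSE` flag rather than an arbitrary
number.

Distance 0 is classified `identical`, 1 `simple`, 2 or more `complex`,
matching the field's terminology for inversions. On the packaged pool the
deepest exact distance needed is 3 (between two derived arm-F sequences);
the worst case stays well under a second, which is why no
Hannenhalli–Pevzner machinery is used — exhaustive small-depth search is
simpler, visibly correct, and sufficient at this scale.

## Population statistics

Sequence frequencies are computed on exact count arithmetic,
`p_i = f(ii) + Σ_{j≠i} f(ij)/2`. Two indices summarise polymorphism: the
percentage of larvae with at least one heterozygous arm, and the mean
number of heterozygous inversions per larva, where **each heterozygous arm
counts exactly once** regardless of how many reversals separate its two
sequences — a complex heterozygote is still one inversion loop in the
scoring sense, and this counting rule is the one that reproduces the
published per-larva means. With aggregated genotype counts instead of
larva-level data, the per-larva share is estimated assuming independence
between arms and flagged as such in the result.

The quantitative panel is the set of populations with more than 10
specimens; panel means are unweighted arithmetic means across populations.

Hardy–Weinberg goodness of fit uses the chi-square test as primary
(appropriate at the published sample sizes and standard in this
literature): expected class frequencies `p_i²` and `2 p_i p_j` from the
sample allele frequencies, classes expected-and-observed zero dropped,
`df = k(k+1)/2 − k`. The published "P > 0.95 / P > 0.99" significance
statements are read as tests at α = 0.05 / 0.01; the package reports exact
p-values and leaves thresholds to the caller. For small samples (n ≤ 50)
`hw_exact_test` enumerates every genotype array compatible with the
observed allele counts (Levene's conditional distribution) and sums the
probabilities of arrays no more probable than the observed one.

B-chromosome carriage is a genomic polymorphism separate from the
inversion system: it is summarised as a carrier frequency but excluded from
heterozygosity indices and Hardy–Weinberg testing.

## Nei distances and trees

Between two populations, with allele frequencies `x_i`, `y_i` per locus,
the package computes Nei's (1972) standard identity with the J terms
averaged across loci **before** forming the ratio:

  J_X = mean_L Σ x², J_Y = mean_L Σ y², J_XY = mean_L Σ x y,
  I = J_XY / √(J_X·J_Y), D = −ln I.

The loci are the seven arms A–G, all of them: a shared monomorphic arm
contributes 1 to each J and legitimately dilutes the distance. Dropping
such arms (or averaging per-locus identities instead) yields a different —
larger — distance and does *not* reproduce the published matrix; the
variant choice is therefore load-bearing and is covered by tests. `I` is
clamped at 1 before the logarithm so that printed-rounding noise cannot
produce negative distances, and matrix entries are compared to the
published table after half-up rounding to 3 decimals.

Neighbor-joining (Saitou–Nei) is delegated to `ape::nj` behind `nj_tree`,
with negative branch lengths clamped to zero. No bootstrap support is
computed: the resampling unit (larvae per probe) is not published.
Serialization uses Newick via `ape`; the published lower-triangle
distance-matrix layout has a dedicated reader (`read_phylip_matrix`).

## Structure types

A population is type `"0"` when the main (serial-1) sequence holds a
strict majority (> 0.5) in every arm; otherwise the label concatenates,
alphabetically, the letters of arms dominated by an alternative sequence.
*Strict majority* rather than plurality is deliberate: it reproduces the
published type calls and stays well-defined for three-allele arms; an arm
with no strict majority is flagged `mixed` and excluded from the label,
and the dominant sequence id per arm is reported alongside (the published
scheme does not distinguish *which* alternative sequence dominates).

## The synthetic generator

`simulate_population` draws per-arm genotypes from
`P(ii) = p_i² + F p_i(1−p_i)`, `P(ij) = 2 p_i p_j (1−F)` — the
one-parameter fixation-index family, chosen over per-genotype deltas
because it is one-dimensional and its sign reads directly as heterozygote
excess (F < 0) or deficit (F > 0), the deviation actually observed in the
survey data. Arms are drawn independently and B-chromosome carriage is
Bernoulli. The generator emulates multinomial sampling of genotypes at
fixed population frequencies; it does **not** model inter-arm linkage,
temporal structure between probes, migration, or scoring error, so passing
calibration here validates the statistical machinery, not those aspects of
real data.

Calibration targets (all in the test suite): under F = 0, k = 2 alleles at
p = 0.3 and n = 250 larvae, the chi-square test's type-I error over 1000
seeded replicates must lie in [0.03, 0.07] at α = 0.05; under F = −0.3 at
n = 259 (the size of the largest published sample) power must reach 0.9.
These sizes keep the whole suite under a minute while leaving the binomial
noise of the rejection-rate estimate well inside the accepted bands.

`simulate_derived_map` plants k random reversals (each at least two bands,
so a planted reversal can never be absorbed by a lone band's free sign)
into a reference listing and re-emits valid notation; the planted scenario
is returned so the reversal-distance search can be checked against a
brute-force breadth-first oracle.

## Source-table provenance

The packaged fixtures keep the published tables exactly as printed; known
internal inconsistencies are surfaced as notes, never silently reconciled:

* The genotype table prints 20 data columns under 19 site headers. The
  alignment packaged here — first column the previously published Rybinsk
  Reservoir sample (n = 100) used in the quantitative panel, second column
  the survey's own four larvae from the same site, the rest in site order —
  is confirmed by every cross-checkable value (heterozygote frequencies
  quoted in the text, the B-chromosome sites, the larvae counts).
* The frequency table's NSK-LI and NSK-OR columns are mutually inconsistent
  with the printed distance matrix: each reproduces the other's row, and
  swapping the two labels reconciles all 12 mismatching pairs (shown in
  `analysis/04_distances_tree.R`). Distance comparisons against the printed
  matrix therefore exclude pairs involving these two populations.
* A genotype row is printed as `h'agiF1.p'agiE2` but sits in the arm-E
  block; it is stored corrected as the arm-E heterozygote. The arm-C main
  sequence appears with both `p'` and `h'` prefixes in different places of
  the source; the fixtures follow the tables (`h'agiC1`).
* The Rybinsk larvae count is 4 in the sites table but 100 in the
  frequency-table header (prior published data); frequency-based work uses
  the 100-larvae sample.
* A few printed per-population values (one monomorphic-looking arm-B
  column, a sequence count of 8 where the column lists 9 distinct
  sequences) do not reconcile with each other; they are carried as printed
  and excluded from quantitative claims.

## Problem sizes and limitations

The packaged analyses are desk-scale: 16 sequences over 6 mapped arms
(37–118 bands each), 10–20 populations, distance matrices of 45 pairs.
The reversal search is exact only to depth `max_d` and is exponential
beyond; for genuinely long rearrangement scenarios a dedicated
sorting-by-reversals implementation would be needed. Transpositions,
translocations and pericentric inversions are out of scope, as is any
mapping of arm G (obscured by its nucleolar organisers) and any
between-probe temporal homogeneity testing (per-probe counts are not
published).
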