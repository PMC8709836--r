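# karyopop

Cytogenetic analysis of chromosomal inversion polymorphism in natural
populations scored on polytene chromosomes, packaged around the published
banding-sequence pool of the midge *Chironomus agilis* (Diptera,
Chironomidae).

In *Chironomus* and other Diptera, alternative banding sequences of one
polytene chromosome arm are related by paracentric inversions and segregate
like alleles of a single locus. A population survey therefore reduces to:
parsing and validating the banding-sequence maps, measuring how many
inversions separate each pair of sequences, estimating sequence (allele)
frequencies from scored larvae, testing arms for Hardy–Weinberg proportions,
summarising polymorphism per population, and comparing populations by
genetic distance. `karyopop` implements each step as a tested, reusable
function and ships the published tables of the *Ch. agilis* survey (19
populations from Eastern Europe, Siberia and the Far East) as plain-text
fixtures, so the printed numbers are reproducible end to end.

## What is implemented

* **Banding-sequence notation** (`parse_sequence_line`, `expand_map`,
  `validate_arm_pool`, `format_sequence_line`): listings such as

  ```
  p'agiB1 25s-q 18n-16a 22a-r 25k-23f 15g-r 21t-i 18o-21h 25p-l 22s-23e 15f-12v C
  ```

  are parsed into oriented band runs ending at the centromere marker `C`.
  The band universe of an arm is inferred from all its listings (letters
  contiguous to the highest observed; never-split sections atomic), and all
  sequences of an arm are checked to be permutations of one band set.

* **Reversal distances** (`common_refinement`, `reversal_distance`,
  `classify_pair`, `single_reversal_breakpoints`): two sequences are
  rendered over a common segment alphabet as signed permutations; the exact
  minimal number of contiguous reversals is found by iterative-deepening
  search with a breakpoint bound, minimising over the free signs of
  single-band segments. Distance 1 is a *simple* inversion, two or more
  *complex*, matching the terminology of the cytogenetic literature.

* **Population statistics** (`allele_frequencies`, `polymorphism_summary`,
  `quantitative_panel_means`, `hw_expected`, `hw_chi_square`,
  `hw_exact_test`, `pool_census`): sequence frequencies
  `p_i = f(ii) + Σ f(ij)/2`, percentage of heterozygous larvae, heterozygous
  inversions per larva (each heterozygous arm counts once), chi-square (and
  small-sample exact) Hardy–Weinberg goodness of fit with
  `df = k(k+1)/2 − k`, and the census of the species' banding-sequence pool.

* **Genetic distances and trees** (`nei_distance`, `distance_matrix`,
  `nj_tree`, `read_phylip_matrix`, `write_newick`): Nei (1972) standard
  distance `D = −ln I`, `I = J_XY / √(J_X·J_Y)` with the J terms averaged
  across the seven arm loci (shared monomorphic arms contribute 1), and
  neighbor-joining trees (via `ape`) with Newick output.

* **Structure typing** (`classify_structure`, `polygon_vectors`): type `"0"`
  when the main (serial-1) sequence holds a strict majority in every arm,
  otherwise the letters of arms dominated by an alternative sequence.

* **Synthetic data** (`simulation_config`, `simulate_population`,
  `simulate_derived_map`): genotype samples under Hardy–Weinberg with a
  fixation-index deviation `F` (negative = heterozygote excess), and
  banding sequences with planted reversals, used to calibrate the test and
  search machinery.

## Worked example

```r
library(karyopop)
fx <- load_fixtures()

# how do the two common arm-B sequences differ?
pool_compare(fx$pool, "B1", "B2")
#> Reversal distance: 1  - simple
#> Scenario (segment intervals): [4,10]
pool_compare(fx$pool, "B1", "B2")$breakpoints
#>  from    to
#> "22c" "23c"
```

One inversion separates p'agiB1 from p'agiB2: reversing the block from band
22c through 23c of the B1 listing reproduces B2 — the "large simple
inversion" of the original description.

```r
# cytogenetic distance between the western-most and a Siberian population
nei_distance(fx$table3[["YAR-RY"]], fx$table3[["NSK-SH"]])
#> Nei (1972) YAR-RY vs NSK-SH: I = 0.9250, D = 0.0780

# arm-B Hardy-Weinberg test in the largest sample (counts from the
# genotype table, n = 259)
hw_chi_square(c("p1/p1" = 8, "p1/p2" = 129, "p2/p2" = 122))
#> HW chi-square: X2 = 14.364, df = 1, p = 0.000151, het excess (n = 259)

classify_structure(fx$table3[["NSK-BE"]])
#> NSK-BE: cytogenetic type B
```

The Shadrikha-river population shows a significant excess of arm-B
heterozygotes, and every Siberian population is of cytogenetic type B (the
alternative sequence p'agiB2 dominates arm B), while the Rybinsk Reservoir
population is type 0.

## Analysis workflow

The survey itself is organised as numbered drivers under `analysis/`, each a
thin narrative script over the package functions, writing its tables under
`results/`:

```sh
Rscript analysis/01_validate_pool.R     # parse + validate the 16 listings
Rscript analysis/02_rearrangements.R    # distances, classes, breakpoints
Rscript analysis/03_polymorphism.R      # frequencies, census, panel means, HW
Rscript analysis/04_distances_tree.R    # Nei matrix, printed-table comparison, NJ tree
Rscript analysis/05_structure_types.R   # structure types, polygon vectors
Rscript analysis/06_simulation_checks.R # synthetic calibration checks
```

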