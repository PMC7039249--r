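---
title: "Methods: censusing low-potential protein electron carrier genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censusing low-potential protein electron carrier genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peccensus)
```

## The problem

Small low-potential protein electron carriers (PECs) — [4Fe-4S] ferredoxins,
[2Fe-2S] ferredoxins and flavodoxins (Flds) — shuttle electrons between
oxidoreductases at potentials small molecules cannot reach selectively.
`peccensus` turns per-gene InterPro signature annotations from thousands of
genomes into a per-organism census of these three families and analyses how
family composition, gene length and environmental niche co-vary.

## Classification model

A gene is assigned to a family purely by its signature set: `IPR017896` marks
[4Fe-4S] Fds, `IPR001041` [2Fe-2S] Fds, and `IPR008254` Flds. Counting is
*per signature*: a gene carrying both ferredoxin cluster signatures increments
both family counts, because the census counts genes having each signature,
not mutually exclusive gene assignments. The number of multi-classified genes
is reported in the census diagnostics so this convention is auditable.
`IPR000813` (7Fe ferredoxins, binding one [3Fe-4S] and one [4Fe-4S] cluster)
is a flag *within* the [4Fe-4S] family — it never creates a fourth count, and
`n_7fe <= n_fd4` holds by construction. Unknown accessions are ignored and
tallied in a diagnostics log.

The size filter retains genes of **at most 200 residues**: "over 200" is
excluded, so a 200-residue gene is kept and a 201-residue gene dropped. The
cutoff focuses the census on small single-domain carriers and suppresses
nitric-oxide-synthase false positives on the Fld signature, whose enzymes
exceed 400 residues. It exceeds the largest single-domain structures of each
family in the packaged reference (106, 128 and 184 residues), so length
variation beyond structurally characterized members remains visible.

## Census statistics

* **Group summaries** report the mean and *sample* (n−1) standard deviation
  per family and for the total; the convention is recorded on the output so a
  population-form comparison can be made externally. Single-organism groups
  report a standard deviation of 0 rather than NA. Groups are ordered by
  descending mean total with alphabetical tie-breaks.
* **Pairwise matrices** cross-tabulate two families' counts and report the
  four quadrant fractions at a threshold of 4 genes; the fractions partition
  the census exactly.
* **Strategy classes**: an organism is `none` (no PEC genes), a `specialist`
  (exactly one family present) or a `generalist` (two or more).
* **Ternary binning** normalizes the three counts to percentages and assigns
  each organism to a triangular cell of 10% step. Cell membership is decided
  in exact integer arithmetic on `count/total`, so a composition like
  (50%, 50%, 0%) is detected as a boundary point without any floating-point
  epsilon. A boundary composition is placed uniformly at random among *all*
  cells whose closed region contains it, under the run seed — the published
  procedure for boundary compositions. Consequently reruns with different
  seeds can only differ on boundary organisms, and bin counts plus the
  zero-total exclusions always sum to the census size.

## Environmental niche analysis

Oxygen requirement uses six ordered classes (obligate anaerobe → obligate
aerobe) and growth temperature four (psychrophile → hyperthermophile).
Label normalization is deliberately conservative: only `thermotolerant`
(→ thermophile), `psychrotolerant` and `psychrotrophic` (→ psychrophile) are
re-mapped; every other label must already equal a canonical class name
(case-insensitively) or it becomes `unbinned`. Nothing is guessed.

The temperature-by-oxygen grids display averages rounded to two significant
figures with `N/A` for empty cells; full-precision values and per-cell genome
counts are always emitted alongside, and the full-precision cells aggregated
with the count grid reproduce the axis-wise means exactly.

The per-pH profile divides summed family counts by the number of organisms
observed at each pH value. The weighted pH mean of a family uses these
normalized counts as weights; the weighted standard deviation uses the
frequency-weight population form `sqrt(sum(w (x - xw)^2) / sum(w))` (the
estimator is recorded on the output, since conventions differ). Family pairs
are compared with a paired two-tailed t-test whose pairing unit is the pH bin
— the only pairing the data supports. The normalized profile is the default
paired quantity; summed raw counts are available behind the
`weights = "raw"` flag because it is genuinely ambiguous which scale such a
comparison should use. Zero-variance difference vectors are handled
explicitly: all-zero differences give p = 1, a constant nonzero difference
p = 0.

## Length profiles

Length distributions are smoothed with a Gaussian kernel on an integer
residue grid. The default bandwidth is Scott's rule `sd(x) * n^(-1/5)` with a
floor of one residue so a degenerate group (one distinct length) still yields
a proper density. The grid spans `[min − 3 bw, max + 3 bw]`; because a
Gaussian kernel leaves roughly 0.3% of its mass beyond three bandwidths, the
density is renormalized by its trapezoidal integral over the grid, making the
integral exactly 1 — the usual display convention for kernel density
estimates. Modes are strict local maxima above a prominence threshold
(default 5% of the global peak); plateaus count once at their centre, and a
flat density has no modes. On synthetic mixtures whose components are
separated by more than three bandwidths, mode recovery within one bandwidth
of each true centre succeeds in at least 99% of seeded runs — the package's
parameter-recovery acceptance bar.

The packaged reference `pdb_pec_lengths_synthetic.tsv` lists the PDB
identifiers of structurally characterized family members with chain lengths.
It is a constructed stand-in assembled without structure files: a few anchor
entries carry published lengths (provenance `reported`, e.g. the family
maxima 106/128/184), and the remaining entries (provenance `constructed`)
were filled in once so the per-family summaries match the published means of
77, 111 and 160 residues and the [2Fe-2S] split of 22 structures under 100
residues and 16 between 103 and 128. Analyses that need per-entry truth
should replace this file with measured chain lengths.

## Phylogeny mapping

Tree work is delegated to `ape`. Pruning keeps exactly the leaves whose
normalized label (case-folded, trimmed, quotes stripped, spaces and
underscores equivalent) matches a census organism id; degree-2 nodes are
collapsed with branch lengths summed. Matching is exact after folding —
unmatched labels are reported, never fuzzily resolved. The annotation export
writes an iTOL-style multi-bar dataset with the three counts per leaf in the
fixed family order [4Fe-4S] Fd, [2Fe-2S] Fd, Fld, and the export agrees
count-for-count with the census by construction (a missing leaf is an error).

## The synthetic generator

The generator exists so every downstream stage is testable without any
download; its defaults are fixed study conditions, not tuning dials. Three
archetypes mirror a 7,079-genome finished-genome survey:

| archetype | n | family means (fd4/fd2/fld) | NB dispersion |
|---|---|---|---|
| archaeon-like | 275 | 10.6 / 1.0 / 1.1 | 5.8 |
| bacterium-like | 6733 | 4.2 / 2.0 / 1.7 | 0.8 |
| eukaryote-like | 71 | 0.3 / 2.1 / 0.4 | 0.2 |

Family totals reproduce the domain means of ~12.7, ~7.9 and ~2.8 genes per
genome; the archaeal split follows the dominant archaeal phylum's proportions
and the eukaryotic split is [2Fe-2S]-dominant. Counts are negative binomial
(variance `mu + mu^2/theta`, Poisson at infinite dispersion); the dispersions
were solved once from the domain-level total standard deviations of 5.7, 6.2
and 5.3 — per-organism variance is otherwise unreported, so overdispersion is
a modelling choice, not an inference. Lengths come from family-specific
Gaussian mixtures truncated to [40, 220] residues (modes near 70/110/170,
90/110/160 and 150/170/200), so the 200-residue filter is exercised on both
sides. Each [4Fe-4S] gene carries the 7Fe signature with an archetype-level
probability; a decoy accession `IPR999999` is planted on a small fraction of
genes and as occasional decoy-only genes, which classification must ignore.
Niche-label probabilities skew archaea anaerobic/thermophilic, bacteria
mesophilic/facultative and eukaryotes aerobic/mesophilic; external pH is
normal per archetype and present for about half the organisms — pH metadata
coverage in real collections is far sparser, but a workable number of pH
strata is needed for the weighted statistics to be exercised at test scale.

Determinism is structural: one substream seed per organism is derived from
the dataset seed and the organism's position, so regenerating with the same
configuration is byte-identical and inserting an organism does not perturb
the draws of others. Trees over the synthetic organisms are uniform random
binary trees (`ape::rtree`) under the dataset seed.

What the generator does *not* emulate: phylogenetic autocorrelation between
related organisms, correlation between niche and family counts (niche labels
are drawn independently of counts within an archetype), niche-dependent 7Fe
rates, and real signature co-occurrence structure. Passing tests therefore
demonstrate that the *pipeline arithmetic* is correct under known truth, not
that real genome collections satisfy the generator's assumptions.

## Problem sizes and numerical choices

The test suite runs archetypes scaled to a few hundred organisms —
Monte-Carlo recovery checks use 3-standard-error windows at n = 800–1500,
where configured means are recovered comfortably and the suite stays quick.
The acceptance script runs the full 7,079-organism condition. Ternary
boundary detection is exact rational arithmetic; percentages in machine
output keep full precision (two-significant-figure rounding is display-only).
Degenerate inputs are defined rather than accidental: empty groups are
omitted with a message, zero-total organisms are excluded-and-counted in the
ternary grid, a class with no [4Fe-4S] genes reports an absent 7Fe fraction,
and fewer than two shared pH bins makes the paired comparison "not
computable" rather than an error.

## Known limitations

* Pre-counted (supplementary-table) input cannot drive the length stage —
  such tables carry no per-gene lengths; the run manifest records the skip.
* The packaged structure-length table is synthetic in the sense described
  above.
* Organism identity is taken at face value: multiple genome entries for one
  species are treated as independent organisms.
* No multiple-testing correction is applied to the three pairwise pH
  comparisons, matching the analysis this package reproduces.
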