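# peccensus

Genome census of small low-potential protein electron carrier (PEC) genes:
[4Fe-4S] ferredoxins, [2Fe-2S] ferredoxins and flavodoxins (Flds).

Small PECs are the low-potential electron hubs of metabolism. Unlike NAD(P)H
or quinones they can evolve partner specificity and tuned midpoint
potentials, and genomes often carry many paralogs of each family. This
package is for comparative genomicists who want to quantify that variation
across thousands of genomes: it consumes per-gene InterProScan-style
signature annotations plus organism metadata (taxonomy, oxygen requirement,
growth temperature, external pH) and produces a per-organism census with the
full downstream analysis suite.

## What it computes

Genes are classified by InterPro signature — `IPR017896` → [4Fe-4S] Fd,
`IPR001041` → [2Fe-2S] Fd, `IPR008254` → Fld, with `IPR000813` flagging the
7Fe ferredoxin subtype inside the [4Fe-4S] family — after excluding genes
encoding proteins of more than 200 residues. From the census
(one row per organism: `n_fd4`, `n_fd2`, `n_fld`, `n_7fe`,
`total = n_fd4 + n_fd2 + n_fld`) the package derives:

* group abundance summaries (mean ± sample sd per family, ordered by mean
  total) by domain, phylum, or any custom grouping;
* count histograms and pairwise family-by-family abundance matrices with
  quadrant fractions at a 4-gene threshold;
* specialist/generalist classification (`none` / `specialist` /
  `generalist` by the number of families present);
* ternary compositional binning at 10% steps with exact-arithmetic boundary
  detection and seeded random placement among adjoining cells;
* niche stratification: per-class profiles and temperature-by-oxygen grids,
  7Fe fractions per oxygen class, per-pH normalized profiles with weighted
  means/standard deviations and paired two-tailed t-tests between families;
* kernel-density length profiles per family grouped by total PEC count or
  niche class, with mode detection and a packaged structure-length
  reference;
* species-tree pruning to the census organisms and iTOL-style stacked-bar
  leaf annotation export;
* a seeded synthetic-data generator (negative binomial counts, truncated
  Gaussian length mixtures, categorical niche labels, random trees) so every
  stage is testable offline, and a `run_pipeline()` driver that emits a
  report bundle with a parameter manifest.

## Worked example

```r
library(peccensus)

ds <- generate_census_dataset(default_archetypes(scale = 0.05), seed = 42)
census <- build_census(ds$genes, ds$metadata)
census
#> PEC census: 355 organisms, 2873 PEC genes total
#>   [4Fe-4S] Fd: 1558 | [2Fe-2S] Fd: 759 | Fld: 556 | 7Fe-flagged: 188

summarize_by_group(census, "domain")[, c("group", "n", "mean_total", "sd_total")]
#>       group   n mean_total sd_total
#> 1   Archaea  14      13.57     5.52
#> 2  Bacteria 337       7.93     6.58
#> 3 Eukaryota   4       3.00     2.00

round(100 * strategy_fractions(census), 1)
#>       none specialist generalist
#>        4.2       20.8       74.9

pairwise_matrix(census, "fld", "fd2")
#> Pairwise PEC abundance: Fld vs [2Fe-2S] Fd (threshold 4, 355 organisms)
#>   both < t: 69.3% | a >= t only: 11.3% | b >= t only: 16.6% | both >= t: 2.8%

ternary_bins(census, seed = 42)
#> Ternary PEC composition grid (step 10%): 340 organisms binned, 15 excluded (total = 0)
```

Reading: at this reduced scale (5% of the default survey), archaea average
~13.6 PEC genes per genome versus ~7.9 in bacteria and ~3 in eukaryotes;
4.2% of organisms carry no small PEC gene, 20.8% use a single family and
74.9% are generalists; 69.3% of organisms carry fewer than four genes of
both the Fld and [2Fe-2S] families; and 15 zero-total organisms are excluded
from (and accounted for by) the ternary composition grid.

Real annotation tables enter through `read_gene_annotations()` +
`read_organism_metadata()`, or pre-counted census sheets through
`read_supplementary_census()` with a column-mapping config; `run_pipeline()`
drives either mode end to end and writes every table plus `manifest.json`.

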