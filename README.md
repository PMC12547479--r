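# strataseq

Habitat-stratified sample subsetting and morphospecies prioritisation for
cost-efficient generation of DNA reference databases.

## The problem

Molecular identification of small, species-rich taxa (soil
microarthropods, plankton, zoobenthos) needs reference databases that
mostly do not exist yet, and building them exhaustively — identifying
random specimens from every sample — wastes scarce taxonomic expertise on
re-identifying the same common species. `strataseq` implements a
prioritisation workflow for research groups who must build their own
references within an ordinary community-ecology study:

1. **Stratified subsetting** — keep a minimal sample subset spanning the
   main turnover gradients: per region × soil-type stratum, one plot from
   the lowest and one from the highest quartile of land-use intensity
   (LUI), drawn at random with inclusive type-7 quartile bounds.
2. **Morphospecies prioritisation** — rank morphospecies by occupancy
   (number of subset samples occupied), tie-break by abundance; select
   those occupying more than `stop_rule_min_occupancy` samples (default
   3) plus flagged rare-but-locally-abundant ones, within a capacity
   budget.
3. **Identification scheduling** — visit pools starting from the most
   adult-rich one, then spread across maximally distinct habitats
   (farthest-point ordering on Hamming distance over region, soil and a
   high/low LUI class); stop when a visit yields nothing new or only
   singletons of new species.
4. **Reference-database gap analysis** — compare the identified species
   list to a catalogue (none < barcode < genome) and emit sequencing
   tasks with voucher bookkeeping.

Around this sit the benchmarking arithmetic (taxon overlap, effort ratio,
abundance-weighted individual coverage $\sum_{t \in \text{detected}}
n_t / N$, coverage–effort curves), the accompanying community statistics
(Bray–Curtis, PERMANOVA with sequential SS, NMDS, richness ANOVA), and a
calibrated community simulator with occupancy–abundance coupling
(presence: logit $p_{ij} = \mu_i + \text{region}_i(j) + \text{soil}_i(j)
- w\,(\mathrm{LUI}_j - \mathrm{opt}_i)^2 / 2\tau_i^2$; abundance:
$1 + \mathrm{NegBin}(e^{a + b\mu_i}, \theta)$).

## Worked example

The package ships the published benchmark comparison of two grassland
Collembola inventories (an exhaustive one and a stratified-workflow one)
as a fixture; every headline number is recomputed from it:

```r
library(strataseq)
tab <- load_table1_fixture()
a <- tab$taxon[tab$strataseq_detected]    # 39 workflow taxa
b <- tab$taxon[tab$benchmark_detected]    # 60 benchmark taxa

match_taxa(a, b)
#> Taxon match (exact_label): 23 shared, 16 only in A, 37 only in B

bench <- data.frame(taxon = b, count = tab$benchmark_count[tab$benchmark_detected])
individual_coverage(a, bench, denominator = attr(tab, "benchmark_identified"))
#> 0.712  (868 of 1219 benchmark individuals belong to detected taxa)

effort_ratio(attr(tab, "effort_strataseq"), attr(tab, "effort_benchmark"))
#> 0.2242 (345 / 1539 specimens given detailed identification)

top_k_share(setNames(bench$count, b), 10)$sum
#> 804   (individuals in the 10 most abundant benchmark species)
```

The detected species list covers 71% of benchmark individuals at 22% of
the identification effort, because a few common, abundant species carry
most of the community — the skew the workflow exploits.

The same machinery runs end to end on a simulated study:

```r
run_pipeline(run_config(seed = 1))
#> Workflow report
#>   22 samples in the habitat-stratified subset (11 strata)
#>   19 of 31 morphospecies selected for identification
#> Effort ledger: 66 prepared + 8 designated for sequencing = 74 total
#>   23 taxa identified; individual coverage 77.3% at 1.9% of exhaustive effort
#>   8 reference-database gaps -> sequencing tasks
```

Here the simulated campaign has 132 plots in 11 region × soil strata; the
stratified subset of 22 samples recovers 23 of the latent species, which
account for 77% of all simulated individuals, after preparing only 66
specimens.

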