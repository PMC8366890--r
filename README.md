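# haplohab

Habitat-assortment tests and single-locus species delimitation for deeply
diverged mitochondrial lineages.

## The problem

A classic line of evidence for ecological speciation in reef fishes is a
deep split in a mitochondrial marker (here, a 723-bp cytochrome *b*
fragment) whose two lineages — a "northern/subtropical" and a
"southern/tropical" haplotype group separated by roughly 5% sequence
divergence — appear to sort into different habitats where they overlap.
Evaluating that claim requires, beyond maps and networks, explicit
statistics: do haplotype frequencies really differ between habitat types
or sites, and does the locus support more than one species at all?

`haplohab` implements that evaluation as a reusable, fully tested pipeline
for population geneticists working with single-locus mtDNA surveys:

* **IO** — aligned FASTA, per-sample metadata (site / habitat / region)
  as TSV, Newick clock trees; validation and joining into one dataset.
* **Distances** — uncorrected *p*, JC69, and TN93 with pairwise deletion
  and explicit saturation flags.
* **Clock tree & lineages** — deterministic UPGMA; lineage assignment from
  the deepest (root) split, optionally oriented by anchor samples;
  haplotype collapsing and a minimum-spanning-tree haplotype network.
* **Population genetics** — pairwise Nei F<sub>ST</sub>
  (F<sub>ST</sub> = 1 − H<sub>S</sub>/H<sub>T</sub>, bias-corrected
  gene diversities, harmonic-mean sample-size correction) between habitat
  types or sites, with the fixed-sample-size permutation null: exact
  exhaustive enumeration when the number of assignments is feasible,
  add-one Monte Carlo otherwise.
* **GMYC** — single-threshold generalized mixed Yule–coalescent species
  delimitation on an ultrametric tree, with maximum-likelihood threshold
  search and a χ² likelihood-ratio test against the one-species
  coalescent null.
* **Simulator** — a two-lineage Kingman coalescent (time in
  substitutions/site; within-lineage diversity θ, divergence τ,
  finite-sites JC69 mutation) with a tunable lineage–habitat assortment
  strength α, so every statistic above can be calibrated on data with
  known truth.

## Worked example

Simulate a survey under the default design — eight sites in three habitat
classes, 78 samples, two lineages at 5% net divergence, no
habitat assortment (α = 0) — then run the full analysis:

```r
library(haplohab)

sim <- simulate_dataset(sim_config(seed = 42))
report <- analyze(sim$dataset, analysis_config(n_perm = 999, seed = 5))
report
```

```
Analysis report: 78 samples, 723 sites
  lineages: 35 northern / 43 southern
  between-lineage divergence: 4.12% (p), 4.24% (TN93)
  haplotypes: 17
  habitat-pooled Fst:
       group1        group2 n1 n2          fst          p
    grass_bed  inshore_reef  5 20  0.112001045 0.02516469
    grass_bed offshore_reef  5 53  0.147712985 0.00800000
 inshore_reef offshore_reef 20 53 -0.002339989 0.52600000
  GMYC: 5 entities, LRT p = 0.2334
```

Reading the output: the two simulated lineages are recovered from the root
split of the UPGMA tree (35 vs 43 samples) at ~4% observed divergence
(the 5% net divergence after Jukes–Cantor saturation and coalescent
variance). The habitat-pooled F<sub>ST</sub> rows show the two small-sample
grass-bed comparisons reaching nominal significance in this particular
α = 0 replicate — exactly the kind of small-n artifact the calibration
harness quantifies (the family-wise type-I rate of the three pairs matches
its multiplicity-adjusted nominal level; see the methods vignette). The
GMYC likelihood-ratio test finds no support for more than one species on
this alignment-derived tree (p = 0.23).

Calibration directly:

```r
estimate_error_rates(sim_config(alpha = 0, seed = 101),
                     replicates = 200, nominal_level = 0.05)
```

reports the fraction of replicates with any habitat pair significant
(raw and Holm-adjusted), with binomial standard errors.

A shell entry point wrapping the same functions is installed at
`inst/cli/haplohab` (subcommands `simulate`, `analyze`, `power`,
`benchmark`); `analyze` writes `report.json`, `fst_pairs.tsv` and
`frequencies.tsv` into an output directory. Benchmark mode analyzes a
locally supplied copy of a deposited alignment — the package never
downloads data.

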