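# sortnscreen

Analysis and simulation of **sorted transposon insertion screens**:
genome-wide functional screens in which a dense transposon mutant library
carrying a fluorescent transcriptional reporter is sorted by FACS into
*high* (~5%), *low* (~5%) and *depleted* (~90%) fluorescence bins, and
transposon–genome junctions are deep-sequenced per bin. Loci whose
disruption raises reporter expression (repressors of the reporter) enrich
in the *high* bin; loci whose disruption lowers it (activators) enrich in
*low*. The method discovers regulators of any promoter of interest —
including regulators of non-coding loci such as CRISPR arrays — without
prior hypotheses, and detects hits in intergenic regulatory regions as
readily as in genes.

## What the package computes

For each genomic feature *f* (annotated genes plus one intergenic feature
per gap, so the universe covers every base), the count unit is the number
of **unique insertion sites** — distinct (position, strand) with ≥1
junction read — in *f* per sample. Counts are modelled as
negative-binomial, NB(μ, φ) with Var = μ + φμ². After deterministic
library equalization, each sorted bin is tested against the depleted
control with a **conditional exact test**: the sum of n replicate counts
is NB(nμ, φ/n), and conditional on the two-group total t = a + b the split
probability is free of μ,

P(x | t) ∝ C(x + n_a/φ − 1, x) · C(t − x + n_b/φ − 1, t − x),  x = 0…t,

reducing to Binomial(t, n_a/(n_a+n_b)) at φ = 0. The two-sided p-value
sums all splits no more probable than the observed one; φ is a common
dispersion estimated from the depleted replicates by trimmed
method-of-moments. Features with Benjamini–Hochberg adjusted p < 0.05 and
signed log2 fold-change > 0.5 are enriched; enrichment in high only /
low only / both / neither yields the calls `up_in_high` / `up_in_low` /
`ambiguous` / `ns`. A screen-overlap module compares significant loci
across screens of different promoters.

The package also ships a fully seeded synthetic screen generator (mutant
pool → per-cell fluorescence with planted regulator effects → quantile
gating → overdispersed per-bin sequencing) emitting the exact file formats
the pipeline reads, plus calculators for the companion assays:
conjugation fold-interference with ">N-fold" detection-floor semantics,
and phage efficiency of plating (EOP) with the one-plaque substitution
rule for clearing-only spot series.

## Worked example

Simulate a desk-scale screen (120 kb genome, 100 genes, one insertion per
18 nt, 2×10⁵ cells sorted in triplicate, 5,000 reads per library) with
three planted 10× repressors, then analyse it:

```r
library(sortnscreen)

cfg <- sim_config(genome_length = 120000, n_genes = 100,
                  cells_sorted = 2e5, n_repressors = 3,
                  screen_id = "demo", seed = 42)
sim <- simulate_screen(cfg)

cm    <- build_count_matrix(sim$profiles, sim$universe)
res   <- enrich_screen(cm, sim$sheet)
calls <- call_regulators(res)

cm
#> <count_matrix> 201 features x 9 samples; library sizes 2737, 1971,
#>   3216, 2772, 1990, 3300, 2813, 1983, 3229
table(calls$call)
#>         ns up_in_high
#>        198          3
merge(calls[calls$call != "ns", ],
      res[res$bin == "high", c("feature_id", "log2FC", "fdr")])
#>   feature_id screen_id       call   log2FC          fdr
#> 1   gene_001      demo up_in_high 8.842350 4.659690e-67
#> 2   gene_050      demo up_in_high 8.503826 6.557931e-53
#> 3   gene_100      demo up_in_high 8.438792 1.119220e-50
sim$truth
#>          feature_id direction effect
#> gene_001   gene_001 repressor     10
#> gene_050   gene_050 repressor     10
#> gene_100   gene_100 repressor     10
```

The three planted repressors — and nothing else — are recovered as
`up_in_high`: disrupting them makes cells bright, those cells concentrate
in the top 5% gate, and their insertion sites are over-represented in the
high-bin libraries relative to the depleted control (log2FC ≈ 8.5, i.e.
several-hundred-fold after equalization).

File-based screens work the same way through `pipeline_config()` +
`run_screen()` (plot files, FASTA, GFF3, sample sheet in; count,
enrichment, call tables and a checksum manifest out), and
`run_comparison()` overlaps calls across screens. A thin command-line
wrapper with `simulate` / `screen` / `compare` / `assay` subcommands is
installed at `inst/cli/sortnscreen`.

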