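---
title: "Methods: analysing sorted transposon insertion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing sorted transposon insertion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortnscreen)
```

## The screen and its statistical question

A sorted transposon screen couples three ingredients: a dense random
transposon mutant library in a strain carrying a fluorescent transcriptional
reporter; fluorescence-activated cell sorting of that library into a bright
tail (*high*, ~5% of cells), a dim tail (*low*, ~5%) and the central mass
(*depleted*, ~90%); and deep sequencing of transposon-genome junctions in
each sorted fraction. If disrupting a locus raises reporter output (the
locus represses the reporter), mutants carrying insertions in that locus
concentrate in the *high* bin; if disruption lowers output, they concentrate
in *low*. The *depleted* bin, holding the bulk of phenotypically neutral
mutants, is the natural control population.

The statistical question per genomic feature is therefore: are unique
insertion sites in this feature over-represented in a sorted tail relative
to the depleted control, beyond what sampling noise explains?

## From reads to counts

**Plot files.** The sequencing side of the screen is summarised per sample
as a per-base *plot file*: one line per genome position, two integer
columns (plus- and minus-strand junction reads). `read_plot_file()`
validates length and integer-ness and `write_plot_file()` inverts it
exactly. Internally the package treats each line as the count of reads
whose insertion point is that base; whether an upstream pipeline encoded
5′ ends or another convention does not affect downstream analysis, because
only the *set of non-zero positions* (and its per-sample depth) enters the
statistics.

**Unique insertion sites.** `profile_to_sites()` reduces a profile to its
distinct `(position, strand)` sites. Unique sites, not read counts, are
the count unit: read depth per site is dominated by library-preparation
amplification, while the number of distinct insertion events in a feature
is what sorting redistributes. Strand-aware identity is the default since
the file format separates strands; `collapse_strands = TRUE` merges the
two orientations at one position for sensitivity analysis.

**Feature universe.** `build_feature_universe()` augments the annotated
genes with one intergenic feature per maximal uncovered gap, named by the
flanking genes. Intergenic regions are first-class testable features —
regulatory sites between genes (promoter/operator regions, small RNAs) are
exactly the loci a reporter screen can reveal and would be invisible in a
genes-only universe. Every genome position is covered, so every site is
assignable; sites in overlapping genes increment every covering feature
and the resulting assignment inflation is flagged rather than fractionally
split, keeping counts integral and auditable. Feature termini are not
trimmed (no exclusion of 3′-tail insertions); this is a documented
divergence risk against pipelines that do trim.

## The enrichment test

**Model.** Unique-site counts of feature *f* in sample *j* are modelled as
negative-binomial with mean proportional to the sample's library size and
a common dispersion φ (variance μ + φμ²). Libraries are first equalized:
counts are rescaled to the geometric mean library size and rounded
half-to-even (`equalize_libraries()`), a deterministic stand-in for
resampling that keeps the test path free of hidden randomness.

**Dispersion.** `estimate_common_dispersion()` uses per-feature
method-of-moments within replicate groups — for feature *f* with replicate
mean *m* and variance *v*, φ̂_f = (v − m)/m² — pooled by degrees of
freedom, then aggregated by a 30%-trimmed mean across features with total
count ≥ 5, floored at 0. In the screen workflow the depleted replicates
supply the estimate, being the deepest and least affected by selection.
The estimator is deliberately transparent and enumeration-testable rather
than likelihood-based; simulation shows it recovers a generating φ = 0.2
as ≈ 0.15–0.18 with 3+3 replicates at 500 features (a known mild downward
bias of trimming a right-skewed estimator distribution) and returns 0 for
Poisson data. With one replicate per group it returns φ = 0 with a
warning.

**Exact test.** For a contrast (bin vs depleted) the group sums
a = Σ bin counts and b = Σ depleted counts are compared conditionally on
t = a + b. The sum of n iid NB(μ, φ) counts is NB(nμ, φ/n) exactly, and
because both group sums share the NB success probability 1/(1 + φμ), the
conditional distribution of the split (x, t − x) is free of μ:

  P(x | t) ∝ C(x + n_a/φ − 1, x) · C(t − x + n_b/φ − 1, t − x)

(`nb_split_probs()`; at φ = 0 this is Binomial(t, n_a/(n_a + n_b))). The
two-sided p-value is the minimum-likelihood rule: the total probability of
all splits no more probable than the observed one, with a 1 + 1e−12
relative tolerance for floating-point ties. This matches the classic exact
workflow for count data with the "small-p" rejection region; the package's
implementation agrees with edgeR's `exactTest(rejection.region = "smallp")`
to ~1e−14 on equalized libraries, and edgeR serves only as a cross-check
in the test suite. Fold-changes are
log2((a + c)/n_a) − log2((b + c)/n_b) with pseudo-count c = 0.5
(configurable) so zero-count features stay finite; c = 0.5 is a
convention, not a claim of equivalence to any other tool's fold-change.

**Thresholds and calls.** Within each contrast, Benjamini–Hochberg
adjustment (`adjust_bh()`, a validated front-end to `stats::p.adjust`)
controls FDR; a feature is *enriched* when adjusted p < 0.05 **and**
signed log2FC > 0.5. The signed criterion is deliberate: enrichment of a
bin over its control is directional by construction, and a feature
depleted from a bin is not a hit in that bin. `call_regulators()` then
classifies: enriched in high only → `up_in_high` (the locus represses the
reporter), low only → `up_in_low` (activator), both → `ambiguous`
(excluded downstream — opposing effects of insertion position within one
locus cannot be separated by this design), neither → `ns`.
`compare_screens()` computes exact subset membership of significant loci
across screens and the percentage of the union shared by all screens.

## The synthetic screen generator

`simulate_screen()` produces everything the pipeline consumes — FASTA,
GFF3, plot files, sample sheet — plus the planted truth, from one seeded
config, so every stage is testable against known ground truth.

The generative model, stage by stage:

1. **Genome and annotation**: a uniform random sequence (non-repetitive
   with overwhelming probability, so exact-match placement is unambiguous)
   tiled with genes occupying 60–85% of equal slots, guaranteeing
   intergenic gaps on both sides of every gene.
2. **Mutant pool**: `n_insertions` distinct `(position, strand)` sites
   drawn uniformly; the default density of one insertion per 18 nt matches
   the observed density of a saturated Tn5 library on a ~5 Mb chromosome
   (~278,000 sites). Relative mutant abundances are symmetric-Dirichlet
   around uniform (concentration 5), emulating outgrowth variation.
3. **Sorting** (per replicate): each of `cells_sorted` cells carries one
   insertion (multinomial over abundances; no double mutants, matching
   single-insertion library construction). Its log-fluorescence is the log
   of the product of effect multipliers of the features covering its
   insertion site — intergenic regulatory regions work identically —
   plus Normal(0, `noise_sd`) noise. Gating is by empirical quantiles with
   stable tie-breaking: exactly `round(n·0.05)` cells low and high, the
   rest depleted, reproducing "5% of the total" by construction. The
   default `cells_sorted = 2e7` is the scale of the real sorts.
4. **Sequencing** (per bin × replicate): `reads_per_sample` reads drawn
   over the bin's cells through normalized gamma weights with common shape
   1/`phi_seq` and scale proportional to cell count, giving per-site read
   counts approximately NB with dispersion `phi_seq` — a single
   overdispersion knob that the dispersion estimator can recover. (A
   literal symmetric Dirichlet-multinomial cannot give every site the same
   per-count dispersion; its variance inflation is depth-coupled, which at
   these depths degenerates into read pile-up on a few sites.)

Defaults that are modelling choices rather than reported study conditions:
`noise_sd = 0.35` (natural-log units; a 10× regulator effect is then ~6.6
noise SDs, strong but not deterministic), planted effect sizes 10× for
repressors and 0.1× for activators (reporter screens target effects well
above noise; true effect sizes are unknown), `phi_seq = 0.05` and
abundance concentration 5 (mild, realistic heterogeneity). These were
fixed before validation and are not tuned per test.

**What the simulator does not model**: FACS compensation and sorter purity
modes, co-reporter channels, outgrowth bottlenecks between conjugation and
sorting, PCR jackpotting beyond the single overdispersion knob, repeat
sequences and multi-mapping, and insertional position effects within a
feature. Passing recovery tests on synthetic screens therefore shows the
statistics and bookkeeping are correct under the stated model — not that
any real screen satisfies that model.

## Problem sizes used for validation

The package's tests and the acceptance script run the full generative and
analysis chain at a desk scale chosen to finish in seconds while keeping
every statistical regime non-degenerate: genome 120 kb, 100 genes (a
~201-feature universe with intergenic regions), one insertion per 18 nt
(≈ 6,700 sites), 2 × 10⁵ cells sorted per replicate, triplicate sorts,
5,000 reads per library. At these depths a depleted library recovers
roughly half the pool's sites and the sorted tails proportionally fewer —
the partial-recovery regime of real libraries, where between-replicate
variance is informative. Null screens (all effects 1) across five seeds
yield zero regulator calls, the null fraction of p < 0.05 at the true
dispersion sits near 0.045, and ten planted 10× repressors among ~200
features are recovered 10/10 as `up_in_high` with no direction inversions
across seeds.

## Numerical and degenerate-input conventions

* Conditional probabilities are computed in log space and normalized by
  log-sum-exp; enumeration is O(t) per feature.
* A zero total (t = 0) returns p = 1 and log2FC = 0 by convention.
* Minimum-likelihood tie comparison uses a 1 + 1e−12 relative tolerance.
* Rounding of equalized counts is half-to-even (base R `round`),
  eliminating directional bias.
* Negative method-of-moments dispersion estimates floor at 0; the φ = 0
  branch of the exact test is the exact conditional binomial, not a limit
  approximation.
* Empty sorted bins sequence to all-zero profiles with a warning; empty
  gene sets make the whole genome one intergenic feature.
* Fluorescence ties in gating break by stable cell order.
* Tag verification counts `N` as a mismatch (conservative, deterministic)
  and applies the tag check before 3′ trimming — the tag must be intact at
  the 5′ end for the read to be a junction read at all, and trimming
  afterwards cannot change the prefix already removed.

## Design choices where the design was open

* **Strand-aware unique sites** by default (the file format separates
  strands; pooling is available as a switch) — whether the original
  tooling pooled strands is unknown, so both modes are testable.
* **Exact-match read placement only** (`place_read()`), reporting
  ambiguity rather than choosing among multiple hits: the mapping stage of
  real screens belongs to dedicated aligners, and real-data users are
  expected to supply plot files produced upstream. The insertion point is
  defined as the genome coordinate of the read's first sequenced base on
  its strand, applied identically in the simulator and the quantifier.
* **Library equalization instead of TMM-style normalization**: the
  conditional test needs comparable library sizes, and unique-site counts
  lack the composition-bias structure TMM targets; which normalization the
  original analysis used is not stated.
* **Per-screen contrasts only** — the depleted control of one screen never
  serves another screen.
* **Detection floors in the assay calculators** (one transconjugant, one
  plaque) reported as bounds (">N-fold"), matching how such assays are
  reported; the one-plaque substitution rule records a plaque at the first
  dilution *without* clearing.

## Known limitations

* The dispersion estimator's downward bias at 2–3 replicates makes the
  exact test mildly anticonservative when counts are truly NB; in the
  screen regime simulated here (site-detection counts, which are
  binomial-thinned and hence under- rather than over-dispersed) the floor
  at 0 makes the test conservative instead. Users with strongly
  overdispersed real libraries can override φ via `enrich_screen(phi=)`.
* Saturated libraries (every site detected in every replicate) drive all
  replicate variance to zero and every p to 1 — sequencing deeper than the
  pool is uninformative for enrichment, which the package reports honestly
  rather than correcting.
* Multi-replicon genomes are handled one replicon at a time; profiles are
  keyed to a single sequence id.
* The comparison of screens assumes identical feature universes; comparing
  screens annotated differently requires re-annotation, not id matching.
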