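---
title: "Benchmarking runs-of-homozygosity detection with rohsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking runs-of-homozygosity detection with rohsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohsim)
```

## The problem

Runs of homozygosity (ROH) are contiguous genomic intervals over which an
individual's genotypes are homozygous; long ROH arise when both chromosome
copies descend from a recent common ancestor, so the fraction of the
autosomes covered by ROH,

\[ F_\mathrm{ROH} = \frac{\sum_i L_{\mathrm{ROH},i}}{L_\mathrm{autosomes}}, \]

is a widely used estimate of individual inbreeding in conservation
genomics. ROH are detected from whole-genome sequencing data, and the
detection is sensitive to everything in the pipeline: sequencing depth,
read length, the contiguity (contig N50) of the reference assembly, and
the phylogenetic distance between the reference and the target population.
`rohsim` quantifies these sensitivities with a fully synthetic, seeded
benchmark in which the true ROH are known by construction, so every
detection can be scored against truth.

## The synthetic population

`sim_config()` + `plant_population()` generate a diploid population in
which each individual carries planted ROH:

* ROH intervals are drawn from a length mix spanning the reporting classes
  (0.5–1, 1–5, 5–10, 10–25, >25 Mb; classes that do not fit the simulated
  contigs are dropped and the weights renormalised) and placed by rejection
  sampling until the truth \(F_\mathrm{ROH}\) is within ±0.5 percentage
  points of its target. The default target ladder is the eight-individual
  inbreeding gradient 5.66%–47.73%.
* Heterozygous SNPs are planted as a Poisson process at rate
  \(\theta = 10^{-3}\) per base strictly outside ROH (a typical mammalian
  genome-wide heterozygosity); homozygous-alternative SNPs are planted at
  rate \(\phi = \theta\) genome-wide, so ROH contain homozygous SNPs and
  remain visible to a density-filtering caller.
* Planted ROH keep a minimum separation of 600 kb (`min_roh_gap`). This is
  a deliberate design choice: the post-processing step that concatenates
  falsely fragmented ROH bridges gaps up to 500 kb, and planting truth
  segments closer than that bound would make them indistinguishable from a
  single segment at the benchmark's own reporting resolution.
* All randomness descends deterministically from `cfg$seed`; identical
  seeds give bit-identical populations.

The generator makes no attempt at coalescent realism: there is no
recombination map, no allele-frequency spectrum, no shared polymorphism
between individuals, and ROH are planted rather than inherited. Variants
are therefore private to individuals, which has one important consequence
discussed under LD pruning below.

## Haplotypes and read simulation

`build_haplotypes()` substitutes each individual's variants into the
reference: homozygous-alternative alleles on both haplotypes, heterozygous
alleles on exactly one haplotype chosen by a seeded fair coin (the input
genotypes are unphased, and phase is irrelevant to ROH truth).
`rederive_genotypes()` inverts the construction and is used as a
round-trip validator.

`simulate_reads()` is a wgsim-style simulator: fragments of normally
distributed length (mean 500, sd 50 — the wgsim defaults) are placed
uniformly along each haplotype, and the two read mates are the fragment
ends. The number of pairs per haplotype is
`round(depth * len / (2 * 2 * read_len))`, so the *pooled* coverage of the
two haplotypes equals the nominal diploid depth — "20×" always means 20×
on the diploid genome. Reads carry their true origin (haplotype, contig,
fragment start), so no alignment stage is needed and the pileup is exact;
`write_fastq()` materialises sequences on demand. Lower depths are derived
from one maximum-depth read set by Bernoulli thinning of read pairs
(`subsample_depth()`), which preserves across-depth correlation within a
replicate.

## The pileup caller and allele dropout

`pileup_call()` counts, per assayable site, the reads overlapping it from
each haplotype; each read reports its haplotype's base. The genotype rule
is threshold-based (`call_config()`): a site with fewer than `min_depth`
reads is missing; an allele counts as observed at `min_allele_reads`
reads; both alleles observed means het, otherwise a homozygote of the
observed allele. With balanced haplotype coverage, a heterozygous site
covered by exactly \(n\) reads is miscalled homozygous with probability
\(2^{1-n}\) — the classical allele-dropout rate — and at Poisson depth
\(d\) the dropout fraction among called sites is
\(\sum_{n \ge m} \mathrm{Pois}(n; d)\, 2^{1-n} / \sum_{n \ge m}
\mathrm{Pois}(n; d)\) with \(m =\) `min_depth`. The acceptance suite
checks the simulation against this closed form.

`min_depth` defaults to 1. This mirrors how likelihood-based callers
behave at low coverage — they emit a genotype from a single read — and it
is what produces the characteristic depth response: at 2× roughly
\(e^{-2} \approx 14\%\) of sites have no reads at all and the window
scan's missing-call allowance breaks down (underestimation), between
roughly 3× and 6× dropout converts scattered heterozygotes to homozygotes
and segments are over-extended (overestimation), and from ~15× both
effects are negligible. Raising `min_depth` trades dropout for
missingness and pushes the whole pipeline towards underestimation at low
depth.

## Reference fragmentation and divergence

`insert_gaps()` degrades contiguity by replacing 300-base runs with `N` at
uniformly random positions. Replacement (rather than insertion) keeps all
coordinates valid across the whole contiguity ladder, which removes any
need for lift-over when comparing against truth; contiguous non-N
segments define the contigs whose N50 `contig_stats()` reports.
`fragment_to_ladder()` repeats insertion cycles — roughly one new gap per
existing contig per cycle, halving the N50 each time — and snapshots the
gap map after each cycle, returning for each target the snapshot with the
closest N50 (required to be within a factor of 2).

Because no re-mapping takes place, the consequence of fragmentation is
modelled as an explicit error channel on called genotypes
(`apply_fragmentation()`): sites inside an N run are omitted (missing),
and sites within `edge_window` = 5 kb of a gap boundary are miscalled
(hom↔het) with probability `edge_err` = 0.02. The window and rate are
artifact parameters: the benchmark's source material quantifies the
*consequence* of fragmentation (erroneous or omitted SNPs near breaks
fragmenting long ROH) but not the per-site error process, so both are
exposed and reported with results.

Two regimes are worth distinguishing on a contiguity ladder. Once the N50
falls below roughly a quarter of the mean planted ROH length, long
segments are broken and the detected segment count *inflates* beyond
truth while mean length falls — the behaviour the benchmark is designed
to expose. Under extreme fragmentation (N50 of a few tens of kb, where
the 5 kb edge windows tile essentially the whole genome), the modelled
edge errors shatter candidates below the 500 kb reporting floor and
detection collapses instead: counts fall and \(F_\mathrm{ROH}\) tends to
zero. The second regime is a property of this phenomenological error
channel at its default rate and is reported as such; the package's ladder
experiments therefore place their lowest rungs in the inflation regime,
just below the contiguity threshold at which the count inflation sets in.

`diverge_reference()` emulates a related-species reference
phenomenologically: base substitutions at a configurable rate plus
rearrangement breakpoints that cut and shuffle the genome. Downstream,
`apply_divergence()` treats the substitution rate as genome-wide genotype
noise and each breakpoint as an implied gap covering a ±500 bp mapping
dead zone (`break_halo` — reads spanning a rearrangement junction cannot
map consistently within roughly a fragment length). This is the mechanism
by which a diverged reference behaves like a fragmented one: as the
breakpoint count grows, long ROH fragment into sub-5 Mb pieces whose
flanks are too short for gap-merging to reconnect. Cross-species
alignment itself is out of scope.

## The ROH callers

`call_roh_window()` reimplements the PLINK `--homozyg` scan:

1. every contiguous window of `window_snps` sites is homozygous iff its
   het count ≤ `window_het_allow` and missing count ≤
   `window_missing_allow`;
2. each site's hit rate is the fraction of windows containing it that are
   homozygous; the site passes at `window_hit_threshold`;
3. maximal runs of passing sites are trimmed so both ends are homozygous
   non-missing calls;
4. runs are split at inter-site gaps above `max_internal_gap_kb`;
5. candidates are kept when they span ≥ `min_kb` kb, contain ≥ `min_snps`
   sites and have mean density ≤ `density_kb_per_snp` kb per SNP (PLINK's
   `--homozyg-density` semantics; a sliding local-density test is out of
   scope).

Knobs not fixed by the published protocol default to the PLINK 1.9 values
(het allowance 1, missing allowance 5, hit threshold 0.05, gap 1000 kb,
density 50 kb/SNP). The scan is verified against an exhaustive-window
brute-force oracle on hundreds of random instances.

`ld_prune()` implements `--indep-pairwise`: within a sliding window, any
kept pair of sites whose allele-dosage \(r^2\) (pairwise-complete across
individuals) exceeds the threshold loses its *later* site — a
deterministic tie-break; the MAF-based choice made by the original tool is
immaterial here because simulated dosage columns are near-symmetric. The
window argument of the published command line (`50 1 0.8`) is a SNP-count
window in the tool itself even though prose descriptions often say "kb",
so the unit is an explicit flag defaulting to SNP count.

The *baseline* pipeline applies no LD pruning (`prune_r2 = NA`). Planted
variants are private to individuals, so any two sites carried by the same
individual have identical dosage patterns and \(r^2 = 1\): on this
synthetic population pruning degenerates into density thinning rather than
the removal of genuine linkage redundancy. Pruning is therefore exercised
where it is the object of study — the parameter-grid driver and the
published presets — and not silently in every sweep.

`call_roh_hmm()` is a deliberately simplified two-state
(ROH / non-ROH) Viterbi caller with Bernoulli het emissions and
distance-dependent transitions (leave-state probability
\(1 - e^{-d/\ell}\) across an inter-site distance \(d\), with \(\ell\) the
mean state tract length; missing sites emit nothing). It exists as a
likelihood-based alternative for caller-comparison experiments — the two
callers disagree mainly on sub-500 kb fragments — not as a bit-for-bit
clone of any named tool. Its Viterbi path is verified against exhaustive
path enumeration on small instances.

`gap_merge()` concatenates falsely fragmented ROH: adjacent segments merge
when the gap between them is at most 500 kb *and* at least one flanking
segment is at least 4 Mb, repeated to a fixpoint. The (gap, flank) rule is
reconstructed from the documented failure condition of the merging step
("either shorter than 4 Mb or the gaps between them were longer than
500 kb") and both bounds are arguments. `filter_min_length()` then keeps
segments strictly longer than 500 kb.

## Metrics

`f_roh()` uses the intact reference's total length as denominator
everywhere (coordinates are preserved across fragmentation, keeping the
comparison fixed-denominator); `f_roh_error_ratio()` is
\((\mathrm{detected} - \mathrm{real})/\mathrm{real}\).
`length_class_table()` bins spans into (0.5,1], (1,5], (5,10], (10,25] and
>25 Mb — right-closed exactly as the classes are conventionally printed,
so a 5 Mb segment belongs to (1,5]. `snp_error_ratio()` is the number of
erroneously called SNPs over the number of truth variant sites, with
missingness reported separately. `detection_ratio()` declares a truth
segment correctly detected when detected segments cover ≥ `overlap_q` of
its bases and extend beyond it by at most \(1 -\) `overlap_q` of its
length; `overlap_q` defaults to 0.9 and is a stated convention (reported
alongside results), not an inference.

## Sweep drivers and problem sizes

`run_depth_sweep()`, `run_n50_sweep()`, `run_readlen_sweep()` and
`run_param_grid()` chain the stages into complete, reproducible grids; a
failed cell is recorded in its row and the run continues. Every cell
carries its replicate seed, the realised depth or achieved N50, and the
full metrics row. `presets()` exposes the published parameter
recommendations (`lowdepth`, `lowdepth_highF`, `fragmented_ref`,
`plink_default`).

The package's own test and acceptance runs use desk-scale genomes chosen
so that every planted length class that fits is represented and the
≥500 kb reporting floor is well resolved: 2 × 25 Mb for the
high-depth truth-recovery check, 1 × 10 Mb (eight individuals, ten
replicate seeds) for the depth response, 2 × 10 Mb with a six-rung ladder
bottoming at 0.3 Mb N50 for the contiguity response, and 1 × 10 Mb for the
read-length comparison. Full chromosome-scale runs (e.g.
`sim_config(n_contigs = 4, contig_len = 150e6)`) are a configuration
choice, not a different code path.

## What passing tests do and do not show

The generator reproduces the *mechanisms* that degrade ROH detection —
allele dropout, missingness, window-scan geometry, reference breaks — under
clean conditions: error-free reads, exact origins, uniform SNP placement,
private variants. Passing the qualitative suite therefore shows that the
pipeline responds to depth, contiguity and read length the way the
benchmark's source observations describe; it does not certify quantitative
error rates for real data, where mapping error, base-quality error,
shared polymorphism and genuine LD structure all contribute. In
particular, absolute \(F_\mathrm{ROH}\) biases at 3–6× are milder here
than with real callers because the synthetic site density outside ROH is
high and unstructured.

## Numerical choices and degenerate inputs

* Dosage correlations with zero variance (constant columns) are treated as
  undefined and never prune a site.
* Viterbi ties are broken towards staying in the current state; with
  continuous emission parameters ties have measure zero.
* `plant_individual()` fails loudly (naming the contig) after 1,000
  placement rejections per interval and 20 whole-individual retries,
  rather than silently biasing the target; targets whose ROH budget is
  below one minimum-length segment are rejected as configuration errors.
* Contigs with fewer sites than one scan window are skipped with a
  warning; contigs shorter than the mean fragment length are skipped by
  the read simulator with a warning.
* All exported randomness flows through explicit integer seeds; internal
  stream separation derives child seeds from (seed, stage, key) so that
  adding a stage never perturbs another stage's stream.
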