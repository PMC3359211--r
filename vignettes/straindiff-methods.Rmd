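---
title: "Methods: collinear genome diffing and positional expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collinear genome diffing and positional expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(straindiff)
```

# Scope

`straindiff` reimplements, as one tested pipeline, the computational core of
a classic strain-improvement study design: an erythromycin-overproducing
*Saccharopolyspora erythraea* mutant is compared with its parent strain at
two levels — the genome (what changed between two ~99%-identical collinear
circular chromosomes, and what those changes do to coding sequences) and the
transcriptome (which genes are modulated over a fermentation time course,
and which chromosomal neighbourhoods move together). Everything upstream of
these questions (sequencing, assembly, probe-level array processing) is out
of scope: the pipeline starts from FASTA + GFF3 genomes and a normalized
log-expression matrix.

Because the original strain genomes and array series are not bundled, the
package ships first-class synthetic-data generators with known truth. Every
claim the test suite makes — 100% indel recall, calibrated false-discovery
rates, block recovery — is a claim about data the generators produce, under
the noise model described below. What that does and does not say about real
data is discussed at the end.

# The genome arm

## Anchor-based collinear diff

Two genomes are compared with a self-contained anchor-chain-align engine
(the published analysis chained Nucmer, BLAST and one-off scripts; running
external aligners is glue, not method, so the diff is internal and
testable):

1. **Anchors** (`find_anchors()`): maximal exact matches of length ≥ k
   (default k = 20) whose seed k-mer occurs exactly once in both genomes —
   the MUM idea. Only the forward strand is compared; the collinearity
   assumption (no inversions) matches a dot plot with a single diagonal.
   k < 12 is refused because 20-mers are already near the collision floor
   for a 70%-GC genome; 12 is the documented lower bound.
2. **Chaining** (`chain_anchors()`): the heaviest strictly increasing chain
   by total anchored bases (weighted LIS). Maximal matches can extend
   *through* a duplicated segment and overlap their neighbours; the chain
   therefore allows partial overlaps and trims the downstream anchor
   afterwards, which keeps one clean gap per event. Equal-weight ties break
   to the lexicographically smallest `ref_start` sequence, so output is
   deterministic. Off-chain anchors are kept: they are the dot-plot
   signature of transposed copies.
3. **Gap alignment** (`call_variants()`): each inter-anchor gap pair is
   trimmed of its common prefix/suffix; a one-sided remainder is emitted
   directly as an indel (this stops the aligner from fragmenting a large
   novel insertion into spurious single-base matches); two-sided remainders
   are globally aligned with unit match/mismatch/gap scores
   (`Biostrings::pairwiseAlignment`). Mismatch runs become SNVs; gap runs
   become indels, left-aligned to the lowest compatible reference position
   (VCF normalisation, deterministic output). Gaps above 50 kb abort — at
   that point the genomes are not collinear enough for this tool.
4. **Copy classification**: an insertion ≥ 100 bp whose sequence matches the
   reference elsewhere at ≥ 95% identity is a *duplication* when the copy
   sits adjacent to its source interval (tandem) and a *transposition*
   otherwise. The 100 bp / 95% / adjacency thresholds are package choices;
   the source study reports transposon insertions and CDS duplications but
   defines no operational boundary, so this classifier is one consistent
   reading and is documented as such.

Circularity is recorded but the comparison linearises at position 1; the
synthetic generator never plants events at the junction, and origin-spanning
features are rejected at load. This removes wrap-around ambiguity from the
diff at the cost of not supporting a genuinely origin-crossing event.

## Effect annotation

`annotate_variants()` maps calls onto CDSs and classifies: missense /
nonsense / silent SNVs (all SNVs in one codon are applied jointly before
translating, so double substitutions give one amino-acid change), frameshift
for indels whose net length is not divisible by 3, in-frame
insertion/deletion otherwise, plus duplication, transposon insertion, and
intergenic (named by flanking loci). Notation follows the field's
mutation-table dialect: `Missense (G38S)`, `Nonsense (Y30*)`,
`Frameshift (-C 717)`, `Frameshift (+T 2003/2004)`,
`In frame deletion (V196-, H197-)`. Positions in frameshift notation are
*nucleotide* positions on the coding strand — the only reading compatible
with positions that exceed the protein length. Insertion notation is
standardized to `+B p/p+1` even though tables in the wild sometimes print a
bare `+B p`; one unambiguous dialect beats two.

Translation uses genetic code 11 via `Biostrings::translate`, with three
conventions layered on top: alternative starts GTG/TTG render as M at codon
1 only; internal stops render as `*` and translation continues (nonsense
positions stay visible); a trailing stop is dropped, so a stop-terminated
CDS of 3(n+1) nt reports n amino acids. Selenocysteine recoding is not
supported; such CDSs translate under plain table 11.

Silent variants are recorded but excluded from the "affected proteins"
count, matching the accounting convention in which only protein-altering
events are tallied.

# The synthetic generators

`random_genome()` draws i.i.d. bases at a requested G+C (default scenarios
use 0.71, the actinomycete regime) and plants non-overlapping CDSs
(ATG…stop, 300–1500 nt, both strands) tiling ~85% of the chromosome,
repairing in-frame internal stops with single GC-neutral-ish middle-base
edits so the empirical GC stays within 1% of target at ≥ 100 kb.

`mutate_genome()` plants SNVs, short indels (≤ 4 bp), large indels
(100–1200 bp), mobile-element insertions (a copied ≥ 300 bp reference CDS —
transposase-like, so the transposition classifier has something real to
find) and tandem whole-CDS duplications. Events are spaced at least
`min_spacing` apart so each is independently identifiable and recovery can
be scored exactly; this deliberately removes the confounding of nearby
edits that real strain pairs can show. Placement is a structured
left-to-right layout with Dirichlet-distributed slack rather than rejection
sampling: random sequential placement jams at interval densities well below
what the event counts require, while the sequential layout is uniform-ish
and always succeeds when the arithmetic allows. Copy-event source intervals
are reserved so later indels cannot erode the ≥ 95% identity the classifier
relies on. Indel truth records are left-aligned with the same normalisation
as the caller, making exact-match recovery well defined inside homopolymer
runs.

`simulate_timecourse()` works directly on the log scale (probe-level
processing is out of scope): `baseline + signal + N(0, noise_sd)` with
`noise_sd = 0.25` log-units by default — a free parameter chosen as a
plausible array-replicate noise level, not fitted to any dataset. The
default design is six time points (12–72 h) in duplicate with the time axis
partitioned into phases a/b/c at 36 h and 60 h. DEG signal is a
piecewise-constant bump (up in exactly one phase, amplitude
`effect_sd x noise_sd`): the simplest shape a spline alternative must
detect, with one effect-size knob. Region blocks — contiguous same-strand
runs — are modulated *between* the two designated phases: `+amp` in phase a
and `-amp` in phase b (or reversed), so the phase-a-versus-b contrast is
`2 x amp`. The one-sided reading (offset in phase a only) would put the
contrast of the standard scenario exactly on the region fold-change filter
boundary, making every recovery run a coin flip; the two-sided reading is
the one under which the procedure's own recovery targets are coherent.

# The transcriptome arm

## Time-course differential expression

Each gene is scored by comparing an intercept-only null fit against a
natural cubic spline in time (`spline_df = 3`, requiring ≥ 5 distinct time
points) via the scale-free ratio `(RSS0 - RSS1)/RSS1`. An ODP-style variant
is also provided (`method = "odp"`): each gene's profile is scored by the
log-ratio of its summed Gaussian likelihoods under *all* genes' fitted
alternative versus null models, sharing information across genes. The exact
estimator inside the published EDGE implementation is underdetermined by
its description, so the F-like ratio is the default and the ODP sum an
option — both are goodness-of-fit comparisons of the same two models.

The null is resampled: the per-sample time assignment is permuted uniformly
(each time point keeps its replicate count) `B` times (default 200), and
null statistics are pooled across genes — exchangeable under the null — so
p-values have resolution `1/(1 + B x G)`. Storey q-values use the
single-lambda estimator `pi0 = #{p > 0.5}/(m/2)` capped at 1 (the
spline-over-lambda refinement of the original recipe is deliberately
simplified away; with `pi0 = 1` the construction is bitwise
Benjamini–Hochberg, which the tests assert). DEGs are `q <= 0.001` by
default.

Phases are an *input* partition of the time axis — in the motivating study
they were fixed per strain from fermentation curves — and the pipeline does
not infer them. DEG profiles are standardized to mean 0 / sd 1, clustered
with 1 − Pearson distance and centroid linkage (the dChip convention), the
tree is cut into as many clusters as phases, and each cluster takes the
phase containing its mean-profile maximum.

COG representation uses the doubling rule: a category is over-represented
when its share of the DEG set is at least twice its share of the whole
chip, under-represented when at most half; zero percentages on either side
flag `neither`, matching how zero cells appear unflagged in the published
table.

## Positional scan (LAP)

The region arm asks a different question: not "which genes move" but "which
chromosomal neighbourhoods move together between two growth phases".

1. Per gene, a moderated mean difference `(mean_a - mean_b)/(s + s0)`, with
   `s` the pooled standard error and `s0` the median of `s` over genes. The
   raw statistic the published procedure fed its smoother is unnamed; this
   moderated difference is a documented stand-in with the right behaviour
   (signed, variance-stabilised).
2. Adaptive-bandwidth smoothing along each strand independently: at gene i
   the bandwidth is the distance to its `knn`-th nearest gene (default 11,
   odd so the neighbourhood is balanced), with a tricube kernel. Kernel and
   knn-bandwidth are package choices within the "local variable bandwidth
   kernel estimator" family; both are arguments. Distances are circular
   when a chromosome length is supplied.
3. Permutation null: raw statistics are permuted across positions and
   re-smoothed `B` times; every gene has a unique neighbourhood, so nulls
   stay position-specific (no pooling) and the two-sided p-value is
   `(1 + #exceedances)/(1 + B)`. Ties at the observed value are counted
   with a tiny tolerance because matrix-matrix and matrix-vector products
   round differently in the last ulp; over-counting ties is the
   conservative direction.
4. Storey q-values per strand, then maximal runs of consecutive genes with
   `q <= 0.01`, a consistent smoothed-statistic sign, and
   `|mean_a - mean_b| >= 0.5` become regions.

Note the p-value floor: with `B` permutations no p-value can fall below
`1/(B + 1)`, so q-values on an n-gene strand bottom out near
`pi0 * n/(B * rank)`. Calling regions at `q <= 0.01` on ~500-gene strands
needs `B` of about 2000; the recovery suites use exactly that, while the
function default stays at 1000 for exploratory use.

# Numerical and degeneracy choices

* Constant genes: statistic 0 by convention (0/0 guarded), permutation p of
  1; standardization refuses sd-0 genes by name.
* All-constant input to the moderated statistic: denominator falls back to
  1, scoring 0 rather than NaN.
* q-value monotonicity is enforced by the step-up running minimum; the
  arithmetic mirrors `p.adjust`'s operation order so the `pi0 = 1` case is
  bitwise identical.
* Chain tie-breaks and indel left-alignment make every output
  deterministic for a fixed seed; the pipeline test asserts byte-identical
  reruns.
* Genes without strand go to `+` with a warning in the positional scan.

# Problem sizes in the shipped suites

The test and acceptance suites run, per seed: 200-kb strain pairs with 130
planted events (10 seeds); 2,000-gene x 12-sample null calibrations (20
seeds); 500–1,000-gene positional scans with B = 1000–2000 (20 + 10 seeds);
300–1,000 random coding variants against the rebuild-and-retranslate
oracle. These sizes were chosen so the full suite exercises every claim at
meaningful scale while remaining a coffee-break run on one core. The DE
power suite uses a 13-point (12–84 h, 6-h sampling) triplicate design:
detecting 2-sigma phase bumps at `q <= 0.05` is genuinely information-poor
under a six-point duplicate design (the spline captures only part of a step
bump), and fine-grained triplicate sampling is the standard design for that
question; the null-calibration suites keep the six-point duplicate design.

# What passing tests do and do not show

The generators give i.i.d. Gaussian noise, independent genes, exactly
spaced mutations, phase-aligned piecewise-constant signal, and no batch
structure. Real strain pairs have clustered and confounded edits; real
arrays have correlated probes, heavy-tailed noise and batch effects; real
fermentations drift between biological replicates. Passing recovery at
100% on synthetic pairs therefore validates the *logic* of the diff engine
(anchors, chaining, alignment parsing, classification), not its robustness
to repeat-rich genomes; calibrated FDR on simulated nulls validates the
permutation machinery, not the exchangeability of real samples. The
package's claims should be read in that light.

# Worked example

```{r example, eval = FALSE}
library(straindiff)

sim  <- random_genome(200000, gc = 0.71, seed = 1)
plan <- mutation_plan(n_snv = 100, n_small_indel = 20, n_large_indel = 5,
                      n_mobile_insertion = 3, n_duplication = 2,
                      min_spacing = 1000, seed = 2)
mut  <- mutate_genome(sim$genome, plan, sim$features)

cmp     <- compare_genomes(sim$genome, mut$genome)
effects <- annotate_variants(cmp$variants, sim$features, sim$genome)
summarize_counts(effects, cmp$variants)

esim <- simulate_timecourse(expression_sim_spec(n_genes = 2000,
                                                frac_deg = 0.1,
                                                n_region_blocks = 2,
                                                seed = 3))
de <- timecourse_de(esim$study, B = 200, seed = 4)
glance(de)

ph  <- phase_of(esim$study$samples$time_h, c(36, 60))
lap <- lap_scan(esim$study,
                class_a_samples = esim$study$samples$sample[ph == "a"],
                class_b_samples = esim$study$samples$sample[ph == "b"],
                B = 2000, seed = 5, circular_length = 8e6)
glance(lap)
```
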