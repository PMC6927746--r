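---
title: "Methods: population genomics and field ecology of selfing wild isolates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics and field ecology of selfing wild isolates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildiso)
```

## Scope and model organismal assumptions

`wildiso` implements the downstream analysis of a wild-isolate survey of a
selfing nematode: strains are collected from field substrates, whole-genome
sequenced, and deduplicated into *isotypes* — groups of isolates sharing
more than 99.9% of their SNVs, each represented by one strain. Because the
species reproduces predominantly by hermaphrodite self-fertilization,
wild genomes are essentially homozygous; all population-genetic statistics
here treat genotypes as haploid (one allele per isotype), and residual
heterozygous calls are interpreted as noise or rare outcrossing and set to
missing before analysis (`haploidize()`).

Upstream read alignment and variant calling are out of scope: the package
starts from a multi-sample VCF of biallelic SNVs and from pairwise
identity-by-descent (IBD) segment tables.

## Variant filtering

Two regimes mirror the two uses of the calls:

* **Concordance grade** (strain deduplication): depth (FORMAT/DP) ≥ 3,
  mapping quality (INFO/MQ) > 40, variant quality (QUAL) > 30, allelic
  depth ratio (FORMAT/AD over FORMAT/DP) > 0.5.
* **Population grade** (population VCFs): depth > 10, MQ > 40, QUAL > 10,
  AD ratio > 0.5, then per-site flags `high_missing` (> 90% missing
  genotypes) and `high_heterozygosity` (> 10% heterozygous calls among
  non-missing). Soft filtering annotates the flags; hard filtering removes
  flagged sites and haploidizes.

All inequalities are applied strictly as written: a ratio of exactly 0.5
fails, 10% heterozygosity exactly is not flagged. Records that lack a
quality field (common in small fixtures) are treated as passing, with a
warning counter in the filter accounting, so toy inputs remain usable
while real runs stay auditable. Calls failing any threshold become
missing; sites left with no called genotype are dropped, with counts
logged — never silently.

## Isotype assignment

Pairwise concordance is the fraction of shared SNVs between two isolates,
computed over sites callable in both. Two readings of "shared" exist, and
the package exposes both:

* **agreement** (default): fraction of jointly-called sites with the same
  genotype;
* **jaccard**: shared ALT sites over the union of ALT sites.

The agreement reading is the default because it makes the published
clone-recovery behaviour attainable: under a realistic allele-frequency
spectrum an isolate carries the ALT allele at roughly `1/a1` of the
segregating sites (about a quarter), so the Jaccard denominator is ~4×
smaller than the number of genotyped sites and a clone pair with per-call
error rate `e` scores about `1 − 2e/0.25` — at `e = 5e-4` that is ~0.996,
below the 0.999 threshold, and true clones would *never* merge. Under
agreement the same pair scores `1 − 2e ≈ 0.999`, and the parent–copy link
(`1 − e`) clears the threshold. The Jaccard switch is kept for
compatibility with the shared-alt-site reading.

Isotypes are single-linkage connected components of the graph with an edge
wherever concordance strictly exceeds 0.999. Single linkage is chosen
because the threshold rule is not transitive and a deterministic
resolution is required; it also mirrors practice, where each new strain is
compared against existing isotype representatives. Isotype ids are the
lexicographically smallest member name; representatives have the fewest
missing calls (ties by name). Pairs with fewer than 100 jointly-usable
sites are flagged low-confidence because tiny denominators make the
fraction unstable.

## Windowed statistics among isotypes

Statistics are computed *among isotypes, not isolates*, to avoid
oversampling near-identical strains collected from the same substrate.
The grid is a 10 kb window sliding in 1 kb steps; windows start at 1 and
the last window is the final full window inside the chromosome, so every
interior position is covered by exactly `window/step` windows.

* **π**: per site, `2·p̂(1−p̂)·n/(n−1)` with `p̂` the ALT frequency among
  non-missing haplotypes; the window value is the site sum divided by the
  *full* window size (including invariant positions), which is what makes
  genome-wide values land on the ~10⁻³ per-site scale.
* **Watterson's θ**: `S/a1` per window, divided by window size.
* **Tajima's D**: the canonical 1989 constants (`a1…e2`); undefined —
  reported `NA`, never 0 — when `S = 0`, `n < 3`, or the variance term is
  0 (the degenerate `n = 3, S = 1` corner).
* **Hudson's F_ST**: per-site numerator
  `(p1−p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1)` and denominator
  `p1(1−p2) + p2(1−p1)`, combined per window as a *ratio of sums* — the
  standard low-bias choice for window estimators — and undefined where the
  denominator sum is 0.

Missing data: allele frequencies use the per-site non-missing count; `n`
in the Tajima constants is the sample's haplotype count; sites with fewer
than half the sample called are skipped (`min_completeness = 0.5`). This
floor only matters for inputs with missingness — the intended population
input contains sites with no missing calls.

Genome-wide π is reported as the unweighted mean over windows by default,
with a pooled normalization (site sum over genome length) as a switch;
the two differ only through edge windows and missingness.

**LD pruning** reproduces the greedy `--indep-pairwise`-style scan used
upstream of ancestry and phylogeny tools: within each window of 50 sites,
while any pair of retained sites has squared dosage correlation above the
cap (0.8 or 0.95 depending on use), the member with the lower minor-allele
frequency (ties: the later position) is removed; the window then advances.
Variants private to a single isotype can be dropped first, as done before
distance-based phylogenies.

## IBD, haplotype blocks, and swept chromosomes

Production analyses use IBDSeq segments (minalleles = 0.01, ibdtrim = 0,
r2max = 0.8 — recorded as provenance on the input); the package also ships
a simple internal detector so synthetic bundles run end to end: per pair,
maximal runs of identical non-missing calls tolerating at most
`max_mismatch` discordances (default 1), reported at spans ≥ 1 Mb with
overlapping runs merged.

Haplotype structure is inferred deterministically: chromosomes are
partitioned at all segment endpoints; within each elementary interval
isotypes are grouped by connected components of the segment graph
restricted to segments fully covering the interval; adjacent intervals
with identical component structure merge; singleton components carry no
group (uncolored regions in haplotype paintings). A group's identity is
its member set within a chromosome, so a recurring sharing pattern keeps
one label, and labels are invariant to input row order.

The *swept haplotype* is the most common group — maximal total bp across
member isotypes — on each of chromosomes I, IV, V and X (ties: more
members, then canonical label). The wording could also mean one
genome-wide haplotype; both scopes are exposed
(`scope = "genome_wide"`), with per-chromosome the default since sweeps
are called per chromosome downstream. Per isotype and chromosome, the
swept haplotype is **retained** when its summed length exceeds 1 Mb *and*
its ratio to the population-wide maximum exceeds 0.03; the chromosome is
**swept** when the retained sum exceeds 3% of that maximum. The two
numerically coincident ratio checks are applied sequentially, exactly as
printed. All three thresholds are strict: a retained sum of exactly
`0.03·max` is not swept. The per-isotype genome swept fraction divides
retained swept bp by the summed lengths of all chromosomes.

## Field ecology

Collection samples (`c_label`) carry island, substrate class (six major
categories: leaf litter, fruit, flower, fungus, invertebrate,
vegetation), GPS coordinates and environmental measurements; isolation
records (`s_label`) carry the genotyping outcome per isolated nematode.
A sample observed under several collection categories is tallied once
under the highest-precedence category (named species first, in legend
order).

* **Enrichment**: 2×2 Fisher's exact test (two-sided,
  minimum-likelihood), species-positive vs not across two substrate or
  island strata. No multiplicity adjustment by default — pass results
  through `p.adjust()` when running several substrate contrasts.
* **Geographic clustering**: single-linkage under haversine distance with
  a 20 m radius; environmental parameters are then averaged per cluster so
  locally oversampled spots contribute once.
* **Group comparisons**: Kruskal–Wallis omnibus plus pairwise Dunn z
  tests with the tie-corrected pooled-rank variance and Bonferroni
  adjustment. An all-tied input is reported degenerate rather than tested.
* **Colocalization**: for each species pair, the number of units
  (samples, or gridsects) yielding both species and the number yielding
  either. When one sample yields two species, its environmental values
  enter both species' distributions.

Environmental values of 0 that are physically implausible for a substrate
are *not* silently coerced; exclusion lists are the caller's choice.

## The synthetic-data generator

Tested statistics depend only on allele-frequency and haplotype-sharing
structure, so the generator uses a transparent site-frequency founder
model rather than a coalescent: each population receives segregating
sites at density `diversity × a1(n)` per bp with derived-allele counts
drawn from the neutral `1/k` spectrum (so expected realized π equals the
configured target and Tajima's D is centred near 0), populations are
separated by privately fixed ALT sites, swept populations share a
designated founder over centred tracts on chromosomes I, IV, V and X,
clone groups copy a parent with independent per-call flips, and admixed
isotypes are two-source mosaics with exponential tract lengths (no
interference).

Forcing sweep carriers onto the founder allele deflates tract
heterozygosity; the generator pre-compensates analytically — the expected
post-forcing heterozygosity under the `1/k` spectrum has a closed
hypergeometric form — so the configured diversity remains the expected
*realized* genome-wide value. This calibration is derived from the model,
not fitted to any output.

Defaults are the study conditions this package targets: a divergent
island population of 43 isotypes at π = 0.00109 and a swept global
population of 233 isotypes at π = 0.000368; collection tables default to
the campaign's composition (2263 samples with the published per-substrate
counts, 2531 isolations, 427 PCR-positive, species frequencies and
published flower/leaf-litter enrichment counts, species environmental
means such as 867 m / 19.4 °C for the high-elevation specialist, all
its sites above 500 m). Where the sources do not fix a value (per-island
sample counts, within-island GPS scatter, environmental standard
deviations, the isolate-per-sample distribution), values a field
ecologist would call realistic were chosen once and documented in
`sim_collections_config()`; they were not revisited.

What the generator does *not* emulate: linkage disequilibrium decay
within populations (sites are exchangeable given frequency),
recombination-rate variation along chromosomes (real diversity dips at
chromosome centres), mutation-spectrum realism, and the demographic
history that shapes joint site-frequency spectra. Passing tests therefore
demonstrate estimator correctness and planted-structure recovery, not demographic
realism; quantities that emerge from real demography (for example the
exact segregating-site excess of one sample over another) are outside
what the model pins down.

All randomness flows through one seeded generator; the caller's RNG
state is saved and restored, and identical seeds reproduce bundles
bit-for-bit.

## Problem sizes and numerical choices

Simulation-backed tests and the acceptance script run at deliberately
scaled problem sizes chosen as the smallest that leave comfortable
statistical margins: six 300–500 kb chromosomes for diversity targets
(tens of thousands of segregating sites; sampling error on π well under
2%), four 15 Mb chromosomes at 1500 markers each for sweep recovery
(marker density ≈ 100/Mb, so non-IBD pairs mismatch ~30×/Mb against an
allowance of 1), and 30 000 sites for clone recovery (expected 15
discordant calls against an allowance of 30 at the 99.9% threshold).
The generator is linear in chromosome length, so these scale freely.

Determinism and tie-breaks are explicit throughout: isotype ids and
representatives, haplotype group labels, LD-prune removals and swept-group
ties all have documented deterministic resolutions, and the pipeline's
manifest records input checksums and parameter digests so unchanged
stages are skipped and reruns are reproducible.

## Known limitations

* The internal IBD detector is a run-length heuristic for synthetic
  bundles, not a replacement for LOD-based detection on real data.
* Fisher enrichment on observational field counts is descriptive, not
  causal; substrate availability varies by site.
* The agreement-vs-Jaccard concordance choice changes absolute values;
  both are exposed, and thresholds are calibrated for the default
  agreement reading.
* Population labels (island vs global, externally fitted ancestry
  groups) are consumed as data; no ancestry model is fitted here.
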