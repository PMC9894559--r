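---
title: "Mining endosymbiont genomes from host sequencing data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining endosymbiont genomes from host sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosym)
```

## The problem

Reference-genome projects sequence single wild-caught specimens, and the raw
reads therefore contain every cobiont present in the animal at sampling time.
For arthropods the most prominent such cobiont is *Wolbachia*, a maternally
transmitted intracellular alphaproteobacterium carried by a large fraction of
insect species. Given accurate long reads, a complete circular *Wolbachia*
genome can be recovered as a by-product of the host assembly — but doing so
reliably requires a chain of decisions: is the endosymbiont present at all;
which reads and contigs belong to it rather than to nuclear insertions of
endosymbiont DNA (NUWTs); how should the resulting circular genome be
normalised and summarised; and what do its gene content, prophage load and
toxin repertoire look like against a clade of relatives?

`endosym` implements that decision chain as a set of small, contract-tested
functions, together with a synthetic strain-set generator that plants every
feature the detectors look for. All statistical claims made by the test suite
are claims about that synthetic world; the sections below state exactly what
is emulated and what is not.

## Marker screening and consensus taxonomy

Presence is decided from SSU rRNA similarity hits. A hit is retained iff

* e-value < 1e-150 **or** aligned length > 1,000 nt, **and**
* percent identity > 90.

All three boundaries are strict, matching the usual "greater than" reading of
screening thresholds. Classification takes the 20 best retained hits (by
bitscore; ties by lower e-value, then target id) and walks the taxonomy from
root to leaf, descending while at least 80% of the considered hits agree on
one taxon. The 80% boundary is *inclusive* — exactly 16 of 20 descends — a
choice the underlying description leaves open; it is configurable
(`consensus_fraction`). With fewer than 20 hits the fraction applies to the
hits that exist. Because the agreement denominator stays at the full
considered-hit count, the consensus lineage is always a lineage prefix of at
least one retained hit.

When two taxonomies are available for the same hits (e.g. NCBI and SILVA
lineages), the classifier runs once per source and the sample is positive
only if both contain the target genus; disagreement is flagged `ambiguous`
and treated as negative.

## Separation and the NUWT filter

Fragments of endosymbiont DNA integrate into host nuclear genomes. A contig
built from endosymbiont-classified reads is accepted as an endosymbiont
replicon only when those reads cover it *fully*: `covered_fraction >= 1.0`,
where covered fraction is the length of the union of alignment intervals over
the contig length. The absolute threshold follows the stricter published
wording; a `full_threshold` knob exists for noisy real data. Coverage is
computed by interval-union sweep, so it is invariant to how alignments are
split into abutting pieces.

Relative abundance — endosymbiont genome copies per host genome copy — is the
ratio of length-weighted *median* 10 kb window depths on the two contig sets.
The median is deliberately robust to copy-number windows such as integrated
prophage; the original analysis does not state its estimator, so this is a
package design choice, validated on simulated mixtures (planted 10:1 depth
ratio recovered within 10%).

Assembly candidates are ranked lexicographically: completeness, then
duplication, then circularity, then contig count, then evenness of coverage
(coefficient of variation of windowed depth — "evenness" is otherwise
undefined upstream), with the assembler label as a final deterministic
tie-break.

## Genome normalisation and the skew index

Circular genomes are rotated so the single-copy origin-proximal anchor gene
(hemE by default) starts at position 0 on the forward strand,
reverse-complementing first when the anchor lies on the minus strand. Genes
cut by the rotation point are split into two parts sharing a `gene_id`,
keeping the interval invariant `start < end` intact. The operation is
idempotent.

GC content excludes N from the denominator. GC skew is computed per circular
window as (G − C)/(G + C); windows with G + C = 0 are *missing*, not zero —
a zero would fabricate a sign.

The genome-level skew index is a self-contained formalisation of the usual
"skew index" summary: over all circular two-arc splits (i, j) of the window
sequence, find the fraction f\* of non-missing windows whose skew sign
matches the best two-arc sign pattern (+ on one arc, − on the other); the
index is 2·max(f\*, 1 − f\*) − 1 ∈ [0, 1]. A genome whose skew flips sign
exactly once at the origin and once at the terminus scores 1; incoherent skew
scores near 0 (random windows average ≈ 0.2–0.3 because the maximisation
overfits the best split). The published analyses delegate this statistic to
an external tool whose exact formula is not restated; numeric parity with
that tool is therefore *not* claimed — the index here is "SkewI-like":
bounded, rotation-invariant and reverse-complement-invariant, which is what
the downstream comparisons use.

## Pairwise comparison: anchors, breakpoints, ANI

No external aligner is used. K-mers (k = 21) unique in genome A and unique
across both strands of genome B are anchors; anchors sharing a diagonal
(forward: posB − posA; reverse: posB + posA) are chained, chains split at
anchor gaps > 2 kb, and chains spanning < 500 nt discarded. Under the
substitution-only synthetic model this is exact: inversions and
transpositions preserve diagonals within segments. It will underestimate
homology between genomes that differ by many indels — a stated non-goal.

Breakpoints are counted between consecutive blocks along A whose B
coordinates are not contiguous in the same orientation within 1 kb, including
the wrap-around junction for circular genomes; the rate is breakpoints per
aligned base (the "adjusted for aligned coverage" normalisation is read as
per-aligned-base; per-aligned-fraction is the documented alternative). The
generator's rearrangement truth — adjacencies broken in the signed segment
permutation — matches this count exactly on the error-free world, which the
acceptance suite checks on 50 random derivatives.

Fragment ANI cuts A into 1 kb fragments, maps each by modal shared-16-mer
offset vote (both orientations), scores ungapped identity at that offset, and
averages fragments with identity ≥ 70%. Identical genomes give ANI 100;
1% uniform substitution gives 99.0 ± binomial noise; the estimate is
symmetric within half a percentage point.

## Pangenome statistics

Families are connected components of the similarity graph at the configured
threshold (single linkage). This deliberately replaces full phylogenetic
orthology inference: the statistics that matter downstream are matrix-level.
Near-single-copy selection is strict — single-copy in *more than* 95% of
genomes. Strain-specific ("novel") counts are gene copies in families present
in exactly one genome.

Rarefaction draws random genome addition orders; `core_k` counts families
present in all of the first k genomes, `pan_k` in any, and curves are means
over permutations with single-genome families excluded by default. The
expectations have closed forms under exchangeability,

E[pan_k] = Σ_f (1 − C(N−n_f, k)/C(N, k)),  E[core_k] = Σ_f C(n_f, k)/C(N, k),

which the acceptance suite uses as an independent oracle; an
`exhaustive = TRUE` mode enumerates all N! orders (N ≤ 8) for exact
equality checks. Permutation count is thus purely a precision knob.

## Prophage detection

Detection is annotation-driven: curated module tags (6 head, 8 baseplate,
6 tail, 6 fibre family slots, plus `phage_linked`) are inputs, not sequence
search results. A region is a maximal run of phage-linked genes in which
consecutive phage genes are separated by at most 5 other genes, seeded by at
least one core-module gene; `phage_linked` tags extend runs but cannot seed.
Gaps are counted in genes, not base pairs, per the source wording. Runs are
joined across the origin of circular genomes before maximality is decided;
wrapped spans are reported with `end > genome length` and counted once in
span fractions.

Completeness requires ≥ 5/6 head, ≥ 7/8 baseplate, ≥ 5/6 fibre and ≥ 5/6
tail *distinct family slots* — a duplicated gene counts once, because
completeness is about module functionality. (The restated "at least 80% of
each module" phrasing agrees numerically with these thresholds.) Cargo (EAM)
genes are the non-structural genes whose start lies inside the region span.

## Toxin pairs and the biotin operon

A gene qualifies as CifA or CifB with a reference hit at e-value ≤ 1e-30 and
query coverage in [80, 120]%; a pair requires a qualifying CifA and CifB
*immediately adjacent* in gene order (either order, any strands, circular
adjacency honoured). Genes qualifying as both roles are ambiguous and
excluded. The type label (I–V) is the best-bitscore reference over both
genes; type V's structural variability gets no bespoke model. `in_eam` is
span intersection with a detected prophage region.

The biotin operon is present iff all six genes (bioA/B/C/D/F/H) occur in one
locus (≤ 2 intervening non-bio genes between consecutive bio genes), with
order conservation judged against a configurable canonical order
(bioA,bioD,bioC,bioH,bioF,bioB or its exact reverse) and disruption flagged
when a transposase-tagged gene lies inside the locus span.

## Phylogeny and PGLS

The in-package tree is distance-based — p- or Jukes–Cantor distances from a
concatenated single-copy supermatrix, then neighbour joining with
deterministic lexical tie-breaking and negative branch lengths clamped to
zero (deficit moved to the sibling, preserving path lengths). Maximum
likelihood and coalescent phylogenetics are out of scope; the tree exists to
exercise the comparative regression.

PGLS uses the Brownian covariance C_ij = shared root-to-tip path length
(midpoint-rooting unrooted trees first), β̂ = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y,
σ² = rᵀC⁻¹r/(n−2), and a generalised R² = 1 − RSS/TSS with TSS taken about
the GLS intercept-only fit. On a star tree with equal branch lengths this
reduces exactly to OLS. Parameter recovery is verified by simulation: 200
Brownian replicates on a fixed 20-taxon tree with planted slope 1.5 recover
the slope within ±0.1 with 95% CI coverage inside [90%, 99%].

## The synthetic world

`generate_strain_set()` is first-class, tested code, and its defaults *are*
the stated world of the target system:

* backbone 1.3 Mb, 35% GC (prophage insertions push total size toward the
  observed ~1.5 Mb mean); 30–150 kb in tests purely for runtime — every
  statistic exercised is scale-free;
* skew amplitude 0.1: composition bias switching sign at the origin
  (position 0) and terminus (midpoint), giving clean leading/lagging strand
  structure;
* divergence: genomes evolve by per-site substitution along a random birth
  tree scaled to ~2% root-to-tip, comfortably inside the within-supergroup
  identity range; substitutions only by default so anchor-based comparisons
  have exact expectations (an indel mode is a stated non-goal);
* gene content: 80% core slots at constant coordinates, accessory families
  gained/lost along branches, and on average 19 strain-specific novel genes
  per genome (the observed average);
* prophages: 0–4 per genome, full 6/8/6/6 module complement minus 0–4
  randomly missing slots, with up to a few cargo genes in the interior;
* Cif pairs: Poisson mean 1.7 per genome, 70% planted inside prophage spans
  (the observed EAM fraction), types drawn uniformly from I–V;
* biotin operon: present with probability 0.06 (≈ 7 of 110 genomes),
  disrupted by a planted transposase with probability 0.3.

Two generator-side constraints exist so that *zero-noise recovery is exact*,
which is what the invariants demand: insertion points stay ≥ 6 genes
(circular gene order) from phage-tagged genes, and never touch a planted
pair/operon block — otherwise independently planted features could merge into
one detected region or gain spurious adjacencies, making truth itself
ill-defined. Similarly, rearrangement cut points keep ≥ 5 kb from all
existing segment boundaries so every junction is an isolated breakpoint.

What the generator does **not** emulate: sequencing error (reads are
error-free HiFi-like by default; Q30–Q40 makes this a reasonable desk-scale
idealisation), indels, repeat-driven assembly ambiguity, horizontal transfer
within the clade, or realistic taxonomies of hits. A green test therefore
establishes algorithmic correctness on the stated world, not robustness to
real-data noise.

## Numerical choices

* Percent reporting rounds half *up* to integer percent ("n (p%)").
* Rank ties everywhere break lexically (hit targets, NJ pairs, assembler
  labels) so all outputs are order-independent and deterministic.
* Interval convention is uniformly 0-based half-open internally; GFF3
  (1-based closed) and BED convert at the boundary; wraparound features are
  two parts sharing a `gene_id`, never `end < start`.
* Windows with no G/C are missing, excluded from skew statistics.
* jc69 distances error (rather than return Inf) at p ≥ 0.75.
* The overlap trim for collinear blocks cuts at the overlap midpoint before
  breakpoint counting.

## Known limitations

* The skew index is not bit-compatible with the external tool it stands in
  for; only its qualitative behaviour is claimed.
* The anchor-chain comparison degrades with indel divergence and with
  genomes dominated by repeats longer than k.
* The breakpoint normalisation (per aligned base) is one of two defensible
  readings of "adjusted for aligned coverage"; absolute rates may differ
  from the original by the aligned-fraction factor.
* PGLS p-values are not computed; with desk-scale n they would not be
  meaningful, and the estimator (slope, SE, R²) is the tested quantity.
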