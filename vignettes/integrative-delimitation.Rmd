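---
title: "Integrative species delimitation with barcogeo: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delimitation with barcogeo: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcogeo)
```

`barcogeo` delimits putative species from single-locus DNA barcodes
(typically COI) by combining three independent lines of evidence —
molecular distances, collection geography, and discrete morphological
characters — and validating candidate species only where the lines agree.
This vignette explains the models and procedures, the parameters that
matter, the design choices made where the design was genuinely open, and
what the bundled simulator does and does not emulate.

## The distance model

Pairwise distances use the Kimura two-parameter (K2P/K80) correction,
which distinguishes transitions (A↔G, C↔T) from transversions. For a
sequence pair, with transition proportion $P$ and transversion proportion
$Q$ over the sites comparable in that pair,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

Gaps, `N`, and (after a logged collapse to `N`) all other ambiguity codes
are removed *pairwise*: each pair keeps every site where both sequences
carry a plain base, and `distance_matrix()` records that per-pair
comparable-site count. Two degenerate cases are flagged rather than
silently propagated: pairs with no comparable site, and saturated pairs
where a logarithm argument is non-positive so the correction is undefined.
Both appear in the `diagnostics` table with `NA` distances; downstream
functions refuse `NA`s unless the user opts into `cap_saturated()`, which
replaces saturated pairs by the maximum observed distance. Explicit flags
beat silent infinities: saturation in barcode data almost always means
contamination or misalignment, and deserves eyes.

`summarize_distances()` pools *pairs*, not group averages: the
intraspecific side collects all within-group pairs and the interspecific
side all between-group pairs, which is what single min–max ranges over a
partition describe. Per-group maxima are attached so a per-group-averaged
summary can be reconstructed if wanted.

## Barcode-gap partitioning

The barcode gap is the discontinuity between intraspecific and
interspecific pairwise distances. `find_gap_threshold()` works on the
ranked distances $d_{(1)} \le \dots \le d_{(m)}$: at rank $i$ the gap is
$g_i = d_{(i+1)} - d_{(i)}$ and the local reference $r_i$ is the mean of
up to `window` (default 10) preceding rank gaps. A rank is *significant*
when $g_i > X \cdot r_i$ with relative gap width $X$ (default 1) and
$g_i > 0$. The scan starts at the last rank at or below the prior
intraspecific divergence $P$; distances below the prior are assumed
intraspecific and never split.

Among significant ranks the **widest** gap wins, and the threshold is its
midpoint $t = (d_{(i)} + d_{(i+1)})/2$. Taking the widest rather than the
first significant gap is a deliberate design choice: ranked intraspecific
distances are dense and noisy, so "first significant" latches onto
sampling fluctuations at small priors and shatters the partition, whereas
the true barcode gap — when one exists — dominates every local reference
and is detected identically across the whole low-prior range. This is
what makes primary partitions stable in the prior scan. Two further
conventions: a rank with no preceding gap has no defined reference and is
skipped, and the significance comparison uses a relative tolerance of
1e-9 so that an exactly uniform ladder of distances (every gap equal to
its reference) yields no gap, as strict inequality demands.

Clustering at a threshold is connectivity (single linkage):
`partition_at_threshold()` joins two specimens whenever their distance is
at most $t$ and takes connected components, so partitions are nested in
$t$. Group labels `G1..Gk` follow first-member input order, making
results deterministic.

`primary_partition()` applies one gap search to the full ranked list and
falls back to $t = P$ when no significant gap exists, keeping the prior
scan total (the fallback is recorded per prior). `recursive_partition()`
re-applies the gap search inside every group of three or more specimens
and iterates to a fixed point (capped at `max_rounds = 20`); groups with
no internal gap are left alone rather than split at the prior, because a
within-group fallback would shatter every group at small priors and
destroy the refinement structure. Recursion can only split, so the
recursive partition always refines the primary one.

`prior_scan()` evaluates both passes over `n_priors = 20` log-spaced
priors between `p_min = 0.001` (about a single nucleotide difference on a
658-bp barcode) and `p_max = 0.14` (an upper bound used for springtail
COI). Plateaus are maximal runs of consecutive priors with equal primary
group count; the widest plateau wins (ties go to larger priors, where
primary partitions are most stable), and the reported partition is the
primary partition at the largest prior of that plateau — inside a clean
plateau the partition is constant, so this choice only matters for noisy
edges.

## Geographic delimitation

Collection sites within a 5 km radius chain (single linkage on great-circle
distance) into localities, and a *population* is the specimens of one
morphospecies at one locality — several species can co-occur at a
locality, but delimitation operates within morphospecies, so populations
carry exactly one morphospecies label. Great-circle distances use the
haversine formula on a sphere of radius 6371.0088 km; at the 5–500 km
scales involved, the sub-0.5% ellipsoidal error is irrelevant.

`geo_delimit()` splits each morphospecies at a distance threshold:
populations farther apart than the threshold become distinct putative
species. Inter-population distance is the *minimum* over member-site
pairs by default (conservative merging, consistent with the radius-based
population rule), with a centroid option. Linkage is single by default —
two distant populations still merge through an intermediate population
within threshold of both — because the complete-linkage alternative makes
the rule order-dependent in spirit; both are available
(`linkage = "single"|"complete"`). Geography never merges morphospecies,
so every geographic partition refines the morphospecies partition, and
under single linkage the putative-species count is non-increasing in the
threshold. `geo_scan()` evaluates the default threshold ladder 10, 20,
50, 100, 200, 300, 400, 500 km and reports plateau structure; plateaus
indicate dispersal-limited range sizes and are where a working threshold
should be chosen.

## Trees, monophyly, and bootstrap

`nj_tree()` is neighbour joining on the K2P matrix (via `ape`), with
negative branch lengths clamped to zero and the deficit moved to the
sister edge so path lengths through the parent are preserved; on additive
matrices the generating topology and branch lengths are recovered
exactly, which the tests assert. `bootstrap_support()` resamples
alignment columns with replacement, recomputes K2P + NJ per replicate,
and reports per-bipartition support; it is seeded and reproducible.
Likelihood and Bayesian inference are out of scope — externally built
trees (e.g. ML/BI newick with support labels) are imported with
`read_tree()` and fed to the same monophyly check. Identical sequences
are kept for NJ; collapsing them is a caller decision.

`monophyly()` requires a rooted tree or an outgroup. Rooting places the
outgroup as a clade whenever its split exists in the unrooted tree (if
the outgroup's MRCA coincides with the arbitrary stored root, the tree is
rooted on the complement instead). A cluster is monophyletic when some
node's descendant leaf set equals it exactly; singletons are `trivial`
(and count as passing the criterion — a single specimen cannot contradict
it), clusters with leaves missing from the tree are `unresolvable` (and
count as failing), and every mismatch is listed, never dropped. When the
workflow builds its own NJ tree and no outgroup is supplied, the
candidate cluster with the largest mean distance to all other specimens
serves as a functional outgroup — with a genuine barcode gap any cluster
would do, and the most divergent one is the closest analogue of a true
outgroup.

## Congruence and validation

"Congruent across methods" is operationalised cluster-wise: a reference
cluster is congruent when its exact specimen set is a cluster of every
other partition. Whole-partition equality would be too strong — a
22-group molecular partition can agree cluster-by-cluster with a larger
geographic partition everywhere except one widespread species, and that
is precisely the interesting signal. The report lists, per cluster, which
partitions disagree, alongside pairwise adjusted Rand indices and the
meet (common refinement) of all partitions.

`validate_species()` combines three per-cluster criteria:

1. **monophyly** on the phylogeny;
2. **congruence** between the molecular candidate and the geographic
   (and any imported) partitions;
3. **morphological diagnosis**: at least one character with
   within-cluster stability at or above `stability_floor` (default 1 —
   no intraspecific variation; lower it to tolerate characters variable
   in a small fraction of specimens), *and* diagnosability against every
   other cluster on at least one character (value sets disjoint).

All three yield a validated species; (1) and (2) without (3) is
morphological stasis — a cryptic species; anything else stays unresolved.
Characters are opaque categorical strings (pseudocelli-style formulae are
compared only for equality; no partial credit for similar formulae), and
specimens flagged deformed (bilateral asymmetry in key diagnostic
features) are excluded from every character statistic.

## The simulator

`simulate_dataset()` plants a known truth with the statistical structure
the analyses assume: a uniform random root sequence; species ancestors
diverging under a K80 process (`kappa = 4`) with branch lengths drawn so
expected between-species tip distances fall in `inter_divergence`
(default 0.09–0.20 substitutions/site — the lower branch bound keeps
ancestor pairs at the configured floor, the upper bound nets out the
within-species contribution); and a star genealogy within species, each
individual adding `Poisson(L * intra_divergence / 2)` substitutions so
pooled within-species distances average `intra_divergence` (default
0.02). The realised barcode gap (max intraspecific < min interspecific)
is asserted per dataset, with regeneration and a logged attempt count on
violation. Geography places range centres at twice the range radius
apart, or pins species to shared localities via `locality_map`; cryptic
pairs share all character values; deformed specimens get a one-sided
aberrant variant of their first character; `two_clade_species` splits
species internally to push intraspecific divergence towards 4–6%; and a
masking option introduces alignment gaps. Everything is driven by one
seed and reproduces byte-identically.

`emulate_study(seed)` is a preset with the headline structure of a
well-sampled regional barcode study of onychiurid springtails: 144
specimens in 22 true species over 17 localities, lumped into 10
morphospecies, 4 cryptic pairs, and 1 widespread species whose two
ranges lie more than 100 km apart. The layout is engineered so geography
can in principle re-split every lumped morphospecies (same-morphospecies
species sit at distinct, well-separated localities; co-occurring species
always differ in morphospecies), leaving the widespread species as the
designed molecular/geographic incongruence.

What the simulator does *not* emulate: coalescent genealogies and
incomplete lineage sorting, rate heterogeneity among sites, indel
evolution (gaps are masking only), character evolution (characters are
species constants), uneven geographic sampling, or real saturation.
Passing tests on simulated data therefore show that the machinery is
correct under its own assumptions — clean star-shaped clusters separated
by a genuine gap — not that any particular empirical dataset will behave
this way. On real data the prior scan can legitimately select different
partitions at different plateau widths, and the geographic threshold
remains a biological judgement about dispersal, supported but not made
by the scan.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full pipeline at the
study scale (144 specimens × 658 bp, 20-prior scans, NJ on the full
matrix) and the oracle comparisons at small scale (≤ 12 specimens,
≤ 50 bp; bootstrap examples at 8–10 specimens × 300–400 bp with 50–100
replicates), sizes at which brute-force oracles are exact and fast.
Distance computation is vectorised through base-count cross-products, so
one full 144-specimen K2P matrix costs a few matrix multiplications.
Other conventions: coordinates are WGS84 decimal degrees with no
projection support; partitions, group labels, and population ids are
deterministic functions of input order; all thresholds compare with `<=`
(a pair exactly at a threshold joins); and every identifier mismatch
between alignment, metadata, tree, and partitions is reported in full
rather than truncated or dropped.
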