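---
title: "Methods: time-course splicing co-expression networks"
author: "heatSpliceNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course splicing co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatSpliceNet)
```

# The analysis in one paragraph

Plants remodel their transcriptome within hours of heat stress, and a
large part of that remodelling is alternative splicing: the relative
abundance of a gene's isoforms shifts even when total gene output does
not. `heatSpliceNet` reconstructs the regulatory layer behind such
shifts from a time-course of transcript-level TPM quantifications. Each
differential-transcript-usage (DTU) transcript is reduced to a
standardized time profile, profiles are grouped into co-expression
modules, and each module's consensus profile (centroid) is correlated
against the profiles of candidate regulators — transcripts of splicing
factors (SFs) and RNA-binding proteins (RBPs) that are heat-responsive,
protein-coding, and carry a nuclear localisation signal. The strongest
correlations, taken as a top percentile of the full candidate pool,
form a bipartite module–regulator network whose clusters are classified
as early (response within 6 h) or late (up-regulation from 12 h
onward). Alongside the network the package quantifies isoform
proportions over time, detects isoform dominance switches, and flags
transcripts carrying the canonical nonsense-mediated decay (NMD)
signature of an exon–exon junction more than 50 nt downstream of the
stop codon.

# Normalisation

Replicates are collapsed by the arithmetic mean per timepoint, and each
transcript's profile over the $T$ timepoints is standardized:

$$ z_t = \frac{x_t - \bar{x}}{s_x}, $$

with the sample standard deviation ($n-1$ denominator; `sdType =
"population"` is available as a sensitivity option). Z-scores are taken
on the TPM scale directly — no log transform — so that the profile
shape, not the expression magnitude, carries all information;
`log2Offset` enables a log transform where heavy-tailed profiles
warrant it. Constant profiles cannot be standardized and are set aside
as degenerate rather than scored. Standardization is invariant to
positive affine rescaling of a profile, which the test suite asserts as
a property.

Whether to standardize the replicate-averaged profile (8 values) or all
samples (24 values) is genuinely open; the package averages first by
default because the network is built from Pearson correlations of
*time* profiles, and averaging is the natural estimator of the
timepoint mean. `per_sample_z = TRUE` switches the pipeline to
standardizing over all samples before averaging; downstream Pearson
correlations are unchanged by the final re-standardization, so the
option isolates exactly the effect of when replicate noise is pooled.

# Co-expression modules

Pairwise Pearson correlations $r_{ij}$ between Z-profiles are soft
thresholded into an unsigned weighted adjacency $a_{ij} = |r_{ij}|^\beta$
(`signed = TRUE` gives $((1+r)/2)^\beta$). The exponent $\beta$
(default 17) controls the contrast between strong and chance
correlation; `selectPower()` reproduces the standard elbow workflow: for
each candidate $\beta$ the connectivity distribution $k_i = \sum_j
a_{ij}$ is binned (10 equal-width bins by default), $\log_{10}$
frequency is regressed on $\log_{10}$ mean connectivity, and the first
candidate whose $R^2$ reaches the scale-free target (0.7) is selected —
falling back to the largest drop in fit-index gains when no candidate
reaches it. The full fit table is always reported; with only 8
timepoints the fit index is a coarse diagnostic, and the default
$\beta$ is deliberately fixed rather than re-estimated per run.

Three dissimilarities are available for clustering: `"adj"`
($1 - |r|^\beta$, the default), `"tom"` ($1 - \mathrm{TOM}$), and
`"corr"` ($1 - |r|$). The topological overlap measure

$$ \mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
   {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
   \ell_{ij} = \sum_u a_{iu} a_{uj} $$

is provided and tested against a brute-force oracle, but it is not the
default here: its denominator is governed by the *smaller* of the two
connectivities, so with short profiles a sparsely connected transcript
that is weakly but uniformly attached to one dense module is pulled
toward it, blurring the module boundary. The plain soft-threshold
dissimilarity preserves the contrast the exponent was chosen to create
and, on the synthetic benchmark below, separates planted modules more
reliably. TOM remains one configuration switch away.

Modules are detected on an average-linkage (`hclust`) dendrogram with a
hybrid dynamic tree cut implemented in this package:

1. Merges above `cutHeightFraction` (0.99) of the dendrogram height are
   ignored.
2. The remaining merges are replayed bottom-up. When two growing
   branches meet and both satisfy the branch criteria — at least
   `minClusterSize` members (default 20), core scatter at most
   `maxCoreScatter`, and a normalised merge gap of at least `minGap` —
   both are frozen as modules. A branch's core is its
   `minClusterSize + floor(sqrt(size - minClusterSize))`
   earliest-joining objects; scatter and gap are measured on merge
   heights normalised to $[0,1]$ between the lowest merge and the cut
   height. `deepSplit` $\in \{0..4\}$ (default 4) maps linearly onto
   `maxCoreScatter` $= 0.64 + 0.08\,d$ with `minGap`
   $= (1-\texttt{maxCoreScatter})\cdot 3/4$, trading module homogeneity
   against the size of the unassigned pool.
3. A core-based refinement settles membership. Every object is ranked
   by its average dissimilarity to a module's core; because a module is
   dense and the rest of the data is far, this ranking has a sharp
   step, and the module boundary is placed at the last near-maximal gap
   in the sorted sequence (searched between the core size and half the
   universe — a module is never most of the data). Objects inside
   several boundaries join the nearest module; modules whose boundary
   sets largely coincide (overlap above half the smaller set) are
   halves of one module and are merged; modules falling below
   `minClusterSize` dissolve. Everything else is the outlier pool,
   label 0, which is removed before any network stage
   (`dropOutlierCluster()`).

Labels are renumbered by decreasing module size, ties broken by the
original label so results are deterministic, and the whole cut is a
permutation-invariant function of the dissimilarity (tested).

# The bipartite regulator network

Regulator candidates are filtered from the catalog by
`(is_DE | is_DAS) & is_protein_coding & has_NLS`: a splicing regulator
must respond to the stress, make a protein, and reach the nucleus.
Module centroids — per-timepoint means of member Z-scores — are
correlated with each regulator's Z-profile, giving one candidate edge
per (module, regulator) pair. The retained network is the top
percentile of this pool by $|r|$ (default `topFraction = 0.01`), using
the nearest-rank rule: with $N$ candidates, $\tau$ is the
$\lceil 0.01\,N \rceil$-th largest $|r|$ and all edges with
$|r| \ge \tau$ are kept, ties included. The retained count may
therefore exceed the nominal rank, which is reported rather than
forced; the sign of $r$ is kept on the edges even though thresholding
is two-sided.

Each retained cluster is classified from its centroid by an explicit
rule: let $t^*$ be the timepoint of the largest absolute departure from
the 0-h level; the cluster is *early* if $t^* \le 6$ h, *late* if
$t^* \ge 12$ h and the departure is upward, otherwise unclassified.
Flat centroids are unclassified. The rule makes the early/late split a
reproducible function of the data rather than a curated annotation.

# Isoform-level analyses

Gene expression at a timepoint is the sum of its isoforms' TPM;
proportions are isoform shares of that sum, undefined (NA) where the
gene is silent. A switch event is a change of the dominant isoform
between two *adjacent* sampled timepoints; intervals where gene TPM
falls below `minGeneTpm` (default 1) at either end are skipped, and
exact proportion ties resolve to the lexicographically first isoform id
so runs are reproducible.

Transcript models keep GTF conventions: genomic coordinates 1-based
inclusive, transcript coordinates 1-based from the 5' end, exons stored
in transcript order on both strands. The stop-codon position is the
transcript coordinate of the last base of the last CDS interval, with
dedicated `stop_codon` features merged into the CDS first so both GTF
dialects yield the same answer. A transcript is NMD-flagged when any
exon–exon junction lies strictly more than 50 nt downstream of that
position — a junction at exactly 50 nt does not flag. The test suite
enumerates distances {0, 49, 50, 51, 200} across strands and exon
counts against this rule.

`compareCdsRegion()` classifies how one isoform's CDS covers a
domain-encoding interval relative to another's: `identical`,
`truncated_in_b` (proper non-empty subset), `absent_in_b`, or
`identical_complement` (exactly the bases the first isoform does not
cover); coverage patterns outside these classes return `"other"`.

# The synthetic benchmark

`simulateHeatStress()` generates the study conditions the analysis
assumes: 8 timepoints {0, 1, 3, 6, 12, 24, 36, 48} h with 3 replicates;
planted modules of 50/40/30 transcripts following three archetype
profiles (early down-regulation with its minimum at 1 h, a transient
peak at 3–6 h returning to baseline by 24 h, and a non-decreasing late
rise maximal at 48 h); 80 background transcripts with independent
profiles; one linked regulator per module plus 5 decoys; and 4
multi-isoform genes whose proportions flip once at a planted interval.
Latent profiles are archetype plus Gaussian noise (`noiseSd`, default
0.2), mapped to TPM as $b \cdot 2^{A z}$ with baseline $b$ log-uniform
in [1, 100] and amplitude $A = 2$; replicates multiply latent TPM by
unit-mean lognormal noise with coefficient of variation `replicateCv`
(default 0.1). The noise defaults are the regime in which a co-expression
analysis of a well-replicated time course is expected to work; at
`noiseSd = 0` the latent profiles equal the archetypes exactly and
module, edge, and switch recovery must be exact, which the acceptance
tests assert.

Background and decoy profiles are drawn with an identifiability guard:
a candidate profile is resampled until its correlation with every
planted archetype is below 0.8 *on the expression scale* (after the
exponential TPM mapping). The mapping concentrates a profile's weight
on its maxima, so a moderate latent correlation can become a
near-perfect observed one — most visibly for the early-down archetype,
which the mapping turns into a spike at 0 h. Without the guard the
planted labels are simply not identifiable from the data, and "recovery"
would be measured against an answer the data do not contain. Decoy
regulators additionally carry `has_NLS = FALSE` so the catalog filter
is exercised.

What the generator does not emulate — and what passing tests therefore
do not show about real data: compositional coupling between transcripts
(TPM is a relative unit), count-level sampling noise at low expression,
correlated replicate effects (batches), partially overlapping or nested
modules, regulators that drive only part of a module, and genuinely
scale-free global topology. The scale-free fit diagnostic is therefore
exercised on a constructed power-law connectivity vector, not on the
generator's output, and the selected power on synthetic data should not
be read as a recommendation for real data.

# Numerical choices and problem sizes

Degenerate (zero-variance) profiles are excluded before correlation,
never silently scored. Dissimilarity matrices are symmetrized
(`(d + t(d))/2`) to absorb floating-point asymmetry from `crossprod`.
Average linkage is delegated to `stats::hclust`, whose deterministic
tie-handling the cut inherits; all remaining ties (dominant-isoform
ties, label renumbering, nearest-module assignment) are broken
lexicographically or by first index. TSV outputs print doubles with 15
significant digits, so a written-and-reread matrix agrees with the
original well below 1e-9, and run manifests record MD5 hashes of every
input and output; two runs with the same configuration and seed are
byte-identical. The test and acceptance workloads use 200-transcript
universes, pools of up to 10,000 candidate edges for the threshold
oracle, and 200 random 5–8-node matrices for the TOM oracle — sizes at
which every stage completes in seconds while still exhibiting the
failure modes the checks target (chance correlation, tie handling,
boundary placement).

# Known limitations

The cut's refinement stage assumes modules are denser than their
surroundings in the chosen dissimilarity; modules embedded in a
correlated background (for example, a global stress response shared by
most transcripts) will be merged or truncated. The early/late rule
classifies from the centroid only and can call a cluster with two
opposite-signed waves by whichever departure is larger. Edge retention
by a global percentile means the network size tracks the pool size, not
an error rate; no significance is attached to individual edges.
`readGtf()` handles the common GTF/GFF3 attribute dialects
(`transcript_id`/`gene_id` and `Parent=transcript:`) but not every
provider-specific variant.
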