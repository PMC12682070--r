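---
title: "Models and methods behind methylripe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylripe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylripe)
library(data.table)
```

# Scope

`methylripe` analyses per-cytosine bisulfite count data from fruit tissues
sampled across ripening stages — the setting where non-climacteric fruits
such as grape gain DNA methylation, most strongly in the asymmetric CHH
context, as ripening progresses. The package takes extractor output
(Bismark-style cytosine reports), never reads or aligns sequencing reads,
and consumes differential-expression verdicts from an external RNA-seq
analysis rather than re-deriving them.

Throughout the package a methylation level over any set of sites is
**coverage-weighted**:

$$ \bar{m} = \frac{\sum_i n^{meth}_i}{\sum_i (n^{meth}_i + n^{unmeth}_i)} $$

never the unweighted mean of per-site levels (functions that report both say
so). Weighting by coverage makes low-depth sites contribute in proportion to
their evidence and gives the exact conservation identity used in the test
suite: the genome-wide weighted level equals the coverage-weighted mean of
any binned track of it.

Coordinates are 1-based closed intervals internally (the
IRanges/GenomicRanges convention); BED and bedGraph exports convert to the
0-based half-open convention those formats require.

# Input processing and QC

Sites are strand-resolved; the two cytosines of a CG dyad are independent
observations, matching extractor output. The context of every site is
recomputed from its trinucleotide (CG when base 2 is G; CHG when base 3 and
not base 2 is G; CHH otherwise) and mismatching rows are rejected rather
than trusted. The validity filter keeps sites with depth at least 4, applied
per sample; comparisons later restrict to the intersection of valid sites
across all replicates of both groups, so every tested site has defined
levels in every library.

Bisulfite conversion efficiency is estimated from the chloroplast, which is
essentially unmethylated in vivo: the conversion rate is one minus the
coverage-weighted methylated fraction over chloroplast sites. A sample
below the threshold (default 0.99) is flagged and warned about, not
discarded — the QC is a report, not a gate. A sample with no chloroplast
coverage raises an explicit error instead of silently passing.

# Differential methylation

## The per-site test

For one site, replicate counts are pooled within each group. With pooled
methylated counts $m_a, m_b$ out of totals $t_a, t_b$, the two-group
binomial likelihood ratio statistic is

$$ \Lambda = 2\left[\ell(m_a, t_a, \hat p_a) + \ell(m_b, t_b, \hat p_b)
   - \ell(m_a{+}m_b,\, t_a{+}t_b,\, \hat p_0)\right], \qquad
   \ell(m,t,p) = m\log p + (t-m)\log(1-p), $$

with $\hat p_a = m_a/t_a$, $\hat p_b = m_b/t_b$ and the pooled null MLE
$\hat p_0$, referred to $\chi^2_1$. The pooled proportions are exactly the
MLEs of a binomial GLM with a group indicator, so this is the closed-form
equivalent of a per-site logistic-regression likelihood-ratio test, with
replicate structure entering through pooling. The convention $0\log 0 = 0$
handles empty cells; the statistic is clamped at zero against float
rounding. The test suite checks the implementation against an independent
`dbinom()`-based oracle over every pooled configuration with group totals
up to 30.

A DMC (differentially methylated cytosine) requires **both** a
context-specific absolute level difference — more than 0.20 for CG, 0.10
for CHG, 0.05 for CHH — and p below 0.05. Raw p-values are the default
deliberately, matching the published procedure this pipeline emulates; a
Benjamini–Hochberg mode (`use_qvalue = TRUE`) exists but is off. Direction
is `hyper` when the second group (conventionally the ripe stage) exceeds
the first.

## From DMCs to DMRs

DMRs are built per context and direction from 200-bp windows advanced in
50-bp steps. A window is a **candidate only when it contains at least
`min_dmcs` (default 10) matching DMCs**; overlapping candidates are
unioned, unions separated by at most 100 bp are merged, and each region is
trimmed to its outermost member DMCs.

The density requirement on individual windows — rather than one DMC per
window with the 10-DMC filter applied only after merging — is a deliberate
design choice, and the place where this package departs from the weakest
possible reading of the procedure. An uncorrected p < 0.05 site test
necessarily leaves a few percent of isolated false DMCs; at typical plant
CHH site densities (~0.15 sites/bp) their mean spacing is a few hundred
base pairs, so single-DMC candidate windows chain through the 100-bp merge
into multi-kilobase false regions that trivially exceed any post-merge DMC
count. Requiring ten DMCs inside one 200-bp window is a demand for local
density that scattered false positives essentially never meet (at a 2–5%
false-site rate, a ~30-site window holds ten of them with probability below
$10^{-4}$), while genuine regional shifts — where most sites in the window
are DMCs — pass easily. This choice is what makes region counts on
realistic data come out in the thousands rather than the tens of
thousands. The brute-force window-enumeration oracle in the test suite
implements the same semantics independently and agrees exactly on small
genomes for `min_dmcs` of 1, 5 and 10.

Hyper- and hypomethylated regions are constructed separately and never
merged into one region. With the candidate-density rule, raising
`min_dmcs` shrinks the candidate set, so stricter regions nest inside
looser ones and total member-DMC counts are non-increasing; the *number*
of regions may fluctuate (a long region can split), which is why the test
suite asserts nesting rather than count monotonicity.

## Tissue specificity of regions

Ripening-induced CHH hyper-DMR sets from two tissues are crossed by
interval overlap: a region overlapping (by at least 1 bp) a region from
the other tissue is *common*, and connected overlap components are
collapsed to their union interval, reported once; unmatched regions are
tissue-specific. The assignment partitions the inputs, and swapping the
two input sets swaps the specific labels while preserving the common set.
Pre-existing inter-tissue differences are probed by comparing, per group,
the coverage-weighted CHH level of every region between tissues at the
immature stage with a two-sided Wilcoxon rank-sum test (exact for combined
n ≤ 20 without ties, normal approximation with tie and continuity
correction otherwise; a fully tied comparison is reported as p = 1 rather
than NaN).

# Methylation-responsive genes

The 2-kb promoter upstream of each TSS is divided into twenty 100-bp bins,
bin 1 adjacent to the TSS, strand-aware (for minus-strand genes the bins
ascend in genomic coordinate from the gene end). Replicates are pooled by
count summation per stage; each bin's difference is the ripe minus
immature coverage-weighted level. A bin is differentially methylated when
its absolute difference exceeds 0.05, counted per sign; a bin without
coverage in either stage is undefined and never differential. A gene is
methylation-responsive in a direction when at least two bins are
differential in that direction, and its gene-level difference is the mean
over its differential bins.

Two readings of the promoter window are possible (upstream-only versus a
window centred on the TSS); the operational upstream definition is the
default, with `window = "tss"` providing the centred alternative. The
threshold is read as a signed difference per direction, since the
downstream analysis concerns hypermethylated gene sets; both directions
are always reported.

Gene categories cross the hyper flags of the two tissues (pulp-specific /
common / skin-specific / none), and the expression integration counts, per
category, genes whose differential expression is restricted in the
matching way: tissue-specific categories against DE in that tissue only,
the common category against DE in both tissues (split by concordant
direction; discordant pairs are tallied as `mixed`). DE verdicts are
consumed from a table; no internal DE test is provided, by design, to
avoid misrepresenting the external RNA-seq analysis step.

# The synthetic study generator

The simulator exists so that every stage of the pipeline can be exercised
against known truth. It emulates the *statistical structure* of a
two-tissue (pulp, skin) by two-stage (immature, ripe) WGBS design with
duplicate libraries on a small genome, not the sequence composition of a
real one.

**Genome and annotation.** By default two 500-kb chromosomes of uniform
random sequence plus a 30-kb chloroplast; 200 genes and 150 TEs placed
without overlap and with at least 200 bp spacing. Strand-resolved cytosine
sites and their trinucleotides are derived from the sequence.

**Methylation truth.** Per-context background levels target mCG 0.373,
mCHG 0.160, mCHH 0.027 genome-wide; CAA/CTA (and CAG/CTG) subcontexts run
hot by fixed multipliers that average to one within their context. TE
bodies and inactive-gene bodies/promoters carry additive enrichment, and
the background is recentred so the genome-wide expectation still equals
the configured baseline — enrichment redistributes methylation rather
than inflating the mean (the law-of-large-numbers check in the tests
relies on this, measured at the immature stage since ripe samples carry
the planted gains).

**Noise model.** Each site's latent level is a single beta draw around its
structural level at precision 50 (mean-precision parameterisation),
made once per tissue and shared by that tissue's stages and replicates;
planted effects shift the latent additively, with clamping to [0, 1].
Replicates then differ through negative-binomial coverage (mean 25,
size 10) and binomial sampling of methylated calls. The beta draw
represents site-to-site biological heterogeneity; making it common to both
stages is what renders unplanted sites exactly null across stages, so the
truth manifest is a complete account of every real difference and
precision/recall against it are meaningful. The alternative — redrawing
the beta per replicate — was evaluated and rejected: it models
overdispersion the pooled test does not absorb, produces several percent
of spurious DMCs at unplanted sites, and makes planted-effect recovery
unscoreable at any threshold. Real libraries do carry replicate-level
overdispersion, which is precisely why passing recovery tests here does
not certify calibration on real data (see Limitations).

**Planted effects.** Thirty CHH hyper-DMRs of 400–600 bp at +0.15
(10 pulp-only, 10 skin-only, 10 both) applied at the ripe stage; a
constant +0.10 pulp offset on the skin-scope regions at both stages (the
synthetic analogue of pre-existing inter-tissue differences, detectable at
the immature stage); twelve responsive genes (4/4/4 scope) with +0.15 on
the three promoter bins adjacent to the TSS at ripe; a matching
expression table in which responsive genes are downregulated in their
scope tissue plus 30 random DE genes. Planted DMRs avoid all gene
promoters, and planted promoter windows avoid all other genes' promoters,
so the two planted effect classes stay disjoint and the manifest stays
complete. The chloroplast is drawn at the conversion-failure rate
(default 0.003) with no biological noise.

**Recovery scoring.** A called DMR matches a planted interval when it
covers at least half of it. Recall is measured over the planted DMRs in a
tissue's scope; precision over all of that tissue's CHH hyper calls
(promoter plants count as true intervals too); group accuracy compares
assigned groups to planted scopes over matched regions; responsive-gene
recovery is set precision/recall on the hyper verdicts. With no calls,
precision is reported as NA, not zero.

# Numerical and implementation choices

* Body positions in metagene profiles map by fractional position
  (`offset / length`) into the body bins, so features shorter than the bin
  count still contribute; a site exactly at the feature end goes to the
  last body bin. Region-centred profiles use an odd bin count with the
  central bin straddling the midpoint.
* Profile bins aggregate all (site, feature) incidences — a site inside
  two overlapping features contributes to both, which keeps the profile
  invariant under feature order permutation and genome mirroring.
* `0 log 0 = 0` in all likelihoods; LRT statistics are floored at zero.
* Beta draws at degenerate levels (0 or 1) short-circuit to the
  degenerate value.
* Exact Wilcoxon p-values are used up to combined n = 20 without ties;
  fully tied inputs return p = 1 by convention.
* Determinism: a study is fully reproducible from its config seed, and
  identical seeds give byte-identical written outputs.

The test suite runs the full default study (two 500-kb chromosomes,
~515,000 cytosine sites per sample, eight samples) across three seeds for
the end-to-end recovery check, a 20,000-site binomial null for test
calibration, and exhaustive small-n enumerations for the exact tests;
these sizes were chosen as the smallest at which the measured properties
are stable.

# Limitations

* The pooled binomial LRT ignores replicate overdispersion and is
  anti-conservative on data where biological replicates truly disagree;
  on real libraries the DMC lists are best treated as candidate sets that
  the window density rule then filters. The simulator's shared-latent
  model means the recovery results certify the pipeline's logic, not the
  per-site test's calibration on overdispersed data.
* The synthetic genome has uniform base composition, uniform site
  density, no mappability structure, no missing-data patterns beyond
  coverage sampling, and no correlated methylation beyond the planted
  regions.
* Group counts and integrated gene counts from the motivating study are
  not reproducible at desk scale and are not targeted; recovery is scored
  on planted truth instead.
* Expression is consumed, never modelled: FPKM values in the simulator
  exist only to drive the activity threshold and DE cross-tabulation.
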