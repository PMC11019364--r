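---
title: "Detecting reference-assembly defects from inbred genotype panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reference-assembly defects from inbred genotype panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refpanelqc)
```

# The model

All analyses in `refpanelqc` start from one observation: in a panel of
fully inbred strains, residual heterozygosity is rare and essentially
random, so *structured* heterozygosity is information about the reference,
not about the animals.

## The het+NA scanning statistic

Let $h_i$ and $m_i$ be the number of heterozygous and missing calls at
site $i$ across a designated subset of samples (by default the
reference-strain samples, whose genome *is* the reference and who should
therefore carry no variants at all). The scan statistic is

$$y_i = \log_2(h_i + m_i + 2).$$

The pseudocount of 2 makes the statistic read like a log2 copy number: a
clean site gives $y = \log_2 2 = 1$ ("two DNA copies"), and a site where
all $n$ subset samples are affected gives $\log_2(n + 2)$ — up to
$\log_2 14 \approx 3.81$ for a 12-sample subset, mimicking a region where
up to seven copies collapsed into one. A collapsed tandem repeat shows up
as a contiguous run of elevated $y_i$, because reads from both copies
co-pile on the single represented copy and disagree at paralogous sites.

Assumptions worth stating: genotypes are jointly called across samples (so
missingness is comparable between samples); the subset samples are truly
inbred; and sex chromosomes are excluded (hemizygosity breaks the
diploid-copy reading; the scan covers autosomes only).

## Segmentation

The series $y_1,\dots,y_n$ of one chromosome is segmented in the circular
binary segmentation style. Within an interval, the best *arc* of
consecutive values is the one maximizing

$$T(i,j] = \frac{|\bar y_{\text{arc}} - \bar y_{\text{rest}}|}
                {\sqrt{1/k + 1/(n-k)}}, \qquad k = j - i,$$

the numerator of the two-sample $t$ statistic with the common scale factor
dropped (it is constant over arcs and invariant under permutation, so it
affects neither the argmax nor the test). The split is accepted if its
permutation p-value $(b+1)/(n_{\mathrm{perm}}+1)$ is below `alpha`, where
$b$ counts permutations of the interval's values whose own best arc reaches
the observed statistic; accepted splits recurse into the up-to-three
resulting pieces. No segment of fewer than `min_width` sites is ever
created, and an interval shorter than `2 * min_width` is returned whole.

Defaults: `alpha = 0.001`, `min_width = 5` sites, `n_perm = 1000`
permutations. With 1000 permutations the smallest attainable p-value is
$1/1001 < 0.001$, so the default alpha is exactly reachable and the test
is valid at finite permutation count.

## The four merging rules

Raw segmentation output is over-segmented. Segments are merged by a
sliding-triplet walk: merge the first two segments of the current triplet
when

1. both means are above the threshold $T = 1.5$ (on the log2 scale), or
2. both are at or below it, or
3. the triplet is high–low–high and the middle segment spans less than
   5 kb (a *positive flicker*), or
4. the triplet is low–high–low with the middle shorter than 5 kb (a
   *negative flicker*).

After a merge (mean recomputed as the site-count-weighted average) the next
triplet is (merged, old third, next); otherwise the window advances by one.
The trailing pair at a chromosome end is merged under rules 1–2 only.
Note the deliberate mix of units: segment widths and statistics are in
*sites* (the statistic is per-site), flicker lengths in *bp* (the 5-kb rule
is genomic).

Two design points where the stated procedure left room:

* **Fixed point.** A single forward pass is not idempotent — merging at
  position $i$ can make the pair at $i-1$ mergeable after the walk has
  passed it. The pass is therefore applied repeatedly until nothing
  changes. The fixed point satisfies the idempotence invariant
  (re-merging the output is the identity) and leaves all small
  hand-checkable cases unchanged.
* **Boundary conventions.** A mean exactly equal to $T$ classifies as LOW
  (HIGH is strict), so flag sets are deterministic. Flagged regions are the
  final segments with mean above $T$, emitted as 0-based half-open BED
  (start = position of first member site − 1, end = position of last),
  with the back-transformed mean count $2^{\bar y} - 2$.

One caution: the number of flagged regions is *not* monotone in $T$ for
the full merge+flag composite — raising $T$ can split one merged high
region into two (high–low–high with a ≥ 5-kb middle merges under rule 1 at
low $T$ but not at high $T$). Monotonicity holds, and is what the tests
assert, for flagging over a fixed merged segmentation.

## Numerical choices in the segmentation

* **Arc-length grid.** Series up to 1000 sites are scanned over every arc
  length (the regime in which the test suite proves exact equivalence to
  an exhaustive arc search). Longer series scan a geometric grid of arc
  lengths (ratio 1.25, plus the mirrored lengths $n-k$) at *every* start
  position; a planted region of width $w$ is then found by a grid length
  within 25 % of $w$ and its boundaries are refined by the recursion once
  intervals drop into the exhaustive regime. This keeps a 60,000-site
  chromosome tractable on one CPU.
* **Permutation early stop.** A permutation run stops as soon as the
  p-value can no longer fall below `alpha` (the exceed count only grows),
  which never changes the accept/reject decision. Homogeneous intervals
  therefore cost only a handful of permutations.
* **Tie tolerance.** An arc and its complement are mathematically tied but
  can differ in the final float ulp depending on which orientation the
  scan evaluates. A permuted maximum within $10^{-9}$ relative of the
  observed one counts as an exceedance; genuinely distinct statistics on
  continuous data differ by far more than that.
* **Degenerate inputs.** A constant series has statistic 0 everywhere and
  is never split. Positions must be strictly increasing; negative counts
  are rejected.

# Shared per-site anomalies

A site is recorded when at least `min_share` samples carry a non-reference
genotype (heterozygous or homozygous-alternate; a missing call is not a
carrier) and — by default — every reference-strain sample is among the
carriers. "Most of the panel" is operationalized as
`min_share = ceiling(0.95 * n)`, configurable. The record class is
`HET_SHARED` when heterozygous carriers are at least as frequent as
homozygous-alternate ones (ties go to the suspicious class), else
`HOM_SHARED`. The per-class read-depth summary averages each site's depth
over *all* samples; the HET/HOM ratio near 2 is the collapsed-repeat
depth-doubling diagnostic. Masking removes exactly the recorded sites and
conserves counts.

# Strain genetics

* **IBS** is the shared-allele fraction averaged over co-called sites:
  identical genotypes 1, het vs either homozygote 0.5, opposite
  homozygotes 0; sites missing in either sample are excluded pairwise, and
  by default only bi-allelic SNVs enter. This is the standard
  identity-by-state convention; published IBS means from other tools may
  use slightly different estimators, so cross-study IBS values should be
  compared qualitatively.
* **UPGMA** joins the minimum-distance pair ($d = 1 - \mathrm{IBS}$), sets
  the node height to half the join distance, and updates distances as
  size-weighted averages; ties break on the lexicographically smallest
  leaf labels so trees are reproducible. The output is ultrametric by
  construction and is verified against a brute-force average-linkage
  oracle (distances recomputed from raw leaf pairs) for all $n \le 8$.
* **Proxy matching** reports, per query strain, the best-IBS sample
  outside the query's own substrain(s), against a 0.995 threshold — the
  rule for declaring a living substrain a proxy of a historical progenitor.
* **Mislabel rules**: same-substrain pairs below `same_low = 0.97` and
  different-strain pairs at or above `cross_high = 0.98` are flagged,
  sorted by distance from the threshold. The defaults bracket the
  documented exemplars (a same-strain pair at 0.92, cross-strain pairs at
  0.98–0.99) while staying clear of ordinary replicate IBS (≥ 0.99) and
  background between-strain IBS (≈ 0.7); both are configurable.

# Coordinate translation

The chain parser validates every record's block arithmetic against its
declared spans. Lifting maps a position by offset within its aligned
block; on minus-strand records the destination coordinate decreases as the
source increases. Unmapped positions carry a reason (`gap` versus
`chrom_absent`), and overlapping chains resolve by score. The
simulated-site evaluation plants a site every 1000 bp starting at position
1 (1-based; the offset convention had to be fixed somewhere) and reports
the liftable fraction. Lifted variants are *not* allele-complemented on
minus-strand blocks — a documented limitation; variant matching keys on
(chrom, pos, alleles).

SNP–gene pairs classify per reference as CIS (same chromosome, distance
strictly below 1 Mb), TRANS (different chromosome or strictly above 5 Mb),
and AMBIGUOUS otherwise — distances exactly 1 Mb or 5 Mb are ambiguous,
because the conventional definitions are written with strict
inequalities on both sides. Any association-strength filtering (e.g.
$p < 10^{-8}$) is the caller's job upstream.

Genetic-map concordance computes, per chromosome, the Spearman correlation
between genetic (cM) and physical (bp) marker order and flags maximal runs
of at least `min_run = 5` consecutive markers with locally decreasing
genetic position as candidate misoriented segments.

# Assembly statistics

Every FASTA record is a scaffold; contigs are obtained by splitting at
runs of at least 10 N (shorter N-runs stay inside a contig and count
toward its length; only N defines a gap — lowercase and other ambiguity
codes are sequence). N50/L50 come from the descending cumulative sum; Nx
is always a member of the input multiset. No minimum-length filtering is
applied anywhere. Cross-assembly folds are quoted conventionally: N50
gains of ≥ 100× to the nearest 10, count folds to the nearest integer.

# What the synthetic generator emulates — and what it does not

`generate_panel()` produces: Poisson-spaced sites at 6/kb; per-strain
homozygous-alternate draws at frequency 0.3 with replicates copying their
strain (giving between-strain IBS ≈ 0.7 and within-strain ≈ 1, a realistic
spread); background heterozygosity and missingness at 0.005 each (so
non-reference samples are ~98 % homozygous among their non-reference
calls); Poisson read depth (mean 40, recorded for no-calls too, as joint
callers do); collapsed regions where every sample's call is replaced with
probability `het_na_rate` by a het call or a no-call (equal odds) and
depth is multiplied; shared error sites, half homozygous-shared at
baseline depth and half heterozygous-shared at doubled depth (the two
anomaly classes with their depth signature); and label swaps applied to
sample metadata only, since mislabel detection must see discordant
metadata over concordant genotypes.

It deliberately does *not* simulate: linkage disequilibrium or phylogenetic
structure between strains (strain alleles are independent per site, so the
UPGMA tree over synthetic strains is star-like apart from replicates);
read-level artifacts (no FASTQ, no mapping bias); structural variants;
recombinant pedigrees; or position-dependent depth trends. Passing tests
therefore demonstrate that the *detectors* recover planted truth under the
stated statistical model — not that the model captures every property of
real WGS panels (e.g. segmental duplications that are polymorphic between
strains produce high-het regions in subsets of samples, which this
generator does not emit).

Planted collapsed regions in the recovery tests are 10 kb: the merge rules
themselves absorb high segments shorter than 5 kb as flickers, so plants
must comfortably exceed the flicker scale, and 10 kb (~60 sites at 6/kb)
keeps desk-scale chromosomes small while matching the lower range of
realistically flagged regions.

# Problem sizes and runtime

The shipped tests run at deliberately modest sizes chosen so that the full
suite completes in a couple of minutes on one CPU while every property is
still exercised: the segmentation oracle on 200 series of up to 25 sites
(the exhaustive-scan regime) with 200 permutations at `alpha = 0.01` (with
`alpha = 0.001` a valid test needs more than 1000 permutations, which an
R-level oracle cannot afford); merge properties on 1000 random
segmentations; UPGMA oracle on 1000 matrices of up to 8 leaves;
end-to-end recovery on a 1.5-Mb chromosome with five 10-kb plants across
12 reference samples; and a full pipeline at 40 samples over two 10-Mb
chromosomes (~120,000 sites). The acceptance script mirrors these at the
same or slightly reduced counts.

# Known limitations

* Read depth is used diagnostically (the HET/HOM ratio) but not as a
  second detection channel in the segment scan.
* The scan assumes a single panel-wide genotype quality regime; it does
  not model batch effects between sequencing centers.
* Chain handling covers single-step liftover only (no chain composition,
  no net/axt).
* The IBS estimator is fixed; reproducing IBS values computed by other
  tools' estimators is out of scope.
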