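---
title: "Differential Hi-C region calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential Hi-C region calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `hicscan`, the
design of its synthetic validation fixtures, and the reasoning behind the
less obvious parameter choices.

## 1. The differential model

Let $C$ and $T$ be binned raw contact maps for control and treated
conditions on a common genome with bin size $b$. Both are scaled by their
overall autosomal off-diagonal contact sum $S = \sum_{i<j} M_{ij}$ (cis
pairs counted once, plus autosomal trans pixels when present), which makes
every downstream statistic exactly invariant to a constant depth factor:
multiplying a map by $c$ multiplies $S$ by $c$, and the scaled pixel
$cM_{ij}/cS$ rounds to the same IEEE double as $M_{ij}/S$, so calls are
byte-identical.

The differential map is
$D_{ij} = \log_2\!\big( (T_{ij}/S_T) \, / \, (C_{ij}/S_C) \big)$,
defined where both raw counts are positive ("mask" policy). The
alternative "pseudocount" policy adds
$\psi = \tfrac12 (1/S_T + 1/S_C)$ — roughly one raw count on the scaled
scale — to both terms, keeping every pixel valid at the cost of shrinkage.
Masking is the default because a zero at short range is informative
missingness: treating it as a strong ratio would let shot noise dominate
window scores.

## 2. Window scan and threshold

A window of $w$ bins (default 10) anchored on the diagonal at bin $i$ has
score
$$Q_i = \sum_{i \le p < q < i+w} D_{pq},$$
the sum over the strict upper triangle of the $w \times w$ diagonal
square. Excluding the main diagonal avoids counting self-interactions;
using the triangle counts each pixel once. Masked pixels contribute 0 and
the fraction of valid pixels is recorded; windows with a valid fraction
below 0.5 are never selected, so deserts of masked pixels cannot produce
spuriously "quiet" scores.

The threshold is the 1st percentile of the genome-wide score distribution
(lower tail for decreases). This is a *calibrated-rate* rule, not a
significance test: under the null it deliberately selects ~1% of windows,
which merge into a handful of short regions — the test suite verifies that
null calls stay within twice that rate. A `mean_sd` rule is provided for
genomes with fewer than 100 windows, where an empirical 1% quantile is
meaningless. Passing windows whose starts differ by at most $w$ overlap
or touch, and merge into one region spanning
$[\text{first}\cdot b,\ (\text{last}+w)\cdot b)$, clipped at the
chromosome end.

## 3. Synthetic generator

The expected matrix for one chromosome is
$$E_{ij} = (|i-j|+1)^{-\alpha}\;\beta^{[\text{same TAD}]}\;
  \delta^{[\text{treated and } (i,j) \text{ in a planted rectangle}]}\;
  \left(\tfrac{|i-j| b}{s_\*}\right)^{-\gamma[\text{treated},\ i \ne j]}$$
with block TADs tiling each chromosome. Both conditions are sampled as
independent Poisson draws of the upper triangle with means rescaled to a
fixed target total, then mirrored. Every draw is a pure function of the
configuration seed.

**Planted regions.** A planted pair marks two adjacent domains; the
rectangle of pixels between them is multiplied by $\delta$ in the treated
expectation. The truth region is the union span of the two domains.

**Why 0.5 Mb TADs.** The demo fixture uses uniform 5-bin (0.5 Mb) domains
at 100 kb resolution, so a planted two-domain motif spans 10 bins — the
same size as the scan window. A window centred on the domain boundary
covers the full depleted rectangle (25 of its 45 pixels), giving an
expected score of $25\log_2\delta = -25$ against a null mean of 0 and a
noise SD of about 1.2 at the fixture's depth, a >15-sigma separation.
With 1 Mb domains the motif would span 20 bins while regions are merged
from 10-bin windows, and a Jaccard of 0.5 against the truth would be
geometrically unattainable for a single passing window; matching motif
and window scale keeps recovery a property of the method rather than of
lucky merging.

**Compaction fixture.** The treated tilt $(s/s_*)^{-\gamma}$ with pivot
$s_* = 3$ Mb and $\gamma = 0.3$ raises short-range and depletes
long-range contacts. Because P(s) curves are *normalized* before
comparison, the sign crossover of the normalized log2 ratio does not sit
at the pivot: it sits where the tilt equals its contact-mass-weighted
geometric mean, which for $\alpha = 1$ on a 60 Mb chromosome is near
1.4 Mb independent of the pivot. The fixture therefore guarantees a
positive probe at 1 Mb and a negative probe at 10 Mb. The tilt is applied
to off-diagonal pixels only; the main diagonal is used by no downstream
statistic, and tilting it would only distort the sampling budget.

**Feature peaks.** Non-overlapping 1 kb peaks are planted by a seeded
Poisson process at 50 per Mb inside truth regions and 10 per Mb
elsewhere, emulating the clustering of regulatory marks in regions of
architectural change, and providing a positive control for the
enrichment test.

## 4. Pileups and relative insulation

For each region the window $[\text{start}-f,\ \text{end}+f)$ (flank $f$ =
1 Mb) is extracted as observed/expected, where the expected value at
separation $s$ is the map's own mean contact at that separation.
Windows of different sizes are rescaled onto a fixed grid by
area-weighted block means, with the flank and region bands rescaled
*independently* so band boundaries align across regions. The flank band
width on an $n$-cell grid is $\mathrm{round}(n f / (2f + \bar{L}))$,
proportional to the flank's share of the mean stacked window — a width
proportional to $f/\bar{L}$ alone would leave no room for the region band
whenever $\bar{L} \le f$. Stacking averages each grid cell over regions,
ignoring masked pixels.

Relative insulation splits the region band at its midpoint into halves
$A$ and $B$:
$$\mathrm{RI} = \log_2 \frac{\text{mean o/e over } A{\times}A \cup B{\times}B}
                            {\text{mean o/e over } A{\times}B}.$$
For a planted pair the halves coincide with the two domains, so the
design value of the treated-minus-control RI gain is exactly
$-\log_2\delta$ (= 1 for $\delta = 0.5$); self-normalization of the o/e
expectation biases the realised gain slightly below that, within the
±0.15 acceptance band.

## 5. Enrichment

Feature enrichment in called regions uses the hypergeometric law with the
autosomal map bin as the sampling unit: $N$ = autosomal bins, $m$ =
feature bins, $k$ = region bins, $q$ = their intersection. Both tail
conventions are reported — the inclusive $P(X \ge q)$ is the usual
enrichment p-value; the exclusive $P(X > q)$ is one pmf term smaller.
An alternative "peak" unit treats each peak of a supplied background
universe as the sampling unit, using midpoint membership. The test suite
checks the pmf and both tails against exhaustive subset enumeration for
all parameters with $N \le 12$, and calibrates the false-positive rate
under a matched-density null.

## 6. Problem sizes and limitations

The implementation is dense-matrix based and intended for desk-scale
validation and analysis: hundreds to a few thousand bins per chromosome
(e.g. whole small genomes at 100 kb, or regions of mammalian genomes).
Only cis contacts are modelled; trans pixels participate in scaling
totals but not in calling. Maps are compared raw (sum-scaled), without
matrix balancing; `ic_balance()` is provided for display purposes only.
Window scores are sums, not variance-stabilised statistics, so the
quantile threshold should be interpreted as a ranking rule with a
calibrated call rate rather than a p-value.
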