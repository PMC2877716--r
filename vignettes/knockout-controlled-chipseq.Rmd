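---
title: "Knockout-controlled ChIP-seq peak calling and motif analysis with skelpeak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockout-controlled ChIP-seq peak calling and motif analysis with skelpeak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelpeak)
```

## Overview

`skelpeak` identifies transcription-factor binding sites from a pair of
ChIP-seq libraries in which the negative control is the same
immunoprecipitation performed in knockout (KO) cells. Because the KO
library captures every source of non-specific pulldown — antibody
cross-reactivity, chromatin shearing bias, mappability — a region counts as
factor-specific binding only when it is enriched in the wild-type (WT)
library *relative to the KO library*. The package covers the statistical
peak calling, the motif analyses that follow (de novo discovery in peaks,
consensus construction from in vitro selection pools, positional affinity
classification), peak-to-TSS annotation, and normalized two-group
expression comparison, together with simulators that generate every input
with known ground truth.

## The window statistic and its Skellam null

The genome is scanned with a sliding window of width $w$ (default 240 bp)
placed every $s$ bp (default 10 bp), anchored at multiples of $s$ from
position 0 of each chromosome; a final partial window is dropped. Each
mapped read contributes only its 5′ position (interval start on the plus
strand, interval end − 1 on the minus strand, in 0-based half-open
coordinates); read length plays no further role because the statistic is a
count, not a coverage. Duplicate positions are kept: no deduplication is
applied, and the estimated background rates absorb whatever duplication the
libraries contain. Windows overlapping a repeat-masked base by at least
1 bp are excluded outright — short reads cannot be assigned uniquely there,
and a conservative 1-bp-overlap rule keeps ambiguous windows out of both
the fit and the calls.

For window $i$ let $R_i$ and $N_i$ be the WT and KO counts and
$D_i = R_i - N_i$. Marginally both counts are well approximated as Poisson
with per-window rates $\lambda_R$ and $\lambda_N$, so under the null of no
specific binding $D$ follows a Skellam distribution:

$$P(D = d) = e^{-(\lambda_R + \lambda_N)}
  \left(\frac{\lambda_R}{\lambda_N}\right)^{d/2}
  I_d\!\left(2\sqrt{\lambda_R \lambda_N}\right),$$

with $I_d$ the modified Bessel function of the first kind of order $d$.
Unequal sequencing depths in the two libraries need no explicit
normalization — they shift the mode of the null. The pmf is evaluated in
log space through a log-scale Bessel series, because at genome-scale window
counts the interesting tail probabilities (around $10^{-8}$ and far below)
underflow a naive evaluation; the unit tests pin the implementation against
a truncated two-Poisson convolution to $10^{-12}$ across rate pairs from
0.01 to 10. Degenerate rates are special-cased: with $\lambda_N = 0$ the
null is a pure Poisson on $d \ge 0$ (and mirrored for $\lambda_R = 0$),
with both rates zero it is a point mass at 0 — the Bessel form is undefined
there but synthetic inputs can reach these corners.

Two estimators for the per-window rates are provided: the arithmetic mean
over all non-excluded windows (default), and a "null fit" mean over windows
with at most 3 reads that damps the influence of true signal windows on the
background rate. At genuine genome scale the two are nearly identical
because signal windows are a vanishing fraction; on the small simulated
genomes used in examples they can differ visibly, which is why both are
exposed.

## Local false discovery rate and the critical difference

Observed window differences are modelled as a two-component mixture
$f(D) = p_0 f_0(D) + p_1 f_1(D)$, with $f_0$ the Skellam null and $p_0$ the
null fraction. The local false discovery rate at integer $d$ is

$$\mathrm{fdr}(d) = \min\!\left(1, \frac{p_0 f_0(d)}{\hat f(d)}\right),$$

where $\hat f$ is the empirical histogram density of $D$ over all
non-excluded windows. Empty interior bins receive a 0.5 pseudo-count so
the fdr is defined at every $d$ up to the observed maximum. Because
histogram noise can make the raw fdr non-monotone, a running minimum is
applied for $d \ge 1$; this guarantees a unique **critical difference**
$d_0$, the smallest $d \ge 1$ with regularized $\mathrm{fdr}(d) \le f_p$.
The threshold defaults to $f_p = 0.01$. A window is then significant iff it
is not masked and $D \ge d_0$. The set-level analogue
$\mathrm{FDR}(d) = p_0 P_0(D \ge d) / \hat P(D \ge d)$ is available as
`tail_fdr()`; both tails are evaluated over the observed histogram range,
which makes the value exactly the $\hat f$-weighted average of the
unregularized local fdr over the called set.

$p_0$ can be fixed or estimated by central matching:
$p_0 = \min(1, \min_{d \in [-2,2]} \hat f(d)/f_0(d))$. The central bins are
where signal contributes least, so the ratio there approximates the null
weight; when the signal fraction is truly small the estimate is close
to 1. On deliberately tiny simulated genomes where signal windows are a
non-negligible fraction the central-matching estimate degrades — the
acceptance-style simulations therefore fix $p_0$ at the known null
fraction, which is also what the mixture model means by $p_0$.

Under the study conditions this machinery is exercised at scale: $10^7$
independent windows with null rates $\lambda_R = 0.15273$,
$\lambda_N = 0.21607$, a $10^{-4}$ signal fraction with five extra expected
WT reads, and $p_0$ fixed at $1 - 10^{-4}$ reproducibly give $d_0 = 6$ — a
window needs six more WT than KO fragments to be called. Simulations with
labelled windows confirm that the realized false-discovery proportion at
$d_0$ stays within a small multiple of $f_p$, and background-only runs of
$10^7$ windows yield on the order of 0.1 falsely significant windows.

## From windows to peaks

Each significant window contributes only its step-bin
$[\mathrm{start}, \mathrm{start} + s)$, and overlapping or adjacent bins
are unioned into peaks. The footprint choice matters: unioning full
240-bp windows would make a single significant window produce a 240-bp
peak, whereas the step-bin union makes the minimum peak exactly $s$ bp
(10 bp) — consistent with the smallest reported peaks being one step wide —
and keeps a peak's extent tied to the span of windows that support it.
Peaks separated by at most 100 bp are merged into one region (positioning
noise splits single binding events), an idempotent operation, and regions
of 20 bp or less are set aside: they are too short to search meaningfully
for a 10–15 bp motif, and they surface in output tables flagged
`"too short"` rather than silently vanishing.

## Motif discovery: ZOOPS Gibbs sampling against a Markov background

Peak sequences are searched for a shared fixed-width motif with a collapsed
Gibbs sampler under a zero-or-one-occurrence-per-sequence (ZOOPS) model —
a motif can be genuinely absent from a called peak, and the observed
motif-bearing fraction in real data is high but not 1. Each iteration
withholds one sequence, rebuilds the position frequency matrix from the
remaining site assignments (pseudocount 0.25 per base), and resamples the
withheld sequence's site over all offsets on both strands plus an explicit
"absent" state (prior weight 0.1, uniform positional prior). Site
likelihoods are weighed against an order-3 Markov background trained on the
searched sequences with add-one pseudocounts and lower-order fallback at
sequence starts, so that locally biased base composition is not mistaken
for a motif. Once per sweep a phase-shift move proposes translating the
entire alignment by a small offset, sampled by complete-data likelihood;
without it the sampler reliably locks onto off-by-one or off-by-two
alignments of the true motif. Restarts alternate between random
initializations and seeded ones (all sequences aligned to their best
Hamming match of a randomly drawn site), and the best of `trials` restarts
by total log-likelihood-ratio score is kept. Results are deterministic for
a fixed seed. Defaults follow the study settings — width 10, 20 trials,
10,000 iterations per trial, order-3 background — and planted-motif
simulations (50 sequences of 100 bp, occupancy 0.9, both strands) recover
the planted consensus within Hamming distance 1, in either orientation, in
at least 18 of 20 seeded datasets.

The model score is $\sum_{\text{sites}} [\log_2 P(\text{site} \mid
\text{PFM}) - \log_2 P(\text{site} \mid \text{background})]$: additive over
sites, zero when empty. Absolute values of this score are
implementation-specific (they grow with site count and sharpen with
overfitting), so only orderings are meaningful — motif models fitted on
bound regions score far above models fitted on matched background
sequence, which the tests assert as a strict paired ordering, never as a
particular number.

The IUPAC consensus reported for a PFM uses two thresholds: a single base
at frequency ≥ 0.6, a two-base degenerate code when the top two reach 0.8
jointly, else `N`. These reproduce the degenerate-code style of published
selection-screen and ChIP consensus motifs and are configurable.
Per-column information content is $2 + \sum_b p_b \log_2 p_b$ bits, the
sequence-logo convention for a uniform genomic background.

## Affinity classification

Competition-EMSA scanning of a 10-bp response element shows a sharply
uneven positional tolerance: changes at positions 3, 6, 7 or 8 (the
A···GAG core) essentially eliminate competition, changes at 1, 9 or 10
partially impair it, and 2, 4, 5 are tolerant. `classify_affinity()`
encodes this as a rule against a reference site (default the
high-affinity instance `AAAGCGAGGC`): any deviation at a critical position
→ `Low`; otherwise any deviation at a moderate position → `Medium`;
otherwise `High`. Position 1 is judged against the reference base A
strictly, although the ChIP-derived consensus tolerates A/G there — the
stricter reading matches how single-base competition probes were
constructed, and the reference and position sets are arguments for anyone
wanting the looser rule. The rule partitions all $4^{10}$ sites (64 High,
4032 Medium, the rest Low — verified by exhaustive enumeration). The
pipeline classifies each peak's best site in whichever orientation better
matches the reference, since the sampler may converge to either strand.

## SELEX consensus

`selex_consensus()` extracts a fixed-width consensus from a
binding-site-selection pool by running the same Gibbs sampler over the
selected oligos, insert plus flanks by default because a selected motif
frequently straddles the insert–flank junction. One caveat is inherent:
the flanks are identical in every oligo, i.e. a perfectly conserved
sequence, and with long flanks a de novo sampler can return the flank
itself rather than the selected insert motif. On simulated pools we
therefore demonstrate recovery on flank-free fixtures; with real flanked
pools the flank sequence should be treated as a known artifact when
interpreting the result (published selection screens face the same bias in
the opposite direction — the selected motif can partially reflect the
flank). `enrichment_trace()` summarizes selection progress as the
per-round mean best-site log-odds of a PWM; on positively selected
simulations the trace rises and plateaus, and on an unselected pool it
sits at the background expectation.

The SELEX simulator draws a round-0 pool of uniform random inserts and, in
each subsequent round, keeps each oligo with probability
$\mathrm{logit}^{-1}(\text{strength} \times \text{best-site log-odds})$
and resamples survivors with replacement back to pool size (the PCR
surrogate). There is no mutation, so the information available at round 4
is bounded by what round 0 contained: realistic recovery of a 12-bp
degenerate consensus needs pools of order $10^4$, from which a
sequenced subsample (a few hundred) is analyzed — mirroring the real
screen, where a vast synthesis pool is bottlenecked to tens of sequenced
clones.

## TSS annotation

Peak positions are summarized as the signed distance from the peak center
($\lfloor (\mathrm{start}+\mathrm{end})/2 \rfloor$) to the nearest
annotated TSS: negative upstream of the TSS on the gene's strand, positive
downstream. Absolute-distance ties prefer the TSS lying upstream of the
peak, then the lexicographically smaller gene symbol, making the result
independent of annotation record order. Tallies use inclusive 1 kB and
10 kB cutoffs on |distance|; "within 10 kB of a gene" is implemented as
distance-to-TSS, not distance-to-gene-body — the positional analysis is
TSS-centred throughout, and gene-body extents are deliberately not
consulted. The positional histogram uses half-open 100-bp bins over
[−1000, 1000).

## Expression comparison

qPCR-style expression values are normalized per sample to a reference gene
(e.g. Gapdh) as a handling control, then scaled so the WT group mean is 1;
a KO value of 1 means no difference. Inputs are linear-scale abundances by
default; a `ct_scale` flag applies the $2^{-\Delta C_t}$ transform for
cycle-threshold data, since summary tables do not always record which
scale "normalized" values are on. Group differences use the equal-variance
two-tailed unpaired Student's t-test with $n_1 + n_2 - 2$ degrees of
freedom (`stats::t.test(var.equal = TRUE)`), pinned in tests against the
pooled-variance closed form.

## What the simulators do and do not emulate

The generators reproduce the statistical structure the analysis assumes:
Poisson per-window background counts at the empirical rates
($\lambda_R = 0.15273$, $\lambda_N = 0.21607$ per 240-bp window), a small
fraction of signal windows with a controlled excess of WT reads, planted
peaks whose genomic sequence carries motif instances drawn from a
specified PWM, logistic-selection SELEX rounds, and normal two-group
expression values. Background genome sequence and tag placement are
uniform (order-0), although motif discovery assumes an order-3 background:
window statistics are composition-blind, and a uniform background makes
planted-recovery results interpretable. Consequently, passing tests
demonstrate correctness of the statistics and algorithms under their own
assumptions — they do not demonstrate robustness to mappability structure,
fragment-length effects, PCR duplication bursts, or composition-biased
genomes, none of which the simulators model. Every generator is
deterministic given a seed, and each serializes its ground truth so
realized error rates can be computed without re-deriving it.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere (BED convention), on disk
  and in memory; tags written at interval $[k, k+35)$ map to 5′ position
  $k$ (+) or $k+34$ (−).
- Skellam pmf via a 200-term log-space Bessel series; survival function
  truncated where the Poisson bound on the remaining mass drops below
  $10^{-16}$.
- locFDR: 0.5 pseudo-count for empty bins, running-minimum regularization
  on $d \ge 1$, fdr clipped to $[0,1]$ before regularization.
- Sampler: PFM pseudocount 0.25/base, absent-state prior 0.1, phase-shift
  window ±(width/3), alternating random and seeded restarts.
- Consensus thresholds 0.6 (single) / 0.8 (pair); both configurable.
- Best-site scan ties break to the smallest offset, then the plus strand.
- Problem sizes in the test-suite simulations ($10^7$ windows for the
  critical-difference fit, $10^6$ for calibration, 20 seeded datasets of
  50×100 bp for motif recovery, pools of 2×10⁴ for SELEX) were chosen as
  the smallest at which the targeted quantities stabilize.

## Known limitations

Fragment-size/shift modelling, input-DNA (non-KO) controls, broad-domain
calling, duplicate filtering, spline-smoothed empirical nulls, informative
positional priors for the sampler, and GO-term enrichment are out of
scope. The locFDR operates on integer count differences; no continuous
smoothing is attempted. The SELEX flank bias discussed above is inherent
to de novo search over constant-flanked oligos.
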