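---
title: "Detecting and dating whole-genome duplications from Ks age distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating whole-genome duplications from Ks age distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksage)
library(dplyr)
```

## The problem

A whole-genome duplication (WGD, polyploidy) duplicates every gene in a
genome at once. Most duplicates are subsequently lost, but the survivors
leave two detectable footprints: a burst of gene pairs with a common
synonymous divergence (a peak in the *K*~s~ age distribution of the
paranome), and long runs of duplicated gene order (collinear, or
homeologous, segments). `ksage` implements the computational chain that
turns raw genome annotations into evidence for and ages of WGD events:

1. **Paranome inference** — cluster all-vs-all protein similarity hits into
   gene families, after correcting the gene-length bias of bit-scores.
2. ***K*~s~ age distributions** — estimate the synonymous distance of every
   duplicate pair and remove the redundancy of non-independent pairs.
3. **Collinearity** — find duplicated segments and extract *anchor pairs*,
   duplicates that reside in them and are therefore the strongest WGD
   evidence.
4. **Rate correction** — place WGDs relative to speciation events while
   accounting for lineage-specific substitution-rate variation.
5. **Mixture modelling and anchor filtering** — locate *K*~s~ peaks and
   select the anchor pairs that belong to them, producing the inputs an
   external molecular-dating engine needs.

Everything operates on tibbles and composes with the pipe; every stage can
also be driven by the synthetic-data module, so the whole pipeline is
testable without downloading a genome.

## Bit-score normalization

Longer genes produce larger bit-scores at equal similarity, which biases
family clustering. For each hit we define the *proxy gene length* as the
product of the query and target amino-acid lengths. Hits are sorted by proxy
length and split into `n_bins` equal-count bins (default 100; a remainder is
spread over the leading bins). Within each bin the top `top_percent` of hits
by bit-score (default 5%, at least one hit per bin) represent the
"same-length, maximal-similarity" envelope; an ordinary least-squares
regression of log10 bit-score on log10 proxy length over those hits gives
the expected bit-score at a given length, and each hit's score is divided by
its expectation:

$$\mathrm{norm} = \frac{b}{10^{\,\hat\alpha + \hat\beta \log_{10}(L_q L_t)}}.$$

Two numerical details matter. Equal-count bins (rather than equal-width)
guarantee that the per-bin top-percentile selection is defined for every
bin. And the procedure is scale-equivariant: multiplying all bit-scores by a
constant shifts only the intercept, leaving normalized scores unchanged,
which the tests assert. If all hits share one proxy length the regression is
undefined; scores are then divided by their geometric mean with a warning.

On simulated hits with a known power law (`bitscore = L^0.8` times lognormal
noise), the regression recovers the exponent and the post-normalization
R² of log score on log length collapses to near zero — the property the
acceptance script reports as `normalization_slope_recovered` and
`normalization_r2_after`.

## Markov clustering

Families are read off a Markov-cluster (MCL) run over the normalized-score
graph. No MCL implementation exists among the installed R packages, so the
package carries its own dense-matrix version: symmetrized weights, self-loops
at each node's maximum incident weight, column-stochastic normalization, then
alternating expansion (matrix squaring) and inflation (entrywise power,
default 2.0, then column renormalization), with entries below `1e-8` pruned
each round, until the maximum entry change falls below `1e-6` or 100
iterations. Clusters are the connected components of the converged matrix's
non-zero structure, which guarantees a partition of the gene set. MCL can
only fragment, never bridge, connected components; a test checks this
against an independent graph-components oracle, and another checks that
inflation 6 fragments a path graph more than inflation 1.2.

## NG86 *K*~s~ estimation

Pairwise synonymous distances use the Nei–Gojobori (1986) counting method
with the Jukes–Cantor correction; maximum-likelihood codon models behind
external tools are deliberately out of scope so the estimator is exact and
fully testable. Per codon, each position contributes the fraction of its
three possible single-nucleotide changes that are synonymous to the
synonymous site count *S*; the remainder goes to *N*, so *S* + *N* equals
three times the number of compared codons (changes creating stop codons are
counted as nonsynonymous sites under this convention). Differences between
two codons are averaged over all orderings of the differing positions,
excluding paths that pass through a stop codon (falling back to all paths
when every ordering is blocked). With $p_s = s_d / S$,

$$K_s = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3} p_s\right),$$

flagged saturated when the argument is non-positive ($p_s \ge 0.75$). A
nine-codon example with a single third-position change in a fourfold
degenerate codon has the closed form $-0.75\,\ln(1 - 4/27) \approx 0.1203$,
asserted to $10^{-3}$.

The synthetic counterpart, `evolve_codon_pair()`, applies uniformly chosen
synonymous single-nucleotide substitutions to a random stop-free sequence
until the pair's NG86 *K*~s~ reaches the target, so the generator and the
estimator validate each other; the evolver never changes the protein, which
is asserted by translating both sequences. Synonymous evolution uses the
standard genetic code only and no among-site rate variation — anything else
would break the exactness of the oracle. Median absolute recovery error over
targets 0.1–1.0 at 300 codons is well inside the 0.05 the tests require.

## Family trees and event deduplication

A family of *n* genes yields $\binom{n}{2}$ *K*~s~ values but only $n-1$
duplication events, and naive histograms overweight large families. Each
family gets an average-linkage (UPGMA) tree built on its *K*~s~ matrix —
implemented in the package rather than via `hclust` because reproducible
output requires a deterministic tie-break (merge the pair of clusters with
the lexicographically smallest representative ids); `hclust(method =
"average")` serves as the independent oracle on random matrices. Saturated
entries enter tree building at a cap (default 5.0). Every leaf pair maps to
its most recent common ancestor node, and either

* **node-weighted**: each pair with MRCA *m* gets weight
  $1/\#\{\text{pairs at } m\}$, so each event's weights sum to exactly 1, or
* **node-averaged**: one entry per node, the arithmetic mean of its pairs'
  *K*~s~, with weight 1.

Property tests over random trees assert the weight sums to within $10^{-12}$
and exactly one entry per internal node in averaged mode.

## Collinearity

The built-in detector is a gap-bounded diagonal chainer in gene-rank space
(the full statistical machinery of dedicated collinearity engines is out of
scope; their segment tables can be imported as TSV instead). Within each
chromosome pair, matches sorted by rank extend a chain when both rank
increments are within `[1, max_gap]`; both orientations are tried so
inverted blocks are recovered as descending chains. Chains need at least
`min_genes` anchors (default 3) and a base-pair span of `min_length_bp`
(default 100 kb) on both regions. Tandem arrays are collapsed to one
representative before chaining, and chains sharing at least half their
anchor pairs are redundant — only the anchor-richest survives. Strand is
ignored: chaining operates at gene-rank granularity.

Three summaries serve diagnosis: `dupstack()` stacks segment intervals along
chromosomes in non-overlapping lanes; `syndepth()` merges regions that
overlap by at least half their rank span and counts homeologous groups per
multiplication level (a triplication yields three pairwise segments that
collapse into one level-3 group); `dotplot_table()` lays out every homolog
pair on cumulative gene indices with anchors flagged and coloured by
*K*~s~. The 50% overlap threshold for syndepth grouping is a configurable
interpretation — how segment groups aggregate into levels is genuinely open
— and the same 50% rule is reused for chain redundancy.

On synthetic genomes with implanted duplications the detector attains recall
and anchor precision 1.0 on clean backgrounds, and precision at least 0.95
with random background homolog pairs at density 0.001.

## Rate correction across lineages

Ortholog *K*~s~ distributions date speciations, paralog distributions date
duplications; comparing them is only meaningful if lineage-specific rate
differences are removed. For a focal species *F* and sister *S*, every
possible outgroup *O* forms a trio. The mode of each ortholog distribution
is the argmax of a Gaussian KDE evaluated on a 512-point grid over
$[0, 1.05\,\max]$ (left-most grid point on ties), with Silverman's
rule-of-thumb bandwidth computed on the weighted sample (effective sample
size $(\sum w)^2 / \sum w^2$). Each distribution is bootstrapped 200 times;
$\mathrm{Mean}(i,j)$ denotes the bootstrap-averaged mode.

The corrected divergence mode is the trio average of
$\mathrm{Mean}(F,O_i) - \mathrm{Mean}(S,O_i) + \mathrm{Mean}(F,S)$, and its
standard deviation combines per-trio variances with cross-trio covariances:

$$\mathrm{std} = \frac{1}{N}\sqrt{\sum_i \mathrm{Var}(\mathrm{trio}_i)
  + 2 \sum_{i<j} \mathrm{Cov}(\mathrm{trio}_i, \mathrm{trio}_j)}.$$

Covariance is estimable because replicates are paired by index and all trios
share one bootstrap stream per species pair — in particular the
$(F,S)$ stream, which induces strong positive cross-trio covariance. With
this pairing the formula is *exactly* the empirical standard deviation of
the trio-averaged replicate vector, an algebraic identity the tests assert
to $10^{-9}$; with one trio it reduces to $\sqrt{\mathrm{Var}}$. The same
three modes decompose into branch contributions
($b_F = (m_{FS} + m_{FO} - m_{SO})/2$), and the rescaled mode per trio is
identically $2 b_F$ — a cross-check between the two modules. Negative branch
estimates are reported as-is with a warning rather than truncated.

## Mixture models

Two families of models locate WGD peaks in a weighted *K*~s~ distribution.
Both run weighted EM: data weights multiply the responsibilities in every
sufficient statistic, so node-weighted distributions are handled natively.
Zero, non-finite and saturated values are excluded first, with counts
reported.

* **Log-scale GMM**: a Gaussian mixture on $\ln K_s$; each component is a
  lognormal on the *K*~s~ scale with peak (mode) $\exp(\mu - \sigma^2)$.
* **ELMM**: an exponential background on the *K*~s~ scale (rate MLE
  $\sum r_{\exp} w / \sum r_{\exp} w x$ in the M-step) plus up to five
  lognormal peaks. The exponential models the continuous attrition of
  small-scale duplicates; the lognormals model discrete WGD bursts.

Initialization spreads component means over weighted quantiles (first
initialization unjittered, later ones jittered; 5 initializations, best
log-likelihood kept), with a shared initial variance and a background weight
of 0.5 for ELMM. Convergence is $10^{-6}$ on the log-likelihood, at most 500
iterations; non-convergence returns the best-so-far fit flagged
`converged = FALSE`. Component log-sds are floored at $10^{-3}$ (warned) so
degenerate inputs cannot collapse a component. EM monotonicity of the
weighted log-likelihood is asserted at every iteration in the tests. Model
choice is by BIC ($-2\ell + k \ln n$) or AIC over the fitted range, ties to
fewer components.

For anchor filtering, the "95% confidence level" of a fitted peak is read as
the central quantile interval of the lognormal component,
$\exp(\mu \pm z_{0.975}\,\sigma)$ — a confidence region on the parameters
would shrink with *n* and is not what anchor selection needs. The upper
bound is truncated at a saturation cutoff (default *K*~s~ = 3). Retained
anchor pairs, their RBH-based orthogroups and the starting species tree are
exported as FASTA plus a control-file template; no dating engine is
executed.

## The synthetic-data module

`build_genome()` lays out chromosomes with uniformly spaced genes (20 kb
spacing, gene lengths uniform in 0.5–1.5 times a typical 100 codons — enough
length spread to exercise the bit-score regression), implants duplicated or
triplicated gene runs whose copies are evolved to a requested *K*~s~, and
records the ground truth: the family partition, every homeologous relation,
and realized per-anchor *K*~s~. `sample_ks()` draws from a specified
exponential + lognormal mixture, keeping component labels for
parameter-recovery tests (never shown to fitting code), with draws above a
cap (default 5) redrawn. `synthetic_hits()` emits hit tables whose bit-scores
follow a known power law in the proxy length.

What the generator does *not* emulate: codon-usage bias, indels and
alignment uncertainty, nonsynonymous divergence, gene loss/fractionation,
tandem-duplication clusters, and rate variation among sites. Passing tests
therefore demonstrate correctness of the algorithms under clean conditions,
not robustness to the full messiness of real genomes — on real data the
anchor *K*~s~ peaks are broader, background homology is denser, and
saturation matters sooner.

## Problem sizes and runtime choices

The bundled end-to-end run uses a 2-chromosome, 600-gene genome with one
implanted WGD at *K*~s~ = 1 and recovers the anchor-pair peak within 0.1;
parameter-recovery simulations use 5,000–10,000 draws; bootstrap analyses
use the default 200 replicates on samples of 1,000 ortholog pairs. These
sizes keep any single check under a few minutes on one CPU while leaving the
statistical tolerances comfortably testable.

## Known limitations

* NG86 with Jukes–Cantor is downward-biased at high divergence relative to
  maximum-likelihood codon models; estimates beyond *K*~s~ ≈ 2–3 should be
  treated as ordinal. This is the package's single largest deviation from
  pipelines that shell out to ML estimators, chosen for exactness and
  self-containment.
* The diagonal chainer is a deliberately simple stand-in for full
  collinearity engines; highly rearranged or fractionated segments that
  require profile alignment will be missed. Externally produced segment
  tables can be imported instead.
* KDE modes inherit Silverman-bandwidth smoothing bias (a few percent to the
  right for right-skewed distributions); this cancels in the trio
  differences the rate correction uses but is visible in raw modes.
* The UPGMA family tree assumes clock-like divergence within families;
  midpoint rooting of an ML tree is not implemented.
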