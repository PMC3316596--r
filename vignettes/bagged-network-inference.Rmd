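---
title: "Bagged C3NET: model, calibration and design choices"
author: "bagc3net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bagged C3NET: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bagc3net)
```

## The inference model

Mutual-information (MI) relevance networks treat every gene's expression
profile as a random variable and connect gene pairs whose dependence,
measured by $I(X;Y) = H(X) + H(Y) - H(X,Y)$, is statistically
significant. C3NET (conservative causal core) restricts this idea: each
of the $n$ genes may contribute at most one edge, namely the pair with
its *maximal* MI, so only $n$ candidate hypotheses are tested rather
than $n(n-1)/2$, and the result is a conservative core of the
dependency structure.

`bc3net()` bags this base learner. From the expression matrix $D$
(genes $\times$ samples) it draws $B$ non-parametric bootstrap datasets
$D_k$ (samples resampled with replacement), infers one C3NET network
$G_k$ per dataset, and aggregates the ensemble into edge weights

$$ w_{ij} \;=\; \#\{k : \{i,j\} \in G_k\} \in \{0, \dots, B\}. $$

Under the null hypothesis that genes $i$ and $j$ are connected only by
chance, $w_{ij}$ is modelled as $\mathrm{Binomial}(B, p)$, where $p$ is
the probability that a pair acquires a chance edge in one ensemble
member. $p$ is estimated by running the identical ensemble procedure on
a whole-matrix permutation of $D$: if it produces $e_{\mathrm{rand}}$
edges in total, then

$$ \hat p = \frac{e_{\mathrm{rand}} + 1}{B \, n(n-1)/2 + 1}, $$

with a one-unit pseudocount in both numerator and denominator so the
binomial test is always defined (at small $n$, $e_{\mathrm{rand}} = 0$
is common). Each observed pair gets the upper binomial tail
$P(X \ge w_{ij})$, Bonferroni-corrected over all $n(n-1)/2$ pair
hypotheses (pairs never seen in the ensemble have $p$-value 1 but still
count in the denominator); pairs surviving at level $\alpha$ form the
final undirected network. Because bagging approximates Bayesian model
averaging with a noninformative prior, the final network can contain
more than $n$ edges — the main practical gain over a single C3NET run.

## Calibration choices

Three places in this pipeline admit a naive implementation that is
statistically wrong. We document the choices here because they are the
package's core design decisions.

**The candidate statistic is a maximum.** A gene's candidate edge
carries the largest of its $n-1$ pairwise MI values. Comparing that
maximum directly against the null distribution of a *single* pair and
then Bonferroni-correcting over the $n$ genes does not control the
family-wise error rate (FWER): under the global null the procedure
rejects with probability on the order of $(n-1)\alpha/2$. `c3net()`
therefore converts the pairwise empirical $p$-value by the Šidák map
$p_{\max} = 1 - (1-p)^{\,n-1}$ — the exact tail of the maximum under
independence — before the Bonferroni step
(`candidateNull = "max"`, the default; `"pairwise"` retains the
uncalibrated variant, and `ordering = "filter-first"` the historical
test-all-pairs-then-select formulation).

**Members run the full algorithm.** Each ensemble member runs C3NET
*including* its multiple-testing correction (`memberMtc = "bonferroni"`,
the default). Running members at the uncorrected per-test level floods
the ensemble with spurious edges; more subtly, a noise dataset's
top-ranked pairs recur across bootstrap resamples, so their weights
approach $B$ while $\hat p$ — which calibrates only the *rate* of chance
edges, not their concentration on recurrent pairs — stays small, and the
binomial test fires on pure noise almost surely. With full-C3NET
members, rejection on noise requires a pairwise permutation tail below
roughly $\alpha / (n(n-1))$, and the measured FWER on the package's own
noise benchmark (30 genes, 50 samples, $B = 50$, 100 replicates,
computed by the test suite) is $\approx 0.09$ at $\alpha = 0.05$ —
within the binomial sampling margin of the nominal level, where the
uncalibrated variants measure 0.95–1.0.

**The null must see bootstrap data.** A bootstrap resample duplicates
samples, so its effective sample size is $\approx 0.63\,n$ and MI
estimates on it are inflated relative to the original data. A shared
null built from un-resampled randomized data therefore sits
systematically below the member statistics. `buildMINull(bootstrap =
TRUE)` — used automatically for the ensemble's shared null — resamples
each randomization round before drawing MI values, matching the null to
the statistics tested against it. Per-member nulls
(`sharedNull = FALSE`) achieve the same at $B$-fold cost.

**Null resolution.** Empirical permutation $p$-values cannot fall below
$1/(n_{\mathrm{draws}}+1)$. With member-level Bonferroni a member edge
needs a pairwise tail below about $\alpha/(n(n-1))$, so
`nDraws` must exceed $n(n-1)/\alpha$ — e.g. $2\times 10^5$ for 100
genes at $\alpha = 0.05$ — or members are empty by construction. The
RM3 scheme makes this cheap: every whole-matrix randomization yields up
to $n(n-1)/2$ distinct pair draws, and the builder re-randomizes the
matrix whenever a round's pairs are exhausted (at genome scale one
round already provides millions of draws).

## Mutual information estimators

Eight estimators are available through one interface
(`miMatrix()`, `miDiscrete()`, `miBspline()`, `miCorrelation()`):

| estimator | data | idea | parameters (default) |
|---|---|---|---|
| `empirical` | binned | plug-in on cell frequencies | `nBins` ($\lceil\sqrt{n}\rceil$), equal-width |
| `miller-madow` | binned | plug-in $+\,(\hat m - 1)/(2N)$ bias term | as above |
| `shrinkage` | binned | James–Stein shrink toward uniform, analytic $\lambda \in [0,1]$ | as above |
| `schurmann-grassberger` | binned | Dirichlet pseudocount $1/K$ per cell | as above |
| `bspline` | continuous | fractional bin weights from B-spline bases | `order` 3, `nBins` 10 |
| `pearson`/`spearman`/`kendall` | continuous | $I = -\tfrac12\log(1-\rho^2)$ | coefficient choice |

All values are in nats and clamped below at zero; $|\rho|$ is clamped
to $1 - 10^{-12}$ so the correlation transform stays finite. Constant
(zero-variance) profiles yield MI 0 against every partner with a
warning rather than an error, since real expression matrices contain
flat probes. Equal-frequency binning uses rank-based quantile cuts and
rejects constant profiles; equal-width binning assigns the maximum to
the last bin.

Two estimator facts worth knowing. First, the finite-sample bias of the
binned plug-in grows like $(K-1)^2/(2N)$ for the joint term, so the
$\sqrt n$ default bin rule is a compromise — at $n = 5000$ it implies
71 bins and a bias near 0.5 nats; pass an explicit `nBins` when
absolute MI values matter. Second, the B-spline estimator's fractional
assignment acts as a soft quantizer: at its canonical settings (order
3, 10 bins) it reports systematically smaller values than the
continuous MI (about 0.24 vs. 0.51 nats for a bivariate normal with
$\rho = 0.8$) and approaches the closed form only as bins grow. Both
effects cancel out of *rank-based* uses such as C3NET's argmax
selection, which is why estimator choice mostly matters through
variance, not bias, for network inference.

## Randomization schemes

Three permutation schemes generate the MI null (`buildMINull()`):
RM1 permutes one profile of each evaluated pair; RM2 additionally draws
both profiles from random gene rows; RM3 permutes the entire matrix at
once and evaluates distinct pairs of the randomized matrix. On data
without dependence structure all three agree (the test suite checks
pairwise Kolmogorov–Smirnov distance of 10,000-draw nulls against the
1% critical value); RM3 is the default because it is the cheapest by a
wide margin.

## The expression simulator

`simulateExpression()` provides ground-truth-wired data for
benchmarking. An undirected truth network (e.g. from
`erdosRenyiNetwork()`, which can hold a block of deliberately
unconnected genes, or `sampleSubnetwork()` of a user-supplied regulatory
network) receives a random acyclic orientation; source genes draw
independent uniform activities per sample; each downstream gene's
activity is the mean Hill-type response
$a^h/(K^h + a^h)$ (coefficient $h = 2$, half-saturation $K$ at the
regulator's mean activity, activation or repression with equal
probability per edge) of its regulators; measured expression is the
log2 abundance plus Gaussian noise of standard deviation `noiseSd`
(default 0.1) on the log scale — i.e. multiplicative log-normal noise,
emulating normalized microarray intensities.

What it captures: monotone saturating regulation, adjacency-linked
statistical dependence detectable by MI, independent unconnected genes,
tunable biological noise. What it does not: mRNA degradation dynamics,
feedback loops (the acyclic orientation removes them), combinatorial
logic beyond averaged single-regulator responses, and technical
artifacts such as batch effects. Passing recovery benchmarks on this
generator therefore demonstrates correct statistical behaviour of the
inference machinery, not performance on any particular platform's real
data.

## Evaluation and enrichment

`confusionCounts()`/`fScore()` classify all $\binom{N}{2}$ unordered
pairs of the gene universe (unconnected genes included — they supply
true-negative and false-positive pairs), `tpGain()` reports the percent
increase in true positives of one method over another with a unit floor
in the denominator, and `randomBaseline()` gives the F-score
distribution of uniformly random edge sets as the chance reference.

`gpeaTest()` performs gene-pair enrichment analysis: with $N$ universe
genes, $T = \binom{N}{2}$ pairs, $M = \binom{m}{2}$ pairs inside an
$m$-gene set, and $E$ network edges of which $k$ fall inside the set,
the $p$-value is the hypergeometric upper tail $P(X \ge k)$ of drawing
$E$ from $T$ with $M$ successes, and $ME/T$ the expected edge count.
The universe defaults to the analyzed network's genes and terms are
restricted to it before $m$ is counted; edges with one endpoint outside
a term count toward $E$ but not $k$. The implicit null — a fully
connected gene set — matches protein-complex annotations and is
deliberately conservative for broader categories; no correction is
applied for that. `nestedComponents()` intersects an inferred network
with a reference (e.g. protein–protein interactions) and
`componentSizePvalues()` assesses component sizes against a gene-label
permutation null. Two null statistics are defensible — comparing each
observed component to the permuted distribution of the same-rank
component, or to the permutation *maximum*; the package uses the
maximum, the conservative choice that also absorbs the multiplicity of
component formation across permutations.

## Numerical and degenerate-input conventions

* Argmax ties in C3NET break toward the lexicographically smallest
  partner label — deterministic and seed-independent.
* Empirical $p$-values use the $(r+1)/(n_{\mathrm{draws}}+1)$
  pseudocount convention and so are always in $(0, 1]$.
* The shrinkage entropy's $\lambda$ is clamped to $[0,1]$ and set to 1
  when its variance denominator vanishes (e.g. exactly uniform counts).
* Empty networks, empty enrichment tables and zero true positives are
  valid results, reported with warnings where user error is plausible
  (e.g. an edgeless network in `gpeaTest()`).
* All randomness flows from one user seed, fanned out into named
  sub-streams (`null`, `bootstrap`, `phat`) so stages are individually
  reproducible; identical configuration and seed give identical
  networks bit for bit.

## Problem sizes used by the test suite

The statistical properties above are exercised at desk scale: Gaussian
closed-form checks at $n = 5000$ over 20 seeds; FWER calibration on
$30 \times 50$ noise matrices with $B = 50$ over 100 replicates;
recovery on Erdős–Rényi truths with 100 genes (10 unconnected), edge
probability 0.01, $n = 200$ samples and $B = 100$ over 20 replicates
(the acceptance script uses 8); randomization-scheme concordance with
10,000 null draws per scheme. The correlation (Pearson) MI estimator
drives the ensemble experiments at these sizes; the simulator's
monotone kinetics make it an appropriate and fast choice there, while
the B-spline estimator remains the package default for general use.

## Known limitations

* FWER control of the full pipeline is approximate: the binomial null
  treats members as independent, while bootstrap ensembles share the
  original data. The measured excess (0.09 vs. nominal 0.05 on the
  noise benchmark) is within the sampling margin but users wanting
  strict control should lower $\alpha$.
* Empirical nulls bound attainable $p$-values; at small `nDraws` the
  member-level Bonferroni threshold may be unreachable and networks
  come out empty (see *Null resolution* above).
* The Kendall estimator is $O(n^2)$ per pair and impractical for
  genome-scale matrices.
* Networks are undirected; no orientation or edge-sign inference is
  attempted, and the GPEA makes no use of the GO graph structure —
  gene sets are flat.
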