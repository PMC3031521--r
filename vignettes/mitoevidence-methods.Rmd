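---
title: "Methods: evidence integration and network function inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence integration and network function inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoevidence)
```

## The integration model

The package treats each genome-scale localization predictor as a binary
channel reporting on one latent state: whether a nucleus-encoded protein is
mitochondrial. Writing $s_i \in \{0, 1\}$ for predictor $i$'s call, the
naive Bayes model assumes the calls are independent given the class, so the
posterior odds of mitochondrial localization factorise into the prior odds
times a product of per-predictor likelihood ratios:

$$O_{\text{post}} = O_{\text{prior}} \prod_{i=1}^{N} L(s_i), \qquad
L(s_i) = \frac{P(s_i \mid \text{mito})}{P(s_i \mid \sim\text{mito})}.$$

Each protein's working score is the summed log-likelihood ratio
$\text{logLR}(p) = \sum_i \log_{10} L(s_i(p))$, and a protein is called
mitochondrial when logLR strictly exceeds a threshold. Log base 10 is used
throughout because the conventional operating thresholds in this problem
(1.27 $\approx \log_{10} 19$, matching prior odds of roughly 1 in 19 for
$\sim$1,500 expected positives among 30,480 proteins, and the conservative
1.37) are only meaningful on that scale.

### Likelihood-ratio estimation

`estimate_likelihood_ratios()` estimates the class-conditional call
probabilities by relative frequencies on the gold-standard positives and
negatives with a symmetric pseudocount $\alpha$:
$P(s = c \mid \text{class}) = (n_{c,\text{class}} + \alpha) /
(n_{\text{class}} + 2\alpha)$. The default $\alpha = 1$ (Laplace) keeps
every ratio finite when a predictor never fires on one class — common for
high-specificity ortholog predictors at moderate sample sizes. With
$\alpha = 0$ a zero cell raises an error rather than returning an infinite
ratio. Proteins a predictor refused to score (missing calls) are excluded
from that predictor's tallies; at integration time missing calls are
skipped by default (absence of evidence contributes $\log_{10} 1 = 0$),
with an `as_absent` policy available for sensitivity analysis that treats
them as 0-calls.

The classification rule is a *strict* inequality at the threshold: a score
exactly at the threshold is negative. Monotonicity in the threshold and
additivity of logLR over predictor subsets are property-tested.

### Group merging

Two reduced-ensemble strategies are provided. The *direct* merge ORs a
group's calls into one feature. The *indirect* merge counts how many group
members call a protein and fires at a configurable record threshold — the
conventional choices being 4 of the nine targeting-signal predictors and 2
of the four phylogenetic predictors. Both reduce to the same voting
primitive (`merge_group_indirect()`, with threshold 1 for the direct case).

## The N50 coexpression predictor

For gene $g$ and expression dataset $d$, the N50 statistic is the number of
gold-standard mitochondrial genes among the $k = 50$ genes nearest to $g$
by Euclidean distance over $d$'s samples. Two conventions are fixed here
because they affect results and are easy to get silently wrong:

* the query gene is **excluded** from its own neighbour list — otherwise
  every gold-standard gene would count itself and inflate its own feature;
* distance ties are broken by **ascending gene id**, making counts
  deterministic and exactly reproducible by the brute-force oracle the
  tests use.

Genes absent from a dataset (real expression panels never cover the whole
genome) contribute a missing count, not zero. The classifier over the
per-dataset count vectors is an axis-aligned decision tree (rpart). Exact
C4.5 behaviour is not a goal; the C4.5-style pruning knob maps to rpart's
complexity parameter as $cp = 0.01 \cdot 0.25 / \text{confidence factor}$
(so the conventional 0.25 gives rpart's default $cp = 0.01$, and weaker
confidence prunes harder), with `min_leaf` mapping to `minbucket`. Missing
counts enter the tree as the sentinel value $-1$, which is separable from
all true counts ($\geq 0$); rows missing in *every* dataset get a missing
call. Performance is estimated by label-stratified 10-fold cross-validation
with deterministic fold assignment given a seed.

## Evaluation

Confusion-matrix metrics are kept at full precision internally; the
reporting layer (`report_percent()`) rounds half-up to two decimals, the
convention used in published performance tables. Ratios with zero
denominators are reported as undefined (`NA`), never as 0.

ROC curves are built by a threshold sweep over the unique score values plus
a $-\infty$ sentinel, with ties moving as blocks; the trapezoid AUC then
equals the Mann–Whitney pair statistic with ties counted one half, which
the tests verify by brute-force enumeration. `select_threshold()` supports
maximum accuracy, maximum Youden index (ties broken toward the larger,
more conservative threshold), and an FPR cap (smallest threshold meeting
the cap).

Cross-validation of the integration re-estimates the likelihood ratios on
each training split and pools held-out predictions into a single confusion
matrix. Folds are stratified by label even though simple equal-sized splits
would usually work: at a 1:1.8 class ratio unstratified folds can
occasionally starve a fold of positives and make LR estimation degenerate.

## Network-based function inference

Functional similarity between interacting proteins is measured on
*inclusive* neighbourhoods $N_p = \{p\} \cup \text{adj}(p)$ — the set
explicitly includes the protein itself. The Czekanowski-Dice distance is
$D(u,v) = |N_u \,\Delta\, N_v| / (|N_u| + |N_v|)$ and the similarity used
everywhere is $S_1 = 1 - D = 2|N_u \cap N_v| / (|N_u| + |N_v|)$. Level-2
association is transitive: each shared intermediate neighbour $w$
contributes $S_1(u,w) \cdot S_1(w,v)$. The contributions are **summed and
capped at 1** by default; a `max`-over-paths variant is provided behind
`funscore_params(s2_mode = "max")` because the aggregation rule is a
genuine modelling choice — summation rewards multiple independent paths,
max is robust to hub-induced path inflation. On sparse planted-module
networks the two differ little; the default follows the path-summation
family of neighbourhood-voting methods.

The score for protein $p$ and function $x$ is

$$\text{FunScore}(p,x) = \frac{\lambda\, r_{\text{int}}\, \pi_x +
\sum_{v \in L1(p)} S_1(p,v)\,\delta(v,x) +
\sum_{w \in L2(p)} S_2(p,w)\,\delta(w,x)}{\lambda\, r_{\text{int}} +
\sum_{v \in L1(p)} S_1(p,v) + \sum_{w \in L2(p)} S_2(p,w)},$$

with $\lambda = 1$, $r_{\text{int}}$ the fraction of edges whose two
endpoints share at least one function (computed over both-annotated edges
only — edges with an unannotated endpoint carry no information about
sharing), and $\pi_x$ the frequency of $x$ among annotated proteins. The
shared denominator $Z$ guarantees scores in $[0,1]$ and makes terms of one
protein comparable. An isolated protein falls back to $\pi_x$; if
additionally $r_{\text{int}} = 0$, $Z = 0$ and the score is undefined
(`NA`), not zero. Annotation levels are restricted to mid-depth tiers
(4–5 by default) so that $\pi_x$ is neither ubiquitous nor vanishing.

Candidate (protein, function) pairs pass a preliminary score filter at
0.03; significance additionally requires an empirical permutation p-value
below 0.05. The permutation unit is the **whole annotation set of a
protein**, shuffled among annotated proteins: this preserves each protein's
annotation count and every term's global frequency, so the null keeps the
annotation structure and only breaks its placement on the network. The
network-derived weights, $r_{\text{int}}$ and $\pi$ are held at their
observed values across permutations (they are global model parameters, and
the constant background offset cancels in the observed-vs-permuted
comparison); p-values use the add-one estimator
$p = (1 + \#\{\text{perm} \geq \text{obs}\}) / (n_{\text{perm}} + 1)$, so
they are never exactly zero and the procedure is reproducible given a
seed.

## Stress subnetworks and enrichment

The stress subnetwork keeps every edge with at least one endpoint in the
seed list, plus incident nodes. This incident-edge rule (rather than the
induced subgraph on seeds only) is the membership rule consistent with
stress networks containing substantially more proteins than seed genes, as
observed in practice. Overrepresentation per term is the hypergeometric
upper tail $p = \sum_{i \geq k} \binom{K}{i}\binom{N-K}{n-i} /
\binom{N}{n}$ via `stats::phyper`, with Benjamini–Hochberg adjustment over
the tested terms; zero-overlap terms are not tested (their $p$ would be 1
and they would only dilute the correction).

## The synthetic-data module

The generators produce data with exactly the statistical structure the
methods assume, which is what makes the property tests meaningful:

* **Gold standard**: 806 positives and 1,464 negatives by default, the
  scale at which the integration is conventionally trained.
* **Predictor calls**: conditionally independent Bernoulli calls at each
  predictor's (sensitivity, specificity); the default
  `reference_profiles()` are the fourteen published operating points of
  the targeting-signal, phylogenetic and coexpression predictors.
* **Expression**: per dataset, positives load on one latent per-sample
  factor, $x = \sqrt{\rho}\, f + \sqrt{1-\rho}\,\varepsilon$, giving
  expected pairwise correlation $\rho$ among positives (default 0.8) and
  independent noise elsewhere — the simplest structure under which N50 is
  informative. Defaults use 24 datasets of 43 samples, mirroring the
  scale of a multi-experiment expression atlas (~1,000 arrays in ~24
  panels).
* **Network**: a planted-partition graph (within-module edge probability
  0.8, background 0.005 by default) with one dominant function term per
  module, member annotation coherence 0.9, and a 10% unannotated
  fraction.
* **Stress seeds**: drawn preferentially from module members so induced
  subnetworks are function-coherent.

All generators are pure functions of (configuration, seed); a single
master seed drives per-generator substreams so modules can be regenerated
independently.

What the generator does **not** emulate — and therefore what green tests
do not establish about real data: correlated predictors (real
targeting-signal tools share training data and features; an optional
coupling of predictors is deliberately left out of the default
conditions), microarray normalisation artefacts and batch effects,
scale-free degree distributions and hub proteins in real interaction
networks, hierarchical (DAG-structured) function terms, and
multi-compartment targeting of real proteins. On real data the integration
gain over the best single predictor will be smaller than on conditionally
independent calls.

## Problem sizes and numerical choices in the test suite

The suite verifies the N50 metric against a brute-force all-pairs oracle on
200-gene instances (100 random trials), ROC AUC against pair enumeration up
to $n = 500$, likelihood-ratio recovery within 5% relative error at $10^5$
proteins per class, integration dominance over the best single predictor in
at least 95% of 50 seeds at gold-standard scale, FunScore top-1 recovery of
deliberately hidden module annotations at coherence 0.9, permutation
p-value uniformity under a random-annotation null (Kolmogorov–Smirnov
statistic below 0.05 over 500 pairs at 1,000 permutations), and
hypergeometric tail probabilities against direct combinatorial summation up
to $N = 30$. These sizes were chosen as the smallest at which the
asymptotic claims are unambiguous; the full suite runs in well under a
minute.

## Known limitations

* The decision tree is rpart's CART, not a bit-for-bit C4.5: split and
  pruning details differ, so trained trees are comparable in accuracy, not
  structure.
* FunScore treats all edges as equally reliable; no confidence weighting.
* The permutation null fixes $r_{\text{int}}$ and $\pi$ at observed
  values; a fully recomputed null would be slightly more conservative for
  proteins whose neighbourhoods dominate those statistics.
* Function terms are independent tags here; no propagation along an
  ontology graph.
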