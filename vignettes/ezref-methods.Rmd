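---
title: "Methods: reference distributions, equivalent z-scores and network clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference distributions, equivalent z-scores and network clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezref)
```

## The model

`ezref` treats the annotation count $y_{gm}$ of enzyme $g$ in metagenome $m$
as approximately Poisson/multinomial — thousands of enzymes, each a small
fraction of the annotations — but with its rate parameter itself varying
across metagenomes processed under comparable conditions. The observable is
the per-million rate

$$\lambda_{gm} = \frac{y_{gm}}{N_m}\,10^6,$$

where $N_m$ is the metagenome's total enzyme annotations. Across a
collection of reference metagenomes the $\lambda_{gm}$ of one enzyme form an
empirical distribution, modelled by a two-parameter density
$f(x;\theta_g)$ from one of four families: normal, lognormal, gamma or
Weibull. Only enzymes with a strictly positive rate in *every* reference
enter the model; this both defines "the reference behaviour of $g$" and
guarantees positive data for the positive-support families.

A query metagenome $k$ is scored per enzyme by its lower-tail probability
$P_{gk} = F(\lambda_{gk};\theta_g)$ and the *equivalent z-score*
$Z_{gk} = \Phi^{-1}(P_{gk})$. The EZS puts every enzyme, whatever its
family, on the same standard normal scale: $Z \ge 2$ means the query rate
exceeds 97.72% of the reference (overrepresented), $Z < -1$ depletion,
anything between is shared behaviour.

### The total $N_m$

$N_m$ is taken as the sum of counts over *retained* enzymes after EC
filtering (incomplete descriptors such as `1.1.-.-` removed unless
whitelisted), so the per-million rates of a table sum exactly to $10^6$.
The alternative reading — totals over raw annotations — is available by
simply not filtering before `compute_rates()`. The upstream annotator's
acceptance thresholds (45% identity, e-value $\le 10^{-4}$) are provenance
metadata on `annotation_filter()`; this package never sees sequences.

## Distribution selection

Fitting is maximum likelihood throughout:

* **normal / lognormal** — closed forms, with the ML variance denominator
  $n$ (not $n-1$); the lognormal likelihood is evaluated on the original
  scale (it includes the $-\sum\log x$ Jacobian), so AICs are comparable
  across families.
* **gamma** — Newton iteration on the profile score
  $\log k - \psi(k) = \log\bar x - \overline{\log x}$, initialized at the
  method-of-moments shape, converged to $|\Delta k| < 10^{-10}$;
  rate $= k/\bar x$.
* **Weibull** — Newton iteration on the profile score
  $\sum x^k \log x / \sum x^k - 1/k - \overline{\log x} = 0$, initialized
  at $k = 1$, same tolerance; scale $= (\sum x^k/n)^{1/k}$.

Both iterative fitters are deterministic (no random restarts) and validated
in the test suite against a brute-force grid maximization of the
log-likelihood and against an independent ML implementation.

The selection rule reflects that the data are frequencies: when
$\bar x > 3s$ (the $n-1$ sample sd, so the condition does not depend on the
fitting convention) the rates are far enough from zero to look symmetric,
and **only** the normal fit is used. Otherwise gamma, lognormal and Weibull
compete; each candidate is screened with the Anderson–Darling statistic

$$A^2 = -n - \frac1n\sum_{i=1}^n (2i-1)\left[\ln F(x_{(i)}) +
\ln(1-F(x_{(n+1-i)}))\right]$$

with parameters treated as fixed at their estimates, and the minimum-AIC
candidate wins. With two free parameters in every family, minimum AIC is
exactly maximum log-likelihood; the AIC is kept because it is the
conventional report. Two deliberate choices:

* **The AD screen never vetoes.** With ~19 reference points the test has
  little power, and rejecting all candidates would leave an enzyme
  unmodelled; a winning fit with AD $p < 0.05$ is returned flagged in its
  diagnostics instead. The $p$-value uses the asymptotic null distribution
  of $A^2$ for a fully specified $F$ (Marsaglia & Marsaglia's polynomial
  approximation, accurate to about 4 decimals). Because the parameters are
  in fact estimated, the screen is conservative — another reason it only
  flags.
* **The normal path bypasses competition.** A
  `selection = "always-compete"` option instead fits all four families and
  takes the global AIC minimum; the default is the literal normal-first
  rule, which is also what the packaged worked example reproduces.

At reference sizes around $n = 19$–30 the three long-tailed families are
hard to tell apart; the suite checks family recovery at $n = 2000$ (where
it is reliable) and checks at reference size only the end-to-end properties
that matter: planted outliers are detected and false-positive calls stay
rare, whichever long-tailed family wins.

## Scoring choices

* Tail probabilities above 0.5 are computed through the distribution's
  upper tail to preserve precision near 1.
* $P = 0$ or $1$ (e.g. a positive-support enzyme absent from the query)
  maps to EZS $\mp 8$, kept finite for sorting; the `clamped` column
  records it.
* Category boundaries: overrepresented at $Z \ge 2$, underrepresented at
  $Z < -1$, shared on $[-1, 2)$. The lower boundary is half-open so that an
  enzyme at exactly $-1$ survives the network filter, which removes scores
  *strictly below* $-1$. Both thresholds are arguments everywhere they
  appear.
* Query enzymes absent from the reference are reported with category
  `unscored`, never dropped; reference enzymes absent from the query are
  scored at rate 0.
* Class summaries use the linear-interpolation quantile convention
  (`quantile(..., type = 7)`); enzymes mapping to several classes count
  once per class, unmapped ones pool under `unclassified`.

## Network reconstruction and clustering

KGML pathway files are parsed into bipartite compound–enzyme graphs: edges
come only from `<reaction>` substrate/product links (relation elements are
ignored — the object of interest is the compound–reaction–enzyme network),
multi-EC entries expand to one node per EC, and `map` entries are skipped.
Pathways are merged by node label, so an EC present in several pathways is
a single node whose membership records all of them. Reversibility does not
duplicate edges; the graph is undirected for clustering. Excluding a
pathway group (e.g. glycan metabolism) is a data-selection step — a list of
pathway ids in `run_config()` — not code logic.

After scoring, enzymes with EZS $< -1$ (and, by default, unscored ones) are
removed together with any compound left isolated.

MCL is implemented from scratch on the dense column-stochastic matrix:
self-loops of weight 1, column normalization, then expansion
($M \leftarrow M^2$) alternating with inflation (entrywise power $r$, then
renormalization), pruning entries below $10^{-5}$ after each inflation,
until the largest entrywise change is below $10^{-8}$ (cap 200 iterations;
non-convergence returns the last iterate with a warning). Clusters are read
off as attractor basins — attractors are nodes with positive self-flow —
and a node attracted by several attractors joins the one with the smallest
node index, then attractor systems are collapsed by following assignments
to a fixed point. The result is a deterministic partition; clusters never
span graph components. Inflation defaults to 1.5; clusters are then
filtered to those with at least 4 enzyme nodes (compounds do not count),
and the cluster × pathway matrix counts, per cluster, its enzymes belonging
to each pathway. The dense matrix is the right trade-off for
EZS-filtered pathway networks (hundreds to a few thousand nodes); very
large graphs would want a sparse implementation.

## Synthetic data: what it emulates, what it does not

`simulate_reference()` draws each enzyme's rate from its true family,
truncates at 1 per million (so every planted enzyme survives
shared-enzyme selection), converts to counts at a configurable total
(default $10^6$, so rates ≈ counts and recovery tolerances stay tight), and
assigns the remaining annotations to a filler enzyme (`9.9.9.9`) — which
therefore behaves as one extra shared enzyme. `simulate_query()` plants
selected enzymes exactly at a target quantile of the *fitted* reference and
draws the rest from the fitted model. `generate_kgml()` emits chain-shaped
pathways sharing a configurable fraction of enzymes, with its own node /
edge / membership bookkeeping as test oracle. All generators are pure
functions of their seed.

What the generators do **not** emulate: correlation between enzymes
(taxonomic structure makes real rates strongly dependent),
annotation-pipeline biases, zero inflation of rare enzymes, multi-EC genes,
or realistic pathway topology (cycles, hubs, currency metabolites). Passing
tests therefore demonstrate the statistical machinery — fitting, scoring,
calibration, clustering — under the stated model, not robustness to those
real-data features.

Problem sizes used by the suite: 19–30 reference metagenomes, panels of up
to 50 enzymes, $n = 2000$–5000 draws for parameter/family recovery, 1000
replicates for EZS calibration, and networks of a few dozen nodes for
clustering — enough for sharp statistical checks while the whole suite runs
in seconds.

## Known limitations

* Two-parameter families only; no zero-inflated or covariate-adjusted
  references. Enzymes absent from any reference metagenome are excluded by
  construction rather than modelled.
* No multiple-testing correction across enzymes: the EZS is a per-enzyme
  descriptive score, and with ~1000 enzymes a few dozen will exceed |2| by
  chance; interpretation should lean on pathway-level aggregation.
* The AD $p$-value treats parameters as known; with estimated parameters it
  is conservative.
* Published per-sample EZS values for real query metagenomes cannot be
  recomputed from the packaged fixture, which contains reference rates
  only; the fixture's printed query EZS values are documentation.
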