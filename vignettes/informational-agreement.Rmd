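---
title: "Measuring inter-rater agreement as information flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inter-rater agreement as information flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infagree)
```

## The problem

Two raters — two radiologists, two devices, a classifier compared with
itself at another time — score the same $N$ subjects on a common ordered
scale with $q$ levels. The evidence is a $q \times q$ contingency table of
counts $n(x, y)$: entry $(x, y)$ counts the subjects scored $x$ by one rater
and $y$ by the other. How much do the raters agree?

The standard answer is Cohen's kappa,
$$\kappa = \frac{p_o - p_e}{1 - p_e},$$
where $p_o = \sum_i n(i,i)/N$ is the observed proportion of matches and
$p_e = \sum_i (n_{i\cdot}/N)(n_{\cdot i}/N)$ the proportion expected if the
raters were independent with their observed marginals. Kappa has two
well-known structural problems. It uses only the diagonals of the observed
and expected matrices, discarding the structure of the disagreements; and
its value is strongly coupled to the marginal distributions, hence to the
prevalence of the condition being rated. With highly *symmetrically
unbalanced* marginals (almost all subjects in one category for both raters)
kappa can be small despite near-total raw agreement, while *asymmetrically
unbalanced* marginals can inflate it — the classical agreement paradoxes.

## The informational agreement index

This package implements an alternative rooted in information theory. Treat
the pair of raters as the two terminals of a virtual *agreement channel*:
one rater's score $X$ is the channel input, the other's score $Y$ the
output, and agreement is the information that flows through. With the
plug-in joint distribution $p(x,y) = n(x,y)/N$, marginal entropies
$$H(X) = -\sum_x p_X(x)\log_q p_X(x),$$
and mutual information
$$MI(X,Y) = \sum_{x,y} p(x,y)\,\log_q\!\frac{p(x,y)}{p_X(x)\,p_Y(y)},$$
the *informational agreement* is
$$IA(X,Y) = \frac{MI(X,Y)}{\min\{H(X), H(Y)\}} \in [0,1].$$

$MI$ is bounded by either marginal entropy, so the normalisation puts IA on
a fixed $[0,1]$ scale: 0 exactly when the raters are independent, 1 when
either score determines the other. Unlike kappa, IA weighs every cell of
the joint distribution — disagreements included — and is invariant to the
logarithm base and to swapping the raters.

```{r}
s5 <- contingency_table(matrix(c(40, 3, 5, 2), 2))
agreement_report(s5)
```

This table is the classical paradox case: 84% raw agreement but
$\kappa = 0.245$ ("fair"). IA is even lower (0.073) — and deliberately so:
almost all the diagonal mass sits in a single cell, so one rater's score
carries almost no information about the other's. The bundled
`agreement_fixtures()` collection contains six such published scenarios,
each self-validated on load against its published kappa.

## The channel view and prevalence

Conditioning on the input factorises the joint as
$p(x,y) = p_X(x)\,\Gamma(y \mid x)$ with $\Gamma$ the column-stochastic
*channel transition matrix*. MI (hence IA) is fully determined by
$(P_X, \Gamma)$:
$$MI = \sum_{x,y} p_X(x)\,\Gamma(y|x)\,
  \log_q\frac{\Gamma(y|x)}{\sum_z p_X(z)\,\Gamma(y|z)}.$$
$\Gamma$ is the prevalence-free "nucleus" of the raters' relation; the
prevalence of the condition enters only through $P_X$. `transition_matrix()`
estimates $\Gamma$ from a table, `mi_from_channel()` / `ia_from_channel()`
evaluate the indices from $(P_X, \Gamma)$ directly (useful for prevalence
sweeps at a fixed channel), and for the dichotomous case
`sensitivity_specificity()` reads $\Gamma(1|1)$ and $\Gamma(2|2)$.

**Orientation.** The conditioning variable $X$ is the *column* rater,
matching the usual printed layout of agreement tables (one rater across the
top). Both kappa and IA are transpose-invariant, so this choice only
affects $\Gamma$-derived outputs; `transition_matrix(..., transpose = TRUE)`
conditions on the row rater instead.

## Parameters and conventions

* **Logarithm base.** Entropies and MI default to base $q$, so both are
  normalised to $[0,1]$ for any scale length; `base = 2` gives bits. IA is
  a ratio of same-base quantities and therefore base-invariant.
* **Zero cells.** Empty cells are handled by the continuity convention
  $0\log 0 = 0$. This equals the right limit obtained by replacing each
  zero count with a pseudo-count $\epsilon \to 0^+$; `ia_epsilon_probe()`
  evaluates that construction at a concrete $\epsilon$ so the equivalence
  can be verified numerically (the suite checks agreement within $10^{-6}$
  at $\epsilon = 10^{-9}$ on every zero-bearing bundled table). The probe
  is a validation device, not the recommended estimator.
* **Degenerate raters.** If a rater uses a single category, its marginal
  entropy is 0 and IA is the indeterminate form $0/0$; likewise $p_e = 1$
  makes kappa indeterminate. Both cases are reported as `NA` with an
  explicit warning and carried in `agreement_report()` as validity flags —
  never silently coerced to 0 or 1, since the data contain no evidence
  either way. Each index is still computed when only the other is
  undefined.
* **Counts.** Inputs are nonnegative integer counts; fractional weights
  are rejected because every probability in the method is a plug-in
  relative frequency.
* **Tolerances.** Probability vectors must normalise within $10^{-12}$;
  identity checks (chain rule, channel decomposition) are asserted within
  $10^{-10}$. MI sums its terms in a canonical sorted order, which makes
  transpose symmetry bit-exact rather than merely approximate.
* **Rounding.** Published tables round half away from zero;
  `round_half_up()` reproduces that convention (R's `round()` rounds half
  to even) and is used for all comparisons against printed values.
* **Kappa bands.** The conventional verbal scale is implemented as a
  partition — half-open bands $[0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8)$
  with $[0.8,1]$ closed — resolving the overlapping band edges sometimes
  printed in the literature. Negative kappa (below-chance agreement) is
  annotated rather than given its own band. No verbal scale is offered for
  IA: its information-theoretic compression of high agreements means the
  kappa cut-points do not transfer.

## Dichotomising an ordered scale

Ordered scales are often collapsed to two classes for clinical action —
e.g. BI-RADS 1–2 ("not significant") versus 3–4–5 ("significant").
`collapse_table(table, t)` merges categories $1..t$ and $t{+}1..q$,
preserving $N$; `threshold_scan()` evaluates kappa and IA at every
threshold and reports each index's argmax (ties broken toward the smaller
threshold, the more conservative split — a documented choice where no
convention exists; thresholds where an index is undefined are flagged and
excluded from the argmax).

```{r}
t2 <- agreement_fixtures()$ABVS_US_5x5   # 186 breast MRI findings, BI-RADS
threshold_scan(t2)
```

Both indices select the standard 1–2/3–4–5 split, reproducing the
published analysis of this ultrasound/ABVS comparison.

## Comparing classifiers

A trained classifier scored entry-by-entry as correct/wrong is a binary
rater, so agreement between two classifiers on the same data set is again a
2×2 table (`correctness_table()`). `agreement_comparison()` evaluates kappa
and IA over all model pairs and correlates the two index sequences with
Pearson's $\rho$ and Spearman's $r_s$ (average ranks on ties — the
`stats::cor` convention; on tie-free data it coincides with the classical
$1 - 6\sum d^2 / (n(n^2-1))$ formula). A high $\rho$ with lower $r_s$ means
the indices agree numerically but order the model pairs differently.
Training the classifiers themselves is out of scope: the package consumes
correctness vectors or ready-made agreement matrices.

## The simulator, and what the tests do and do not show

`simulate_ratings(p_x, gamma, n, seed)` draws $n$ subjects through a
specified channel: $x \sim P_X$, then $y$ from column $x$ of $\Gamma$. It
emulates exactly the generative model underlying the channel view —
independent subjects, a fixed transition matrix, multinomial sampling — and
is used for parameter-recovery tests: the estimated $\Gamma$ returns to the
truth at the usual $O(1/\sqrt n)$ rate (the suite checks a 0.02 max-abs
error at $n = 50{,}000$ across 200 seeds, a bound chosen from the binomial
standard error). Real rating data can violate the model in ways the
simulator does not emulate — correlated subjects, rater drift over time,
scale use that depends on unmodelled covariates — so passing recovery
tests certifies the estimator under the stated model, not robustness to
those violations. Sampling uses R's default Mersenne–Twister generator
under an explicit seed, and the caller's RNG state is restored afterwards.

Property-style tests run on randomly generated tables and joints (1000
cases under a fixed seed per property): the chain-rule identity
$MI = H(Y) - H(Y\!/\!X)$, the $MI \le \min\{H(X),H(Y)\}$ bound, the
equality of the channel decomposition with the direct joint computation,
range and symmetry of both indices, and the independence null
$\kappa = IA = 0$ on outer-product tables. These sizes keep the full suite
under a minute on one CPU while exercising dimensions $q = 2..5$.

## Known limitations

* Plug-in (maximum-likelihood) frequencies are used throughout; no
  small-sample bias correction for MI (Miller–Madow and relatives) is
  applied, so IA on very small $N$ inherits the upward bias of plug-in MI.
* No confidence intervals or significance tests are provided for IA.
* Only single-threshold dichotomisation is supported; multi-cut coarsening
  of an ordered scale is out of scope.
* The indices are defined for two raters; multi-rater generalisations
  (Fleiss-type) are not covered.
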