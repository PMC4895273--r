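---
title: "Methods: boosted-tree prediction of relative solvent accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boosted-tree prediction of relative solvent accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsaboost)
```

## The problem

The relative solvent accessibility (RSA) of a residue is its solvent
accessible surface area (ASA, from structure, here read from DSSP's ACC
field) divided by the maximum accessibility of that residue type in an
extended Gly-X-Gly tripeptide — a value in $[0,1]$ describing how buried or
exposed the residue is. Predicting RSA from sequence alone is a standard
intermediate step toward tertiary-structure prediction, fold recognition
and binding-site analysis. `rsaboost` treats this as real-valued regression:
each residue is described by a feature vector $x$ assembled from
sequence-derived tracks, and a gradient boosted regression trees (GBRT)
model learns $y = F_M(x)$.

## The boosting model

GBRT builds an additive model
$$F_M(x) = F_0 + \nu \sum_{m=1}^{M} u_{m,\mathrm{leaf}_m(x)},$$
starting from the constant $F_0$ minimising the total loss (mean for
squared error, median for the Huber loss). Stage $m$:

1. sets the Huber transition point $\delta_m$ to the $\alpha$-quantile
   (default $\alpha = 0.9$) of the absolute current residuals
   $|y_i - F_{m-1}(x_i)|$, floored at $10^{-12}$;
2. computes pseudo-residuals — the negative loss gradient: the raw
   residual within $\pm\delta_m$, clipped to $\pm\delta_m$ beyond;
3. fits a least-squares CART regression tree to the pseudo-residuals
   (exhaustive scan over features and midpoints between consecutive
   distinct values; leaf value = mean);
4. replaces each leaf's value by the line-search update $u_{m,l}$ on the
   *true* residuals (below) and advances $F$ with shrinkage
   $\nu \in (0,1]$ (default 0.1).

The default loss is Huber's robust loss
$$\Psi_\delta(e) = \tfrac12 e^2 \;(|e|\le\delta), \qquad
  \delta(|e| - \delta/2) \;(|e|>\delta),$$
which limits the influence of residues whose experimental RSA is atypical
(crystal contacts, chain termini, quaternary context); squared error is
available mainly because every step then has a closed form, which makes
the learner testable against an independent naive reference loop.

### Exact per-leaf line search

Generic gradient boosting writes the stage update as a global step length
times the tree's leaf means. A single global multiplier is dominated by
choosing the best constant *per leaf region*, so the two are collapsed
into one per-leaf line search. For squared error the optimum is the mean
leaf residual. For the Huber loss the leaf objective
$\sum_i \Psi_\delta(r_i - u)$ is convex and its minimiser solves the
monotone piecewise-linear equation
$\sum_i \operatorname{clip}(r_i - u, \pm\delta) = 0$; the package solves
it exactly (leftmost root, by linear interpolation between the sorted
knots $r_i \pm \delta$) rather than using the common
median-plus-clipped-mean approximation. Exactness buys two properties the
test suite relies on: per-leaf updates agree with brute-force grid
minimisation to well under $10^{-3}$, and (by convexity, for any
$\nu \le 1$) the training loss evaluated at that stage's $\delta_m$ can
never increase across a stage.

### Determinism and numerical conventions

* Quantiles use R's type-7 linear interpolation everywhere
  (`huber_delta` and its test oracle share the convention).
* Split ties are broken toward the lowest feature index, then the lowest
  threshold; there is no subsampling, so fitting is bit-reproducible
  given data and configuration. Seeds only enter fixture generation and
  fold shuffling.
* Tree size is capped by depth (default 4) with a minimum of 5 samples
  per leaf; the tree of a constant target collapses to a single leaf.
* Predictions are clipped to $[0,1]$ by default, since RSA is a
  normalised value in that range; raw additive output is available via
  `clip = FALSE`.
* Models serialise to versioned JSON with 17 significant digits, which
  round-trips IEEE doubles exactly; reloaded models predict
  bit-identically.

## Feature encoding

Each residue's vector concatenates, for window length $L = 2l + 1$:

| family | per-residue channels | columns | neutral pad |
|--------|---------------------|---------|-------------|
| PSSM   | 20 log-odds scores, logistic-normalised $x' = 1/(1+e^{-x})$ | $20L$ | 0.5 |
| SS     | PSIPRED coil/helix/strand probabilities | $3L$ | 1/3 |
| DISO   | DISOPRED disordered/ordered probabilities | $2L$ | 0.5 |
| SCE    | six side-chain-environment propensities | $6$ | — |
| CS     | conservation score | $L$ | 0.5 |

giving $26L + 6$ columns with everything enabled (188 at the default
$L = 7$). Window slots that fall beyond a terminus receive the family's
neutral pad. All encoded values lie in $[0,1]$.

**Conservation score.** The package uses the PSSM information-per-position
column, min-max scaled to $[0,1]$ with bounds estimated on the training
residues and stored in the model (test-time values are clipped; a
degenerate zero-range training set maps to 0.5). It is windowed over $L$
positions like the other local tracks, for consistency; a scalar variant
would be a trivial restriction.

**Side-chain environment (SCE).** The six classes split burial
(RSA $< 0.09$ buried, $0.09 \le$ RSA $< 0.36$ partially buried,
RSA $\ge 0.36$ exposed) by the polar fraction $F$ of side-chain area
covered by polar atoms ($B_1/B_2/B_3$ at $F < 0.45 / < 0.58 / \ge 0.58$;
$P_1/P_2$ at $F < 0.67 / \ge 0.67$). The definition needs structure, which
is unavailable at prediction time, so the feature enters the model as a
*propensity lookup*: on the labelled training proteins the relative
frequency of the six classes is tabulated per amino-acid type (add-one
smoothing, rows sum to 1), and at encoding time every residue receives its
type's 6-vector. This keeps prediction strictly sequence-side; it is an
interpretation, and the alternative (one-hot of the true environment)
would leak structure into training features. Unknown residue letters
(e.g. `X`) receive the uniform $1/6$ vector. The polar fraction itself is
supplied as a sidecar TSV (`id`, `index`, `F`) for real data and is
generated directly by the fixture module.

**Labels.** RSA labels come from DSSP ACC values divided by the residue
type's maximum accessibility and clamped to $[0,1]$ (real structures
occasionally exceed the tripeptide maximum). Published Gly-X-Gly maxima
differ between references, and a larger maximum systematically lowers RSA
and hence apparent error, so the table identity ("miller1987" by default)
is recorded in every bundle and is user-overridable.

## Protocol

Cross-validation splits **by protein**, never by residue: adjacent
residues share most of their windows, so residue-level splits would leak
held-out information into training. Within each training fold the SCE
propensity table and the conservation bounds are re-estimated from the
fold's training proteins only. Grid search scans window lengths
$L \in \{3, 5, \ldots, 17\}$ and stage counts
$M \in \{100, 150, \ldots, 1500\}$ (configurable; desk-scale subgrids are
supported), training once per $(\mathrm{fold}, L)$ at the largest $M$ and
reading smaller $M$ off the staged predictions. Selection minimises pooled
CV MAE (PCC selection available), with ties broken toward smaller $M$,
then smaller $L$ — the cheaper model.

## The synthetic generator

Real inputs require PSI-BLAST/PSIPRED/DISOPRED runs against large
databases plus solved structures, none of which suit a test suite. The
generator plants a controlled relationship instead: each residue carries a
latent code $u_i \sim U(0,1)$; the planted RSA is a centred moving average
of $u$ over `window_span` residues (default 7), amplified about 0.5,
clamped to $[0,1]$ and perturbed with Gaussian noise (`noise_sd`, default
0.05). Feature tracks encode the *local* $u_i$ only — five PSSM columns
carry a quantised linear image of $u_i$, helix/strand probabilities fall
and disorder probability rises with $u_i$, and the information column
falls with $u_i$ (conserved residues tend to be buried) — so recovering
RSA genuinely requires integrating a window at least as wide as the
smoothing span; this is what makes window-length selection testable. The
polar fraction is drawn anti-correlated with Kyte–Doolittle
hydrophobicity. DSSP-style files are written in a "DSSP-minimal dialect"
populating exactly the columns the parser reads, with
ACC $= \mathrm{round}(\mathrm{RSA} \cdot \mathrm{maxASA})$, so labels
round-trip within the half-Ångström quantisation bound. All randomness
flows from a single seed and the caller's RNG state is restored, making
output byte-identical across runs.

What the generator does **not** emulate: realistic PSI-BLAST score
statistics, secondary-structure segment grammar, inter-protein homology,
or structural noise in DSSP. Passing tests therefore demonstrate that the
algorithmic machinery is correct and that planted signal of realistic
strength is recovered — not that any particular accuracy will be attained
on real proteins.

Default study conditions used by the heavier checks: about 2000 residues
(20 proteins of length 80–120), noise 0.05, $M = 300$, $\nu = 0.1$,
depth 4, with held-out proteins for evaluation; unit tests use smaller
fixtures (typically 6–10 proteins of length 30–60 and a few dozen
stages).

## Known limitations

* The Huber initial value uses the median rather than the (undefined
  before the first iteration) exact Huber minimiser.
* SCE as a type-level propensity discards residue-specific environment
  information; it is the price of sequence-only prediction.
* The conservation score is a pragmatic reading of "information per
  position"; other conservation measures exist.
* No stochastic subsampling or out-of-bag estimation; training on very
  large residue sets is $O(M \cdot \mathrm{nodes} \cdot p \cdot n \log n)$.
* Two-state calls use a strict `rsa < threshold` burial rule; residues
  exactly at the threshold are exposed.
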