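---
title: "Methods: bimodal switches, coupling networks and causal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bimodal switches, coupling networks and causal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the statistical model behind every stage of the
pipeline, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the method description left the design
open. It states no empirical result that the test suite does not itself
compute.

## 1. Mixture model and the bimodality call

Each analyte (an RPPA antibody measurement, a phosphosite, or a
transcript) is modelled marginally across cell lines as a two-component
Gaussian mixture with unequal component variances,

$$x \sim \pi\,\mathcal N(\mu_\mathrm{high},\sigma_\mathrm{high}^2)
  + (1-\pi)\,\mathcal N(\mu_\mathrm{low},\sigma_\mathrm{low}^2),$$

fitted by EM (`fit_gmm2()`). The one-component competitor has the closed
form (sample mean, ML variance). Both models are compared through
$\mathrm{BIC} = k\ln n - 2\ell$ with $k = 2$ and $k = 5$ free parameters
respectively, and an analyte is called bimodal iff
$\Delta\mathrm{BIC} = \mathrm{BIC}_1 - \mathrm{BIC}_2 > 2$ — a strict
inequality, so $\Delta\mathrm{BIC} = 2$ is unimodal. The direction of the
difference is chosen so that positive values favour bimodality; whether
the original analysis thresholded a signed or absolute difference is not
stated anywhere, so the signed convention is a recorded design decision
here, not an inference.

Numerical choices:

* **Initialisation and restarts.** EM is restarted `n_restarts = 10`
  times: once from a 2-means partition of the values, then from random
  binary partitions. The best final log-likelihood wins. Restarts are
  seeded per analyte (seed + row index), so results do not depend on the
  order in which analytes are fitted.
* **Variance floor.** Component variances are floored at $10^{-3}$ times
  the sample variance. The unpenalised Gaussian-mixture likelihood is
  unbounded (a component can collapse onto one point); the floor keeps
  the maximisation well-posed without affecting non-degenerate fits.
* **Convergence.** EM stops when the log-likelihood improves by less
  than $10^{-8}$ (absolute) or after 1000 iterations; non-converged fits
  are returned with `converged = FALSE` rather than discarded. The hot
  loop is implemented in C++ and verified in the test suite against a
  plain-R reference implementation of the same update equations.
* **Degenerate input.** Constant vectors and analytes with fewer than 10
  finite values are rejected ("degenerate analyte"); `fit_layer()`
  additionally skips analytes below the coverage threshold
  (`min_cells = 40` by default, matching the RPPA coverage filter).

Components are always relabeled so $\mu_\mathrm{low}\le\mu_\mathrm{high}$,
and the per-cell posterior probability of the *high* component is
computed by Bayes' rule. Two invariants are enforced by tests: the mean
posterior equals $\pi$ on converged fits (EM stationarity), and negating
the data mirrors the fit and maps posteriors $p \mapsto 1-p$.

## 2. Tissue diversity and switch classes

Cells are assigned to the low component when $p < 0.5$ and to the high
component when $p \ge 0.5$. Within each group the Shannon entropy
$H = -\sum_t q_t \ln q_t$ of the tissue frequencies is computed in
natural log; the base only rescales all entropies and the tertile
boundaries are rank-based, so the choice is immaterial — nats are used
for definiteness. A group left empty scores 0 with a warning: a switch
populated from a single tissue side is minimally diverse either way.

Bimodal analytes are stratified into tertiles of
$\min(H_\mathrm{low}, H_\mathrm{high})$; the lower tertile is the
tissue-confounded stratum excluded from network analyses. Tertile
breakpoints are computed **over the bimodal analytes only** (whether the
original computed them over all analytes is unstated; bimodal-only is the
recorded decision, since non-bimodal analytes have no meaningful
component split). A switch is **common** when the minor mixing weight
$\min(\pi, 1-\pi)$ exceeds $1/4$ and **rare** otherwise; the boundary
value exactly $1/4$ is rare (strict), so "common" means both states are
genuinely well-populated.

## 3. Coupling networks and communities

The bimodal coupling coefficient $r_b$ between two analytes is the
Spearman correlation (average ranks for ties) of their posterior vectors
over pairwise-complete cells, with a p-value from the large-sample
$t$ approximation. Pairs with fewer than `min_overlap = 30` shared cells
are not tested — and not counted in the multiple-testing family — because
rank correlations on tiny overlaps are unstable (the method description
is silent; 30 is the recorded choice).

The network keeps edges with $|r_b| > 0.3$ (strict) **and** adjusted
$p < 0.05$. The stated control ("FDR < 5%, Bonferroni") is internally
contradictory; Bonferroni family-wise control is implemented because it
is the named procedure, with Benjamini–Hochberg available via
`correction = "BH"`. Isolated nodes are retained. Communities are found
by Newman's leading-eigenvector method on the *unsigned, unweighted*
adjacency: the graph is already thresholded on $|r_b|$, and signs are
used for display, not membership. The eigen solver is run under a fixed
internal seed so memberships are deterministic.

## 4. Anchor signatures and discordant cells

`derive_signature()` couples one bimodal anchor analyte (E-cadherin
protein in the motivating analysis, but any bimodal analyte works — the
same machinery supports Claudin-7 or Rab25 anchors) against all
transcripts and keeps $|r_b| > 0.5$ (strict), split into positive and
negative arms by the sign of $r_b$. The absolute-value reading is used
because the negative arm exists in the motivating analysis' own output.

`call_discordant()` reads "high-confidence assignment ($p<0.1$)" as
symmetric posterior tails: state high iff $p \ge 1-\mathrm{conf}$, low
iff $p \le \mathrm{conf}$, default $\mathrm{conf} = 0.1$, else uncertain.
The posterior is a single number per cell, so symmetric tails are the
only consistent reading. The discordant set of interest is mRNA-high /
protein-low ($+-$).

`export_updown()` writes query-ready gene lists: in `induce` mode the
up-list is the negative arm and the down-list the positive arm (a
perturbation pushing cells out of the anchor-high state); `reverse`
swaps them. Symbols are deduplicated and uppercased. Only the list
export is in scope; querying enrichment or perturbation services is not.

## 5. Landscape analyses

* **Distances.** Plain Euclidean distance over pairwise-complete
  features, *not* rescaled by the number of shared features (that is
  what the method names); because unequal feature counts bias distances,
  `rescale = TRUE` is offered as an option. Features are not z-scored by
  default (unstated in the source; `embed_cells()` scales for PCA only).
* **Combination.** Each distance matrix is divided by the sum of its
  non-missing entries before adding, so each data type contributes
  equally regardless of scale.
* **k-NN.** Leave-one-out 3-nearest-neighbour tissue classification;
  vote ties are broken by the class of the nearest neighbour among the
  tied classes (deterministic and distance-consistent; the source is
  silent on ties).
* **Gap statistic.** Average-linkage tree cuts for $k = 1..k_\max$;
  $W_k$ is the within-cluster sum of pairwise squared distances
  normalised per cluster size; the reference distribution is uniform
  over the observed range of each feature (Tibshirani's simpler
  reference, $B = 50$, seeded); chosen $k$ is the smallest with
  $\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$.
* **Distance regression.** OLS of the vectorised upper triangle of the
  target distances on the predictor distances; residuals quantify
  layer-specific deviations, tissues are ranked by the mean residual of
  their within-tissue pairs.
* **Embeddings.** Thin wrappers: PCA on centred, unit-variance features
  and Barnes-Hut t-SNE (perplexity 30, 5000 iterations by default),
  both seeded. Missing values are imputed by iterative rank-5 SVD
  (tolerance $10^{-6}$), mirroring svdImpute-style imputation.

## 6. Causal structure search

The score is the penalised Gaussian log-likelihood
$S(v \mid P) = -\frac n2 \ln(\mathrm{RSS}_v/n) - c\,(|P|+1)\frac{\ln n}2$
with penalty discount $c = 4$ by default; larger $c$ gives sparser
graphs. The search is a two-phase greedy walk in DAG space — forward
single-edge additions under acyclicity until no improvement, then
backward deletions — with the result reported as its CPDAG (compelled
edges directed, reversible edges undirected, via Chickering's
order-and-label algorithm). This is deliberately *not* a line-for-line
port of the fast greedy equivalence search implementation the motivating
analysis ran; the named parameters map directly onto this score and
search. `depth = 3` is interpreted as the cap on the parent-set size
explored when re-scoring a node; the cited implementation's exact
semantics cannot be confirmed from the description, so this
interpretation is recorded, not asserted.

One consequence of walking DAG space is that the gains of `x -> y` and
`y -> x` tie (up to float noise) whenever neither endpoint has parents;
committing to the wrong orientation early can strand the search in a
triangle-completing local optimum around colliders, which
equivalence-class search avoids by construction. The search therefore
runs `n_restarts = 5` passes with randomized tie-breaking among
score-equivalent moves (ties quantized at 6 significant digits) and
keeps the best final score; the first pass breaks ties deterministically
and the tie-breaking stream is seeded, so the procedure is reproducible.

Bootstrap robustness resamples cells with replacement ($M = 200$ by
default), reruns the search, and reports per-pair frequencies of the
edge in any orientation and in each orientation separately (a pattern
mixes directed and undirected edges, so "any orientation" is the
primary frequency). Centralities: betweenness on the directed graph with
reversible edges entered as reciprocal arcs (they are traversable in
some member of the class), subgraph centrality as the diagonal of the
matrix exponential of the undirected adjacency, and in/out-degree over
compelled edges only. Ensemble comparison correlates `freq_any` over the
union of detected edges restricted to shared nodes, absent edges
contributing 0 — note that under this definition two ensembles with
disjoint confident edge sets are strongly negatively correlated by
construction, so the meaningful null statement is the absence of
*positive* association.

Missing data: structure learning requires complete rows; the CLI applies
the coverage filter and then mean-imputes residual missingness with a
warning reporting the imputed fraction.

## 7. The synthetic-data generator: what a green test establishes

`simulate_multilayer()` states the world the acceptance tests check:

* One latent Bernoulli($\pi_\mathrm{high}$) module state per cell and
  switch; each member analyte copies it with probability
  $\rho = $ `coupling_rho`, else flips. The expected between-member
  state correlation is $(2\rho-1)^2$, which makes coupling recovery
  quantitatively testable. The motivating analysis observes coupled
  modules but never states a generative model; this is the simplest one
  with a tunable coupling strength.
* Values are $\mathcal N(\mu_\mathrm{low} + s\,\Delta\mu\,\sigma,
  \sigma^2)$ given state $s$; equal component SDs by default, the
  simplest identifiable planted truth. `delta_mu = 0` degenerates to a
  single Gaussian and is recorded as non-bimodal truth.
* `tissue_bias` replaces the global $\pi_\mathrm{high}$ by per-tissue
  probabilities, creating the tissue-confounded switches the entropy
  filter must catch.
* Unimodal background analytes get per-tissue baseline shifts
  $b_t \sim \mathcal N(0, \texttt{tissue\_effect\_sd}^2)$, emulating
  lineage structure for the landscape analyses.
* Missingness is completely at random per layer; the real pipeline
  treats missingness only through coverage filters, so no informative
  missingness mechanism is modelled.

Defaults follow the stated world of the acceptance criteria: cohort
sizes 736 (RPPA panel scale) and 381 (matched-cohort scale),
$\Delta\mu = 4$, $\sigma = 1$, balanced $\pi$, $\rho = 0.95$ for coupled
modules. What the generator does **not** emulate: antibody-specific
noise models, batch effects, normalisation artifacts, informative
missingness, or correlated background structure beyond tissue baselines.
A green acceptance suite therefore establishes that the implementation
recovers planted truth under the stated model — not that the model
captures every property of real RPPA data.

`simulate_sem()` generates linear-Gaussian SEM data in topological order
from an explicit weighted DAG and is the ground truth for the causal
module (chains, colliders, random DAGs with expected degree 2 and
weights $\pm[0.5, 1.5]$).

## 8. Known limitations

* Only two-component Gaussian mixtures; no heavier-tailed or >2-state
  models (multi-stable intermediate EMT states are approximated by the
  module structure, not by multi-component fits).
* The bimodality call inherits BIC's large-$n$ behaviour: at panel sizes
  in the hundreds, weakly separated mixtures ($\Delta\mu \lesssim 2$)
  are usually called unimodal.
* The causal search assumes acyclicity, no latent confounders and
  linear-Gaussian relations; restarts mitigate but do not eliminate
  DAG-space local optima.
* Community detection treats couplings as unsigned; signed community
  methods are out of scope.
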