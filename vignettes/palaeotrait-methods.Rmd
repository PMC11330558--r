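---
title: "Models and methods behind palaeotrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind palaeotrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(palaeotrait)
```

palaeotrait analyses the macroevolution of a continuous trait — maximum body
length on the natural-log scale, in cm — on time-calibrated phylogenies
whose tips are fossils, so the trees are rooted, non-ultrametric, and dated
in Myr. The motivating system is the eurypterids ("sea scorpions"),
Palaeozoic chelicerates spanning adult lengths from under 2 cm to over
2.5 m, which repeatedly evolved giant (≥ 1 m) body sizes and repeatedly
colonized continental fresh water. The package asks the questions such a
clade raises: is size evolution gradual or pulsed, does the trait track
palaeotemperature or dissolved oxygen, do habitat regimes carry their own
adaptive optima, and did a mass extinction restructure the landscape?

## The eleven trait models

All models describe the evolution of $x = \ln(\text{length in cm})$ along
the tree, rooted at a free ancestral value $z_0$.

* **BM** — Brownian motion with rate $\sigma^2$ (per Myr): covariance
  between tips equals $\sigma^2$ times their shared root-to-MRCA path
  length. $k = 2$ parameters.
* **TREND** — BM plus a directional drift $\mu$ per Myr in the mean.
  Identifiable only on non-ultrametric trees; on ultrametric input the fit
  refuses rather than silently confounding $\mu$ with $z_0$. $k = 3$.
* **EB** — early burst: the rate decays (or grows) exponentially with time
  from the root, $\sigma^2(t) = \sigma^2 e^{rt}$; both signs of $r$ are
  allowed, bounded to $[-2, 2]$. $k = 3$.
* **KAPPA** — Pagel's branch-length exponent: every branch length is raised
  to the power $\kappa \in [0, 3]$ before the BM covariance is built.
  $\kappa = 0$ makes change independent of branch duration (punctuational),
  $\kappa = 1$ recovers BM. $k = 3$.
* **OU** — Ornstein–Uhlenbeck with pull $\alpha$ toward an optimum
  $\theta$. The root is a free parameter (non-stationary, fixed-root form),
  because fossil trees give no licence for a stationarity assumption; the
  covariance formula is valid for tips of unequal age. $k = 4$.
* **PULSED** — BM plus compound-Poisson normal jumps: jumps arrive at rate
  $\lambda_J$ per Myr and displace the trait by $N(0, \delta^2)$. $k = 4$.
* **ENV_OU_TEMP / ENV_OU_OXY** — OU whose optimum tracks an environmental
  curve linearly, $\theta(t) = \theta_0 + \beta E(t)$, with $E$ the
  sea-surface temperature (°C) or dissolved-oxygen (µM) series. $k = 5$.
* **OUM3_HABITAT / OUM2_HABITAT / OUM3_CRISIS** — multi-peak OU on a regime
  painting of the tree: habitat regimes (marine / marginal / continental,
  or marginal vs other), or a pre-extinction regime plus one regime for
  each clade surviving the crisis. With $m$ regimes sharing $\alpha$ and
  $\sigma^2$, $k = 3 + m$; freeing per-regime rates and pulls adds 2 per
  extra regime.

Parameter counts are fixed as listed so AICc values are reproducible.

## Likelihood computation

The Gaussian models evaluate an exact multivariate-normal density: the
model's mean vector and covariance matrix are built from the tree (shared
path lengths, tip ages) and the density is computed by Cholesky
factorization. The multi-peak models accumulate means, variances and
discount factors segment by segment along the painting, in log space for
the discounts so deep strong-pull paths do not underflow. The
environment-coupled models integrate the mean ODE
$\dot m = \alpha(\theta(t) - m)$ along every root-to-tip path treating the
curve as piecewise linear at 0.25 Myr resolution — the same granularity at
which the curves are interpolated — using the closed-form update for a
linear optimum over each substep, so linear curves are handled exactly.

### The pulsed likelihood

Conditional on the number of jumps on every branch the pulsed model is
Gaussian, so the message passed rootward from any subtree is a finite
mixture of Gaussians in the ancestral state. The pruning algorithm:

* a branch of length $t$ adds variance $\sigma^2 t + \delta^2 k$ with
  Poisson weight on $k$, truncated at tail mass $< 10^{-10}$; branches
  expecting more than ~32 jumps aggregate adjacent jump counts into 24
  weighted classes (by then the compound distribution is within numerical
  tolerance of its Gaussian limit, so the variance quantization is
  negligible);
* at a node, two mixtures multiply pairwise (each Gaussian product yields a
  Gaussian times a scalar); components below $10^{-12}$ relative weight are
  dropped;
* when a message exceeds the component cap (4096 for reported likelihoods,
  128 during optimization search) it is reduced by moment-preserving
  collapse on a (mean, log-variance) grid. Collapse conserves mixture mass
  exactly, so the likelihood degrades smoothly in accuracy — never in
  probability mass — as the cap tightens; at the default cap the error is
  below $10^{-3}$ log units on 135-tip problems.

On trees small enough for exact summation the algorithm reproduces the
truncated-series value to $10^{-8}$, and on 4-tip trees it agrees with a
$10^6$-draw Monte-Carlo likelihood within Monte-Carlo error (both are
tested). The jump kernel is normal; other Lévy kernels are out of scope.

## Fitting

Linear mean parameters ($z_0$, optima, drift, $\beta$) and the overall rate
$\sigma^2$ are profiled out analytically by generalized least squares, so
the numerical search runs only over shape parameters: $\alpha$ (on the log
scale in $[10^{-8}, 10^2]$), $\kappa \in [0, 3]$, $r \in [-2, 2]$, and for
the pulsed model $(\log\sigma^2, \lambda_J, \log\delta^2)$ with
$\lambda_J \in [0, 10]$ and the root state profiled inside the mixture
kernel by golden-section search. Optimization is bounded multi-start local
search (`nlminb`) seeded from Latin-hypercube draws plus moment-based warm
starts; ten restarts by default, fewer where a caller chooses speed over
belt-and-braces coverage. Fits are deterministic given the option seed.
Non-convergent fits are flagged and excluded from ranking; a model that
fails on more than half the trees is dropped with a warning.

Identifiability varies: $\sigma^2$, $\mu$, $r$, $\kappa$, $\beta$ and the
regime optima are well identified at the 135-tip scale; $\alpha$ is
notoriously weak (its median recovers the truth only within about a factor
of two here), and $\lambda_J$ and $\delta^2$ trade off against each other
so that their product — the jump variance flux per Myr — is the quantity
recovered within tight tolerance. The tests encode exactly these
expectations.

## Model ranking

Within each tree, AICc weights are computed over the converged fits,
$w_i = \exp(-\Delta_i / 2) / \sum_j \exp(-\Delta_j / 2)$ with $\Delta$
relative to the tree's best model; models are ranked by the **median**
weight across the posterior tree set (the mean is reported alongside), ties
breaking toward fewer parameters. Medians are robust to the occasional
pathological tree, which is why they anchor the ranking.

## Habitat evolution

The three-state habitat character (marine, marginal marine, continental)
is analysed with Mk machinery: a pruning likelihood with eigendecomposition
transition probabilities (falling back to a uniformization series for
defective rate matrices, which sparse structures routinely produce), ML
fitting of ER/SYM/ARD structures selected by AICc, and a reversible-jump
MCMC over groupings of the six transition rates into shared-rate classes
including a zero class. The rjMCMC prior is uniform over structures and
exponential on class rates with a data-scale mean (parsimony changes per
total tree length); reassignment moves that create a class draw its rate
from the prior, so the acceptance ratio reduces to the likelihood ratio
times discrete proposal asymmetries — including the move-type probability,
which differs in the all-zero state. The sampler provably targets its prior
when run without data (tested by KL divergence on the two-entry structure
space).

Stochastic character maps are drawn exactly: node states from their joint
conditional distribution (pruning up, sampling preorder), then each branch
history conditional on its endpoints by uniformization, with rejection
sampling kept as an independent test oracle in spirit via exhaustive
enumeration checks on small trees. Summaries give per-node marginal state
frequencies, state-dependent lineage-through-time bands (median and 95%
across maps), transition-count distributions, and colonization counts —
transitions whose destination is a chosen state. Paintings derived from
maps (three-peak, two-peak with marine and continental merged as "other")
and the crisis painting (PRE before the crisis age, two surviving-clade
regimes after, branches split exactly at the boundary; post-crisis lineages
outside both clades stay PRE) feed the multi-peak models.

## Downstream analyses

The root size is reconstructed by GLS under BM, with the 95% CI formed on
the log scale and back-transformed to cm. Origins of large (≥ 0.5 m, i.e.
ln 50) and giant (≥ 1 m) size are counted as edges whose parent
reconstruction lies below the threshold and whose child value reaches it.
This crossing count is *not* monotone in the threshold: an ancestor
reconstructed above a low bar contributes no crossing there, while several
of its descendants can each cross a higher bar independently, so a clade of
large-bodied species containing multiple giants yields more giant origins
than large origins. This is a real feature of the independent-origins
notion, not a numerical artefact — under the pulsed scenario the giant
count indeed exceeds the large count — and the test suite documents it
with a deliberately failing monotonicity assertion next to the exact-count
checks that pass.

PGLS of log size on palaeolatitude uses the Pagel-λ correlation structure
with λ = 1 by default (plain BM) or ML-estimated in [0, 1]; on a star tree
it reduces to OLS. The ecospace analysis standardizes the four count
variables (potential predators, potential prey, co-occurring eurypterids,
assemblage richness), and compares the two size groups split at 0.5 m with
a PERMANOVA pseudo-F (Anderson's form, with degrees of freedom) and
$p = (1 + \#\{F^* \ge F\}) / (1 + n_\text{perm})$ over label permutations.
Predator/prey tallies follow fixed size-ratio rules: predators are
carnivorous fish, nautiloids or eurypterines over 2× the focal length,
sweep-feeding stylonurines only over 5×; suspension-feeding
hibbertopterids are never predators; prey are mobile benthic or nektonic
species under half a predatory eurypterid's length, sessile taxa excluded.
The correlation screen is deliberately non-phylogenetic and is labelled as
such.

## The synthetic scenario

Because the real data underlying such a study (posterior tree samples from
tip-dated inference, curated measurement tables) cannot ship with a
package, a generator produces data with the statistical structure the
analysis assumes:

* a fossilized birth-death tree over a 467–252 Ma window with
  λ = 0.08, µ = 0.06, ψ = 0.045 per Myr and no extant sampling, thinned to
  135 tips — the scale of the motivating dataset. Fossil tips are the last
  sampling event on lineages without later sampled descendants; sampled
  ancestors are not represented as degree-two nodes, a simplification
  relative to the full FBD reconstructed process that preserves the
  properties the analysis cares about (non-ultrametric, fossil-rich shape);
* pseudo-posterior trees made by log-normal branch-length jitter
  (sd 0.15) on the reference topology — temporal, not topological,
  uncertainty;
* body sizes simulated under the pulsed model rooted at ln 16.7 cm with
  σ² = 0.001, λ_J ≈ 3 per root-to-tip path, δ² = 0.5, spanning roughly
  2–250 cm and beyond;
* a habitat history with structural zeros on the direct
  marine↔continental rates (terrestrialization only through marginal
  settings) rooted in the marine state;
* smooth bounded temperature (≈ 28 ± 4 °C) and oxygen (≈ 190 ± 30 µM)
  series on a 1 Myr grid, and palaeolatitudes drawn independently of size
  so the regression truth is a null.

What passing tests on these data show is that the machinery recovers known
truths under the model family's own assumptions at realistic scale. They do
not validate the biological claims on real data: the generator has no
preservation or collection bias, no measurement error on sizes, no
topological uncertainty, and habitat codings are error-free.

## Problem sizes used by the test suite

The acceptance-style tests run at the analysis scale: 100 random small
trees for likelihood-oracle equivalence plus two 10⁶-draw Monte-Carlo
pulsed comparisons; 50 simulate–refit replicates per model at 135 tips; 20
replicate eleven-model rankings on pulsed data; 20 000 stochastic maps
against exhaustive posteriors; 20 rjMCMC structure-recovery runs at 4000
iterations on histories carrying ~150 events (detecting that a rate is
exactly zero rather than merely small is a Bayes-factor question, and
pilot runs showed sparser histories — tens of events — simply do not carry
that information on a 135-tip tree); 1000 null datasets for
permutation-test calibration. The
synthetic-data oracle comparisons use 1500 package and 1000 independent
forward simulations. These sizes are the package's chosen balance between
statistical resolution and a test suite that completes in tens of minutes
on one core.

## Known limitations

* One continuous trait; no multivariate extension and no measurement-error
  term.
* The pulsed model's jump kernel is normal; no other Lévy kernels.
* rjMCMC explores rate-class structures of a single Mk character — no
  hidden states, covarion behaviour or correlated characters.
* The FBD simulator is a data generator, not an inference target; it makes
  the sampled-ancestor simplification described above.
* Environment-coupled fits require the tree to sit entirely inside the
  curve's range on an absolute timescale (`root_age_ma`); extrapolation is
  a hard error by design.
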