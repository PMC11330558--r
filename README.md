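# palaeotrait

Phylogenetic comparative analysis of body-size macroevolution on fossil
time-trees, built around the eurypterids ("sea scorpions") — Palaeozoic
chelicerates that ranged from under 2 cm to over 2.5 m and repeatedly,
independently, evolved giant size while colonizing continental fresh water.
The package is for palaeobiologists who have a set of time-calibrated,
non-ultrametric phylogenies (e.g. a posterior sample from tip-dated
inference), per-taxon trait and habitat data, and environmental series, and
who want to ask which macroevolutionary process best explains a trait and
whether extrinsic drivers shaped it.

## What it computes

Maximum-likelihood fits and small-sample AICc ranking of eleven models of
log body-size evolution $x = \ln(\text{length, cm})$:

* gradual: Brownian motion (rate $\sigma^2$), Ornstein–Uhlenbeck
  ($dx = \alpha(\theta - x)\,dt + \sigma\,dW$, fixed free root $z_0$),
  directional trend ($\mu$ per Myr), early burst
  ($\sigma^2(t) = \sigma^2 e^{rt}$);
* punctuational: Pagel's $\kappa$ (branch lengths raised to a power) and a
  pulsed Lévy model — BM plus compound-Poisson jumps of variance $\delta^2$
  at rate $\lambda_J$ per Myr, evaluated by Gaussian-mixture pruning;
* extrinsically driven: OU with an optimum tracking sea-surface
  temperature or dissolved oxygen, $\theta(t) = \theta_0 + \beta E(t)$, and
  multi-peak OU on regime paintings (three or two habitat peaks from
  stochastic character maps, or pre/post extinction-crisis peaks).

Around the model core: Mk habitat model selection by maximum likelihood and
by reversible-jump MCMC over transition-rate structures (including
structural zeros), stochastic character mapping by uniformization with
state-dependent lineage-through-time summaries and colonization counts,
GLS root-size reconstruction with convergent-origin counting at the 0.5 m /
1 m thresholds, PGLS of size on palaeolatitude, and a PERMANOVA plus
predator/prey tallying over community tables. A synthetic-data module
generates fossilized birth-death trees, trait and habitat histories,
environmental curves and communities so the whole pipeline runs end to end
without proprietary data.

## Worked example

```r
library(palaeotrait)
sc <- simulate_scenario(seed = 42, config = list(n_posterior_trees = 4L))
x   <- setNames(sc$traits$log_size, sc$traits$taxon)
hab <- setNames(sc$traits$habitat, sc$traits$taxon)

fit_trait_model(sc$mcc, x, "BM")
#> <trait_fit> BM: lnL = -137.482, k = 2, n = 135, AICc = 279.055
#>    z0 = 2.678, sig2 = 0.01082
fit_trait_model(sc$mcc, x, "PULSED")
#> <trait_fit> PULSED: lnL = -103.453, k = 4, n = 135, AICc = 215.214
#>    z0 = 2.704, sig2 = 0.001463, lambda_j = 0.01165, delta2 = 0.6578

mk <- select_mk_model(sc$mcc, hab)
maps <- stochastic_map(sc$mcc, hab, mk$Q, n_maps = 100, seed = 1)
count_colonizations(maps, "continental")[c("median", "ci95")]
#> $median: 12      $ci95: 10 15

root <- ancestral_root(sc$mcc, x)
sprintf("root size: %.1f cm (95%% CI %.1f-%.1f)",
        root$estimate_cm, root$ci95_cm[1], root$ci95_cm[2])
#> "root size: 14.6 cm (95% CI 6.9-30.9)"
count_size_origins(sc$mcc, x, log(50))
#> 7
```

The pulsed model improves on BM by ~64 AICc units because the data were
generated with rare large jumps over weak Brownian noise; the
reconstructed root is small (the scenario roots at ln 16.7 cm) and large
size originates several times independently.

`run_pipeline(config)` chains every stage (read → curves → habitat → fits →
ranking → root/origins → PGLS → ecospace) from a YAML config and writes CSV
and JSON reports plus a manifest; `make_demo_data(dir, seed)` emits a
ready-to-run synthetic scenario. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

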