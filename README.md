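# dirmatch

Movement-influence networks for group-living animals, inferred from sparse,
asynchronous GPS fixes.

When a field observer sweeps repeatedly through a moving group — a baboon
troop travelling and foraging — each animal yields a GPS fix only every few
minutes, and never at the same instant as its groupmates. `dirmatch` turns
such data into a directed, weighted **influence network**: which animals'
positions consistently predict which other animals' movement decisions, and
what group-level structure (a core of mutually interdependent animals, a
single despotic leader, or diffuse influence) those dyadic biases generate.

The chain, end to end:

1. **Direction matching.** For each focal animal $i$, the observed unit
   direction of travel over a step is regressed (Bayesian, no intercept,
   regularising Normal(0, 0.1) priors, x/y stacked) on unit vectors toward
   every other adult ($\hat v_{i,j}$), toward the centroid of the others
   ($\hat v_{cm}$), and along the previous heading ($\hat v_{t-1}$):
   $\hat v_t = \sum_{j\ne i}\beta_{i,j}\hat v_{i,j} + \beta_{cm}\hat v_{cm} + \beta_{t-1}\hat v_{t-1}$.
   Neighbour positions at the step's start are linearly interpolated; the
   focal's never are.
2. **Model comparison.** A group-only model (persistence + centroid) is
   fitted on the same steps; `dwaic = waic_reduced − waic_full > 0` means
   individual identities matter beyond the group as a whole.
3. **Network.** Dyadic coefficients whose 99% HPDI excludes zero become
   edges (influencer → influenced), split into attraction (+) and repulsion
   (−) subgraphs; in/out-strengths and alpha centrality summarise them.
4. **Rank model.** $\beta_{i,j} = \beta_r\,\Delta\mathrm{rank}_{i,j} + g_i$
   with varying intercepts and posterior $R^2$ (rank-only vs rank +
   intercepts).
5. **Core/periphery.** Weighted k-shell decomposition
   ($k' = \sqrt{k\cdot s}$) of the attraction network;
   $D_{core} = \sum_i\sum_j |x_i - x_j|$ tested against 10 000-style
   Erdős–Rényi permutations of the observed edge weights.
6. **Simulator.** An attraction–repulsion agent-based model (the generative
   mirror of step 1) plus an observer-sweep degradation model, so every
   stage is validated by recovering planted influence structures.

## Worked example

Simulate a 6-agent group with a despotic leader (`A01`), observed for 100 h
by a single observer with an 8-minute mean revisit, then recover the
structure:

```r
library(dirmatch)

cfg <- make_scenario("leader", 6, seed = 42, duration = 100)
sim <- simulate_group(cfg)
obs <- degrade_observations(sim$trajectories,
                            observer_schedule(cfg$agent_ids, dwell = 80),
                            seed = 43)

steps <- build_steps(obs, "A02")
fit   <- fit_full_model(steps, seed = 44)
tidy(fit)
#> # A tibble: 7 × 8
#>   focal model term  role      estimate hpdi_low hpdi_high excludes_zero
#> 1 A02   full  A01   neighbour  0.647     0.595     0.693  TRUE
#> 2 A02   full  A03   neighbour -0.00859  -0.0569    0.0477 FALSE
#> 3 A02   full  A04   neighbour  0.0914    0.0214    0.161  TRUE
#> 4 A02   full  A05   neighbour  0.150     0.0653    0.229  TRUE
#> 5 A02   full  A06   neighbour -0.0174   -0.0856    0.0469 FALSE
#> 6 A02   full  cm    cm         0.0915   -0.0137    0.194  FALSE
#> 7 A02   full  prev  prev       0.157     0.116     0.202  TRUE
```

`A02`'s strongest influence is its planted attraction to the leader
(0.65, 99% HPDI well above zero); the centroid term is indistinguishable
from zero; the weaker `A04`/`A05` edges are indirect influence picked up
through shared attraction to `A01` — the "downstream" artefact the package's
simulation study quantifies. The full model crushes the group-only model
(`compare_models(fit, fit_reduced_model(steps, seed = 44))` gives
`dwaic = 868 ± 69`), and at the network level the leader dominates exerted
influence:

```r
fits <- fit_all_focals(obs, reduced = FALSE, seed = 45, quiet = TRUE)
net  <- build_influence_network(fits)
node_strengths(net, "attraction")
#> # A tibble: 6 × 5
#>   node  in_strength out_strength influence responsiveness
#> 1 A01         0.769        3.53      3.53           0.769
#> 2 A02         0.887        0         0              0.887
#> 3 A03         1.03         0.251     0.251          1.03
#> 4 A04         0.965        0.705     0.705          0.965
#> 5 A05         0.828        0.723     0.723          0.828
#> 6 A06         0.736        0         0              0.736
```

`A01` exerts 3.5 units of influence — five times any other animal — while
exerting follows no-one, the signature of a despotic regime.
`weighted_kshell()`, `d_core()` and `permutation_null()` complete the
group-level analysis; `autoplot()` methods and `plot_network()` visualise
each result, and `run_pipeline()` drives the whole chain from a YAML config
to a directory of CSV/JSON artefacts with a reproducibility manifest.

For field data, start from `load_observations()` (CSV of
`animal_id,t,x,y`, planar metres) and `load_ranks()`.

## Package layout

| module | contents |
|---|---|
| `R/io.R` | observation/rank CSV ingestion and validation, network export (edge-list CSV, GraphML) |
| `R/simulate.R` | agent-based simulator, scenario presets, observer-sweep degradation |
| `R/interpolate.R`, `R/steps.R` | track interpolation and step-dataset construction |
| `R/bayes.R`, `R/direction-fit.R` | Gibbs sampler, full/reduced fits, WAIC |
| `R/rank.R` | dyadic rank model with posterior R² |
| `R/network.R` | screening, strengths, alpha centrality, weighted k-shell, D_core, permutation null |
| `R/pipeline.R` | `run_pipeline()`, `experiment_recovery()`, recovery scoring |
| `vignettes/direction-matching.Rmd` | the model, its assumptions, and what the recovery tests do and do not show |
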