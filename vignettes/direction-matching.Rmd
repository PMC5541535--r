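---
title: "Inferring movement-influence networks from sparse GPS follows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring movement-influence networks from sparse GPS follows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirmatch)
library(dplyr)
```

## The problem

In stable social groups on the move — a baboon troop travelling and foraging
— who influences whom? A field observer with a handheld GPS can collect
positions for every recognisable adult by sweeping back and forth through the
group, but the resulting fixes are sparse (several minutes between revisits
to the same animal) and asynchronous across animals. `dirmatch` implements a
complete inference chain from such data to a directed movement-influence
network and its core/periphery structure, together with an agent-based
simulator that makes every stage of the chain checkable by parameter
recovery.

## The direction-matching model

For each focal animal $i$ in turn, the observed unit direction of travel
between two successive fixes is regressed on three kinds of predictor, all
unit vectors evaluated at the step's start:

$$\hat v_t \;=\; \sum_{j \ne i} \beta_{i,j}\,\hat v_{i,j}
\;+\; \beta_{cm}\,\hat v_{cm} \;+\; \beta_{t-1}\,\hat v_{t-1},$$

where $\hat v_{i,j}$ points from the focal to group member $j$, $\hat v_{cm}$
points to the centroid of all other members, and $\hat v_{t-1}$ is the
previous heading (directional persistence). A positive $\beta_{i,j}$ is an
*attraction* (consistent movement toward $j$), a negative one a *repulsion*.
Because the non-focal animals are observed at other times, their positions at
the step's start are linearly interpolated between flanking fixes; the
focal's own positions are never interpolated.

The model is fitted per focal in a Bayesian framework with regularising
Normal(0, 0.1) priors on all coefficients, no intercept (an intercept would
encode an absolute compass bias), the x- and y-components stacked as
independent observations with a shared residual standard deviation
(half-Normal(1) prior), and a Gibbs sampler (conjugate coefficient draws,
slice-sampled residual scale). Treating x and y as independent understates
the interval widths, so edges are screened conservatively: a dyadic
coefficient becomes a network edge only when its **99% highest-density
interval excludes zero**. A group-only model (persistence + centroid only) is
fitted on the same steps and compared with WAIC on the deviance scale;
`dwaic = waic_reduced - waic_full > 0` means individual identities improve
prediction beyond the group as a whole.

A second-stage dyadic model relates the fitted coefficients to dominance:
$\beta_{i,j} = \beta_r\,\Delta\mathrm{rank}_{i,j} + g_i$, with
$\Delta\mathrm{rank}_{i,j}$ the ordinal-rank difference (influenced minus
influencer) on a single merged group-wide ordering (males above females by
default — the convention is configurable), varying intercepts $g_i$ for the
influenced animal, and posterior $R^2$ computed per draw by variance
partition: $R^2_{\text{fixed}} = V_f/(V_f+\sigma_g^2+\sigma^2)$ and
$R^2_{\text{full}} = (V_f+\sigma_g^2)/(V_f+\sigma_g^2+\sigma^2)$, summarised
by posterior medians (the nesting guarantees
$R^2_{\text{full}} \ge R^2_{\text{fixed}}$). Point estimates of
$\beta_{i,j}$ enter as data; first-stage uncertainty is deliberately not
propagated (a two-stage design, documented as a limitation).

At the group level, the screened attraction network (edge = influencer
$\to$ influenced, weight = posterior mean) is decomposed with a weighted
k-shell: the directed graph is symmetrised (reciprocal weights summed), each
node scored $k' = \sqrt{k \cdot s}$ (degree $\times$ strength), and nodes
pruned in batches at a rising threshold; the shell value is the threshold at
removal. The scalar $D_{core} = \sum_i \sum_j |x_i - x_j|$ over all ordered
shell pairs measures the magnitude of core/periphery structure, and is
compared against a permutation null that reassigns the observed multiset of
edge weights to uniformly drawn distinct directed pairs of the same node set
(edge count fixed), declaring structure when the observed $D_{core}$ exceeds
the null's 95% quantile.

## The simulator and what it emulates

`simulate_group()` is the generative mirror of the regression: per tick each
agent's new heading is the normalised weighted sum of its previous heading,
signed unit vectors toward specific group members (the planted influence
matrix $W$), and the unit vector toward the centroid of the others, rotated
by Gaussian angular noise; the agent then advances a fixed distance.
`degrade_observations()` emulates the field protocol: one observer sweeps
the group cyclically, so each animal is revisited every
`n_agents * dwell` seconds, with Gaussian timing jitter and isotropic GPS
error. Scenario presets (`make_scenario()`) plant a despotic leader, a
mutually attracting core with an attached periphery, a homogeneous diffuse
system, or a following chain.

Defaults, chosen once as field-realistic and kept fixed: tick 30 s, speed
10 m/tick, heading noise 0.3 rad, GPS noise 5 m, visit jitter 10 s, 12-h
observation days, group attraction 0.2, persistence 0.5, planted influence
1 per following agent. The simulation studies use 6–9 agents observed for
100 h at an 8-min mean revisit (roughly 700 usable steps per focal); the
field regime this stands in for is ~14 adults, ~700 h, 9-min mean revisit.
Analysis defaults: minimum step displacement 5 m (the GPS noise floor —
direction is undefined for stationary fixes), interpolation/step gap limit
30 min, complete-case steps (a step is dropped if any neighbour cannot be
interpolated), at least 50 usable steps per fitted focal, sampler
1000/1000/2 (draws/warmup/chains) for analyses and 400/400/2 in replicated
recovery studies.

## What recovery tests do and do not show

Simulation-based checks of this chain must distinguish three very different
kinds of "error", and the package's test suite treats them separately.

**Screening specificity is only testable on a genuinely null dyad.** With
any shared dynamics — group attraction, or a common influence target — the
direction to a specific neighbour is *genuinely* informative about a focal's
next step even when that neighbour exerts no direct influence, because an
8-minute step aggregates many 30-s decisions: over the step, the positions
of group members are correlated proxies for where the attraction has been
pulling. We verified this mechanism directly: fitted at full 30-s resolution
the spurious dyadic coefficients shrink substantially, and with all coupling
removed they vanish, while observation noise contributes almost nothing.
Specificity is therefore calibrated on independent persistent walkers (no
influences, no group attraction), where the 99% intervals cover zero for
over 95% of dyads. On cohesive data the same intervals flag many indirect
dyads — that is not a calibration failure but the *downstream-influence
artefact*: in a following chain A ← B ← C, the method attributes influence
of C on A. The package reproduces this artefact deliberately, and the
chain's mid-links illustrate its flip side: direct influences get diluted
across collinear up-chain directions, so who-follows-whom is not resolvable
at field resolution even though *that* an animal is influential is. Dyadic
sign recovery is therefore asserted on the leader scenario, where
attribution is identifiable, and recovery rates on the chain are reported
rather than asserted.

**The WAIC comparison asks a coarser, robust question.** Whether individual
positions matter beyond the group as a whole is answered positively for
every planted follower, in every replicate — matching the motivating
analysis, where the full model won for every animal. The scenario heads
(a leader or chain head follows no-one) are excluded from this assertion,
since for them the reduced model is the truth. A corollary of the
aggregation mechanism above: even data generated by pure group attraction
produce a positive `dwaic`, because the neighbour columns genuinely improve
step-scale prediction — the comparison detects *predictive* structure, not
generative wiring.

**Core/periphery magnitude needs sparsity to be testable.** The permutation
test has excellent power on sparse heterogeneous networks of the kind the
field analysis reported (a strongly connected core, weak spokes, several
isolated animals): synthetic networks of that shape exceed the null's 95%
quantile in every replicate of the suite's power check, and the test is
calibrated (≈5% false alarms against its own null). But the *fitted* networks of the simulation scenarios
are dense — the common-target confounding floods them with mid-weight
edges — so the weighted k-shell collapses to a single shell and the observed
$D_{core}$ falls *below* the null. The detected core is thus over-inclusive
to the point of uninformativeness at simulation scale, an amplified version
of the over-inclusiveness the simulation literature reports; the package's
scenario-discrimination test relies instead on in-strength concentration
(a leader's single dominant hub vs the flat profiles of diffuse and
core/periphery regimes), which separates the regimes cleanly.

## Numerical and design notes

* All randomness is seeded and local: every stochastic function takes a
  `seed`, restores the caller's RNG, and derives child seeds arithmetically,
  so pipelines are bit-reproducible from `(config, seed)`.
* Unit vectors are undefined below 0.1 m displacement; steps lose their
  record (complete-case) rather than being zero-filled. An agent whose
  weighted heading sum is numerically zero keeps its previous heading.
* The k-shell pruning removes all nodes at or below the running threshold in
  one batch, then rescores; with unit weights and no reciprocal edges this
  reduces exactly to the classic k-core (verified against an independent
  implementation on random graphs).
* In the stored network orientation (source = influencer), the field
  literature's "in-strength" (how much others respond to an animal) is the
  node's *outgoing* strength; `node_strengths()` returns both conventions
  explicitly (`influence`, `responsiveness`). Alpha centrality is oriented
  so that influencers score high, consistent with its reported redundancy
  with the field's in-strength; its attenuation defaults to 0.9 divided by
  the spectral radius.
* The permutation null fixes the edge *count* and reassigns the observed
  weight multiset (rather than redrawing a density), matching the
  "rearranging attractions without reference to identity" reading; the
  alternative is noted but not implemented.
* The merged rank ordering (males above females) is a configurable
  convention; the default synthetic roster has 2 males and 12 females,
  labelled by sex and within-sex rank.
* The package is a library, not a shell tool: `run_pipeline()` (config-file
  driven, manifest-writing) and `experiment_recovery()` are the orchestration
  surface, and `scripts/acceptance.R` reproduces the headline numbers.

## Known limitations

Interpolation of neighbour positions uses fixes on both sides of the query
time, so predictors contain some future information; the residuals of
consecutive steps are autocorrelated and the stacked x/y treatment
understates uncertainty — both inherited from the modelling tradition this
package implements, and both reasons the 99% screening rule and sign-based
interpretation are used. First-stage uncertainty in the dyadic coefficients
is not propagated into the rank model. The simulator omits habitat, speed
modulation, fission–fusion and non-adult group members.
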