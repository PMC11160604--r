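---
title: "Simulating the hit-to-lead DMTA cycle: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the hit-to-lead DMTA cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmtaSim)
```

## The problem

Hit-to-lead optimization is a stochastic process. A medicinal-chemistry team
starts from weakly active screening hits and iterates design-make-test-analyze
(DMTA) cycles: ideate synthesizable analogs of the most promising compounds,
score them with imperfect predictive models, synthesize a batch, measure it,
and fold the measurements back into the next round of decisions. The program
succeeds if some tested compound satisfies every objective of the target
candidate profile (TCP) before the synthesis budget runs out.

`dmtaSim` simulates this process end to end, so that questions which would be
prohibitively expensive to answer with real programs — how much is a more
accurate affinity model worth per prediction? what batch size should we
order? how adventurous should analog ideation be? — can be answered
statistically, by running thousands of simulated campaigns and reading
success probabilities and expected costs off their cumulative distribution
functions.

## The DMTA loop

One cycle of `runCycle()` performs:

* **Design / ideation.** The top-utility tested molecules (default 5, the
  number of starting hits) are parents. Each parent yields analogs by two
  moves: *replacement* — a building block of its synthetic route is swapped
  for a library block drawn by Boltzmann-weighted fingerprint similarity —
  and *growth* — the parent product joins a random size-admissible block in a
  compatible reaction, appending a route step. A campaign-level cache of
  canonical SMILES prevents re-ideating known structures. When the parents'
  neighborhoods are exhausted, ideation escalates to the next tier of tested
  molecules; a cycle that produces no new structures at all counts as a
  stall, and three consecutive stalls end the campaign.
* **Design / scoring.** The `scoringRatio × batchSize` new candidates are
  scored on every TCP objective by noisy oracles: the ground-truth oracle
  value plus i.i.d. Gaussian error of spread `sigma` (the model-error knob).
  `sigma = 0` is a perfect model; a huge `sigma` (1e6) is an uninformative
  one.
* **Design / selection.** Corrected predictions are mapped to per-objective
  utilities, candidates are partitioned into successive Pareto fronts of
  non-dominated molecules, ranked within fronts by weighted-mean utility, and
  a batch is drawn epsilon-greedily: each slot goes to a uniformly random
  remaining candidate with probability `epsilon` (default 0.1), otherwise to
  the best-ranked one.
* **Make + Test.** The batch is marked synthesized (depleting the budget;
  the final batch truncates to what remains) and measured with the noiseless
  oracles. Making and testing one molecule costs `costPerCompound` (default
  $3000).
* **Analyze.** Measurements supersede predictions. Because selected
  high-predicted scores are overestimates on average (regression to the
  mean), the prediction–measurement pairs accumulated so far are used to
  refit, per objective, an ordinary least-squares bias model
  `measured = alpha + beta * predicted` (active once 10 pairs exist); future
  predictions are corrected through it before selection. Finally the TCP is
  checked: a tested molecule inside every objective's success window ends the
  campaign as a success.

## The utility function

Each TCP objective has an *acceptable* and an *ideal* window. Per-objective
utility maps a measurement into `(-Inf, 1]`:

* `1` anywhere inside the ideal window — every ideal value is equally prized;
* a linear ramp from 0 to 1 between each finite acceptable bound and its
  ideal bound;
* a quadratic penalty `-(d / w)^2` outside the acceptable window, where `d`
  is the overshoot and `w` the same-side ramp width, so the penalty grows
  without bound but joins the ramp continuously with comparable slope. If the
  ideal and acceptable bounds coincide on a side there is no ramp; the
  penalty is scaled by 10% of the dynamic range and the function necessarily
  steps from 0 to 1 at that bound (values at the bound count as ideal).
  Sides with an infinite acceptable bound never penalize.

The composite utility is the weighted arithmetic mean over objectives
(uniform weights by default); it saturates at 1 exactly when every objective
is ideal. Missing values map to `-Inf` so that unevaluable molecules never
win a selection. The default TCP is the oral-drug profile used throughout:
affinity (pIC50) acceptable `[8, Inf)` / ideal `[9, Inf)`, lipophilicity
(Log P) `[0, 4]` / `[0, 3]`, solubility (Log S) `[-4, 0]` / `[-3, 0]`.

## Ideation knobs: temperature and n-replacement

Replacement candidates for a route position are ranked by Tanimoto similarity
(hashed circular fingerprints, radius 2, 2048 bits — computed natively over
the molecular graph for speed and cross-platform determinism, with other
fingerprint types available through the ChemmineOB backend) and drawn without
replacement with probability proportional to `exp(similarity / T)`,
max-subtracted for numerical stability. `T = 0` degenerates to the
deterministic top-k most similar blocks (maximally conservative);
`T = Inf` to uniform random selection. `nReplace` controls how many route
blocks are swapped per analog (`Inf` = all positions), the second creativity
knob: single conservative swaps cap how dissimilar a descendant can get,
while all-replacement at high temperature is effectively random search.
Scores are raw similarities in `[0, 1]` (not ranks), so at `T = 1` the
maximum weight ratio is `e` — already close to random selection. Sampling
without replacement is the default so one draw enumerates distinct analogs;
with-replacement sampling is available as a configuration flag.

Growth is always on (half of each parent's analog quota by default,
configurable through `replaceFraction`), joining the parent product with a
uniformly random compatible block of at most `growthMaxHeavyAtoms` heavy
atoms under a uniformly random compatible template.

## Chemistry layer

Structures are canonical SMILES throughout (OpenBabel, via ChemmineR /
ChemmineOB, does all parsing, sanitization, and canonical writing); the dedup
key of a compound is its canonical SMILES. Reaction products are constructed
by direct molecular-graph edits — bond formation plus leaving-group removal —
then re-sanitized and canonicalized on the way back to SMILES. The repertoire
is a registry of four standard two-component med-chem couplings (amide
coupling, sulfonamide formation, reductive amination, Suzuki-type aryl–aryl
coupling), identified by their reaction SMARTS strings; functional-group
sites are located by explicit graph rules rather than a general SMARTS
engine, so reaction files are restricted to this registry. Polyfunctional
reactants enumerate one product per site combination (deduplicated);
`protect = TRUE` bars all but one designated site from reacting. Products
that fail sanitization (including fragmented results) are dropped and
counted. Every compound record carries a replayable synthetic route: each
step stores its template, reactant references (library blocks or earlier step
products), and the product chosen among the enumerated possibilities, so
`replayRoute()` can verify any molecule by forward synthesis.

## Synthetic study conditions

All external dependencies are replaced by a self-contained fixture
(`defaultFixture()`): a 120-block catalog built by seeded combinatorial
decoration of ring/chain scaffolds with the six functional handles of the
repertoire (every reactant role is guaranteed at least 5 compatible blocks);
the four-reaction repertoire; five fragment-sized starting hits; and three
oracles.

* **Affinity (pIC50).** A hidden-optimum landscape over an 8-descriptor
  physicochemical space (Log P, MW, TPSA, H-bond acceptors/donors, ring
  count, fraction Csp3, heavy atoms), z-scored against a 250-product probe of
  the reachable space:
  `pIC50 = 4.0 + 4.5 * exp(-d^2 / (2 * 2.2^2)) + cliffs`, clipped to
  `[3, 11]`, where `d` is the Euclidean distance to the optimum. The optimum
  is placed on an actual reachable one-step product with lead-like
  lipophilicity, toward the periphery of the product cloud (95th percentile
  of distance from its center): unguided sampling, which concentrates near
  the cloud's center, rarely wanders into the acceptable basin, while
  similarity-guided hill climbing can follow the gradient. Two rare
  substructure motifs act as activity cliffs — an aromatic fluorine (-2.0)
  and an extended hexyl chain (-1.8) — so a one-heavy-atom change can break
  potency (adding an aryl F, or the CH2 that completes the chain) while the
  bulk of the space keeps smooth structure–activity relationships. The
  kernel width, penalty motifs, and optimum placement were calibrated once so
  the fixture exhibits the documented SAR, cliff, and solvability properties,
  then frozen.
* **Lipophilicity (Log P).** Atomic-contribution (Crippen-type) Log P from
  the descriptor backend; deterministic.
* **Solubility (Log S).** An ESOL-style linear surrogate
  `0.4 - 0.75 LogP - 0.005 MW + jitter` (structure-hashed deterministic
  jitter, SD 0.25), clipped to `[-8, 1]`; the strong built-in
  anti-correlation with Log P reproduces the usual
  lipophilicity–solubility trade-off that makes the TCP genuinely
  multi-objective.

The fixture TCP keeps the Log P and Log S windows of the oral-drug profile
verbatim and rescales the affinity thresholds to the landscape's achievable
range (acceptable `[8.2, Inf)`, ideal `[8.4, Inf)` against a peak of 8.5) —
a docking pIC50 scale does not transfer to a synthetic landscape. Starting
hits are screened the way a fragment screen delivers chemical matter: true
affinity in a weak-active window (`[4.4, 5.0]`) and free of the cliff
(liability) motifs, so campaigns start on the smooth SAR flank. Default
campaign knobs: ideation temperature 0.08 (calibrated as the productive
middle ground for this fixture), 1-replacement, batch size 8, scoring ratio
5, epsilon 0.1, budget 120 made.

### What the fixture does and does not emulate

The fixture reproduces the *mechanisms* that make hit-to-lead optimization
hard — SAR with activity cliffs, anti-correlated objectives, imperfect
models, a finite reaction-constrained space — at desk scale (a ~10^4–10^5
compound space instead of 10^21, minutes instead of cluster-days). It does
not emulate docking-score distributions, assay-specific error structure,
synthesis failure rates, or the absolute magnitudes of full-scale docking
campaigns; tests that pass on it establish that the machinery
produces the right *orderings* (in model error, scoring ratio, batch size,
ideation temperature), not that any absolute success rate transfers to real
programs.

## Econometrics

Ensembles (`runEnsemble()`) run trials under per-trial seeds mixed from a
base seed. Success is summarized by the empirical CDF of resource cost over
*all* trials, with failures right-censored at the budget (they never count at
any resource level, so the CDF plateaus at the overall success fraction).
`expectedCostAtRate()` inverts the CDF at a target rate with a seeded
bootstrap interval (1000 resamples) and reports an explicit unattainable
sentinel rather than extrapolating. Cost-versus-model-error points are fitted
by ordinary least squares in log space (`cost = a * exp(k * sigma)`), with
R-squared and MAE reported on the natural molecules scale; log-space OLS is
deterministic and stable where nonlinear least squares would need starting
values. The breakeven value of a scoring model is
`(medianCostNoModel - medianCostWithModel) * costPerCompound / nScored` — the
per-calculation price at which using the model stops paying for itself —
using 50th-percentile molecules-made counts of successful trials (medians,
following the cost summaries used for breakeven arithmetic; means are
sensitive to censoring). The no-model baseline makes every ideated molecule
(random selection among candidates, nothing scored).

Property trajectories pool made molecules across trials on a normalized
progress axis (the m-th of M made molecules sits at `100 m / M` percent) and
report per-bin means of the TCP objectives and standard drug-likeness
descriptors, including ligand efficiency (pIC50 / heavy atoms), lipophilic
efficiency (pIC50 - Log P), rings per 1000 heavy atoms, fraction Csp3, and
QED. QED uses the published desirability parameterization with the
structural-alerts term fixed at zero alerts — the fixture chemistry carries
none of the alert motifs, and no installed descriptor backend provides the
alert catalog.

## Numerical and design choices

* **Determinism.** All randomness flows through named RNG streams (ideation,
  oracle noise, selection) mixed from the campaign seed, so a campaign is
  byte-reproducible and changing the noise level never perturbs the ideation
  sequence. Ties are broken lexicographically by dedup key everywhere a total
  order is needed.
* **Pareto sorting** is a deterministic non-dominated sort (the partition
  itself is a deterministic object; a stochastic genetic partitioner would
  make testing impossible). During selection, fronts are peeled exactly only
  until twice the batch size is covered; the remainder forms one residual
  front ordered by scalarized score — greedy slots never reach it, and
  uniform random slots are order-insensitive, so selection is unchanged while
  large candidate pools stay cheap.
* **Noise** is resampled on every scoring call by default (a model's error is
  per use); `frozenNoise = TRUE` fixes one draw per molecule. A huge finite
  sigma (1e6) stands in for an uninformative model, avoiding non-finite
  arithmetic.
* **Bias regression** is fit as `measured ~ predicted` (the correction
  target is the prediction); the reverse form is a configuration away by
  swapping the pair columns, but correcting predictions toward measurements
  is the natural direction for selection.
* **Make and Test are coupled** (every made molecule is tested): the cost
  unit is "make and test one compound". The ledger supports decoupling for
  assay-cascade studies but the bundled experiments do not use it.
* **Degenerate inputs.** Unparseable structures become `NA` oracle values and
  `-Inf` utilities; role-mismatched reactants yield empty product sets, not
  errors; a final batch larger than the remaining budget truncates;
  requesting more selections than candidates selects all.
* **Ensemble problem sizes.** The bundled ordering experiments use 50 trials
  per condition at budgets of 40 (model error, temperature, scoring ratio)
  and 160 made molecules (batch size) over the 120-block fixture — sizes at
  which every documented ordering is resolved well beyond binomial noise
  while a full sweep stays a coffee-break computation.

## Known limitations

* The reaction engine covers the built-in coupling registry, not arbitrary
  reaction SMARTS; reaction files referencing other transforms are rejected.
* Aromaticity perception is a kekulized-ring heuristic adequate for the
  generated chemistry; exotic aromatic systems outside the fixture space may
  be misperceived.
* Ideation cannot combine addition and replacement in one move, and growth
  ignores structure beyond role compatibility and block size.
* The descriptor-space landscape makes similarity-guided search *possible*,
  not trivially easy: fingerprint distance correlates with descriptor
  displacement only partially, which is also why mild prediction noise costs
  relatively little compared to severe noise.
* Breakeven arithmetic follows the stated formula
  `(savings in molecules) * costPerCompound / nScored`; with a $3000
  compound cost, saving 400 molecules over 12000 calculations is worth $100
  per calculation.
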