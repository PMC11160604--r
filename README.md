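# dmtaSim

Stochastic simulation and econometrics of hit-to-lead
design–make–test–analyze (DMTA) campaigns in small-molecule drug discovery.

Hit-to-lead optimization is a race between two quantities: progress toward a
**target candidate profile** (TCP — potency plus ADME windows a lead must
satisfy) and a finite synthesis **budget**. Every cycle, a team ideates
synthesizable analogs of its best compounds, scores them with imperfect
predictive models, makes a batch, measures it, and feeds the measurements
back into the next round of decisions. `dmtaSim` simulates this loop over a
reaction-based chemical space and derives the campaign econometrics that a
single real program can never give you: success-probability CDFs over
resource axes, expected costs at target success rates, exponential fits of
cost versus model error, and the **breakeven value of a predictive model** —
the price per scoring calculation at which using the model stops paying for
itself.

## The model in brief

* **Ideation.** Analogs come from two moves on a compound's recorded
  synthetic route: *replacement* of a building block by a library block drawn
  with probability ∝ `exp(similarity / T)` (Tanimoto on circular
  fingerprints; `T` is the creativity temperature, `nReplace` how many blocks
  swap at once), and *growth* by a random compatible coupling. A canonical-
  SMILES cache keeps campaigns from retreading old chemical space.
* **Scoring.** Each TCP objective has a ground-truth `Oracle`; a `NoisyOracle`
  adds Gaussian error of spread σ, modeling a predictive model of stated
  inaccuracy.
* **Utility and selection.** Objective values map into `(−∞, 1]`: 1 inside
  the ideal window, a linear 0→1 ramp across the acceptable shoulder, a
  quadratic penalty outside. Candidates are partitioned into Pareto fronts of
  non-dominated molecules, scalarized by weighted-mean utility within fronts,
  and selected ε-greedily.
* **Analyze.** Measurements supplant predictions; the overestimation bias of
  selected predictions is regressed out (`measured = α + β·predicted`) from
  accumulated prediction–measurement pairs; the campaign succeeds when a
  tested molecule satisfies every TCP objective before the budget (molecules
  made × $3000 by default) is exhausted.
* **Synthetic testbed.** A bundled fixture generator stands in for every
  external dependency: a combinatorial building-block catalog, four standard
  couplings (amide, sulfonamide, reductive amination, Suzuki), fragment-sized
  screening hits, a Crippen-type Log P oracle, an ESOL-style Log S surrogate
  anti-correlated with Log P, and a synthetic affinity landscape with smooth
  structure–activity relationships and one-atom activity cliffs.

See the methods vignette (`vignettes/dmta-methods.Rmd`) for the full model,
parameter meanings, and design choices.

## Worked example

```r
library(dmtaSim)

fx <- defaultFixture(seed = 1)         # catalog, reactions, hits, oracles, TCP
cfg <- campaignConfig(fx$tcp, fx$oracles,
                      sigmas = c(affinity = 0.5),   # affinity model error (pIC50)
                      budget = 120, seed = 42)
res <- runCampaign(cfg, fx$hits, fx$library, fx$templates)
show(res)
#> CampaignResult: SUCCESS in 3 cycles; 29 made (budget 120), 120 scored, cost $87,000

led <- res@ledger
best <- led[which.max(led$utility), ]
#> lead: CCOCCS(=O)(=O)Nc1ccsc1C
#>   pIC50 8.50 | Log P 2.99 | Log S -3.54 | utility 0.82
```

The campaign found a sulfonamide lead in three cycles: its measured pIC50
(8.50) and Log P (2.99) sit in their ideal windows and Log S (−3.54) in its
acceptable window, so the TCP is met; composite utility 0.82 reflects the
not-yet-ideal solubility. Twenty-nine molecules were made and tested
($87,000) while 120 were only scored — the whole point of a scoring model.

Ensembles turn single anecdotes into statistics:

```r
rs <- runEnsemble(cfg, fx$hits, fx$library, nTrials = 20, baseSeed = 7,
                  templates = fx$templates)
successRateAtBudget(rs, 120)   #> 1.00
medianSuccessCost(rs)          #> 29  (median molecules made by successful trials)
```

With these per-σ medians, `fitCostModel()` fits `cost = a·exp(k·σ)` and
`breakevenValue()` prices a model per calculation:
`breakevenValue(1000, 600, 3000, 12000)` — a model that cuts the median cost
from 1000 to 600 molecules at $3000 each over 12000 calculations — is worth
`$100` per calculation.

Command-line wrappers live in `inst/scripts/`: `make-fixtures.R` emits the
fixture inputs in the standard formats (catalog CSV, reaction SMARTS file,
hits SMILES, landscape JSON), `run-campaign.R` runs one campaign from those
files, `run-ensemble.R` runs sweeps and writes tidy per-trial CSV plus
summary JSON.

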