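Package: dmtaSim
Title: Stochastic Simulation and Econometrics of Hit-to-Lead
    Design-Make-Test-Analyze Campaigns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A testbed for the economics of small-molecule hit-to-lead
    optimization. Simulates design-make-test-analyze (DMTA) cycles over a
    reaction-based chemical space: analogs of promising compounds are
    enumerated by similarity-guided building-block replacement and fragment
    growth, scored by noisy surrogate models, selected by Pareto-front
    scalarization with epsilon-greedy exploration, and assayed against a
    target candidate profile until the profile is met or the synthesis
    budget is exhausted. Ensemble statistics (success-probability CDFs,
    expected costs, exponential cost-versus-model-error fits, breakeven
    model value, progress-normalized property trajectories) quantify how
    ideation creativity, batch size, scoring ratio, and predictive-model
    error move the probability of program success. Ships a self-contained
    synthetic fixture generator (building blocks, reaction repertoire,
    fragment hits, and a structure-activity landscape with activity
    cliffs) so experiments run without external catalogs or docking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'rng.R'
    'chem-core.R'
    'fingerprint.R'
    'descriptors.R'
    'reactions.R'
    'AllClasses.R'
    'catalog.R'
    'routes.R'
    'tcp.R'
    'oracles.R'
    'ideation.R'
    'selection.R'
    'campaign.R'
    'econometrics.R'
    'fixtures.R'
    'io.R'
    'dmtaSim-package.R'
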