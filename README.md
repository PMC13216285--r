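# trensh

Electrical-network simulation of brain arteriovenous malformation (bAVM)
hemodynamics and of transvenous retrograde embolization manoeuvres.

## The problem

Plexiform bAVMs shunt arterial blood through a nidus of fragile
interconnected microvessels into draining veins. TRENSH — *transvenous
retrograde nidus sclerotherapy under controlled hypotension* — proposes
treating them backwards: lower the systemic arterial pressure (optionally
occlude a feeder with a temporary balloon, raise central venous pressure, or
time the injection to diastole), then inject a liquid sclerosant
retrogradely through a draining vein so it permeates the nidus against the
weakened antegrade flow. `trensh` is a simulator for exploring these
manoeuvres *in silico*: it generates stochastic nidus architectures, solves
their steady-state hemodynamics, and scores each scenario by nidus filling
and rupture risk. It is aimed at computational-hemodynamics and
neurointervention researchers studying treatment strategy, not at clinical
decision-making.

## The model

* **Hagen–Poiseuille / Ohm analogy.** Each vessel is a rigid cylinder with
  resistance `R_v = 8 L mu / (pi r^4)` (blood at 3.5 cP), so `Q = dP / R_v`.
* **Kirchhoff steady state.** Flow is conserved at every node and pressure
  drops sum to the EMF around every cycle. The solver assembles the
  equivalent sparse nodal-potential system, factorizes once per topology,
  and solves all pressure sets of a topology in one batched call; cycle
  residuals are verifiable post hoc to 1e-9 mmHg.
* **Nine EMFs.** A systemic source (74/70/50/25 mmHg for normotension and
  mild/moderate/profound hypotension), one per arterial feeder (AF1–AF4),
  one per draining vein (DV1–DV3, retrograde: adding 10/20/30 mmHg models a
  transvenous injection), and a central venous source (6 or 12 mmHg).
* **Stochastic nidus.** 3–6 compartments x 3–7 columns of plexiform
  microvessels (~950 on average), `2*C*K` intercompartmental vessels, and a
  large-radius fistula from AF2 to DV2.
* **Filling = reachability.** A vessel fills when its flow-entry node is
  reachable from the injection site along flow-oriented nidus vessels; an
  antegrade closure models sclerosant egress after the injection stops.
* **Rupture risk.** `ln(P_exp/4) / ln(74/4) * 100%`, clamped to [0, 100],
  with `P_exp` the per-vessel pressure drop `|R_v Q|` by default.

See the methods vignette (`vignettes/trensh-model.Rmd`) for assumptions,
the calibration of the bundled vessel-dimension table, and known limits.

## A worked example

```r
library(trensh)
config  <- sim_config()
network <- attach_nidus(build_extranidal_template(config),
                        sample_architecture(42, config))
network
#> <trensh_network>
#>   nodes: 860, vessels: 1344, EMFs: 9
#>   nidus: 6 compartments x 4 columns, 942 intranidal vessels (seed 42)

normo    <- solve_flow(network, pressure_set("normo",    config = config))[[1]]
baseline <- solve_flow(network, pressure_set("profound", config = config))[[1]]
total_nidal_flow(normo, network)     # 423.8 mL/min for this architecture
total_nidal_flow(baseline, network)  # 118.4 mL/min under profound hypotension
nidus_risk_summary(normo, network)   # mean 2.0%, max 32.9% rupture risk

inj     <- pressure_set("profound",
                        injection = list(site = "DV2", pressure_mmHg = 30),
                        config = config)
treated <- solve_flow(network, inj)[[1]]
filled  <- egress_closure(baseline, ingress_filling(treated, network), network)
percent_filling(filled, network)     # 100% of this nidus filled
```

Profound hypotension cuts this architecture's antegrade nidal flow from
424 to 118 mL/min; a 30-mmHg retrograde injection through the dominant
draining vein then permeates the entire nidus. Population means over many
seeds (the quantity the model reports) are computed by `run_main_grid()`,
summarized by `aggregate_results()`, and compared with
`compare_groups()` (Student's t / one-way ANOVA, alpha 0.05).

A thin command-line front end (`inst/cli/trensh.R`) exposes
`generate`, `simulate`, `batch`, `stats`, `sweep` and `animate`
subcommands over the same functions, e.g.

```sh
Rscript inst/cli/trensh.R batch --n-arch 10 --seed 1 --out results.csv
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates, from scratch with the installed package, the headline
generator aggregate (the mean nidus vessel count over 500 seeded
architectures at default settings) and writes it as JSON.
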