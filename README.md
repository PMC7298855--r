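# dcelink

Design, simulation, estimation and forecasting tools for discrete choice
experiments (DCEs) on public acceptability of research uses of anonymised
linked health and administrative data.

## The problem

Health researchers increasingly link primary-care, hospital, social-care and
administrative records.  Whether the public finds a particular *use* of
linked data acceptable depends on who the researchers are, what data are
linked, the purpose, what happens to any profit, and who oversees the
process.  A DCE measures those preferences: respondents repeatedly choose
between two hypothetical data-use scenarios (or opt out, saying neither is
acceptable), and a random-utility model turns the choices into part-worth
utilities.

The package implements the complete analysis pipeline for a two-country
(Scotland / Sweden) study of this kind, with five attributes at
(4, 4, 3, 4, 4) levels — 768 possible scenario profiles, blocked into
40 × 6 choice sets:

* **Design** — seeded generation of blocked main-effects choice-set designs
  with dominance filtering, level-balance and D-efficiency diagnostics, and
  Orme's minimum-sample-size rule (`generate_design()`,
  `design_diagnostics()`, `orme_minimum_n()`).
* **Simulation** — respondent panels under demographic quotas, sequential
  route-out screening, and choice generation from a random-utility model
  with Gumbel errors and an opt-out alternative (`simulate_population()`,
  `simulate_screening()`, `simulate_choices()`).
* **Estimation** — in-package maximum likelihood for the conditional logit
  family (`dce_clogit()` and wrappers): per-country models, a pooled model
  with nationality interactions, and a heteroskedastic model with a group
  scale parameter λ = exp(θ) capturing cross-country differences in choice
  consistency.
* **Forecasting** — scenario acceptance probabilities
  P = e^V / (e^V + e^δ), where V is a scenario's observable utility and δ
  the opt-out constant, plus attribute-level what-if analysis and
  split-sample subgroup forecasts (`forecast_scenarios()`,
  `delta_analysis()`, `subgroup_forecasts()`).

## The model

Utility of alternative *j* for respondent *i* is
`U_ij = λ_i V_ij + ε_ij` with iid standard Gumbel ε, where
`V_ij = x_ij' β + optout_ij δ` (+ nationality interactions γ in pooled
models), attributes dummy coded against each attribute's "worst" base
level, and `λ_i = exp(θ · scot_i)` in the heteroskedastic model (reference
country λ = 1).  Choice probabilities within a set are multinomial logit;
estimation is by maximum likelihood with analytic gradients, standard
errors from the inverse observed information (respondent-clustered
sandwich optional).

## Worked example

Forecast the built-in scenarios from the bundled published pooled
heteroskedastic coefficient estimates:

```r
library(dcelink)
fit <- reference_estimates("heteroskedastic")
fc  <- forecast_scenarios(fit)          # default rule: 5%-significant
fc$P <- round(fc$P, 3)                  # interactions, scale not applied
print(fc, row.names = FALSE)
#>    scenario  country     V delta     P
#>     typical   Sweden 2.411  0.62 0.857
#>   best_case   Sweden 1.718  0.62 0.750
#>  worst_case   Sweden 0.000  0.62 0.350
#>     typical Scotland 2.162  0.62 0.824
#>   best_case Scotland 1.570  0.62 0.721
#>  worst_case Scotland 0.000  0.62 0.350
```

A "typical" scenario (university or health-service researchers, primary
care linked to other health records, general public benefit, profit
invested in public services, oversight by the relevant public service) is
forecast acceptable with probability 85.7% in Sweden and 82.4% in
Scotland; with every attribute at its worst level the probability falls to
35.0%.  What happens if the linked data became the most expansive type?

```r
typ <- builtin_scenarios()$typical
delta_analysis(typ, "data_type", "health_all_incl_private_sector",
               fit, "Scotland")
#> $P_before  0.824
#> $P_after   0.698
#> $drop_pp   12.6
```

Acceptance drops by 12.6 percentage points.  The full pipeline —
design → simulate → fit → forecast — runs end to end with

```r
res <- run_pipeline(seed = 1, out_dir = "out")
```

or from a shell via the thin CLI in `inst/scripts/dcelink`
(subcommands `design` / `simulate` / `fit` / `forecast` / `pipeline`).

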