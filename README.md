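# vlcost

Micro-costing of centralized HIV viral load testing networks.

In many low-prevalence, low-resource countries every viral load test used to
monitor antiretroviral therapy runs through one national reference
laboratory: the patient travels to a specimen collection site (SCS), the
site draws blood and ships it under cold chain, the laboratory batches
specimens into assay runs, and results wind back through regional
intermediaries. `vlcost` prices that whole chain, tier by tier, for the
three parties that pay for it — the patient, the collection site, and the
laboratory — and then computes what each *delivered* result really costs
once attrition in results reporting is accounted for. It is aimed at health
economists and programme planners costing ART monitoring services, and at
anyone studying the batch economics of kit-based assays.

## The model in brief

**Patient tier.** Per-visit cost at location ℓ:
`c_ℓ = fare_ℓ + nights_ℓ·rate_ℓ + food_ℓ + days_ℓ·wage_ℓ`, averaged over a
site's catchment with patient-count weights, plus patient-weighted medians,
extremes and below-threshold fractions.

**Clinic tier.** Per-specimen cost at the SCS: supplies + labour +
accommodations + transport, with per-session labour amortized over the
collection session and the shipment trip cost amortized over the specimens
per shipment.

**Laboratory tier.** Reagents are consumed by whole kits: a run of `n`
specimens with `c` controls per run and `t` tests per kit uses
`K(n) = ceil((n + c)/t)` kits, so reagent cost per specimen is
`K(n)·p/n` — a sawtooth in `n` with minima at full kits (`n = k·t − c`).
Disposables and labour follow `a/n + b`; facilities enter per specimen.
`optimal_batch()` minimizes the total over `1..n_max`, and
`infer_kit_config()` solves the inverse problem: recover `(t, p)` from
observed reagent costs plus structural constraints (optimal batch,
dominance), reporting ambiguity honestly when the data underdetermine it.

**Delivery.** With fractions `f1` (results reaching the SCS) and `f2`
(reaching the patient), cost per delivered result is `C/f1` and
`C/(f1·f2)`, an attrition increase of `(1/(f1·f2) − 1)·100` percent.

A seeded generator (`generate_network()`) produces synthetic networks with
the assumed structure — near/remote distance mixture, linear fare–distance
law, distance-tiered visit lengths, per-site delivery fractions — so the
pipeline is testable at any scale without field data.

## Worked example

```r
library(vlcost)

net <- reference_network()     # six-site, single-laboratory network
tier_share_report(net)
#>     site patient patient_share clinic clinic_share laboratory laboratory_share  total
#> 1 site 1    3.70           3.7   6.58          6.6      88.73             89.6  99.01
#> 2 site 2    8.90           8.8   3.31          3.3      88.73             87.9 100.94
#> 3 site 3    8.78           8.4   6.41          6.2      88.73             85.4 103.92
#> 4 site 4   10.27           9.0  14.97         13.1      88.73             77.9 113.97
#> 5 site 5   14.93          12.0  20.92         16.8      88.73             71.2 124.58
#> 6 site 6   14.62          13.0   9.48          8.4      88.73             78.6 112.83
```

A test costs $99.01–124.58 depending on the site, and the laboratory tier
(the same $88.73 everywhere, since the network is centralized) is 71–90% of
it. The batch economics behind that laboratory figure:

```r
opt <- optimal_batch(reference_lab_profile(), 24)
opt$n_opt
#> [1] 22
money_round(opt$curve$total[c(10, 11, 22)])
#> [1]  97.15 168.67  88.73
```

A 22-specimen batch fills two 12-test kits exactly (22 specimens + 2
controls); one specimen past a kit boundary (n = 11) nearly doubles the
per-specimen cost. The kit configuration itself can be recovered from the
printed costs alone:

```r
infer_kit_config(data.frame(n = c(10, 22), cost = c(87.50, 79.55)),
                 controls_per_run = 2, optimal_n = 22, n_max = 24,
                 dominant = 10, dominated = 11:19)
#> <kit_configuration> 12 tests/kit @ $875.00, 2 control(s)/run
```

Attrition converts cost per test into cost per delivered result — the
dearest site at the worst observed SCS delivery fraction:

```r
cost_per_delivered_result(124.58, delivery_chain(0.81, 0.99))
#> <delivered_cost_report>
#>   per test performed        124.58
#>   per result at SCS         153.80
#>   per result to patient     155.36
#>   attrition increase           25%
```

`emit_report_tables(net, "out/")` writes the five standard report tables
(tier costs and shares, patient costs, SCS costs, itemized laboratory costs
per batch size, delivery summary) plus a JSON run manifest.
`load_network_config()` / `write_network_config()` round-trip networks
through a strict YAML schema, and a thin command-line front end ships at
`inst/cli/vlcost.R` (verbs `run`, `patient`, `site`, `lab-curve`,
`delivery`, `simulate`, `infer-kit`).

See the vignette (`vignettes/costing-model.Rmd`) for the full model,
calibration notes and limitations.

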