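# vlcea — cost and impact of plasma vs dried-specimen viral load scale-up

`vlcea` is an R package for health economists and laboratory-network
planners weighing how to scale up HIV viral load (VL) monitoring when
plasma — the gold-standard specimen — cannot reach every clinic. Dried
specimens (dried blood spots, DBS; plasma separation cards, PSC) need no
cold chain and restore access at low-volume and remote facilities, but they
misclassify more patients at the 1000 copies/mL failure threshold, and PSC
kits are expensive. The package asks: per patient with a *correct* VL
result, what does each collection strategy cost?

## The model

For a facility panel stratified into high-volume, low-volume reachable and
plasma-unreachable classes, each scenario (plasma only; plasma + DBS;
plasma + PSC; DBS only; PSC only) is evaluated as:

* **Access**: patients/year = Σ round(mᵢ·Nᵢ) with flat multipliers mᵢ
  (0.80 high-volume; 0.40 low-volume plasma, 0.80 dried; unreachable sites
  served only by dried specimens).
* **Cascade**: every patient gets an initial test; a fraction
  q = p·Se + (1−p)·(1−Sp) screens positive and gets one confirmatory
  repeat. The failure prevalence p is calibrated by inverting this
  relation on the base-case plasma volumes (p ≈ 0.1409).
* **Effective performance**: dried specimens split across platforms get
  volume-weighted Se/Sp.
* **Correct results**: N·Se·Sp (product model, default) or
  N·(p·Se + (1−p)·Sp) (prevalence-weighted).
* **Cost**: tests × per-test unit cost (plasma $18.40, DBS $18.93, PSC
  $23.01) + one $3.65 facility visit per test + scenario transport cost.
* **CEA**: average cost-effectiveness ratios vs the plasma-only status
  quo, and ICERs along the efficient frontier after eliminating strict and
  extended (weak) dominance.

A deterministic sensitivity layer sweeps any scalar input by dotted path
and solves break-even prices by root bracketing.

## Worked example

```r
library(vlcea)
fit <- vl_model(default_config(), mode = "golden")
summary(fit)
```

```
Viral-load scale-up cost-outcomes model (mode "golden")
Config 1984ed47, seed 1, version 0.1.0

<vl_cea_table> ordered by effect (correct VL results)
    scenario       cost  effect avg_cer           status   icer
 plasma_only 23 792 767 795 342     ...      undominated    ...
    dbs_only 28 430 049 856 476   75.85 weakly_dominated    ...
    psc_only 31 935 955 884 844   90.98        dominated    ...
  plasma_dbs 28 436 396 920 243   37.18      undominated  37.18
  plasma_psc 29 403 971 929 857   41.71      undominated 100.64

Access vs plasma_only: plasma_dbs +19%, plasma_psc +19%, dbs_only +19%, psc_only +19%
```

Reading: the plasma-only status quo reaches 814,066 patients (795,342 with
a correct result) for $23.8M/year. Adding dried specimens at low-volume
sites lifts access 19% to 965,587. Plasma + DBS is the cheapest route to
an additional correct result ($37.18 vs the status quo); plasma + PSC buys
the most correct results (929,857) at an incremental $100.64 each over
plasma + DBS. The all-dried scenarios are (weakly) dominated — more costly
per correct result than mixtures of the others. And the break-even:

```r
thr <- threshold_solve(default_config(), "unit_costs.psc.consumables",
                       scenario_gap_metric("plasma_psc", "plasma_dbs"),
                       bracket = c(0, 5))
thr$value
#> [1] 2.726595
```

— if the PSC kit price fell from $5.00 to about $2.73, plasma + PSC would
match plasma + DBS per correct result.

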