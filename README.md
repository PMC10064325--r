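# nhabx — antimicrobial stewardship indicators for nursing homes

`nhabx` turns facility-level pharmacy-claims data (dispensings, resident
stays, clinical events) into a consensus set of **24 antimicrobial
stewardship indicators** for nursing homes, classifies each proxy
indicator against its consensus target band, and benchmarks facilities
against regional median/IQR summaries. It is written for
pharmacoepidemiologists and regional stewardship networks who have
reimbursement extracts but no clinical records.

## The indicators

**Quantity metrics (QM1–QM14)** measure prescribing volume from the ATC
hierarchy and WHO defined daily doses (DDD):

* QM1/QM2 — antibiotic (J01) prescriptions and DDDs per 100
  resident-days; QM3 — % residents with ≥1 antibiotic per year
* QM4–QM11 — prescriptions and DDDs per 100 resident-days for
  amoxicillin/clavulanate (J01CR02), cephalosporins (J01D), quinolones
  (J01M) and MLSK (J01F)
* QM12 — % parenteral (IV/IM/SC) among oral + parenteral J01
* QM13/QM14 — urine cultures per 100 resident-days; % residents with
  ≥1 urine culture

**Proxy indicators (PI1–PI10)** estimate appropriateness from claims
alone, each with a target (`optimal` / `acceptable` / `non_compliant`):

* PI1/PI2 — ratio of first-choice urinary drugs to drugs-to-avoid in
  the week following a urine culture, for men and women
* PI3 — % quinolone prescriptions preceded by another quinolone within
  180 days (target: optimal 0, acceptable <10%)
* PI4/PI5 — seasonal variation `(cold/hot − 1) × 100` for all
  antibiotics and for amoxicillin/clavulanate (target <20%)
* PI6 — first-line (amoxicillin ± clavulanate) over second-line
  (quinolones + cephalosporins + MLSK) ratio (target >1.5)
* PI7 — % courses of eight monitored drugs estimated **>7 days** from
  packages dispensed (optimal <5%, acceptable <20%)
* PI8 — % antibiotics with a same-day systemic NSAID (optimal 0)
* PI9 — cold-season flu-vaccine doses per 100 cold-season residents
  (target ≥90%)
* PI10 — % oral among oral + parenteral cephalosporins (optimal <10%)

Since claims carry no prescribed duration, PI7 estimates it as
`packages × units-per-package ÷ units-per-day` from an editable pack
reference; DDDs come from an editable ATC-keyed DDD reference.

## Worked example

The package ships a small hand-checked facility (`f1`, six residents,
1470 resident-days in 2019):

```r
library(nhabx)
demo <- system.file("extdata/demo", package = "nhabx")
loaded <- read_claims_dataset(file.path(demo, "dispensings.csv"),
                              file.path(demo, "stays.csv"),
                              file.path(demo, "events.csv"),
                              analysis_year = 2019)
loaded$report
#> <validation_report> PASS
#>   records: dispensings=18, stays=6, events=8
#>   errors: 0  warnings: 0

fi <- compute_facility_indicators(loaded$dataset, "f1")
fi[fi$indicator_id %in% c("QM1", "QM12", "PI3", "PI7"),
   c("indicator_id", "numerator", "denominator", "value", "compliance_class")]
#> # A tibble: 4 x 5
#>   indicator_id numerator denominator  value compliance_class
#>   <chr>            <dbl>       <dbl>  <dbl> <chr>
#> 1 QM1                 16        1470  1.09  <NA>
#> 2 QM12                 1          16  6.25  <NA>
#> 3 PI3                  2           3 66.7   non_compliant
#> 4 PI7                  2          10 20     non_compliant
```

Reading: this facility dispensed 16 antibiotic prescriptions over 1470
resident-days (1.09/100 resident-days, QM1), one of them parenteral
(6.25%, QM12). Two of its three quinolone courses followed another
quinolone within 180 days (66.7%, PI3 — far above the acceptable <10%
band), and 2 of 10 monitored courses exceeded 7 estimated days (20%,
PI7 — exactly on the strict acceptable bound, hence non-compliant).

The full analysis workflow lives under `analysis/`:

```sh
Rscript analysis/01_simulate.R            # synthetic 20-facility region
Rscript analysis/02_compute_indicators.R  # 24 indicators per facility
Rscript analysis/03_benchmark.R           # regional medians vs ground truth
Rscript analysis/04_facility_reports.R    # per-facility improvement targets
```

Each step prints what it found and writes its tables under `results/`.
Synthetic-data generation (`generate_dataset()`) is seeded and returns
the analytic expectations implied by its parameters
(`expected_indicators()`), so the whole pipeline is testable end to
end; see `vignettes/methods.Rmd` for the generative model, every
convention and threshold, and known limitations.

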