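---
title: "Methods: claims-based stewardship indicators for nursing homes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based stewardship indicators for nursing homes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Nursing-home residents are among the most antibiotic-exposed groups in
high-income countries, yet most facilities have no on-site pharmacy and
no clinical surveillance infrastructure. What *is* available, almost
universally, is reimbursement data: every dispensing by a community
pharmacy generates a claim carrying the resident, facility, date, ATC
drug code, route and the number of packages — but no diagnosis and no
prescribed duration. This package computes a consensus set of 24
indicators of antibiotic use in nursing homes from exactly that claims
structure:

* **14 quantity metrics (QM1–QM14)** measure the *volume* of
  prescribing: dispensing counts and defined daily doses (DDD) per 100
  resident-days, overall (J01) and for amoxicillin/clavulanate
  (J01CR02), cephalosporins (J01D), quinolones (J01M) and MLSK (J01F);
  the share of residents treated; the parenteral route share; and
  urine-culture frequency.
* **10 proxy indicators (PI1–PI10)** estimate the *appropriateness* of
  prescribing without clinical data, each with a consensus target band:
  drug choice after a urine culture by sex, repeat quinolone courses,
  seasonal variation, first- versus second-line balance, prolonged
  courses, NSAID co-prescription, flu-vaccine coverage, and the oral
  cephalosporin share.

All indicators are computed per facility and calendar year, with the
reimbursed dispensing (one drug, one date) as the counting unit, and
are then benchmarked regionally as median (IQR) over facilities.

## Denominators

Exposure is measured in **resident-days**: the sum over stays of the
calendar days shared with the analysis period, counting both endpoints
(a same-day admission and discharge contributes one day). Open-ended
stays are truncated at the period end. Resident counts
(QM3, QM14, PI9) are distinct residents with at least one day of
overlap, regardless of length of stay. Rates are scaled per 100
resident-days; share indicators (QM3, QM12, QM14 and the percentage
PIs) are reported on a 0–100 scale, matching the magnitudes on which
such indicators are conventionally published. For the ratio indicators
(PI1, PI2, PI6) the value is the plain numerator/denominator ratio.

A ratio with a zero denominator is **undefined**, carries a
`zero_denominator` flag, and is excluded from regional medians rather
than coerced to 0 or infinity — proxy-indicator ratios are extremely
dispersed across small facilities, and coercion would distort the
benchmark. A configurable `min_denominator` additionally suppresses
values computed on denominators too small to be meaningful (default 0:
only true zeros are suppressed).

## Event linkage and time windows

* **Urine-culture linkage (PI1, PI2).** A dispensing is
  culture-linked when the same resident has a urine culture dated 0–7
  days *before* it (inclusive of day 0: same-day treatment after
  sampling is the common clinical pattern). The window applies to both
  the numerator and the denominator drug sets; the `uc_window`
  argument makes it configurable.
* **Repeat quinolones (PI3).** A quinolone dispensing counts as a
  repeat when the same resident had another quinolone 1–180 days
  earlier. The look-back crosses the year boundary, so the engines
  accept (and the generator produces) a look-back extract covering the
  180 days before the analysis year; without any pre-year record the
  value carries a `no_lookback_data` completeness flag.
* **Seasons (PI4, PI5, PI9).** Cold-weather season is January–March
  plus October–December of the analysis year; hot-weather season is
  April–September. Seasonal variation is
  `(cold/hot − 1) × 100`.
* **Prolonged courses (PI7).** With durations absent from claims,
  treatment length is estimated from the quantity dispensed:
  `packages × units-per-package ÷ units-per-day`. A course is
  prolonged when the estimate is *strictly* greater than 7 days; a
  course of exactly 7.0 days is not prolonged. Only the eight
  monitored drugs (amoxicillin, amoxicillin/clavulanate, cefuroxime,
  cefpodoxime, roxithromycin, clarithromycin, pristinamycin,
  nitrofurantoin) enter either term.
* **Co-prescription (PI8).** An antibiotic counts when the same
  resident has a systemic NSAID (M01A) dispensing on the *identical*
  calendar date.

## Reference data and conventions

DDD values (`ddd_reference.csv`) and package contents
(`pack_reference.csv`) ship as editable configuration keyed by
7-character ATC code, covering the drugs the indicators name. The DDD
figures follow the WHO convention (grams per assumed daily dose); the
units-per-day values used for duration estimation are implementation
choices — one therapeutic dose rhythm per drug (e.g. 2 units/day for
14-unit amoxicillin packs, 3 units/day for 21-unit nitrofurantoin
packs), chosen so that one standard package corresponds to a 7-day
course for the monitored oral drugs. Users with market-specific
package data should replace these tables.

Further conventions, each chosen where the indicator definitions are
silent:

* **Unknown values are explicit** (`unknown` route and sex, `NA`
  units), never imputed. Records with unknown route are excluded from
  both terms of the route-share indicators (QM12, PI10) and counted in
  a data-quality flag, to avoid biasing the share either way.
* **Flu vaccines** are recognized either as `flu_vaccine` events or as
  dispensings with ATC prefix J07BB (the influenza-vaccine class); the
  numerator counts doses dispensed, not vaccinated residents, so
  values above 100 are possible and flagged (`over_coverage`); a
  distinct-resident variant exists behind a flag and is marked as
  deviating from the dose-count definition.
* **PI9 denominator**: any resident with ≥1 cold-season stay-day
  counts (no minimum stay).
* **Duplicate same-day, same-drug rows** count separately — claims
  extracts legitimately contain repeat dispensings — unless
  `dedupe = TRUE`.
* **Compliance bands** follow the printed target symbols exactly:
  strict `<`/`>` where stated (e.g. seasonal variation at exactly 20
  is non-compliant; a drug-choice ratio of exactly 1.5 is
  non-compliant), inclusive `≥ 90` for flu coverage, and "optimal 0"
  meaning exactly zero. Three bands (optimal / acceptable /
  non-compliant) where two bounds exist, two bands otherwise;
  undefined values classify as `undefined`.
* **Quartiles** use linear interpolation (`stats::quantile` type 7) so
  that reported IQRs are reproducible across implementations; the
  regional summary publishes nothing on fewer than 2 defined values
  (configurable). Percentile ranks in facility reports use the midrank
  convention.

## The synthetic region

Real national reimbursement microdata are not redistributable, so the
package ships a generator whose output has the same structure and a
known generative truth. Its central design principle: **all antibiotic
dispensings of a resident come from a single Poisson budget** at
`abx_rate` per 100 resident-days. Urinary-tract episodes, drug class,
route and package count are *marks* on that budget, never additional
insertions — so the expected QM1 equals `abx_rate` exactly and
parameter recovery is a meaningful end-to-end test. Seasonality is
applied as per-day sampling weights (`m·H/C` on cold days, with H and
C the hot/cold season day totals), making the expected cold/hot count
ratio exactly the seasonal multiplier `m` and the expected PI4 equal
to `(m − 1) × 100` for full-year stays.

The default preset is *france-2019-like*: 20 facilities of ~90
residents (SD 35), 75% women, mean age 87, 25% turnover, 0.52 J01
dispensings and 0.15 urine cultures per 100 resident-days, 30% winter
excess, 9% parenteral share, 50% two-package dispensings, 2% NSAID
co-prescription and 81% flu coverage — plausible magnitudes for
community nursing homes, documented as illustrative rather than as a
reproduction of any published population.

`expected_indicators()` returns the implied expectation for each
indicator with a `basis` column: `analytic` (exact for long stays),
`approximate` (ratio-of-expectations for PI1/PI2, which ignores
accidental culture links of non-UTI dispensings, and a
Poisson-thinning argument for PI3), or `none` (QM3 and QM14 depend on
the distribution of stay lengths and have no useful closed form).
Window-linked truth is additionally available from the per-record
`tags` (origin: `base`, `uti`, `fq_repeat`, `nsaid`, `lookback`).

What the generator deliberately does **not** emulate: transmission or
resistance dynamics, prescriber-level behaviour, facility case-mix
differences, coding errors, or hospital-dispensed antibiotics.
Passing tests therefore demonstrate that the indicator arithmetic,
linkage windows and classification logic are correct on data of the
documented structure — not that the indicators are valid measures of
appropriateness in any real population.

## Verification strategy and problem sizes

Three independent routes check the engines:

1. **A hand-enumerated composite fixture** (6 residents, 1470
   resident-days, 17 in-year dispensings, one look-back row, 4 urine
   cultures, 4 vaccinations) exercising every indicator; all 24 values
   and their compliance classes are frozen in the tests from manual
   enumeration of the CSVs.
2. **A naive reference implementation** (per-record loops, day-by-day
   exposure counting, written independently of the engine code) is
   compared with the engines on 100 randomized micro-datasets of up to
   ~80 records each, to within floating-point round-off.
3. **Parameter recovery**: over 40 seeds of a 10-facility region with
   ~50 residents per facility, the pooled regional estimates of QM1,
   QM12, PI4, PI6, PI8 and PI9 must lie within 3 Monte-Carlo standard
   errors of their analytic expectations. Pooled (summed
   numerator/denominator) estimators are used for the ratio-form
   indicators because facility-level ratio averages carry a small
   Jensen bias at these denominator sizes.

These sizes keep the whole suite to a few minutes on one core while
leaving the Monte-Carlo bands tight enough to detect percent-level
systematic errors.

## Known limitations

* Duration estimation inherits the package-content assumptions; it
  cannot see dose adjustments, and a deliberately long low-dose course
  is indistinguishable from a standard one.
* One multi-drug prescription appears as several dispensing rows and
  is counted as several "prescriptions"; the claims structure does not
  distinguish them.
* PI1/PI2 apply the culture window to both numerator and denominator
  drugs; cultures and dispensings recorded in different facilities for
  the same resident still link (resident-level linkage).
* The regional benchmark is a crude median over facilities: no age,
  sex or case-mix adjustment is attempted, mirroring how such
  indicators are published.
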