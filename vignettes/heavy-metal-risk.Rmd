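---
title: "Assessing dietary heavy-metal and ethanol risk in alcoholic beverages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing dietary heavy-metal and ethanol risk in alcoholic beverages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmrisk)
library(dplyr)
```

## The model

`hmrisk` implements the US EPA deterministic framework for chronic dietary
exposure to chemical mixtures, applied to trace metals and ethanol in
spirits. For a consumer ingesting a drink with contaminant concentration
$M_C$ (mg per kg of drink), the lifetime **average daily intake** is

$$
\mathrm{ADI} \;=\; \frac{M_C \cdot IR \cdot CF \cdot EF \cdot ED}{BW \cdot AT_n}
\quad \left[\tfrac{\text{mg}}{\text{kg}\cdot\text{day}}\right]
$$

with $IR$ the ingestion rate (g/day; $CF = 10^{-3}$ converts grams to kg),
$EF$ the exposure frequency (day/year), $ED$ the exposure duration
(years), $BW$ body weight (kg) and $AT_n$ the averaging time (days).
Non-cancer risk per analyte is the **target hazard quotient**
$\mathrm{THQ} = \mathrm{ADI}/\mathrm{RfD}$, where RfD is the oral
reference dose; quotients are summed over co-occurring analytes into the
**hazard index** under an additivity assumption, interpreted as *safe*
(HI < 1), *concern* (1 ≤ HI < 5) or *high* (HI ≥ 5), with a "1-in-x"
reading ($x = \operatorname{round}(1/\mathrm{HI})$) for sub-unit indices.
Lifetime **carcinogenic risk** is $\mathrm{CR} = \sum \mathrm{ADI}_a
\cdot \mathrm{CSF}_a$ over the analytes with a cancer slope factor (As,
Cr(VI), Pb in the shipped reference table); all other analytes are
reported as excluded rather than silently contributing zero.

The default exposure profile is the adult sachet-consumption scenario of
the Acoli (northern Uganda) study population: 2.5 sachets of 100 mL 40%
(v/v) spirit per day, giving an ethanol-mass ingestion rate of
$2.5 \times 100 \times 0.40 \times 0.7854 = 78.54$ g/day; drinking on 5
days a week (EF = 240 day/year); consumption from age 15 over a
58.65-year life expectancy (ED = 43.65 years; $AT_n$ = 21,407 days); body
weight 60 kg.

```{r adi}
profile <- acoli_exposure_profile()
adi_ethanol <- average_daily_intake(ethanol_mc(40), profile)
signif(adi_ethanol, 3)                       # 256 mg/kg/day
signif(target_hazard_quotient(adi_ethanol, 62), 2)  # THQ 4.1
```

### Unit conventions and the two ethanol modes

Metal levels are measured in µg/L; $M_C$ requires mg per kg of drink. The
package adopts a drink density of 1 kg/L (µg/L ≡ µg/kg), so
$M_C = \text{level} \times 10^{-3}$; the density is a profile field for
users who want a different convention. For ethanol, the default
`mass_fraction` convention treats an x% (v/v) drink as x g ethanol per
100 g of sample, i.e. $M_C = x/100 \times 10^6$ mg/kg. This is the only
convention that reproduces the published intake of 256 mg/kg/day with
the parameters above; the literal tabulated value of 4000 mg/kg is
retained as the selectable `table2` convention for comparison.

The ethanol pathway additionally supports two arithmetic **modes**. Mode
`"paper"` (default) reproduces the published calculation, in which the
ingestion rate is already an ethanol mass *and* $M_C$ is the ethanol
mass fraction — the 40% strength therefore enters twice, and the result
(256 mg/kg/day, THQ 4.1) matches the published table. Mode `"strict"`
removes the double count by setting ethanol $M_C = 10^6$ mg/kg (the
ingested IR mass *is* ethanol), giving ≈ 641 mg/kg/day. We default to
faithful reproduction and expose correctness as an option; the mode is
recorded in the run manifest.

Similarly, ED is stored in years and $AT_n$ in days, exactly as the
published parameter table uses them. The quotient $ED/AT_n$ is therefore
not dimensionless — the equation is evaluated as printed, which is what
reproducibility requires.

## Non-detects and descriptive statistics

Censored cells (below the per-analyte method detection limit) are never
silently imputed: the censoring flag travels with the panel, and a
substitution policy — `zero` (default), `half_mdl` or `mdl` — is applied
explicitly and recorded. The source tables this layout emulates show
near-zero entries for the faint analytes, which motivates `zero` as the
conservative default; because the original substitution rule is not
documented, the policy is a switch rather than a constant, and every
downstream risk figure is monotone non-decreasing along
zero → half-MDL → MDL (a property the test suite checks end-to-end).

Quartiles use linear interpolation between order statistics at position
$p(n-1)+1$ (`stats::quantile` type 7, the common spreadsheet
convention); the convention is recorded on the summary so that any other
convention can be swapped in for comparison against historical software.
The sample standard deviation uses the $n-1$ denominator. The outlier
rule is the strict inequality mean $> 2\times$IQR — with the study-like
panels, Cu trips it and nothing else does.

```{r descriptive}
gen <- generate_panel(generator_config(seed = 7))
summarize_analytes(gen$panel) |>
  filter(outlier)
```

## The risk surface of a panel

`assess_risk()` runs the full four-step assessment over a panel:

```{r assess}
assessment <- assess_risk(gen$panel, profile = profile)
assessment
glance(assessment)
```

The THQ matrix is also emitted **row-percentage transformed** (each
brand's quotients rescaled to sum to 100): a compositional view that
keeps the Cu-dominated artisanal brands from swamping every other
signal when profiles are compared. Whether the published per-brand
hazard indices were computed from raw or row-percent quotients cannot be
established from the printed material alone, so both are emitted: `hi`
carries the raw sums, and `hi_analyte` (the per-analyte index across
brands) is the column sum of the row-percent matrix. The "1-in-x" ratio
uses nearest-integer rounding of 1/HI; some published rows are not
internally consistent under any fixed rounding rule, and no attempt is
made to match those.

## Cluster analysis of THQ profiles

Brand (or metal) risk profiles are compared by agglomerative clustering
under **Ward's minimum-variance criterion** on **squared Euclidean**
distances, implemented from scratch via the Lance–Williams recurrence.
Design choices that the dendrogram depends on:

* **Heights** are the Lance–Williams distances (twice the
  within-cluster sum-of-squares increment), under which squared
  Euclidean input admits no inversions; the published dendrogram axis
  convention is unknown, so ours is documented rather than matched.
* **Tie-breaks** on equal merge costs take the candidate pair with the
  lexicographically smallest pair of smallest leaf indices, so runs are
  reproducible across platforms.
* **Exclusions** default to Cu (the flagged outlier) and ethanol (a
  constant across brands), mirroring the published procedure; they are
  plain config lists, and excluding an analyte is the exact identity of
  deleting its column (tested as such).
* **No column standardization** is applied beyond the row-percent
  transform; whether the original analysis standardized cannot be
  determined, and the row-percent scale is already commensurate.

Dendrogram fidelity is measured by the cophenetic correlation, and
cluster stability by the published randomization: items receive random
numbers, are sorted and split into halves, each half is re-clustered and
compared to the full partition. The original account does not name a
quantitative agreement statistic, so we use pairwise co-membership
agreement (a Rand index) restricted to the half's items.

```{r cluster}
cl <- cluster_thq(assessment, exclude = c("Cu", "ethanol"), k = 3)
signif(cl$cophenetic, 4)
stability <- split_half_stability(cl$matrix, n_splits = 10, seed = 42)
attr(stability, "mean_agreement")
```

The published dendrogram coefficients (0.8952 for metals, 0.9494 for
brands) and exact memberships derive from supplementary THQ tables that
are not printed; they are deliberately **not** acceptance-matched.
Instead the clustering layer is validated against an exhaustive greedy
oracle on small instances, against its no-inversion and
permutation-invariance properties, and by planted-structure recovery on
synthetic panels.

## What the synthetic generator emulates — and what it does not

The generator is the package's stand-in for the study's ICP-MS
measurements and the ground truth for pipeline validation. It emulates:

* ~18 brands × 20 metals, with per-analyte **log-normal** baselines
  (positive, right-skewed trace-element levels; medians set at the low,
  industrial end of the observed summaries with `sdlog = 0.5`);
* an **artisanal class** whose Cu is elevated by a systematic
  condensation-tube mechanism: the boost (default 1200×, landing in the
  observed 1230–12100 µg/L range) multiplies the baseline Cu median,
  with a tighter dispersion (`sdlog = 0.25`) than ambient baselines
  because the contamination source is process-driven. Artisanal Cu then
  exceeds all other metals combined, as in the real panels. A boost of
  1 disables the mechanism entirely, giving the negative control;
* one **outlier brand** with every metal multiplied by 10 (the
  many-metal contaminated brand), which dominates the industrial hazard
  ranking but — being a uniform rescaling — is row-percent invisible,
  exactly as a compositional view implies;
* **duplicate-measurement noise**: mean-one log-normal with CV 5%, with
  the duplicate SD recorded as CV × level;
* **left-censoring** at per-analyte MDLs chosen so the faint analytes
  (Be, Cd, Ag, Tl, V) are frequently non-detected.

Deliberately not emulated: instrument drift, isobaric interference,
calibration error, and correlated contamination across metals
(each analyte is drawn independently). Consequently, passing tests show
the pipeline recovers structure the generator plants; they do not show
that real spirits data contain such structure, nor can they validate
the published supplementary values. Baseline brand-to-brand dispersion
is conservative (the real spread between the cleanest and dirtiest
industrial brands is wider); the explicit outlier and artisanal
mechanisms, not the baseline tails, carry the extremes.

Estimation in the parameter-recovery suite uses the closed-form
Gaussian MLE on log levels when nothing is censored and the censored
log-normal likelihood (`fitdistrplus::fitdistcens`) otherwise.

```{r recovery}
cfg <- generator_config(seed = 100, n_industrial = 30, n_artisanal = 0,
                        outlier = FALSE, include_ethanol = FALSE)
cfg$analytes$mdl <- 0
parameter_recovery_suite(cfg, n_reps = 20) |>
  summarise(median_std_bias = median(abs(bias / se)))
```

## Numerical and degenerate-input conventions

* Missing RfD → THQ `NA`, listed as excluded; never zero.
* All-zero brand rows in compositional shares, and all-zero rows in the
  row-percent transform, are reported missing, not as zeros.
* Zero carcinogenic risk reports infinitely many persons per case, not
  an error; `persons_per_case(CR) × CR ≈ 1` otherwise.
* Hazard boundaries are half-open: HI = 1 is *concern*, HI = 5 is
  *high*; the outlier rule is strict (mean exactly 2×IQR is not an
  outlier).
* A censored cell with no recorded MDL is an error under every policy —
  the package refuses to guess a detection limit.
* Cut heights partition by merges strictly below the threshold, so a
  cut at height 0 returns singletons.

## Problem sizes used by the validation suite

The test and acceptance suites run entirely on synthetic and in-text
data: oracle equivalence on 200 random instances of up to 7 items;
planted-structure recovery over 100 seeded 18-brand panels;
parameter recovery over 200 replicates of 50-brand panels. These sizes
give stable Monte-Carlo estimates of the properties checked (e.g. a
95% recovery criterion estimated from 100 runs) while keeping the whole
suite in the one-minute range on a single core.

## Known limitations

* Ingestion is the only exposure route; no dermal or inhalation terms.
* Deterministic point estimates only — no Monte-Carlo exposure
  distributions.
* Additivity of THQs ignores synergistic or antagonistic interactions,
  and bioaccumulation kinetics are out of scope.
* The shipped RfD/CSF table is a convenience snapshot with per-row
  provenance strings; users with regulatory requirements should supply
  their own reference table.
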