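---
title: "Candidate-gene analysis of fattening performance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene analysis of fattening performance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fattenassoc)
```

## The analysis this package implements

Candidate-gene association studies in fattening cattle ask whether
genotypes at a small panel of biallelic SNP markers — typically in genes
involved in appetite regulation, lipid metabolism and growth (leptin,
fatty-acid binding proteins, calpain/calpastatin, growth hormone receptor,
IGF1, and similar) — are associated with growth and feed-efficiency
phenotypes. The design analysed here is a single commercial cohort of
fattening bulls weighed monthly on a scale with 100 g sensitivity and fed
ad libitum with daily dry-matter-intake (DMI) recording, with all animals
slaughtered once they pass the last of a ladder of target body weights
(by default 100, 200, 300, 400 and 450 kg, labelled W1–W5).

`fattenassoc` covers the full chain:

1. **Trait derivation** from raw weigh/feed records (`derive_traits()`).
2. **Marker characterisation**: allele frequencies, Hardy–Weinberg tests
   and diversity indices (`popgen_summary()`).
3. **Association**: a fixed-effects linear model per marker × trait with
   least-square means, Tukey groupings and an interaction mechanism
   (`assoc_scan()`, `fit_model()`, `fit_interaction()`).
4. **Gene action**: additive and dominance effects from genotype means
   (`gene_action_table()`).
5. **Synthetic herds** with planted genotype effects
   (`simulate_herd()`), so that every stage is testable end to end
   against known truth.

## Trait definitions

For each animal the day on which a target weight is first attained
(*days to reach*, DTR) is obtained by linear interpolation between the two
weigh records bracketing the first upward crossing; a record hitting the
target exactly returns that day, and when a series dips locally the first
upward crossing wins. No extrapolation is performed: an animal whose
records never reach a target is excluded from every trait anchored at that
target, and the exclusion is logged with a machine-readable reason.

Between consecutive targets $W_a$ and $W_b$:

* fattening period $\mathrm{FP} = \mathrm{DTR}_b - \mathrm{DTR}_a$ (days);
* interval intake $\mathrm{DMI}$ sums the daily feed records over
  $[\mathrm{DTR}_a, \mathrm{DTR}_b)$, pro-rating the boundary days by
  fractional coverage, because DTR is fractional while feed is recorded
  per calendar day;
* $\mathrm{DDMI} = \mathrm{DMI}/\mathrm{FP}$,
  $\mathrm{ADWG} = (W_b - W_a)/\mathrm{FP}$ and
  $\mathrm{FCR} = \mathrm{DMI}/(W_b - W_a)$, with the *target* gain
  (exactly 100 or 50 kg) as the FCR denominator.

These definitions force the identity
$\mathrm{FCR} \times \mathrm{ADWG} = \mathrm{DDMI}$, which the test suite
asserts to machine precision on every simulated animal — a cheap, strong
internal-consistency check on the whole feed-integration path.

Whole-window totals (TDMI, TDDMI, TFCR, TADWG) run from
$\mathrm{DTR}_{W1}$ to the final weighing, with the final recorded weight
as FW. Anchoring totals at the first analysed target rather than at
fattening day 0 is a design choice: W1 is the first state common to all
analysed animals, and it keeps the totals comparable across animals that
entered the unit at different weights.

Season is assigned by meteorological quarter (Dec–Feb winter, Mar–May
spring, Jun–Aug summer, Sep–Nov autumn); source datasets in this field
rarely state their season boundaries, and the meteorological convention is
the least surprising default for temperate-zone husbandry data.

## Marker characterisation

From genotype counts $(n_{11}, n_{12}, n_{22})$ the first-allele frequency
is $p = (2n_{11} + n_{12})/2n$ by gene counting. The diversity indices are
the classical Botstein set, generic in the number of alleles:

$$H_o = \sum_i p_i^2, \quad H_e = 1 - H_o, \quad N_e = 1/H_o, \quad
\mathrm{PIC} = H_e - \sum_{i<j} 2 p_i^2 p_j^2 .$$

$H_o + H_e = 1$ and $N_e H_o = 1$ hold identically, and for a biallelic
marker PIC is maximised at $p = 0.5$ (PIC $= 0.375$); the suite checks all
three properties over randomly generated frequency vectors.

Hardy–Weinberg equilibrium is tested with the Pearson chi-square of the
observed counts against $n(p^2, 2pq, q^2)$ on one degree of freedom (three
genotype classes minus two estimated allele frequencies), without
continuity correction; a class with zero observed count still contributes
$E$ to the statistic, which is what makes a cohort with a missing
homozygote class strongly significant.

One reporting convention deserves a note. Published marker tables print
allele frequencies to two decimals, and the diversity indices printed next
to them are, in the sources this package is benchmarked against,
internally consistent with those *rounded* frequencies rather than with
the exact count-derived ones (the difference reaches the third decimal of
$H_e$ when $p$ is far from a two-decimal grid point). `popgen_summary()`
therefore exposes `freq_digits` (default 2): the indices in the summary
are computed from the frequencies at their reporting precision, so the
printed table is reproducible from its own columns. Pass
`freq_digits = NULL` for exact-frequency indices. The chi-square test
always uses exact frequencies — that is the convention under which the
published statistics reproduce to three decimals.

## The association model

Each trait is analysed marker by marker with the fixed-effects model

$$y_{ijk} = \mu + \beta A_i + S_j + G_k + e_{ijk},$$

where $A_i$ is the animal's age (days) at the trait's reference point
(the target weight for DTR traits, the interval end for interval traits,
slaughter for totals and FW), $S_j$ the season at that same anchor and
$G_k$ the genotype. All terms are fixed; no random term is specified, so
ordinary least squares is the estimator (`stats::lm`). Genotype classes
are typically very unbalanced (a common homozygote with >200 animals next
to a rare one with 10), so per-term p-values are partial (Type III) F
tests — each term assessed against the model with that term dropped — via
`drop1()`; for these additive models this equals the classical Type III
analysis and is order-invariant.

Least-square means are predictions at the covariate grand mean with equal
weight on every season level, with standard errors from the coefficient
covariance (the `emmeans` reference grid). Pairwise genotype contrasts use
the Tukey–Kramer adjustment on the studentized-range distribution with the
residual degrees of freedom, and the compact letter display is assigned
greedily from the largest mean downward (ties broken by level name):
levels sharing no letter differ at $\alpha$.

Two-locus interactions are handled by crossing the genotype factors into a
combined factor (`"CCxAA"`); combinations observed fewer than `min_count`
times (default 3) are excluded before fitting and logged. The literature
excludes "very low frequency" combinations without quantifying the
threshold; three is the smallest class size for which a within-class
variance contribution is even defined, and the flag is configurable.

Model choice between candidate specifications uses adjusted $R^2$
(`compare_models_r2()`), with ties resolved toward fewer parameters and
then deterministically by position. No multiplicity correction is applied
across the marker × trait grid — that matches the practice of the studies
this mirrors, where $P < 0.05$ is reported per test — but a
Benjamini–Hochberg FDR column is emitted alongside for the reader; it
never gates any output.

## Gene action

With genotype means (least-square means, not raw means) $\bar y_{11},
\bar y_{12}, \bar y_{22}$ ordered by lexically sorted alleles, the
single-locus decomposition is

$$a = \frac{\bar y_{22} - \bar y_{11}}{2}, \qquad
  d = \bar y_{12} - \frac{\bar y_{11} + \bar y_{22}}{2},$$

with degree of dominance $d/a$, left undefined (flagged, not divided)
when $|a|$ is below a tolerance of about $10^{-9}$ of the trait scale.
The reconstruction identity — midpoint $\pm a$ and midpoint $+ d$ recover
the three means exactly — is asserted property-style. A marker missing a
homozygote class (as happens in real cohorts) yields a `not_estimable`
flag rather than a dropped or fabricated row.

## The synthetic herd generator

The generator is first-class, tested code, not a fixture. It emulates the
study conditions the analysis assumes:

* **Cohort**: 296 animals by default; 15 biallelic markers whose allele
  frequencies and Hardy–Weinberg departures are parameterised from the
  packaged genotype-count table (`default_marker_panel()`), so the
  simulated marker panel has the same frequency spectrum — including one
  marker with a missing homozygote class — as a real genotyped cohort.
* **Genotypes**: class probabilities $p^2 + fpq,\; 2pq(1-f),\; q^2 + fpq$
  with a single inbreeding-like $f$ per marker. One interpretable knob
  reproduces any observed heterozygote deficit or excess;
  `solve_hwe_departure()` inverts observed proportions to $f$.
* **Growth**: a daily latent-gain scale — baseline ADWG (0.90 kg/day,
  the scale of commercial Holstein fattening), plus the marker genotype
  values $(-a, d, +a)$, a seasonal shift (±0.02–0.03 kg/day by
  meteorological quarter), and a per-animal effect
  ($\mathrm{SD} = 0.08$ kg/day). Planting effects on the latent daily
  gain makes them exact on the ADWG scale the analysis estimates.
  Observed weigh records perturb each weigh-to-weigh interval gain so the
  observed interval ADWG has SD exactly `residual_sd` (0.05 kg/day)
  around its latent mean, and are recorded at 0.1 kg resolution (the
  scale's sensitivity). Initial weight is 85 ± 7 kg, placing fattening
  start just below the first 100 kg target; slaughter is the first weigh
  past the last target.
* **Intake**: $\mathrm{DMI} = c\,W^{0.75} + \text{genotype value} +
  \varepsilon$ with $c = 0.105$ kg per kg$^{0.75}$ per day and daily noise
  0.3 kg — metabolic-weight scaling spanning roughly 4.9 kg/day at 150 kg
  to 9.8 kg/day at 425 kg, the DDMI range of commercial fattening data.
  With the growth defaults this yields cohort mean TADWG inside the
  0.85–0.95 kg/day band typical of published Holstein fattening cohorts.
* **Reproducibility**: all randomness flows from one integer seed; each
  animal draws from a substream keyed by its index, so any animal's
  records are bit-identical whether it is simulated alone or within a
  larger cohort, and identical seeds give byte-identical CSV output.

With every noise term at zero the trajectories collapse to closed forms
(weight $W_0 + gt$, intake $c (W_0 + gt)^{0.75}$), which the tests use as
exact oracles for the whole trait-derivation layer.

What the generator does *not* emulate: pedigree/sire structure (the
target design genotypes few progeny per sire and fits no sire effect),
climate-performance links beyond additive season shifts, ration changes
(grower/finisher), illness or culling, and genuine measurement artefacts
such as gut-fill swings. Passing tests on synthetic herds therefore show
that the estimators recover what the generating model planted under
realistic noise — not that any particular real-data association is true.

## Calibration and recovery checks

Three statistical acceptance properties are simulated at the study's own
scale (n = 296):

* the Hardy–Weinberg test holds its nominal size (rejection rate
  0.05 ± 0.02 over 1000 cohorts drawn in equilibrium);
* the genotype partial-F test holds its nominal size over 1000 null
  cohorts with age and season effects present but no genotype effect;
* a planted additive effect of 0.05 kg/day on daily gain is recovered by
  the full simulate → traits → model → gene-action path within two
  standard errors of the replicate mean over 100 herds.

The recovery check deliberately fits the *marginal* one-way genotype
model. For a growth trait, the age and season at the trait's reference
point are downstream consequences of the genotype (a faster-gaining
genotype reaches every target younger and in a different season):
mediators, not confounders. Conditioning on them attenuates the total
genotype effect — in pilot runs the full covariate model recovered only
about 0.04 of a planted 0.05 kg/day — so the unbiased comparison for
parameter recovery is the marginal model, while the covariate-adjusted
model remains the default for the association scan, where the covariates
control environmental variation exactly as in the mirrored study design.
Users comparing genotypes on growth traits should be aware of this
attenuation when interpreting covariate-adjusted LSMs.

## Numerical choices and degenerate inputs

* Interpolation tie-break: the first upward crossing defines DTR on a
  locally decreasing series; an exact hit returns the record's day.
* Boundary feed days are pro-rated by fractional coverage; an empty
  window integrates to zero, and a zero-length fattening period is a
  degenerate-interval error rather than an Inf.
* Monomorphic markers make the Hardy–Weinberg statistic undefined and
  raise an error naming the marker; an empty cohort errors at the
  frequency stage.
* Singular association designs (fully confounded factor levels) raise a
  `singular design` error naming the aliased terms instead of silently
  dropping coefficients.
* Genotype strings are normalised by sorting allele symbols, so `"TC"`
  and `"CT"` are one heterozygote class everywhere.
* Test problem sizes — 296-animal cohorts, 1000-replicate calibration
  loops, 100-herd recovery, 20 randomized oracle designs of n ≤ 30 —
  are the package's chosen balance between statistical resolution and a
  test suite that runs in a few minutes.

## Known limitations

* Only biallelic markers are modelled end to end; the diversity formulas
  accept general frequency vectors but the simulator and counting layer
  are two-allele.
* The association stage fits fixed effects only; cohorts with strong
  family structure need a relationship-matrix model this package does not
  provide.
* Published tables in this field sometimes carry internal inconsistencies
  (sign slips, un-halved homozygote differences, misprinted cells); the
  packaged reference tables reproduce the sources verbatim, and the test
  suite documents — rather than silently corrects — the cells that do not
  reconstruct from their own inputs.
* DTR values in the mirrored study design are ages from birth, whereas
  this package's day scale starts at fattening; the mechanics are
  identical, but absolute DTR magnitudes are not comparable across the
  two conventions.
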