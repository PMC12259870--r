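---
title: "Methods: seasonal spring-water quality and health-risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal spring-water quality and health-risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(springrisk)
```

springrisk implements an integrated assessment workflow for seasonal
spring-water chemistry: quality-control of the ionic analysis,
hydrochemical facies classification, composite water-quality and
contamination indices, deterministic and probabilistic human health
risk, and corrosion/scaling potential. This vignette is the package's
own account of the models it implements, the parameters that matter,
the numerical choices made where conventions diverge, and what the
synthetic test bed does and does not demonstrate.

## Data model and units

A dataset is a plain `data.frame`, one row per site x campaign, with
fixed units: concentrations in mg/L (columns named by chemical symbol:
`Ca`, `Mg`, `Na`, `K`, `HCO3`, `Cl`, `SO4`, `NO3` and eleven trace
metals), `temperature` in °C, `ph` in pH units, `ec` in µS/cm. Values
reported below a method detection limit are stored *at* the detection
limit with a logical flag (the `bdl` attribute, serialised as `<value`
tokens in CSV). Substituting the MDL itself — rather than MDL/2 or
zero — reproduces the arithmetic convention of monitoring reports that
print censored metals as a constant (lead at 0.002 mg/L is the
motivating case), and the flag preserves the information for readers
who prefer another convention.

Milliequivalent conversion uses fixed two-decimal equivalent weights
(`equivalent_weights()`): Ca 20.04, Mg 12.15, Na 22.99, K 39.10,
HCO₃ 61.02, Cl 35.45, SO₄ 48.03, NO₃ 62.00 g/eq. They are exposed as a
function argument so alternative rounding conventions can be injected;
every meq-based quantity in the package flows through this one
conversion.

The charge-balance error is

$$\mathrm{CBE} = 100\,\frac{\sum mc - \sum ma}{\sum mc + \sum ma}$$

in meq/L, sign preserved, with the conventional ±5 % acceptance band.
Derived bulk quantities fill only what is absent: TDS as the sum of
major ions (an EC-based estimate, 0.64 × EC, is behind an explicit
option because it is dataset-dependent), alkalinity as
HCO₃ × 50.04/61.02 mg/L as CaCO₃, calcium hardness as
Ca × 100.09/40.08, and total hardness from the Ca and Mg equivalents.
Carbonate ion is taken as zero throughout: all waters handled here sit
well below pH 8.3, where CO₃²⁻ is negligible.

## Hydrochemical facies

`piper_coordinates()` reduces each sample to cation percentages (Ca,
Mg, Na+K as meq % of total cations) and anion percentages (HCO₃, SO₄,
Cl). The facies label follows the diamond-quadrant dominance rule —
alkaline earths versus alkalis, weak acids versus strong acids —
yielding the four canonical types (Ca–Mg–HCO₃, Ca–Mg–Cl/SO₄, Na–Cl,
Na–HCO₃). `chadha_coordinates()` is the same information folded into
two axes, x = (Ca+Mg) − (Na+K) and y = HCO₃ − (Cl+SO₄); its x equals
the Piper (%Ca + %Mg) − %NaK identically, which the tests exploit as a
cross-module consistency check. Quadrants map to recharge, reverse
ion exchange, seawater-type and base-exchange waters.

`gibbs_ratios()` follows the original mass-concentration convention
(Cl/(Cl+HCO₃) and Na/(Na+Ca) in mg/L; a meq variant is an option). The
boomerang-shaped mechanism fields are approximated by documented
rectangular boxes: a ratio ≥ 0.5 with TDS ≤ 100 mg/L is labelled
precipitation-dominated, with TDS ≥ 1000 mg/L evaporation-dominated,
and everything else rock weathering. The rectangles are deliberate:
they are reproducible constants rather than digitised curve polygons,
and at the TDS ranges of upland springs (roughly 150–450 mg/L) the two
conventions agree.

The chloro-alkaline indices use the Schoeller definitions,
CAI-I = (Cl − (Na+K))/Cl and CAI-II = (Cl − (Na+K))/(SO₄+HCO₃+CO₃+NO₃),
all in meq/L. NO₃ is kept in the CAI-II denominator (the full Schoeller
form); at drinking-water nitrate levels its influence on the sign — the
only interpreted feature — is negligible. Positive values indicate
reverse ion exchange, negative direct exchange; with Cl = 0, CAI-I is
undefined and the label falls back to CAI-II.

Na-normalised end-member ratios (Ca/Na, Mg/Na, HCO₃/Na, NO₃/Na, SO₄/Na,
Cl/Na) are molar, the convention of silicate/carbonate end-member
diagrams, while the bivariate pairs (Ca+Mg vs SO₄+HCO₃, Na vs Cl, …)
are in meq. The (Ca+Mg)/HCO₃ equivalent ratio is reported with its
conventional 0.5 interpretation threshold.

## Quality and contamination indices

**CWQI.** The CCME index combines scope
(F1 = 100 × failed parameters / total parameters, a parameter counting
once however many of its tests fail), frequency (F2 = 100 × failed
tests / total tests) and amplitude. Excursions are value/objective − 1
for ceiling objectives and objective/value − 1 for floors; their sum
over all tests divided by the number of tests is nse, and
F3 = nse/(0.01 nse + 0.01). The score is

$$\mathrm{CWQI} = 100 - \frac{\sqrt{F1^2 + F2^2 + F3^2}}{1.732},$$

floored at zero, with bands 95–100 Excellent, 80–94 Good, 65–79 Fair,
45–64 Marginal, 0–44 Poor. Two printed-source ambiguities are resolved
here: the score formula is the standard CCME 2001 form (the only one
that keeps scores in [0, 100] and reproduces published "Good" values
from the same inputs), and a score of 96.52 is classified *Excellent*
per the banding table even though narrative summaries sometimes call
such values "Good" — the table is taken as authoritative. A parameter
may carry both a floor and a ceiling (pH does); each measurement is one
test regardless of how many bounds it is checked against.

**HPI** is the weighted mean of sub-indices Qᵢ = 100 Cᵢ/Sᵢ with weights
Wᵢ = 1/Sᵢ, where Sᵢ is the drinking-water standard; weights are used
as-is, not renormalised. The published five tiers overlap as printed;
they are resolved into disjoint ordered bands preserving every stated
boundary: < 15 Excellent, 15–30 Good, 30–76 Poor, 76–100 Very Poor,
> 100 Unsuitable.

**HMI** is the plain sum of concentration-to-allowable-limit ratios,
with bands < 0.3 Very Clean up to > 6 Seriously Polluted. **ERI** is
the Hakanson sum of Eᵣ = Tᵣ Cᵢ/C_bg, the toxic response factor times
the concentration-to-background ratio, with bands < 30 low up to
> 120 very high. The shipped toxic-response and background tables
(`load_toxicity()`) cover the ten risk-assessed metals; the shipped
guideline file (`load_guidelines()`) holds WHO-2017-based objectives
and is editable YAML, so none of these constants is hard-coded.

By default the indices that take a single concentration vector are fed
the per-site mean across campaigns. Monitoring studies rarely state
whether indices were computed per campaign or on annual means; the
per-site mean is the default because it matches single-number-per-site
reporting, and the per-campaign mode remains available
(`aggregation = "campaign"` in the pipeline).

## Deterministic health risk

Chronic daily intakes follow the USEPA drinking-water forms:

$$\mathrm{CDI_{oral}} = \frac{EF \cdot IR \cdot ED}{BW \cdot AT}\,C,
\qquad
\mathrm{CDI_{dermal}} = \frac{EF \cdot ET \cdot ED \cdot K_p \cdot SA
\cdot CF}{BW \cdot AT}\,C$$

with receptor constants from editable YAML (`exposure_profile()`):
adult IR 2.2 L/d, ED 70 y, BW 70 kg, SA 18 000 cm², ET 0.58 h/d; child
IR 1.8, ED 6, BW 15, SA 6 600, ET 1; EF 350 d/y and CF 10⁻³ L/cm³ for
both. The carcinogenic averaging time is 25 550 days. For the
non-carcinogenic averaging time the package defaults to AT = ED × 365
(25 550 adult / 2 190 child): reference tabulations sometimes print a
different adult literal (10 950 days), but the ED × 365 rule is the one
that reproduces published per-metal hazard quotients exactly, and the
literal remains available via `use_literal_at_nc = TRUE`.

HQ = CDI/RfD and HI sums HQs — per pathway over metals for the headline
totals, per metal over pathways for the HQ_oral + HQ_dermal form; both
aggregations are supported. The dermal reference dose is
RfD_dermal = RfD_oral × ABS; the absorption fraction enters *only*
there, never inside CDI_dermal — a deliberate reading of the intake
equation, verified against published dermal HQs for Hg, Cr, Ni and Pb.
Cancer risk is CR = CDI(AT = 25 550) × CSF, summed within a pathway for
the cumulative risk and compared against the 10⁻⁶–10⁻⁴ tolerable band.
Slope factors are carried for Cd, Cr and Pb (oral 6.1, 0.5, 0.5;
dermal 6100, 500, 500), but the default carcinogen set for cumulative
reporting is Cr + Pb, the two metals consistently quantified well
enough for cancer-risk work; cadmium's factors stay in the table for
users who want them.

Two published dermal values (Cd adult 3.58 × 10⁻⁵, Mn child
1.27 × 10⁻³) cannot be reproduced from these equations with any
concentration inside the reported ranges; they are treated as source
errata and excluded from the golden-value suite.

## Monte-Carlo uncertainty

`run_mc()` draws every input of the target formula (C, IR, EF, ED, BW,
SA, ET, Kp, AT) from declared distributions — point, uniform,
triangular, normal or lognormal, truncated at zero — and evaluates each
draw through the *same* deterministic intake functions, so there is one
code path and point-mass inputs collapse exactly onto the deterministic
value (a property the tests assert with `expect_identical`). The
source study does not declare its distribution families, so the
defaults are triangular for exposure factors (mode at the tabulated
value, ±20 %) and uniform over the observed min–max range for
concentrations; both live in `default_mc_distributions()` and are
overridable, and no claim is made of reproducing any published
percentile band — the acceptance property is that the deterministic
value falls inside the published bands, not band reproduction.
Parameters are sampled independently (no correlation structure is
declared in the source material); 10 000 iterations is the default.
Percentiles use type-7 linear interpolation on order statistics, stated
explicitly because p5/p95 summaries are decision-adjacent.
`cumulative_cr_mc()` shares exposure-factor draws across carcinogens
within each iteration and sums per-draw risks.

## Corrosion and scaling

The saturation pH is the Langelier form

$$\mathrm{pHs} = 9.3 + A + B - (C + D)$$

with A = (log₁₀ TDS − 1)/10, B = −13.12 log₁₀(T[K]) + 34.55,
C = log₁₀(Ca hardness as CaCO₃) − 0.4, D = log₁₀(alkalinity as CaCO₃).
Some printed sources drop the −(C + D) term; it is required by every
standard Langelier formulation and by the negative LSI values such
waters actually produce, so it is kept. "Ca²⁺" in the C term means
calcium hardness expressed as CaCO₃, the standard usage. From pHs:
LSI = pH − pHs, RSI = 2 pHs − pH (so RSI + 2 LSI ≡ pH, a property the
tests check on random inputs), PSI = 2 pHs − pHeq with the Puckorius
equilibrium pH pHeq = 1.465 log₁₀(alkalinity) + 4.54, and
AI = pH + log₁₀(alkalinity × Ca hardness).

The ratio family: Revelle RI = Cl/HCO₃ and Larson–Skold
LS = (Cl + SO₄)/HCO₃ in meq/L (the Larson–Skold convention), CSMR =
Cl/SO₄ as a mass ratio in mg/L — it is a *mass* ratio by name. Each has
a unit-override flag. Classification thresholds (LSI sign; RSI 6.8;
AI 10 and 12; PSI 6; LS 0.8 and 1.2; CSMR 0.5) ship as editable YAML;
RI is reported without a class, as a buffering descriptor.

## The synthetic test bed

`generate_springs()` emulates a six-spring, four-campaign (November,
February, May, August) monitoring year: three recharge-type
carbonate-buffered springs and three mixed-type springs whose strong
acids exceed bicarbonate in equivalents — the two facies groups such
upland networks actually show. Each parameter follows a one-harmonic
cosine year,

$$x = \mu + a\cos\!\big(2\pi(m - m_{peak})/12\big) +
\varepsilon,\quad \varepsilon \sim N(0, (cv\,\mu)^2),$$

with winter-peaking Ca, Mg, HCO₃, SO₄, NO₃ and summer-peaking Na, Cl
(plus late-summer Fe/Mn/Sr and an autumn Hg peak), default noise CV
10 %. One harmonic is the simplest model that reproduces the
winter-peak/summer-trough structure. Amplitudes default to a
peak-to-trough swing of about half the observed range width
(a = width/4), clipped so μ ± a stays inside the observed range; a
literal half-range amplitude around per-spring means would routinely
leave the ranges the generator is required to respect. Gaussian noise
is unbounded, so draws are clamped to the observed per-parameter
ranges.

Each spring's mean bicarbonate is chosen to close the charge balance of
its mean composition, and after drawing, HCO₃ — the largest and most
variable anion, hence the natural closure ion — is minimally
re-adjusted whenever |CBE| exceeds the 5 % tolerance (to 95 % of the
tolerance, leaving numerical headroom), within its own observed range;
a sample that cannot be balanced is redrawn a bounded number of times.
Lead and aluminium are held at their detection limits with
below-detection flags, mirroring the reporting convention for metals
never quantified above MDL. The default year has 6 × 4 = 24 samples;
`drop_one = TRUE` yields the 23-sample variant corresponding to one
missed field visit.

What the generator does *not* emulate: spatial correlation between
springs, discharge/flow dependence, inter-parameter correlation beyond
the charge-balance closure, EC–TDS consistency, analytical error
structure, or multi-year trends. Tests passing on this test bed
demonstrate that the pipeline's arithmetic, classifications and
invariants behave correctly over realistic magnitudes and facies
structure — not that any real spring network has these properties.

## Numerical choices and degenerate inputs

* Zero denominators (Gibbs ratios, Na-normalised ratios, CAI-I, the
  corrosion ratios) yield flagged `NA`s, never silent propagation; zero
  totals where a quantity is undefined (charge balance, Piper
  coordinates, log arguments) are errors naming the offending field.
* CWQI scores are floored at 0; category bands are closed on their
  published boundaries (95 is Excellent, 80 is Good, …).
* Quantiles: type 7 everywhere.
* Reproducibility: the generator and both MC entry points take explicit
  integer seeds and are bit-reproducible under them; the pipeline's
  JSON summary is byte-identical across reruns of the same
  configuration.
* Problem sizes in the shipped tests: 24-sample generations, 100-seed
  facies-recovery sweeps, 10 000-iteration MC runs — sizes chosen to
  exercise the study design at full scale while keeping the suite quick
  to run.

## Worked example

```{r example}
samples <- generate_springs(generator_config(seed = 42))
nrow(samples)
range(charge_balance_error(samples))

table(piper_coordinates(samples)$facies)

risk <- site_risk(reference_site_metals(), exposure_profile("child"))
risk

cw <- cwqi(samples[samples$site_id == "R1", ])
cw
```

`reference_site_metals()` is a reconstructed worked-example
concentration set (four reported extrema plus six values back-derived
from published hazard quotients, all inside the reported ranges); it is
synthetic in the sense that it is not a deposited measurement record.

## Known limitations

No speciation or activity-coefficient chemistry (saturation-index
modelling of mineral phases needs a thermodynamic engine and database
and is out of scope); no inhalation pathway and no age-interpolated
lifetime risk beyond the two receptors; no spatial interpolation or
mapping; CWQI results depend on the guideline file supplied, and the
shipped WHO-2017-based file mixes health-based and aesthetic
objectives where WHO sets no health value, which users should review
for regulatory work.
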