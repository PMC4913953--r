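---
title: "Methods: 5-CNL scoring, dietary profiling and substitution simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5-CNL scoring, dietary profiling and substitution simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnlsim)
```

`cnlsim` chains five pieces of machinery: a nutrient-profiling scorer, a
24-h-record processor, a dietary-pattern clusterer, a food-substitution
simulator, and an adequacy evaluator, plus the synthetic-data generator
that feeds them. This vignette documents the model behind each piece, the
parameters that matter, the numerical choices, and what the synthetic
data can and cannot tell you.

## The scoring model

The score is the UK FSA/Ofcom nutrient profile, per 100 g: four
unfavourable A components (energy in kJ, total sugars, saturated fat,
sodium; 0–10 points each) minus three favourable C components
(fruit/vegetables/legumes/nuts percentage, NSP fibre, protein; 0–5 each).
Points are a non-decreasing step function of the component value; a
threshold must be *strictly* exceeded to award its points. Protein points
are withheld when A reaches 11 and the fruit/vegetable component scores
fewer than 5 points, with cheese exempt. The achievable total runs from
−15 to +40, which `enumerate_score_range()` confirms by enumerating all
achievable point combinations (11⁴ A-combinations × 4·6·6 C-combinations
≈ 2.1 M) under the gate rule.

Three category adaptations follow the French implementation: beverages
are scored on much steeper energy and sugar tables; added fats replace
the saturates component with the saturates/total-lipids ratio (%); and
cheese always keeps its protein points. The per-component thresholds for
the standard tables are the published FSA/Ofcom values (energy 335…3350
kJ, sugars 4.5…45 g, saturates 1…10 g, sodium 90…900 mg; fvln 40/60/80 %
→ 1/2/5 points; NSP fibre 0.7…3.5 g; protein 1.6…8 g). The beverage and
added-fat tables are **editable defaults**: the public documents that
define the 5-CNL hold them, and `cnl_config()` exposes every list so a
user with the authoritative tables can drop them in. The fibre table uses
NSP cut-offs (not AOAC); feed NSP-equivalent fibre values.

Colour classes are fixed score bands — foods: Green −15…−1, Yellow 0…2,
Orange 3…10, Pink 11…18, Red ≥ 19; beverages: Yellow ≤ 1, Orange 2…5,
Pink 6…9, Red ≥ 10, with Green reserved for plain water and unsweetened
hot beverages regardless of score. Alcoholic beverages are scored and
classed like other beverages but excluded from colour-share profiling and
from substitution; their energy still counts toward total intake for the
under-reporting screen (the exclusion the analysis needs is only for the
clustering input).

## Records, screening, colour shares

Daily intake is a weighted mean of the repeated 24-h records: each record
weighs (days of its type per week)/7 divided by the number of records of
that type — 5/14 per weekday record and 2/7 for the weekend record in the
standard 2+1 design. Other mixes re-weight by the same rule (a day type
with no records at all renormalises the remaining weights); an *empty*
declared record keeps its weight and contributes zero.

Basal metabolic rate uses the Schofield age- and sex-banded linear
equations (kcal/day from weight in kg; adults only — the pipeline refuses
ages under 18). Expenditure is BMR × PAL with the category map
{low 1.4, moderate 1.6, high 1.8}. Under-reporting is flagged by the
Goldberg/Black lower confidence limit on EI/BMR:
`PAL·exp(−z·S/100/√n)` with `S = √(CV²wEI/d + CV²wB + CV²tP)`, defaults
CVwEI = 23 %, CVwB = 8.5 %, CVtP = 15 %, d = 3 record days, n = 1,
95 % confidence — a cut-off near 1.01. Whether the reference PAL is the
individual's own multiplier or a population value (1.55) is a config
switch (`goldberg$pal_source`), defaulting to the individual PAL; the
choice matters only for populations whose activity varies widely.

Colour energy shares divide each person's daily energy from foods of each
colour by total non-alcohol energy; they always sum to 100.

## Clustering

The partition reproduces the classic two-stage SAS workflow structurally:
Ward (`ward.D2`) hierarchical clustering seeds k centroids (on a random
subsample of at most 1500 rows when n is larger — seeded, hence
reproducible), then Lloyd k-means refines on all rows until assignments
stabilise (at most 300 iterations; Lloyd's exact stopping rule is
stricter than any small centroid-shift tolerance). The five share
variables enter unstandardised — they already live on one percentage
scale — with a config switch for z-scoring.

Diagnostics come from the Ward merge sequence: R²(k) = 1 − WSS(k)/TSS,
semi-partial R² (the R² lost merging k → k−1), the pseudo-T² of the merge
undone at each k, and the cubic clustering criterion computed with the
published SAS approximation (hyperbox null; the share matrix is rank-4,
which the hyperbox dimension selection handles). The suggested k is the
first local CCC peak that agrees with the semi-partial-R² elbow (the k
with the largest drop in semi-partial R² after it), falling back to the
first peak; a monotone CCC — the signature of unclustered data — yields
no suggestion. Candidacy is deliberately peak-based rather than gated on
CCC > 2: realistically overlapping dietary profiles produce a clear local
peak at negative CCC values, while a hard threshold would only fire on
near-separated clusters. Cluster labels are rule-based: max Green share →
Healthy, then max Pink → Western, then max Yellow → Traditional,
remainder OtherN; ties break to the lower cluster index.

## Substitution scenarios

Substitution operates within food groups of similar culinary use, on the
consumption event level, and never across the food/beverage scale
boundary; alcoholic beverages are ineligible. The replacement composition
is the **unweighted** nutrient-wise mean over the group's distinct foods
in the target classes (even choice among healthier foods, not
consumption-weighted — the config of the generator, not the module,
decides what is in the group). S1 pools all strictly better classes
present in the group; S2 the nearest better non-empty class (stepping
over empty classes keeps the substitution defined; such steps are visible
in the ledger); S3 applies S2 to a simple random sample of
round(0.30 × eligible) events per 24-h record, seeded. Quantities are
retained exactly; unsubstituted events are byte-identical.

Replacements are represented as *virtual* compositions, appended to the
food table and re-scored under the group's own category rules (the
added-fat ratio table, the cheese protein exemption) so post-substitution
colour energies remain well defined. Because the point tables are
nonlinear, a pooled mean can occasionally re-score worse than the worst
class that contributed to it; such cases are logged on the result as
`findings` rather than silently accepted.

## Adequacy

Seven rules are evaluated per person: energy (intake strictly below 105 %
of expenditure), lipids 35–40 %E, carbohydrates 40–55 %E, proteins
10–20 %E, saturates < 12 %E, added sugars < 10 %E, fibre ≥ 25 g/d.
Percent-of-energy rules use Atwater factors (4/4/9, alcohol 7 kcal/g)
over total energy. The band values are configuration, not printed
constants — they follow the public French recommendations and should be
replaced wherever an authoritative table is available. Band bounds are
closed below and open above. Descriptive intake tables can be
energy-adjusted by the residual method (nutrient regressed on energy;
residual plus fitted value at mean energy); adequacy itself always uses
raw intakes.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with ground truth at every stage.

*Food table.* 26 groups (fruits through alcoholic beverages), each mapped
to a composition archetype with a "healthy" and an "unhealthy" pole per
100 g. A food is drawn by interpolating between the poles at an intensity
tied to a target colour class, with multiplicative log-normal noise, and
redrawn (up to 25 times, nudging the intensity) until it scores into its
target class; all five classes are represented overall and in most
groups, and a warning reports any colour with no food. Compositions are
internally consistent: energy follows Atwater from the macros, sugars sit
within carbohydrates, saturates within lipids. The archetype poles were
set so the baseline population lands on a realistic French adult intake
profile — about 37–39 %E lipids, 14–16 %E saturates, 15–16 %E protein,
8–10 %E added sugars, 1700–2300 kcal/d — with within-group quality
gradients expressed mainly through saturate fraction, sodium and sugar
rather than total fat, as in real food groups.

*Population.* Each person draws a latent profile from three specs
(Healthy/Western/Traditional) with mixture weights 0.293/0.348/0.351 and
target colour-share means and SDs set to the three observed dietary
patterns (Green 44/21.2/22.5 %, Pink 20.6/40.3/22.8 %, …). Shares are
drawn Gaussian around the profile mean on the 100-simplex: independent
normals are clamped at zero and renormalised, and a short self-calibration
pass (20 000 internal draws) pre-shifts the latent means so the realised
means match the targets to ~0.1 share points despite clamping; the
projection shrinks marginal SDs slightly (≈ 10 %) relative to the specs.
Given the target shares, each record's energy is split across colours
exactly, foods are sampled within colour with group propensities (a base
frequency-of-use weight times profile affinities — Healthy towards
fruit/vegetables/whole grains/fish, Western towards soft drinks, pastries
and cheese, Traditional towards bread, potatoes, meat and dairy
desserts), and quantities are set from each food's energy density, so
realised shares equal the drawn targets to machine precision.
Anthropometrics come from plausible adult ranges (78 % female, age
~N(43, 15), BMI ~N(23.5, 3.5)); reported energy is centred on expenditure
with log-normal person- and day-level noise; a configurable 10 % of
persons are deliberate under-reporters whose records are scaled so
reported energy is exactly 60 % of expenditure — a clean planted truth
for the screening sensitivity check.

*What passing tests do not show.* The generator reproduces the
colour-share geometry, a realistic macro profile and the record/screening
mechanics; it does not reproduce a real food composition database,
within-person day-to-day food repertoires, correlated micronutrients,
seasonal or social covariates, or measurement error in portion sizes.
Results on synthetic data demonstrate that the pipeline's machinery is
correct and that directional claims (e.g. saturated-fat adequacy rising
under substitution) follow from the label logic; they are not estimates
for any real cohort. Two consequences are worth naming. First, with the
printed profile SDs the three share distributions overlap substantially,
so no clustering method can recover the latent labels much beyond ~89 %
accuracy (adjusted Rand ≈ 0.7) — the diagnostics still select k = 3
decisively. Second, label-guided substitution lowers total fat along with
saturated fat, so the share of subjects inside a two-sided 35–40 %E lipid
band stays roughly flat on synthetic data (within Monte-Carlo error)
rather than rising sharply; the large lipid gains reported for real
cohorts depend on their actual composition database.

## Numerical choices and problem sizes

Threshold comparisons are strict inequalities throughout (the FSA
convention); class bounds are inclusive upper bounds per class. The
scenario-3 event count rounds to nearest (round-half-even, minimum 0).
Degenerate inputs: all-identical share rows collapse to a single cluster
with a warning; a person with zero non-alcohol energy is an error for
colour shares; an empty target class within a group leaves the food
unchanged with a distinct log entry. All randomness flows from explicit
integer seeds; the pipeline writes a manifest with seeds and file hashes,
and identical configurations produce byte-identical tables.

The test suite and the analysis scripts run the generator at n = 400 for
module properties and n = 2000 for the cluster-recovery and share-mean
checks, sizes at which the diagnostics are stable and the whole suite
completes in about a minute on one CPU; the statistical conclusions do
not change at larger n.
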