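---
title: "Methods: tensor-algebra 3D descriptors and QSPR modeling of quinoline hydrogenation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tensor-algebra 3D descriptors and QSPR modeling of quinoline hydrogenation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midasqspr)
```

## The problem

Homogeneous hydrogenation of quinoline (Q) to 1,2,3,4-tetrahydroquinoline
(1THQ) by Ru, Rh, Os and Ir complexes is a model reaction both for
hydrodenitrogenation chemistry and for liquid organic hydrogen carriers:
quinoline stores up to five H~2~ per molecule, a gravimetric capacity of
about 7.2 %wt (`h2_capacity(c(C = 9, H = 7, N = 1), 5)`). The measured
quantity is the initial rate r~0~ (M s^-1^), modeled on the log10 scale to
smooth its five-decade spread. The package ships the 32-catalyst rate
compilation (25 training + 7 external-validation records,
`table1_fixture()`), a tensor-algebra 3D descriptor engine, the model
building and validation machinery, and the applicability-domain tools for
virtual screening, wired together by the numbered scripts under
`analysis/`.

## The descriptor engine

Every molecule is an ordered, element-labeled 3D point set. For a chosen
pair metric the order-2 matrix **G** holds the metric value for every atom
pair; the order-3 and order-4 tensors extend this to triples and
quadruples, with the tuple entry defined as the *sum of the pairwise
metric over all pairs inside the tuple*. This form is symmetric under any
permutation of the tuple, reduces to the pair metric at order 2, and is
exposed as a registry entry so alternatives (perimeter, max) can be added.
Tuples with repeated atoms are zero by convention, as is the order-2
diagonal.

A descriptor name is an 11-token underscore string, e.g.
`I50_F_AB_nCi_2_M12_SS1_T_LGP[5]_s_MID`:

| position | token | meaning |
|---|---|---|
| 1 | `I50` | aggregator (S, GM, VC, I50, AM, N1, N2, MAX, MIN, V, RA) |
| 2 | `F` | algebraic form: F linear, B bilinear, Q quadratic |
| 3–4 | `AB`, `nCi` | atom-based, non-chiral flags (recorded, semantic no-ops) |
| 5 | `2` | tuple order (2, 3, 4) |
| 6 | `M12` | metric: Minkowski p = k/10 for k ≥ 10, p = k otherwise; `CH` Chebyshev |
| 7 | `SS1` | normalization (NS/SS/DS/MP) + matrix power |
| 8 | `T` | scope (T total; L local is parsed but not computed) |
| 9 | `LGP[5]` | cutoff: keep-all, bond-count lag, or distance window in Å |
| 10 | `s` | weight property id(s), hyphen-separated for bilinear |
| 11 | `MID` | suffix |

The grammar choices for the `M<k>`, `SS<k>`, `NS<k>` numerals are this
package's documented interpretation: the fractional-Minkowski reading is
forced by tokens like `M12`/`M15` denoting orders between 1 and 2, and the
trailing numeral on a normalization is read as a matrix power applied
after normalizing (`SS3` = simple-stochastic matrix cubed, `power = 0`
gives the identity). The form letters pair with the weight counts: one
property for linear and quadratic, two for bilinear.

The processing pipeline for a spec is *canonical frame → metric → cutoff →
normalization → power*, after which local vertex invariants (LOVIs) are

* linear: \(L_i = \sum_j g_{ij} x_j\) (unit probe row),
* quadratic: \(L_i = x_i \sum_j g_{ij} x_j\),
* bilinear: \(L_i = x_i \sum_j g_{ij} y_j\),

with orders 3/4 extending the inner sum over the remaining tuple indices
and the second weight vector applied at every non-leading slot. The LOVIs
always sum to the full algebraic form value (tested at 1e-10), and the
aggregator turns them into the global descriptor.

### Why a canonical frame

Minkowski metrics with p ≠ 2 (and Chebyshev) depend on the coordinate
axes, so computed on raw Cartesian input they would change under rotation
of the molecule — unacceptable for a 3D descriptor. `compute_lovis()`
therefore first moves the molecule to a canonical frame
(`canonicalize_molecule()`): centroid at the origin, axes along the
principal axes of the coordinate covariance (eigenvalues descending), axis
signs fixed by the third moment of the projections (fifth moment as a
fallback), third axis by cross product so the transform is a proper
rotation. The frame is deterministic, independent of input orientation and
of atom order, which makes every descriptor invariant under rigid motion
and relabeling (tested at 1e-9 on 200 random molecules). The low-level
`pair_matrix()`/`tuple_tensor()` functions deliberately act on the frame
as given, so closed-form examples (a 3-4-5 triangle has Minkowski-1
distance 7 in its own frame) remain inspectable. Near-degenerate principal
axes (highly symmetric point sets) would make the frame ill-conditioned;
random and real organometallic geometries are far from that regime.

### Cutoffs and zero neighborhoods

Cutoffs apply *before* normalization so that stochastic rows renormalize
over the surviving neighbors. A window cutoff can empty an atom's
neighborhood entirely; inside the descriptor pipeline such rows are left
zero (the atom simply contributes nothing) rather than raising, because
legitimate geometries produce them. A direct call to `normalize_matrix()`
still errors on zero rows by default — silent zero rows in user-assembled
matrices usually indicate a mistake. Double-stochastic (Sinkhorn)
balancing alternates row and column scaling to tolerance 1e-8 with a
10,000-iteration cap and is defined for order 2 only.

## Atomic weights

Ten per-atom properties weight the molecular vectors: mass (amu), van der
Waals volume (Å^3^, from standard radii), polarizability (Å^3^), Pauling
electronegativity, an element-level logP contribution, Gasteiger–Marsili
charge (e), polar surface area contribution (Å^2^), molar refractivity,
hardness (eV) and softness (1/eV, tabulated as 1/hardness). The tables
ship as versioned CSVs under `inst/extdata/atomic_properties/` (header
`element,value`) and are element-level approximations compiled from
standard sources; logP and PSA in particular ignore the atom-type
resolution of the original fragment schemes. Charges are computed, not
tabulated: the PEOE iteration transfers charge across each bond of the
covalent bond graph proportionally to the electronegativity difference,
attenuated by `damping^k` (defaults: 6 iterations, damping 0.5 — the
classic scheme), conserving total charge exactly. Transition metals have
no PEOE parameters; by default a metal atom holds its formal charge and is
excluded from transfer (a strict mode errors instead), since the original
study computed charges with external software whose metal handling is
unspecified.

## The regression model and its validation battery

The model is ordinary least squares with intercept on k = 4 descriptors
over n = 25 training records; the response is log10(r~0~). The published
fit prints R^2^ = 0.902, s = 0.210, F = 46.1; the shipped training
response reproduces these jointly (SST = 8.998 gives s = 0.210 at 20
residual df, and R^2^ = 0.902 at (4, 20) df gives F = 46.0). The printed
"F(5,20)" label is treated as counting the intercept; degrees of freedom
are computed as (k, n − k − 1). Because the published text is ambiguous
about the sign of the logarithmic response ("reciprocal logarithm"), the
sign is a flag (`response_sign`, default +1); the intercept −5.72 sitting
next to the training mean of log10(r~0~) = −5.84 supports the default.

Validation components:

* **Q^2^~LOO~** from the PRESS identity e~i~/(1 − h~i~) on a single fit,
  equal to the n explicit refits at 1e-10 (tested on 100 random datasets).
* **Q^2^~BOO~**: 500 case resamples, each predicting its out-of-bag rows;
  pooled out-of-bag squared errors against SST/(n − 1).
* **Y-randomization**: 5,000 response permutations; under the null the
  expected R^2^ is k/(n − 1) = 4/24 ≈ 0.167, matching the published
  0.17 — this is the quantity `scripts/acceptance.R` recomputes.
* **Residual diagnostics**: Shapiro–Wilk via `stats::shapiro.test`;
  Durbin–Watson d with a two-sided permutation p-value (the published
  p-value's method is unstated; permuting the residual order, 10,000
  seeded permutations, is distribution-free and matches the statistic's
  exchangeability null); VIF from auxiliary regressions.
* **GA selection**: fixed-size subset chromosomes, tournament selection,
  uniform crossover at 50%, per-gene mutation at 1%, single elitism,
  fitness Q^2^~LOO~ on training rows only. Desk-scale defaults are 200 ×
  100 (population × generations); the study's 10,000 × 1,000 is reachable
  through the parameters. Elitism makes the best fitness non-decreasing,
  which is asserted on every run.
* **Split robustness**: repeated random 25/7 splits at fixed model
  columns, summarized by medians and IQRs (the study ran 75,000 splits;
  the analysis script runs 2,000, which already stabilizes the medians to
  well under the reported precision).

## Applicability domain and screening

The Williams plot uses training leverages from the hat diagonal and query
leverages x~0~^T^(X^T^X)^−1^x~0~, with the standard thresholds
h\* = 3(k + 1)/n and ±3 standardized residuals. The published text
mentions a training leverage of 0.48 being "at the defined limit", which
no standard h\* formula reproduces for n = 25, k = 4 (3·5/25 = 0.6); the
package keeps the standard formula and reports thresholds explicitly so
any convention can be checked against the numbers.

NCA learns a 2-row linear transform maximizing the stochastic-neighbor
leave-one-out classification objective by gradient ascent with
backtracking line search from an identity start (deterministic; the
objective is non-decreasing across accepted steps, and the analytic
gradient is verified against finite differences in the tests). Class
labels are response tertiles — the published analysis maps activity onto
the NCA space without stating its class definition, and tertiles
reproduce its three-region reading of the space. LOF is the classic
reachability-distance formulation; queries are scored against the
reference set only. Screening candidates get a prediction from the
packaged reference model (intercept −5.72; coefficients 7.90, 1.72,
−0.443, 0.161) plus an in-domain flag (leverage ≤ h\* and LOF < 1.5,
configurable); out-of-domain candidates are flagged, never dropped.

## What the synthetic generators emulate

`make_linear_qspr()` reproduces the study's statistical geometry: n = 25
(or 32 with the 7 held-out rows), k = 4, residual sd 0.21 log units,
constant predictor cross-correlation 0.1 so VIF stays near 1, and a
default effect size (β~j~ = 0.28) chosen so the generating R^2^ is ≈ 0.90.
`make_point_molecules()`/`make_chain_molecules()` produce element-labeled
point sets — chains guarantee a connected bond graph with covalent-range
neighbors, and optionally carry exactly one Ru/Rh/Os/Ir center. These are
geometric stand-ins, not chemically valid complexes: they exercise the
metrics, normalizations, cutoffs, invariances and the modeling battery,
but passing tests on them says nothing about agreement with descriptor
values computed from real optimized geometries (which are not
distributed), nor about exact numerical compatibility with the original
descriptor software, whose full equation set is not printed.

## Numerical choices and problem sizes

All stochastic operations take explicit integer seeds (default 20250430).
Sinkhorn tolerance 1e-8; bond tolerance 0.25 over covalent radii sums;
PEOE 6 × 0.5; LOF k = min(10, n − 1); NCA 200 accepted steps, gain
tolerance 1e-7. Geometric-mean aggregation uses absolute values and
returns 0 when any LOVI is 0; the variation coefficient returns NaN for a
zero mean. The test suite runs the invariance battery on 200 molecules,
the PRESS identity on 100 datasets, coefficient-recovery coverage on 500
simulations at n = 200, and the GA recovery at 200 × 50
(population × generations) — sizes chosen to pin the properties tightly
while keeping the default suite fast on a single CPU.

## Known limitations

* The published headline statistics (R^2^ = 0.902, Q^2^~LOO~ = 0.847,
  Q^2^~EXT~ = 0.860) cannot be recomputed from scratch: they require the
  optimized 3D geometries and the exact descriptor equation set, neither
  of which is distributed. The package instead verifies every
  desk-reproducible printed number and the full property battery.
* Local-scope descriptors, angular cutoffs and the Bhattacharyya metric
  are recognized by the parser but not computed (no published descriptor
  needs them; Bhattacharyya can be enabled via `register_metric()`).
* Atomic property tables are element-level; Ghose–Crippen logP and Ertl
  PSA lose their atom-type resolution.
* Geometry optimization, vibrational analysis and steric-map (%V~buried~)
  computation are out of scope; structures come from files or generators.
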