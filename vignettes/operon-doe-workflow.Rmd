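---
title: "Designing, building and screening a combinatorial operon library"
author: "operonDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, building and screening a combinatorial operon library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonDesign)
```

## The problem

Heterologous metabolic pathways are tuned by swapping regulatory parts:
which constitutive promoter drives the operon, which ribosome binding site
(RBS) sits in front of each gene, and in what order the genes appear. For a
three-gene carotenoid operon with five promoters, three RBS choices at each
of three positions and all `3! = 6` gene orders, the combinatorial space is
`5 * 3 * 3 * 3 * 6 = 810` configurations — too many to build and screen
exhaustively, but few enough that a designed subset can estimate the main
effect of every factor.

`operonDesign` implements that campaign end to end: it ranks characterised
parts by relative strength, enumerates the full factorial, selects a
D-optimal run subset, plans the acoustic liquid-handler picklist that builds
it, converts screening measurements into titres, screens factor effects by
least squares, and predicts the configuration most likely to maximise
product titre. A seeded simulator generates screening outcomes with the
statistical structure the analysis assumes, so the whole pipeline is
testable without wet-lab data.

## Part ranking and factor coding

Promoters and RBSs are *discrete numeric* factors: their levels are ordered
by relative strength (e.g. RPU measured against a reference constitutive
promoter), and the model sees the strength *rank*, with 1 the weakest part.
Ranks within a class are always a permutation of `1..k`; ties in measured
strength are broken lexicographically by part id (distinct numeric levels
are required) and reported with a warning. Gene order is a *categorical*
factor whose levels are all permutations of the gene list, labelled with
hyphen-joined single-letter gene codes ("E-I-B") in lexicographic
permutation order — the enumeration order, and therefore every downstream
artifact, is deterministic.

For modelling, rank `r` of a k-level numeric factor is coded onto
`[-1, 1]` as `x = 2 (r - r_min) / (r_max - r_min) - 1`; a categorical factor
with k levels gets k-1 effects-coded columns (last level `-1` everywhere),
so its effects sum to zero and per-level effects are directly comparable.

## D-optimal reduction by coordinate exchange

The screening model is main-effects only by default: intercept, one linear
column per numeric factor and the effects-coded gene-order block — `p = 10`
columns for the three-gene space. An `n`-run design maximising
`det(X'X)` concentrates information about exactly these effects; we report
D-efficiency `100 * det(X'X)^(1/p) / n`, which is 100 for an orthogonal
two-level design and necessarily below 100 when a 6-level categorical block
must share runs with numeric factors.

The search is a coordinate (row) exchange over the explicit candidate list:
starting from a random nonsingular subset, each design row in turn is
tested against all 810 candidates and swapped for the best replacement
whenever the determinant improves by a relative factor above `1e-9`,
sweeping until a pass makes no change (at most 50 passes), best of 10
random starts. Determinant ratios are computed with the rank-one update
`(1 - d_i)(1 + d_j) + d_ij^2`, and the log determinant is recomputed from a
factorisation at the end of each search to shed accumulated rounding.
Singular starting subsets are redrawn (up to 100 times). Runs are distinct
by default; replicates can be allowed explicitly. Given `(seed, nStarts)`
the selected run set is bit-reproducible. On candidate sets small enough to
enumerate all subsets, the search attains the exhaustive optimum (this is a
standing test); on the 810-candidate space it reliably beats thousands of
random designs. The shipped campaign uses `nRuns = 88`, a 9.2-fold
compression of the candidate set.

## Build planning

Selected configurations are realised as ordered constructs following the
linker-based modular assembly template `[promoter, linker(rbs1), cds_1,
linker(rbs2), cds_2, linker(rbs3), cds_3, terminator] + backbone` — each
RBS travels inside the assembly linker that carries it. Constructs get
zero-padded stitch IDs in configuration order. The picklist allocates one
destination well per construct (row-major), one transfer per DNA element
plus one shared master-mix transfer, with all volumes rounded *up* to the
2.5 nL droplet quantum of Echo-class acoustic dispensers so molar targets
are met or exceeded. Default transfer volumes (25 nL parts and linkers,
500 nL mix, 12 uL well capacity) are configuration placeholders, not
protocol constants; the protocol fixes only the working concentrations
(76 nM part plasmids, 1 uM linkers). The plan is a pure function of its
inputs: reruns are byte-identical.

## Quantification

The units contract is fixed: concentrations mg/mL, volumes mL, dry cell
weight (DCW) g, titre mg per g DCW. OD600 converts to DCW with the
calibration `DCW/OD = 0.36` g per litre per OD unit, corrected for culture
volume. The LC standard curve is an ordinary least-squares line of peak
area on concentration, fitted with an intercept by default (a zero-intercept
variant is available). Because no limit of detection is printed for the
assay, the detection floor is taken as the smallest nonzero standard:
concentrations below it are flagged undetected. Titre uses the 471 nm
channel by default (the lycopene absorbance maximum of the two recorded
wavelengths); 450 nm is selectable. Areas below the intercept are clamped
to zero concentration with a warning; a signal above the detection floor in
a well with zero biomass is an error, while sub-floor traces at zero DCW
are treated as blank wells.

## Effect screening and optimum prediction

Constructs that failed to grow or produced no detectable product are
excluded from the titre fit — the screen models producers — and replicates
are reduced to the per-construct mean by default (`perReplicate = TRUE`
switches). The fit is ordinary least squares on the coded model matrix;
rank deficiency in the observed runs raises an aliasing error naming the
confounded columns rather than silently dropping terms.

Each factor is tested with a partial (Type-III-style) F test under the
sum-to-zero coding: the full fit against the fit without that factor's
columns. LogWorth is `-log10(p)`, capped at 320 to guard against p-value
underflow, and a factor is flagged significant when LogWorth strictly
exceeds 2 (p < 0.01). With the F reference distribution exact under the
model, the LogWorth > 2 rule flags a true-null factor in about 1% of
screens — a calibration the test suite checks empirically on pure-noise
simulations.

The optimum is predicted by evaluating the fitted linear predictor over all
810 configurations. Ranks are dense; predictions equal within a relative
tolerance of `1e-8` share a rank and are all reported, so exactly
symmetric fits (e.g. a gene-order-indifferent truth) return their tied
co-optima rather than an arbitrary winner. A companion logistic fit of
failure against coded promoter strength quantifies the failure trend.

## What the simulator emulates — and what it does not

The simulator draws, per construct, an assembly/growth failure from
`Bernoulli(plogis(alpha0 + alpha1 * x_prom))` — failures become more likely
as promoter strength rises — and, for surviving constructs, per-replicate
titres `max(0, mu + Normal(0, sigma))` from a linear predictor on the coded
factors, censored below a detection floor. The shipped calibration mirrors
the screening campaign the package is designed around:

* effect sizes `beta0 = 1.7`, `beta_prom = -0.55`, `beta_rbs = (0, 0,
  -0.35)` mg/g in coded units and gene-order effects `(-0.5, 0.9, -0.6,
  0.6, -0.7, 0.3)` — gene order dominant, promoter second, position-3 RBS
  third, the first two RBS positions null, and the favourable direction
  "weaker is better" for promoter and RBS;
* residual SD `sigma = 0.3` mg/g and detection floor `lod = 0.05` mg/g, so
  detected titres span roughly 0.05–4.6 mg/g DCW;
* failure slope `alpha1 = 0.5`, with `alpha0` solved numerically so the
  expected failure fraction over the extreme coded promoter levels
  (`x = -1, +1` — the levels a D-optimal main-effects screen actually
  selects) is 53%.

These are calibrations, not estimates: the underlying screening titres are
not publicly tabulated. Consequently, passing tests demonstrate that the
pipeline recovers the structure this generator encodes — linear main
effects, promoter-dependent failure, floor censoring — not that real
screens obey it. Real data add features the simulator deliberately omits:
part-part interactions, non-Gaussian and heteroscedastic titre noise,
plate and batch effects, context dependence of part strength, and
failure modes unrelated to promoter load.

## Numerical choices and degenerate inputs

* Determinants are always handled on the log scale via `determinant()`;
  exchange updates use the closed-form ratio and are re-anchored exactly
  after each sweep. Accepted swaps are monotone in log-det by construction.
* Single-level factors are constant and silently excluded from the default
  model; *requesting* one is a degenerate-term error.
* `nRuns < p` is refused up front; an all-singular set of starting draws
  (100 attempts) is a singularity error rather than a silent fallback.
* Exact interpolation (`residual df = 0`) is allowed for fitting but
  effect tests require at least one residual degree of freedom; a
  zero-variance fit reports p at the cap with a warning instead of NaN.
* Prediction ties share a dense rank under a relative tolerance of `1e-8`,
  chosen well above double-precision fit noise and well below any
  scientifically meaningful titre difference.

## Problem sizes used in the shipped checks

The standing test suite exercises the full 810-candidate, 88-run campaign;
oracle-equivalence checks run the exhaustive subset search on 6- and
12-candidate spaces; parameter recovery uses 200 seeded screens at the
default calibration; type-I calibration uses 2000 pure-noise screens; and
the failure-rate calibration averages 500 seeded screens of the 88-run
design. These sizes give the empirical rates binomial standard errors a
few times smaller than the margins they are checked against.

## Limitations

The package models main effects by default; interactions must be requested
and are only estimable if the design supports them. It does not design
linker chemistry, drive instruments, or integrate a LIMS — the picklist CSV
is the hand-off. Strength ranks discard the magnitude spacing between
parts; two nearly identical promoters and two very different ones both
become adjacent ranks, which is faithful to rank-based screening practice
but limits extrapolation between ranks.
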