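---
title: "Work-schedule trajectories and later health: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Work-schedule trajectories and later health: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(workseq)
library(dplyr)
```

## The analysis in one paragraph

`workseq` implements a two-step life-course analysis. Step one is sequence
analysis: each person's work schedule over a 10-year age window (for example
ages 25–34) is coded as a length-10 sequence over six states — not working
(`NW`), standard daytime (`ST`), evenings 3–9 pm (`EVE`), nights 9 pm–6 am
(`NGT`), other nonstandard schedules such as irregular hours or weekends
(`ONS`), and missingness (`MIS`), which is carried as an ordinary sixth
state because panel attrition is itself informative. Pairwise dissimilarity
between sequences is the optimal-matching (OM) edit distance computed by the
Needleman–Wunsch dynamic program with insertion/deletion cost 1 and
substitution costs derived from empirical transition rates; Ward's
hierarchical method groups the sequences, with the number of clusters chosen
by the Calinski–Harabasz pseudo-F and Duda–Hart stopping indices. Step two is
regression: standardized health outcomes at the window-end age are regressed
on cluster membership (reference: the mainly-`ST` cluster) with
sociodemographic adjustment, by OLS for continuous outcomes and logistic
maximum likelihood for binary ones. Because the household panels this design
targets are restricted-access, the package ships a synthetic panel generator
with known latent trajectory classes and injected health effects, so every
stage is testable end to end.

## The optimal-matching model

The distance between sequences $x$ and $y$ is the minimum total cost of an
edit script transforming one into the other, with single-element insertions
and deletions at cost $c_{\mathrm{indel}} = 1$ and substitutions at cost

$$\mathrm{sub}(a, b) = 2\,c_{\mathrm{indel}} - p(a \to b) - p(b \to a),$$

the TRATE convention, where $p(a \to b)$ is the empirical probability of
moving from state $a$ at one position to state $b$ at the next, pooled over
all persons and all adjacent position pairs. States that frequently exchange
are cheap to substitute; states that never meet cost the maximum
$2\,c_{\mathrm{indel}}$, at which point substitution is never cheaper than
a deletion plus an insertion. The dynamic program is the standard
$(|x|+1)\times(|y|+1)$ recurrence

$$D_{ij} = \min\big(D_{i-1,j} + c_{\mathrm{indel}},\; D_{i,j-1} +
c_{\mathrm{indel}},\; D_{i-1,j-1} + \mathrm{sub}(x_i, y_j)\big),$$

implemented in C++ and verified in the test suite against brute-force
enumeration of all edit scripts on the complete grid of sequence pairs of
length at most 4 over a 3-state alphabet. The resulting distances are
symmetric, satisfy the triangle inequality (edit scripts compose), and are
bounded by $c_{\mathrm{indel}}(|x| + |y|)$. Distances are not
length-normalized: every retained sequence has nominal length 10.

Two estimation choices are configurable but deliberate. Transition rates are
pooled across window positions rather than estimated per position — the
canonical construction, and the one that is stable at realistic sample
sizes. And `MIS` takes part in both rate estimation and alignment like any
other state; no special gap handling is applied, because attrition-driven
missingness is part of the trajectory being classified.

## Ward clustering and the stopping indices

OM distances are not Euclidean, so the package adopts the
squared-dissimilarity convention (`ward.D2`): within-cluster sum of squares
is defined directly from distances as

$$SS(C) = \frac{1}{|C|} \sum_{i < j \in C} d^2(i, j),$$

which coincides with the squared deviation from the centroid whenever the
distances are Euclidean. Merge heights are reported as the increase in total
within-cluster SS. The agglomeration itself is delegated to
`stats::hclust(method = "ward.D2")`; the test suite checks the resulting
heights against an independent greedy coordinate-based Ward implementation
on Euclidean fixtures.

Candidate cluster counts (default 4–8) are compared by the
Calinski–Harabasz pseudo-F,
$\mathrm{CH}(k) = \frac{(T - W)/(k-1)}{W/(n-k)}$, computed from the same
distance-based SS; the selected $k$ maximizes CH, with ties broken by the
larger Duda–Hart ratio $Je(2)/Je(1)$ of the split that refines cut $k$ into
cut $k+1$, then by smaller $k$. The two indices are reported side by side
for every candidate $k$, but an arbitration rule between them had to be
chosen; CH-primary is a documented package choice, not an empirical claim.
"Conceptual relevance" — a substantive judgment — is represented as an
explicit `force_k` override, never automated.

## Cluster profiles and labels

Profiles are direct tabulations: per-position state frequencies (the data
behind sequence-distribution plots), overall state shares, the mean number
of year-to-year state changes per person (counting changes into and out of
`MIS`, consistent with `MIS` being an ordinary state), and covariate
distributions. Labels follow a deterministic cascade on the non-`MIS` state
shares — "`X` only" at a 0.90 share, "mainly `X`" at 0.60, "`X` + `Y`" when
the top two states each reach 0.25, "volatile" at a mean of 3+ transitions,
otherwise "mixed" — with a "to missing" suffix when the `MIS` share reaches
0.20 and at least half of the `MIS` mass sits in the last three positions
(trailing attrition). All thresholds are configurable; they are reproducible
stand-ins for labels that are normally assigned by inspection, and the
boundary values have no substantive interpretation beyond that.

## Outcomes and regression

SF-type physical and mental function scores are standardized to sample mean
50 and sample SD 10 (n−1 denominator), so a 1-point regression contrast is
one tenth of a standard deviation. Standardization is applied within the
analysis sample per outcome age; this is configurable because the reference
population of the transform is genuinely underdetermined. Self-rated health
is dichotomized to poor/fair versus otherwise. Distress caseness uses
conventional published cutoffs — Kessler-10 ≥ 22, GHQ-12 (0-0-1-1 scoring)
≥ 4, CES-D ≥ 16 — all configurable, since no single cutoff is canonical
across the instruments' literatures.

Continuous outcomes are fit by OLS with conventional homoskedastic standard
errors (an HC1 robust option exists); binary outcomes by logistic maximum
likelihood via IRLS (tolerance 1e-10), with degenerate outcomes and
(quasi-)perfect separation raised as errors rather than returned as
divergent estimates. The exposure is the cluster factor under reference-cell
coding with the largest `ST`-dominant cluster as reference; when no such
cluster exists the largest cluster is used and a warning issued. Gender
interactions are fit as cluster × gender product terms and summarized by the
count significant at α = 0.05 with no multiplicity correction — the
accompanying note states explicitly that some significant interactions are
expected by chance. Significant-effect summary tables round point estimates
to integer points (tenths of an SD) and display binary-outcome directions as
+/− symbols, leaving non-significant cells blank.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *structure* of the restricted household panels
this design targets: 10-year windows, five schedule states plus `MIS`, one
contiguous observed span of 7–10 years per person (weights .35/.30/.15/.20,
majority 7–8 years, so trailing missingness is common) placed uniformly in
the window, person-level covariates (gender, education, partnership),
window-end outcomes on the standardized scale with additive class effects in
points (default injected effects on physical function: 0 for mainly-ST, −4
for mainly-NW, −2 for mainly-NST, −3 for volatile; residual SD 10), logistic
models for binary outcomes, and optional item nonresponse and covariate
missingness. A single seeded RNG stream drives each generation call.

Latent classes follow per-year Markov chains built from an initial-state
distribution, a switch kernel, a *home* state set, and a volatility
parameter: rows for home states leave home with probability $v/9$ (so $v$
is the expected number of switches out of home per decade), and rows for
non-home states return at a fixed rate 0.8. The home/return construction
is what keeps archetypes coherent: without it a single switch is
quasi-permanent under a uniform stay probability, and nominally "sticky"
classes drift apart internally. The four default archetypes — mainly `NW`,
mainly `ST` (weight .45, the reference), mainly nonstandard (concentrated
on `ONS`/`NGT`), and volatile (uniform churn at 5 switches/decade) — were
designed to be well separated in OM-distance space, which is a premise of
the recovery properties the tests assert, not a finding. Default class
weights are .20/.45/.15/.20.

Real panels differ in ways the generator does not emulate: no
country-specific institutions or recoding, no survey weights, annual
observation only (no biennial interview spacing), covariates constant within
a window, and outcomes generated directly on the standardized scale. Passing
recovery tests therefore demonstrate that the pipeline's machinery is
correct and well-calibrated under its own stated conditions — not that any
particular real dataset would yield clusters this clean.

## Numerical and design choices

- **Problem sizes in the test suite.** Cluster recovery uses n = 400 over 5
  seeds; effect recovery uses n = 2000 end to end for the point estimate and
  200 replicates at n = 250 (true class labels, OLS) for confidence-interval
  coverage. Coverage is checked on true labels because it is a property of
  the estimator; estimated-cluster misassignment would confound it with
  classification error.
- **"At least half" denominators.** Primary hours/occupation majorities are
  computed over *observed* working years by default (configurable to the
  fixed 10-year denominator): a person observed 8 years with 4 professional
  years is primarily professional; panel entry/exit would otherwise force
  "mixed" on eligible 7-year persons. "Approximately equal" shares are
  implemented as exact ties — any tolerance would be arbitrary.
- **Eligibility.** The longest run of consecutive non-`MIS` positions must
  reach 7 (configurable); the filter is monotone in the threshold and never
  alters record contents.
- **Ties.** Modal-sequence ties break by alphabet order (`NW` first);
  agglomeration tie order is inherited from `stats::hclust` and is
  deterministic for fixed input.
- **Floating point.** Costs and distances are doubles; equality in tests is
  asserted at 1e-9 or tighter. The distance-matrix text format uses 17
  significant digits so write/read round trips are bit-identical.
- **Degenerate cases.** Zero-variance vectors refuse to standardize; a
  zero-SS parent in Duda–Hart returns ratio 1 and pseudo-T² 0; a perfectly
  separated partition reports CH = ∞; empty sequences are legal OM inputs
  (pure indel cost).

## Known limitations

Transition-rate pooling across positions is an assumption, not an estimate
of position-specific dynamics. The label cascade can assign the same label
to two clusters (they are then disambiguated by cluster id in regression).
The Duda–Hart/CH arbitration is one defensible rule among several. The
generator's archetypes are calibrated for separability; analyses of real
panels should expect lower recovery and should lean on the diagnostics table
and the explicit `force_k` override rather than the automatic selection
alone.

## A worked run

```{r example, eval = FALSE}
sim <- generate_panel(generator_config(n_persons = 400, seed = 1))
cfg <- pipeline_config(windows = list(c(25, 35)), seed = 1)
run <- run_pipeline(sim$panel, sim$covariates, sim$outcomes, cfg,
                    out_dir = "ws_run")
run$windows[["25"]]$solution$diagnostics
tidy(run$windows[["25"]]$profiles)
run$windows[["25"]]$effects
autoplot(run$windows[["25"]]$profiles)
```
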