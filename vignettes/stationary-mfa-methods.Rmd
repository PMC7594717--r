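---
title: "Stationary 13C metabolic flux analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary 13C metabolic flux analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuflux)
```

## Scope

`emuflux` estimates intracellular metabolic fluxes of *Corynebacterium
glutamicum* growing in a glucose-limited chemostat from isotopically
stationary ¹³C labeling data. The workflow is the classical one: a
carbon-atom-mapped network model, steady-state simulation of mass isotopomer
distributions (MIDs) by the elementary-metabolite-unit (EMU) method,
correction of raw MS data for natural isotope abundance, variance-weighted
least-squares flux fitting with a χ² acceptance test and profile-likelihood
confidence intervals, Fisher-information-based a priori tracer design, and
the chemostat balance/kinetics layer (Pirt maintenance regression, ODE
bioprocess model) that supplies the extracellular rates. A synthetic-data
generator reproduces the measurement structure of the labeling experiment so
that every stage can be exercised and calibrated without any external data.

## The network model

The bundled network (`cg_network()`) is a reconstruction of central carbon
metabolism — glycolysis, pentose phosphate pathway (PPP), TCA cycle,
anaplerosis (pyruvate carboxylase, PEP carboxylase/carboxykinase, malic
enzyme), the glyoxylate shunt, protocatechuate (PCA) degradation through the
β-ketoadipate pathway, one-carbon metabolism, and lumped amino acid
synthesis. The original model document is not redistributable, so the file
`inst/extdata/cglutamicum_ccm_reconstruction.yaml` was rebuilt from the
published pathway inventory and dimension counts; it is labeled a synthetic
reconstruction. After scrambling expansion it has 87 reactions
(22 bidirectional, 65 unidirectional) over 45 balanced intracellular and 4
non-balanced extracellular pools, and 27 free fluxes (7 net + 20 exchange)
once the substrate uptakes and the growth-scaled biomass drains are fixed —
matching the published model dimensions exactly. Reconstruction choices that
deserve flagging:

* The reaction and bidirectionality counts include the scrambling variants
  of the C-symmetric pools (succinate, fumarate, *meso*-diaminopimelate);
  variants of one parent share its net and exchange flux with weight 1/2, so
  the 20 free exchange fluxes are the 20 bidirectional parent reactions.
* The lumped biomass equation is realized as 27 growth-scaled unidirectional
  drains from precursor pools with coefficients (µmol gCDW⁻¹) assembled from
  standard *C. glutamicum* biomass composition, adjusted once so that the
  preset flux map reproduces the published steady-state physiology (65.6% of
  substrate carbon to biomass, ~2.07 mol CO₂ per mol glucose, PPP split
  31.6%). They are inputs of the reconstruction, not fitted quantities.
* CO₂ is a balanced 1-carbon pool with separate in/out transport, so
  carboxylation reactions can draw partially unlabeled CO₂.
* Measured panel: 28 metabolites whose full carbon backbones give exactly
  164 mass traces. From the printed metabolome table this forces the panel
  to include tyrosine and to exclude asparagine (pool size 0.01 µmol gCDW⁻¹,
  plausibly below MID quantification), phenylalanine and tryptophan.
* The published rate set names four bioprocess-model rates (µ, r_GLC,
  r_CO₂, r_PCA) but counts six extracellular measurements. The default
  dataset uses six rate rows: the four named rates plus an electron-balance
  oxygen uptake (0.5 mol O₂ per NADH/FADH₂ equivalent, from per-reaction
  cofactor annotations) and the biomass carbon formation rate (TOC-derived).

## EMU simulation and its oracle

`decompose()` performs the standard EMU reduction: starting from the target
EMUs (full backbones of the measured panel) it follows atom maps backwards,
collecting the minimal closure, and organizes it into size-ordered linear
systems `A X = B Y` whose coefficients are linear in the directed
(forward/backward) fluxes. Levels are solved by dense direct solves — the
bundled model yields 315 EMUs with level sizes well below 150, where sparse
methods would gain nothing. Exchange fluxes enter through the
forward/backward decomposition `fwd = max(net, 0) + exch`,
`bwd = max(-net, 0) + exch`.

`isotopomer_oracle()` is a deliberately independent implementation: it
iterates the full positional-isotopomer balance (2ⁿ states per pool) to a
fixed point and marginalizes to MIDs. Two numerical details matter. First,
condensation reactions square small normalization errors, which then grow
multiplicatively across iterations; each pool distribution is therefore
projected back onto the probability simplex every sweep. Second, pools with
zero total flux are treated as errors, not pruned — a zero-influx pool has
no defined labeling state, and the preset keeps trace activity (0.15% of
uptake) on the glyoxylate shunt so every pool of the bundled model is
flux-carrying. Simulator and oracle agree to below 10⁻⁹ on randomized toy
networks and on the full bundled network, which is the package's core
correctness argument.

## Natural-abundance correction

`correction_matrix()` builds `raw = M %*% true` from IUPAC isotope
abundances of every atom of the detected ion *except* the backbone carbons
being inferred (¹³C 0.0107 by default, configurable). With
`include_backbone = TRUE` the binomial ¹³C contribution of the unlabeled
backbone positions is folded in; this is the right matrix when the tracer
substrate itself carries natural ¹³C on unlabeled positions, and the
round-trip simulate-with-abundance → correct → tracer-only simulation is
exact to numerical precision because the backbone contribution commutes with
the (linear) EMU propagation. Corrected MIDs are renormalized; negative
entries above −10⁻³ are clipped with a warning, larger ones are errors.

## Flux fitting

The objective is the variance-weighted SSR over 164 MID traces (flat SD
2.5 mol%, the study's stated measurement uncertainty) and the rate
measurements. Parameters are the 7 free net fluxes (rescaled by the glucose
uptake so all optimizer variables are O(1)) and the 20 exchange fluxes
through the bounded transform `x01 = x/(1+x)` with a scale of 0.1 × uptake
at `x01 = 0.5`. The 28 measurement-group scale factors are projected out
analytically inside every evaluation (`fit_group_scale()`, variable
projection) — mathematically equivalent to carrying them as optimizer
variables, so the reported parameter count stays 27 + 28 = 55 and the
acceptance test uses 170 − 55 = 115 degrees of freedom
(`chi2_acceptance(170, 55)` ≈ 141.0 at 95%).

The multi-start heuristic mirrors the two-stage published procedure:
each random start (free net fluxes uniform in physiological boxes, exchange
transforms uniform in [0, 0.9), infeasible draws rejected) runs a
gradient-free Nelder–Mead polish followed by bounded Levenberg–Marquardt on
the residual vector; the winner gets a deep LM round plus a handful of
jittered LM restarts (SD 0.02 in scaled units), which reliably escapes the
shallow side minima of the sloppy valley. Feasibility (non-negative
unidirectional fluxes) is enforced by smooth penalty residuals rather than a
hard cliff so that LM steps remain well-behaved near the boundary.
Everything is deterministic given the seed.

Confidence intervals default to simultaneous profile likelihood: each free
net flux is walked outwards, re-optimizing the remaining parameters, until
the SSR exceeds the optimum plus the χ²(n_params) 95% quantile; searches
that exhaust the admissible range are flagged non-identifiable (the toy
futile cycle with identical atom maps demonstrates the flag). A linearized
mode uses the finite-difference Jacobian at the optimum and falls back to
profiling when the curvature is singular.

On synthetic data at the study conditions, noise-free datasets are inverted
to the true free net fluxes to better than 10⁻³ (relative, with a
1 µmol gCDW⁻¹ h⁻¹ floor for the inactive fluxes), the SSR at the true
parameters is χ²-calibrated, and 95% profile intervals cover the truth in
well over 85 of 100 noisy replicates of the fast toy configuration
(100 replicates with 5 starts each — problem sizes chosen so the whole
statistical battery stays convenient to re-run).

## Tracer design

`fisher_information()` computes `J = Sᵀ Σ⁻¹ S` with central
finite-difference sensitivities of all simulated measurements at a prior
flux state; `design_score()` implements D-optimality as the
log-pseudo-determinant on the identifiable eigenspace (the publication does
not state its criterion; D is the field's default and an A-criterion is
provided). `optimize_mixture()` scans the candidate simplex on a
deterministic grid (1% default, lexicographic tie-break) — exact and
reproducible for the ≤ 3 active tracers considered here. The six candidate
glucose tracers and the chosen 67/33 U-¹³C/1-¹³C mixture are bundled
(`glucose_tracers()`, `cg_tracer_mixture()`).

## Chemostat layer

The steady-state identities µ = D, `q_GLC = D·c_feed/c_X`, and
`Y = c_X/c_feed` are implemented directly, gas-phase respiratory rates use
an inert-balance (constant N₂ flow) formulation with the dissolved
inorganic carbon carry-out term `D·TIC/c_X`, and the Pirt regression is an
ordinary least-squares line `q_GLC = µ/Y_real + m_S` (glucose molar mass
180.16 g mol⁻¹ for unit conversion). The ODE bioprocess model tracks
biomass and glucose through batch → wash-in → steady state with Monod
kinetics and Pirt uptake, and CO₂ evolution proportional to glucose
consumption. External rates are estimated by weighted least squares; their
SDs come from a parametric bootstrap (noise resampling of the fitted
trajectory, jittered multi-start re-initialization per replicate) — the
published description of "Monte-Carlo runs with random initial parameter
values" is ambiguous between multi-start and bootstrap, and this
implementation combines both, documented here as the package's reading.
A single-dilution-rate experiment determines the maintenance split only
weakly; rate recovery at realistic noise is ~10%, consistent with the
published ±4% rate uncertainty from richer process data.

## What the generator does and does not emulate

`simulate_dataset()` adds independent Gaussian noise (flat 2.5 mol%) per
mass trace, truncates to [0, 1] and renormalizes per metabolite; rates get
Gaussian noise with the published SDs. This reproduces the first two
moments the analysis assumes but not instrument-level features of real
LC-MS data: correlated residuals within a spectrum, intensity-dependent
variance, missing traces, or chromatographic interference. Passing the
recovery and coverage tests therefore validates the estimator under its own
statistical assumptions — it does not certify those assumptions for any
particular instrument. Likewise the bundled network is a reconstruction:
dimension counts and pathway content match the published model, but
individual atom-map conventions (e.g., citrate arm orientation) follow the
standard literature mappings and may differ in detail from the original
model document.

## Known limitations

* Isotopically nonstationary MFA, tandem-MS positional data, compartments
  and thermodynamic constraints are out of scope.
* The isotopomer oracle is exponential in pool size and intended for
  verification, not production fitting.
* Exchange fluxes are reported through their bounded transform; several are
  structurally or statistically non-identifiable (as expected), and only
  net fluxes get confidence intervals by default.
* The χ² acceptance threshold is reported for dof = n_meas − n_params; the
  published threshold of 114 implies a different dof convention (≈ 91) that
  the original software does not document, so both numbers can be compared
  by calling `chi2_acceptance()` directly.
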