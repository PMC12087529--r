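---
title: "Methods: circuit-theory woodland connectivity and invertebrate occurrence"
author: "woodflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circuit-theory woodland connectivity and invertebrate occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodflow)
```

# The question the pipeline answers

Woodland restoration policy increasingly assumes that better-connected
woodland benefits biodiversity, but for most invertebrate taxa that
assumption has never been quantified. `woodflow` implements, end to
end, an analysis that asks: after accounting for the amount of
woodland in a landscape, does the *configuration* of that woodland —
its potential functional connectivity — affect where
woodland-associated invertebrate species occur? And does the benefit
of connectivity depend on how much woodland there is?

The pipeline has six stages, each usable on its own:

1. **Synthetic data** — binary two-class (broadleaf/conifer) woodland
   rasters, smooth climate surfaces, and multi-scheme citizen-science
   occurrence records with realistic visit structure.
2. **Circuit connectivity** — omnidirectional moving-window cumulative
   current flow over a resistance surface, aggregated with cover to a
   coarse analysis grid and standardised.
3. **Visit building** — records to visits to per-species binary
   detection/non-detection data with list-length effort classes.
4. **Occurrence models** — per-species Bayesian spatio-temporal
   logistic models; credible-interval classification of woodland
   association.
5. **Meta-analysis** — a measurement-error random-effects model
   pooling species-level coefficients across recording schemes.
6. **Prediction surface** — pooled cover, connectivity and interaction
   effects combined into occurrence predictions over the
   cover–connectivity plane.

# Circuit-model connectivity

## The model

The landscape is treated as an electrical network. Every fine-grid
pixel is a node joined to its 8 neighbours; the resistor between two
adjacent pixels has resistance equal to the mean of the two pixel
resistances, scaled by $\sqrt{2}$ on diagonals. Woodland pixels get
resistance 1 and non-woodland ("matrix") pixels resistance 100 by
default. Only the habitat:matrix *ratio* matters for current patterns
(scaling every resistance by a constant rescales voltages but leaves
currents unchanged — a property the test suite checks), so unit
habitat resistance is a normalisation, and the matrix value is the
meaningful parameter: movement through matrix is 100 times harder
than through woodland.

For each *target* woodland pixel, a circular window of radius $r$ is
cut out, one unit of current is injected at every other woodland pixel
in the window, the target is grounded, and the grounded graph
Laplacian system $L_{-t}\,v = I$ is solved (sparse Cholesky). The
per-pixel current magnitude

$$c_i = \tfrac12\Big(\sum_{j \sim i} |(v_i - v_j)\,g_{ij}| + |I^{\mathrm{inj}}_i|\Big)$$

is accumulated over all target windows into the cumulative
current-flow map. High cumulative current marks pinch points and
corridors through which many source–target paths funnel.

## Choices a user should know about

* **Injection convention.** One unit per source pixel, no
  normalisation across windows (`injection = "unit"`). Windows with
  more woodland therefore inject more total current, which makes
  cumulative current grow with both cover and aggregation — the
  behaviour the cover-versus-connectivity analysis relies on.
  `injection = "total"` (one unit split over sources) is available.
* **Lattice.** 8-neighbour with mean-resistance edges; 4-neighbour via
  `neighbours = 4`.
* **Radius.** Expressed in metres; the analysis-scale default of
  4 km at 25 m resolution corresponds to 160 pixels. Desk-scale runs
  in this package use 6–15 pixels; cumulative current at different
  radii is strongly rank-correlated, so the qualitative contrast
  survives.
* **Block size.** `blockSize = b` subsamples targets to one
  representative woodland pixel per $b \times b$ block and multiplies
  that window's contribution by the block's woodland count — the
  standard performance knob for national-scale runs; the default (1)
  solves every woodland target.
* **Verification.** Window solves are checked against a dense
  pseudo-inverse oracle on random small lattices (relative error
  $\le 10^{-8}$), Kirchhoff conservation holds at every interior node,
  and Rayleigh monotonicity (halving matrix resistance can only
  increase source–target conductance) is tested across random
  landscapes.

## Aggregation and standardisation

Cover (fraction of fine pixels per class) and connectivity (median
cumulative current over *all* pixels of the cell) are aggregated to
the coarse grid — coarse cell $(i,j)$, 0-based row-major, covers the
half-open fine-pixel block $[ik,(i+1)k) \times [jk,(j+1)k)$. Every
covariate is then centred and scaled by its mean and *population*
(divide-by-$n$) SD pooled over both time periods, so one unit of any
effect is one SD of the covariate over the whole spatio-temporal
domain; the parameters are stored for back-transformation.

# The occurrence model

For one species, visits $v$ carry a binary response $z_v$ (detected /
not detected). The model is Bernoulli-logit with

$$\eta_v = \beta_0 + \beta_{\mathrm{bl}} x_{\mathrm{bl}}
 + \beta_{\mathrm{con}} x_{\mathrm{con}}
 + \beta_c x_c
 + \beta_{\mathrm{bl} \times c}\, x_{\mathrm{bl}} x_c
 + \beta_{\mathrm{con} \times c}\, x_{\mathrm{con}} x_c
 + \gamma_{\ell(v)}
 + \sum_{k=1}^{5} f_k(w_{kv}) + g(\mathrm{week}_v)
 + u(s_v, p_v)$$

where $x_{\mathrm{bl}}, x_{\mathrm{con}}, x_c$ are standardised
broadleaf cover, conifer cover and connectivity; $\gamma$ are
list-length contrasts (single = reference, short = 2–3 species,
long = 4+) absorbing recording effort; $f_k$ are second-order
random-walk (RW2) smooths of the five climate covariates over 20
equal-count bins; $g$ is a cyclic RW2 over 52 weeks capturing
phenology (week 53 folds into 52 to keep the cycle fixed); and
$u(s,p)$ is a Gaussian Markov random field over a coarse lattice of
field nodes (default one node per 5×5 coarse cells) whose two
period-specific realisations are linked by an AR(1) correlation
$\rho_t$. Variants: `no_cover` removes all cover and interaction
terms (used for the cover-quartile analyses), `quadratic` adds
$\beta_{\mathrm{bl}^2} x_{\mathrm{bl}}^2$, and `under30` is the main
formula on the spatial subset of landscapes below 30% cover.

## Priors and numerical choices

* Fixed effects: zero-mean Gaussian, SD 1 by default (configurable;
  `Inf` gives the flat-prior logistic-regression limit used for oracle
  testing).
* RW2 blocks: innovation SD `smoothSd` (default 0.3). The intrinsic
  RW2 prior is made proper by a soft sum-to-zero constraint (a rank-1
  precision term on the block mean) plus a $10^{-6}$ ridge; the
  sum-to-zero constraint keeps the intercept identifiable.
* Spatial field: precision built from the Whittle–Matérn lattice
  operator $\kappa^4 I + 2\kappa^2 L + L^2$ ($L$ the lattice graph
  Laplacian, $\kappa = \sqrt{8}/\mathrm{range}$), normalised
  numerically so the mean marginal variance equals `fieldSd`^2, then
  AR(1)-coupled across periods via the 2×2 precision kronecker factor.
  This is a deliberate simplification of triangulated-mesh SPDE
  machinery: any Matérn-type GMRF satisfies the model contract at
  desk scale.
* Cyclic wrap-around is structural: the phenology penalty couples
  weeks 1 and 52 (verified by a test on the penalty matrix).

## Inference

The default backend is a **Laplace approximation around the joint
posterior mode**: all latent components are Gaussian, so Newton
iterations on the joint penalised likelihood (with step halving)
converge quickly, and the Gaussian curvature at the mode supplies
posterior SDs and 95% intervals for the fixed effects. The
convergence flag requires both Newton convergence and a positive
definite joint Hessian; degenerate responses (all 0 or all 1) are
flagged rather than fitted, and flagged results carry no summaries.

Latent-component SDs are *fixed* at their `modelSpec` values by
default. `estimateHyper = TRUE` optimises them by empirical Bayes
(maximising the Laplace-approximate marginal posterior with
exponential priors on the SDs — a penalised-complexity-style
shrinkage). Full hyperprior integration is intentionally out of
scope: the package's contract is posterior summaries of the fixed
effects, and at the data sizes involved the fixed-effect summaries
are insensitive to moderate changes in the latent SDs.

An **independence-Metropolis MCMC backend** (proposal = the Laplace
approximation, 4 chains, split-$\hat R$ < 1.05 required) is provided
as a cross-check; it is accurate exactly when the posterior is near
Gaussian, which holds for the fixed-effect configurations it is used
to validate.

With smooths and field disabled and flat priors the posterior mode
must equal an independent logistic-regression fit; the test suite
verifies agreement to $10^{-4}$ on simulated datasets, and a
200-replicate simulation checks that the 95% interval for the
connectivity coefficient has nominal (90–98%) coverage.

## Association classification

From the main-variant fit: *broadleaf-associated* if the broadleaf
cover effect's 95% interval lies entirely above zero; *coniferous*
likewise; *both* when both hold; *avoiding* when both upper bounds
are below zero; otherwise *none*. The rules are exhaustively unit
tested, including the overlap case.

# Meta-analysis

Species-level estimates $y_i$ with known standard errors $s_i$ are
pooled with

$$y_i \sim N(\theta_i, s_i^2), \qquad
\theta_i = \mu + a_{\mathrm{scheme}(i)} + b_i, \qquad
a_s \sim N(0, \tau_{\mathrm{scheme}}^2), \quad
b_i \sim N(0, \tau_{\mathrm{species}}^2).$$

The species effect is identifiable with one observation per species
because $s_i$ is known. Priors: $\mu \sim N(0, 10^2)$, half-Normal(0,
1) on both SDs. The sampler is a blocked Gibbs scheme designed for
the near-boundary behaviour of $\tau_{\mathrm{scheme}}$: $\mu$ and
$a_s$ are drawn from Gaussian conditionals with $b$ analytically
marginalised, and the two SDs are slice-sampled on the log scale —
$\tau_{\mathrm{scheme}}$ against the *fully* marginal likelihood
(both random-effect layers integrated out via the compound-symmetry
within-scheme covariance and Sherman–Morrison). Four chains;
convergence requires split-$\hat R$ < 1.01 on $\mu$ and both SDs.

Cross-checks: a single-scheme fit agrees with the DerSimonian–Laird
estimator; shrinkage vanishes as $s_i \to 0$; a zero generating
between-scheme SD concentrates the posterior near the boundary; and
at the full design (800 species, 15 schemes, SEs uniform on
[0.05, 0.5]) the pooled mean and both SDs recover their generating
values. Separate models are fitted per coefficient (connectivity,
cover, interaction); draws are combined across models only in the
prediction stage, and independently, mirroring how the models are
fitted.

# Prediction surface

Per posterior draw $d$ and grid point $(x_{\mathrm{cov}},
x_{\mathrm{conn}})$ (standardised units):

$$\eta_d = \eta_0 + \beta_{\mathrm{cov},d}\, x_{\mathrm{cov}}
 + \beta_{\mathrm{conn},d}\, x_{\mathrm{conn}}
 + \beta_{\mathrm{int},d}\, x_{\mathrm{cov}} x_{\mathrm{conn}},
 \qquad p_d = \mathrm{logit}^{-1}(\eta_d).$$

The baseline $\eta_0$ defaults to 0 (probability 0.5 at mean
covariates): the predictions are *relative*, shaped entirely by the
pooled effects. Conifer terms are held at their standardised mean of
zero. Predictions are masked to the observed envelope — per cover
bin, the observed connectivity range in the covariate grid — because
the bilinear interaction extrapolates without bound outside it. With
a positive connectivity effect and a negative interaction, the
marginal connectivity slope $\beta_{\mathrm{conn}} +
\beta_{\mathrm{int}} x_{\mathrm{cov}}$ is positive in low-cover
landscapes and crosses zero at $x_{\mathrm{cov}} =
-\beta_{\mathrm{conn}}/\beta_{\mathrm{int}}$ (2.96 cover SDs at the
default generating means), which is the policy-relevant statement:
connectivity matters most where cover is low.

# The synthetic-data generator

The generator exists so that every downstream stage is testable
without any restricted-access data, and doubles as the simulation
engine for the recovery experiments.

* **Landscapes** threshold Gaussian-smoothed white noise at the
  cover-target quantile (top-$k$ pixels of the smoothed field). Cover
  and spatial aggregation are therefore controlled *independently* —
  exactly the contrast the cover×connectivity analysis needs.
  Realised cover is exact to pixel rounding and monotone in the
  target. Conifer is drawn independently and conflicts resolve in
  favour of broadleaf (the classes are disjoint by construction).
  Period 2 applies loss (random woodland removal) then gain
  (conversion of matrix pixels 8-adjacent to remaining woodland).
* **Climate** surfaces are smoothed white noise with a shared
  component giving configurable inter-variable correlation; the
  period-2 stack adds smooth noise so periods stay strongly
  correlated. Units are arbitrary because everything is standardised
  downstream.
* **Records.** Visits get a uniform random cell, a uniform date
  within the period window (phenology enters detection, not visit
  timing — the model corrects for phenology, so the generator puts it
  where the model expects it), a scheme, and a latent effort class.
  Every species in the visiting scheme's pool is then detected with
  probability $\mathrm{logit}^{-1}$ of the full generative linear
  predictor, and only detections are emitted; zeros are reconstructed
  by the visit builder, mirroring unstructured recording-scheme data.
  The later period receives twice the visit weight of the earlier
  one, reflecting the growth of recording effort.
* **Generating defaults are the study conditions.** Pooled fixed
  effects default to intercept −1, broadleaf cover 0.246,
  connectivity 0.148, interaction −0.050 (per standardised unit) —
  the values used as generating truths in the recovery experiments —
  with between-species SD 0.33 and between-scheme SD 0.03 in the
  pipeline's species sampler, and per-species SEs spanning 0.05–0.5
  in the meta recovery design. Values with no stated counterpart were
  fixed once at field-plausible magnitudes and are not tuned:
  list-length contrasts +0.7 (short) and +1.4 (long) on the logit
  scale (more effort, markedly higher detection); a unimodal
  midsummer phenology of amplitude 0.8; two mildly non-linear climate
  responses (saturating in growing degree days, inverted-U in
  coldest-month temperature) and three null ones; spatial field SD
  0.4 with AR(1) 0.8 between periods.
* **What it does not emulate** — and hence what passing tests do not
  show about real data: recorder spatial bias (visits are spatially
  uniform), real geography and coastline effects, taxonomic
  verification error, and any separation of occurrence from
  detection beyond list length. The real analysis conflates
  occurrence and detection through the list-length correction; the
  generator's split into a latent effort class plus occurrence-scale
  coefficients is one of many processes consistent with the fitted
  model, flagged as a modelling choice.

# Problem sizes and determinism

Desk-scale defaults keep every stage inside seconds-to-minutes on one
CPU: landscapes up to 200×200 pixels for generator checks, circuit
lattices of 5–10 pixels against the dense oracle, 50×50-pixel
end-to-end runs with 10-pixel radius, occurrence fits at 1 200–4 000
visits, coverage at 200 replicates of 2 000 visits, and
meta-analysis recovery at the full 800-species / 15-scheme design.
These sizes are the package's validation choices; all radii,
resistances and sample sizes scale up through configuration without
code changes. Every stochastic stage takes an explicit seed (the
pipeline derives per-stage seeds from a master seed), and identical
configs reproduce byte-identical output tables — also under test.

# Known limitations

* The spatial field is a lattice GMRF, not a triangulated SPDE mesh;
  at national scale with coastline effects a mesh would be preferable.
* Hyperparameters of the latent components are fixed or
  empirically-Bayes optimised, not integrated over; fixed-effect
  intervals ignore that (small) source of uncertainty.
* The MCMC backend's independence proposal is only efficient while
  the posterior is near-Gaussian; it is a cross-check, not a general
  sampler.
* Cumulative current is summed with unit per-source injection;
  normalisation alternatives change the map's scale and
  cover-dependence, which is why the convention is config-exposed.
* Quartile and under-30% subsetting drop visits outside the retained
  landscapes entirely, rather than keeping them for field estimation
  only.
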