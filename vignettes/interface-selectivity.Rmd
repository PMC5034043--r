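---
title: "Methods: alchemical affinities, hydrogen-bond occupancy, and interface selectivity at desk scale"
author: "fepsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alchemical affinities, hydrogen-bond occupancy, and interface selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepsel)
```

## The scientific question

Heteropentameric ligand-gated ion channels such as the synaptic GABA-A
receptor present several chemically distinct subunit-interface cavities to
a small hydrophobic ligand. Alkylphenol anesthetics (propofol and its
analogues) appear to occupy these interfaces *asymmetrically*: interfaces
whose cavity residues can accept a hydrogen bond from the ligand hydroxyl
bind one to two orders of magnitude more tightly than interfaces where
cavity hydration out-competes the ligand. Three quantitative strands
support that picture, and `fepsel` implements all three as a tested,
desk-scale pipeline:

1. **Alchemical free-energy estimation.** Per-interface standard binding
   free energies from windowed decoupling simulations, turned into
   dissociation constants with an uncertainty band.
2. **Hydrogen-bond occupancy.** The probability `P_hb` that the ligand
   hydroxyl is hydrogen bonded to the site, from a geometric criterion
   applied frame by frame, and the regression of pK_D on P_hb.
3. **Quantitative affinity-based protein profiling (ABPP).** Enrichment
   factors from isobaric-tag (TMT) reporter ratios and the two-stage
   capture/protection decision rules, exercised on synthetic spike-in
   proteomes.

The atomistic molecular dynamics engine and the mass spectrometer are
replaced by a toy host–guest simulator and synthetic-data generators with
recorded ground truth. That replacement is the point of the package: every
estimator can be validated against an oracle (deterministic quadrature,
closed forms, or generator bookkeeping) rather than against unavailable
raw data.

## The toy host–guest model

The ligand is a rigid three-atom C–O–H fragment (a stand-in for the
alkylphenol hydroxyl and its attached carbon; C–O 1.4 Å, O–H 1.0 Å,
C–O–H 109.5°, typical covalent values). It moves in a rectangular box
containing a composite Gaussian-well site potential

$$U_{\mathrm{site}}(r) = -\sum_i \varepsilon_i
  \exp\!\left(-\frac{|r - c_i|^2}{2 w_i^2}\right) \le 0 ,$$

where position wells act on the oxygen and optional narrow *directional
sub-wells* act on the hydrogen, modelling a hydrogen-bonding micro-site in
front of an acceptor. Alchemical decoupling scales the whole site
potential linearly, $U_\lambda = \lambda\,U_{\mathrm{site}}$. Linear
coupling needs no soft-core treatment here because Gaussian wells are
bounded — there is no endpoint singularity to regularize.

Sampling is Metropolis Monte Carlo over position and orientation:

* local moves — uniform translation of the oxygen (default half-width
  0.6 Å) plus rotation about a random axis (default half-angle 0.6 rad);
* occasional independence jumps (default probability 0.4) — half of them
  move the ligand to a uniformly random position *and* orientation
  (well-to-well hopping in multi-well sites), half resample orientation
  only (keeps the hydroxyl direction mixing inside deep wells, where
  whole-box jumps are almost always rejected).

All proposals are symmetric, so plain Metropolis acceptance applies. The
box confines the *oxygen* by proposal rejection (hard wall, no periodic
wrap); consequently the fully decoupled reference volume for the oxygen is
exactly the box volume, which is what the decoupling free energy is
defined against. Randomness comes from R's RNG, so a seed makes every
trajectory bit-reproducible; the seed is stored in the trajectory
metadata.

```{r toy}
sys <- toy_single_well()
traj <- sample_trajectory(sys, thermo_state(300), lambda = 1,
                          n_frames = 2000, seed = 1)
traj
```

## Free energies: windowed exponential averaging

For each adjacent pair of a strictly decreasing schedule
$\lambda: 1 \to 0$ (default 24 windows), the sampler evaluates the
perturbation energies $\Delta U = (\lambda_{k+1}-\lambda_k)\,
U_{\mathrm{site}}$ on equilibrated samples of the $\lambda_k$ state, and
the window free energy is the exact exponential average

$$\Delta G_k = -RT \ln \left\langle e^{-\Delta U / RT}
  \right\rangle_{\lambda_k},$$

computed with a max-shifted log-sum-exp so it is finite whenever the
samples are. The windowed total is validated against deterministic
midpoint-rule quadrature of the configuration integral
$Z(\lambda) = \int e^{-\lambda U/RT}\,d^3r$ on the packaged single-well
and three-well systems; at 24 windows and 10^4 samples per window the two
agree within 0.1 kcal/mol, and on Gaussian work distributions the
estimator reproduces the closed form $\mu - \sigma^2/2RT$. The Jensen gap
$\langle\Delta U\rangle - \Delta G$ and the maximum reduced perturbation
$|\Delta U|/RT$ per window are carried as overlap diagnostics.

The standard binding free energy assembles as

$$\Delta G^0 = -(\Delta G_{\mathrm{decouple}} + \Delta G_{\mathrm{solv}})
  - RT \ln (V_{\mathrm{site}} / V_0),$$

with $V_0 = 10^{27}/N_A \approx 1660.5$ Å$^3$ the volume per molecule at
1 mol/L (commonly quoted rounded to 1,660 Å$^3$) and $V_{\mathrm{site}}$
the volume of the flat-bottom spherical region declared "bound". Two
conventions deserve emphasis because the literature is loose about them:

* **Sign convention.** Here $\Delta G^0$ is the *binding* free energy,
  negative when favorable, and $K_D = e^{\Delta G^0 / RT}\cdot 1\,$M.
  Texts that write $K_D = e^{-\Delta G^0/RT}$ are using the positive
  unbinding free energy; micromolar affinities are only consistent with
  the favorable-negative reading, which is why this package fixes it.
* **Solvation.** $\Delta G_{\mathrm{solv}}$ is an injectable constant
  (default 0): in the toy the "solvent" is the empty box, and a second
  atomistic decoupling leg is out of scope by design.

A free-energy uncertainty $\delta$ (the conventional 1 kcal/mol)
propagates into a multiplicative band
$(K_D e^{-\delta/RT},\, K_D e^{+\delta/RT})$. Printed bands are rounded to
one significant figure with halves away from zero — the style of published
affinity tables (2.0 µM maps to 0.4–10 µM, 200 µM to 40–1000 µM at
300 K); raw values are always retained. A small relative epsilon protects
decimal halves (0.35) from binary representation error during rounding.

The temperature default is 300 K throughout — the thermostat setpoint of
the simulations this toy replaces, not body temperature. Whether the
published per-interface constants used 300 K or another temperature for
the exponential conversion would not change the one-significant-figure
bands.

## Hydrogen-bond occupancy

A donor–hydrogen–acceptor triple is bonded when the donor–acceptor
distance is at most 3.3 Å and the deviation angle at most 40° — the
geometric criterion of the standard trajectory-analysis tools. Two angle
conventions exist in the wild, and the criterion stores which one it
uses:

* `hda_at_donor` (default): the angle H–D–A measured *at the donor* —
  how far the covalent D–H bond points away from the acceptor. This is
  the convention of the VMD-family tools.
* `dha_from_180`: 180° minus the angle D–H–A measured at the hydrogen.

Ties at either cutoff count as bonded; both comparisons are `<=` and are
stated explicitly because reproducibility at the cutoff is otherwise
undefined. A frame is bonded when *any* candidate triple across both
donation directions qualifies (the ligand hydroxyl donates to site
acceptors and accepts from site donors). `P_hb` is the bonded fraction of
frames after discarding an initial burn-in, expressed as a *fraction*
(default 0.25, mirroring the common practice of discarding the first
quarter of a production run) because toy trajectories have arbitrary time
units. Sites classify as "high" above 0.8 and "low" below 0.3, strict
inequalities on both sides.

The implementation is validated against an exhaustive triple-enumeration
oracle (exact equality), is invariant under rigid motions of all
coordinates, and is monotone in both cutoffs.

## The selectivity regression

Per-interface records $(K_D, P_{hb})$ are regressed as
$\mathrm{p}K_D = a\,P_{hb} + b$ by unweighted ordinary least squares (a
weight option exists for sensitivity analysis; no weights are the default
because none are justified by the data). Standard errors come from the
residual variance; the band shown is the *mean-response* confidence band
(not a prediction band) with the t-quantile at $n - 2$ degrees of
freedom. With the typical four interfaces that leaves two residual degrees
of freedom, so the band is wide — a property of the data that the fit
deliberately does not hide. The exact per-interface coordinates behind the
published fit are not printed anywhere, so the published coefficients
($a = 3.4 \pm 0.8$, $b = 3.4 \pm 0.1$, $r^2 = 0.94$) serve only as a
plausibility reference; the package's tests instead verify exact recovery
of lines constructed at those coefficients and agreement with a
normal-equations oracle.

```{r selectivity}
phb <- c(0.2, 0.3, 0.8, 0.9)
rec <- interface_affinities(paste0("if", 1:4), 10^-(3.4 * phb + 3.4), phb)
suppressWarnings(fit_pkd_vs_phb(rec))
```

## ABPP quantification

The entry point is a protein-by-replicate table of three reporter-channel
intensities: UV+ (probe photo-crosslinked), UV− (no irradiation control)
and protected (probe plus excess competing ligand). Upstream stages —
spectral search, FDR filtering, peptide rollup — are out of scope; the
decision rules the package owns are:

* **Enrichment factor** = mean over replicates of the per-replicate
  UV+/UV− ratio. "Mean ratio" is read literally as the mean of ratios;
  the pooled-intensity alternative is available as an option because the
  two differ when channel totals vary.
* **Capture gate**: high capture iff EF strictly exceeds 10.
* **Protection rule** (evaluated only for high-capture proteins):
  ligand-specific iff protection $100\,(EF_c - EF_p)/EF_c$ strictly
  exceeds 50% *and* the enrichment factor decreases by at least 5. The
  percentage is defined against the same protein's capture EF — the
  natural reading of "percent protection", made explicit here because no
  formula is standard.
* **Zero denominators** flag the record and exclude it from
  classification. No pseudo-count imputation: silent pseudo-counts
  reorder EF ranks, and no imputation rule is canonical.

The synthetic proteome generator draws background proteins with true EF
log-normally distributed tightly around 1 (so the thresholds are actually
exercised rather than trivially separated), spike-in targets with
prescribed EF and protection, and multiplicative log-normal replicate
noise specified in log2 space — matching how replicate agreement is
conventionally reported for isobaric-tag data (the default 0.28 log2 SD
is a typical published replicate spread). At 1,000 proteins and four
replicates, the pooled replicate SD is recovered within 10% and strong
spike-ins (EF drop ≥ 10, protection 80%) are classified with perfect
recall and precision at the default thresholds.

## Pharmacology fits

`fit_hill()` fits the four-parameter logistic with variable Hill slope,
parameterized internally in $\log EC_{50}$, with deterministic starts
from a log-grid scan over $EC_{50} \in [\min c/10,\ \max c \times 10]$
crossed with a small set of slopes. One design deviation is worth
recording: descending (displacement) curves are fitted by the *same*
parameterization with the sign of the Hill slope carrying direction
(negative = descending, `top` still the upper plateau), rather than by
inverting the response and restoring the sign afterwards — the fits are
mathematically identical and one code path is easier to trust than two.
Confidence intervals are asymptotic by default (t-quantile at $n - p$
degrees of freedom, the EC50 interval formed on the log scale); a seeded
residual bootstrap is available because the CI method behind published
tables is usually unstated commercial software.

`cheng_prusoff()` converts a displacement IC50 to the inhibitor's
dissociation constant, $K_D = IC_{50}/(1 + [probe]/K_D^{probe})$.
`fit_exp_decay()` fits $A_0 e^{-kt}$ with $k$ kept positive through a
$\log k$ parameterization and reports the half-life $t_{1/2} = \ln 2 / k$
with its interval transformed from the $\log k$ interval; flat signals are
flagged as the $k \to 0$ boundary rather than fitted. Coverage of both
fits' 95% intervals is checked by simulation at realistic generating
values (EC50 6.1 µM with Hill slope 3, as for an anesthetic immobility
endpoint; half-life 25 min, as for diazirine photolysis): at least 93 of
100 seeded repeats must cover the truth, the empirical behavior of a
well-calibrated asymptotic interval at these sample sizes.

## The demo study and its engineered sites

`run_demo_study()` chains simulator → free energies → hydrogen bonds →
regression on four packaged sites engineered to reproduce the qualitative
selectivity pattern: two deep sites (14.5 and 13.5 kcal/mol) carry a
narrow directional sub-well (4.6 and 4.4 kcal/mol, width 0.35 Å) in front
of a site acceptor; two shallower sites (11.5 and 10.5 kcal/mol) share the
acceptor geometry but lack the sub-well. The sub-well depths were chosen
by a Boltzmann estimate so that equilibrium hydrogen occupancy of the
directional patch is about 0.9 — comfortably above the "high" threshold —
while the plain sites sit near the purely geometric baseline of about
0.1 (the chance that a freely rotating hydroxyl points within 40° of the
acceptor). The resulting dissociation constants span roughly two to four
orders of magnitude, echoing the separation between high- and
low-affinity interfaces.

```{r demo, eval = FALSE}
study <- run_demo_study(run_config(seed = 1))
study
```

## Problem sizes and numerical choices

Default problem sizes — chosen as the sizes at which every stochastic
check is comfortably resolved: 24 windows × 10^4 samples per window
(10^3 equilibration) for the free-energy validation; 2 × 10^4 recorded
frames (thinning 2) for occupancy; 10^3-protein proteomes with 4
replicates; 100-repeat coverage simulations. Quadrature uses a 96-point
midpoint grid per axis, accurate to well below 0.01 kcal/mol for
Gaussian-well integrands; it supports position wells only, since
orientation-dependent sub-wells would make the reference integral
five-dimensional — which is why the demo's rank check compares sampled
affinities against the engineered depth order instead.

Other numerical choices: Metropolis acceptance uses energies evaluated in
double precision with a hard failure on non-finite values; the Zwanzig
estimator is max-shifted; OLS is delegated to `lm`, nonlinear fits to
Levenberg–Marquardt (`minpack.lm`) with deterministic starts; rounding of
printed bands is half-away-from-zero at one significant figure.

## What the toy shows — and what it cannot

Passing tests demonstrate that the *estimators* are correct at the study
conditions: the exponential averaging, the standard-state bookkeeping, the
band arithmetic, the geometric criterion, the decision rules and the fits
all agree with independent oracles. They do not demonstrate anything
about real receptors: absolute interfacial dissociation constants require
all-atom alchemical simulations; the published regression coefficients
cannot be regenerated from printed data; and proteome-scale capture
fractions or subunit counts depend on mass-spectrometry data that are not
available. Those quantities are covered qualitatively — by the engineered
demo pattern and by synthetic spike-in recall — and only qualitatively,
which is stated here deliberately rather than implied away.
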