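# fepsel

Desk-scale analysis of **asymmetric small-molecule binding to the subunit
interfaces of heteropentameric ligand-gated ion channels** — the
computational core behind studies of alkylphenol anesthetic (propofol-type)
selectivity at GABA-A receptor interfaces, rebuilt as a tested R package
with toy simulators and synthetic data standing in for the atomistic MD
engine and the mass spectrometer.

The package implements, end to end:

* **Alchemical free energies.** A Metropolis Monte Carlo host–guest
  simulator (rigid C–O–H ligand in a composite Gaussian-well site,
  `U_λ = λ·U_site`), windowed Zwanzig exponential averaging

  `ΔG_k = −RT ln ⟨exp(−ΔU/RT)⟩`,

  the standard-state site-volume correction `−RT ln(V_site/V0)` with
  `V0 = 10^27/N_A ≈ 1660 Å³`, the conversion `K_D = exp(ΔG0/RT)·1 M`
  (ΔG0 negative = favorable), and the δ-uncertainty band
  `(K_D e^{−δ/RT}, K_D e^{+δ/RT})`.
* **Hydrogen-bond occupancy.** The geometric criterion (donor–acceptor
  distance ≤ 3.3 Å, deviation angle ≤ 40°), per-frame bond detection in
  both donation directions, burn-in exclusion, `P_hb`, and the
  high (> 0.8) / low (< 0.3) site classification.
* **Selectivity regression.** `pK_D = a·P_hb + b` by OLS with standard
  errors, r², a mean-response confidence band, and affinity ranking with
  fold differences.
* **Quantitative ABPP.** TMT enrichment factors (mean UV+/UV− replicate
  ratio), the capture gate (EF > 10) and protection rule (> 50%
  protection and ΔEF ≥ 5), and proteome summaries (log2 histograms,
  replicate SD).
* **Pharmacology fits.** Variable-slope Hill dose–response with EC50
  confidence intervals, the Cheng–Prusoff correction, and
  single-exponential photolysis decay with half-life.
* **Synthetic data generators** for every input, with ground truth
  recorded, plus an end-to-end demo study on four engineered interface
  sites.

## Worked example

The demo study chains simulator → free energies → hydrogen bonds →
regression on four packaged sites: two deep wells carrying a directional
hydrogen-bond sub-well, two shallower wells without one.

```r
library(fepsel)
study <- run_demo_study(run_config(seed = 1))
study
#> demo_study (per-site results):
#>       site       dg0 kd_molar      p_hb phb_class
#>  deep-hb-1 -9.754499 7.83e-08 0.8886000      high
#>  deep-hb-2 -8.363152 8.08e-07 0.8792667      high
#>  shallow-1 -5.317683 1.34e-04 0.1035333       low
#>  shallow-2 -4.481743 5.43e-04 0.1066667       low
#> selectivity_fit: pK_D = a P_hb + b; a = 3.9 +/- 0.74, b = 3.16 +/- 0.47, r^2 = 0.932 (n = 4)
```

The two engineered hydrogen-bonding sites come out as high-`P_hb`,
sub-micromolar binders; the plain sites bind 3–4 orders of magnitude more
weakly and rarely hydrogen bond — the qualitative selectivity pattern in
which hydrogen bonding, not well depth alone, separates high- from
low-affinity interfaces. Per-site free energies carry their full
bookkeeping:

```r
study$fep[["deep-hb-1"]]
#> free_energy_result:
#>   dG_decouple =   11.080 kcal/mol  (24 windows)
#>   dG_volume   =    1.326 kcal/mol
#>   dG_solv     =    0.000 kcal/mol
#>   dG0         =   -9.754 kcal/mol
#>   K_D         = 7.83e-08 mol/L  (band 1.46e-08 - 4.19e-07)
```

and the band arithmetic reproduces the familiar printed table style:

```r
kd_uncertainty_band(2.0e-6, delta = 1, thermo = thermo_state(300))
#> K_D = 2e-06 (band 3.74e-07 - 1.07e-05; rounded 4e-07 - 1e-05) [delta = 1 kcal/mol]
```

i.e. 2.0 µM with δ = 1 kcal/mol at 300 K prints as 0.4–10 µM at one
significant figure.

## Documentation

The methods vignette (`vignettes/interface-selectivity.Rmd`) documents the
model and its assumptions, every default with its units and provenance,
the sign and angle conventions, the synthetic generators' scope, and what
the desk-scale validation does and does not show about real receptors.
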