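# stackdyn

Trajectory analysis and rare-event kinetics for one-dimensional
supramolecular polymers assembled from quadruple-hydrogen-bonded dimers —
the ureido–pyrimidinone (UPy) motif, where two monomers bind through four
self-complementary hydrogen bonds in a DDAA pattern and the resulting
planar dimers stack at ~0.37 nm into fibres. The package is aimed at
molecular-simulation practitioners who want to characterize **monomer
exchange**: where dimers rupture (defect formation), what the freed
monomers do (stay attached and rattle, slide along the polymer, dissolve),
how defects self-heal, and on what timescales.

Three method layers:

* **Structural observables** — continuous H-bond coordination through the
  rational switching function *s(r) = (1 − x⁶)/(1 − x¹²)*, *x = (r −
  D₀)/R₀* (R₀ = 0.12 nm, D₀ = 0.27 nm), evaluated against each monomer's
  *t = 0* partner (`hb_dim0_series`); per-monomer radial distribution
  functions normalized by monomer count (`rdf_per_monomer`); Shrake–Rupley
  solvent-accessible surface area (`sasa_per_monomer`); aggregation
  propensity AP = Σ SASA(isolated stacks)/SASA(assembly)
  (`aggregation_propensity`); inter-stack contacts (`inter_stack_contacts`)
  and dimer planarity (`dimer_planarity`).
* **Dynamic descriptors and domains** — rotation-invariant SOAP power
  spectra of the H-bond–center density (`soap_vector`, r_cut = 0.6 nm),
  the frame-to-frame τSOAP descriptor normalized to [0, 1]
  (`tau_soap_series`), the LENS neighbour-shuffling descriptor
  (`lens_series`), a three-component Gaussian-mixture classification of
  τSOAP into monomer domains — III travelling < I stacked-bound < II
  stacked-unbound (`fit_domains`, `assign_domains`) — and defect /
  self-healing / exchange event detection from domain transitions
  (`detect_events`).
* **Rare-event kinetics** — infrequent well-tempered metadynamics time
  rescaling *t = Σᵢ Δtᵢ e^{βV(tᵢ)}* (`unbiased_time`), Poisson CDF fitting
  *P(t) = 1 − e^{−t/τ}* for characteristic timescales (`fit_poisson_cdf`,
  `compare_timescales`), and free-energy-surface reweighting with
  *w = e^{β(V − c(t))}* (`reweight_fes`).

A kinetic Monte Carlo generator (`build_stack`, `simulate_exchange`,
`make_bundle`, `sample_biased_transitions`) produces synthetic stack
trajectories with planted exchange dynamics and bias traces with known
rates, so the whole pipeline is testable without molecular dynamics. See
the methods vignette (`vignettes/stack-exchange-dynamics.Rmd`) for the
models, parameter choices and limitations.

## Worked example

Simulate a 20-dimer stack with tip-only ruptures, classify monomer
dynamics, and estimate a planted rupture timescale:

```r
library(stackdyn)
params <- synthetic_params(n_dimers = 20, k_tip = 5e-4, k_back = 0, seed = 42)
built  <- build_stack(params)
sim    <- simulate_exchange(built$topology, built$coords0, params)
print(sim$truth)
#> ground_truth: 40 monomers x 400 frames; 12 events ( 6 ruptures, 4 rebinds )

rdf <- rdf_per_monomer(sim$trajectory, built$topology, r_max = 1.2, bin = 0.02)
rdf_peaks(rdf, 2, min_g = max(rdf$g) * 0.05)
#> [1] 0.37 0.59
```

The first two RDF peaks sit at the stacking (0.37 nm) and dimerization
(0.6 nm, within one 0.02 nm bin) distances of the lattice. Clustering the
τSOAP series recovers the three dynamic domains:

```r
tau   <- tau_soap_series(sim$trajectory, built$topology)
model <- fit_domains(tau, seed = 1)
print(model)
#> domain_model (k = 3 ):
#>   III mean 0.0000 sd 0.0001 weight 0.043
#>   I   mean 0.1214 sd 0.0472 weight 0.915
#>   II  mean 0.6337 sd 0.3510 weight 0.042

labels <- assign_domains(tau, model, dwell_min = 5)
events <- detect_events(labels, class = label_tips(built$topology, 2))
print(events$by_class)
#>             tip backbone
#>   defect      6        0
#>   self-heal   3        0
#>   exchange    4        0
```

Domain III (travelling monomers, empty neighbourhoods) sits at τSOAP ≈ 0,
domain I (stacked bound) at ≈ 0.12, domain II (stacked unbound, rattling)
at ≈ 0.63 — and every detected defect lies in the end region (end dimers
and their first neighbours), none in the backbone, matching the planted
tip-only rupture dynamics. Finally, recover a planted 100 ns timescale
from 30 biased runs:

```r
bt  <- sample_biased_transitions(true_tau = 1e5, n_runs = 30, seed = 7)
tu  <- sapply(1:30, function(r) unbiased_time(bt$traces[[r]], bt$transition_times[r]))
fit <- fit_poisson_cdf(tu)
print(fit)
#> cdf_fit: tau = 120490 ps (MLE 108750 ), n = 30 uncensored
```

The CDF fit returns τ ≈ 1.2 × 10⁵ ps against the planted 10⁵ ps — within
the ~18% relative standard error inherent to 30 runs.

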