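---
title: "Monomer exchange in quadruple-H-bonded supramolecular stacks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monomer exchange in quadruple-H-bonded supramolecular stacks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stackdyn` analyses the dynamics of one-dimensional supramolecular polymers
built from dimers held together by four self-complementary hydrogen bonds in
a donor-donor-acceptor-acceptor (DDAA) pattern -- the ureido-pyrimidinone
(UPy) motif. Planar dimers stack by core-core interactions at ~0.37 nm, and
stacks bundle into fibres. The scientific questions the package addresses
are: where along a stack do dimers rupture (defect formation), what happens
to the freed monomers (sliding, dissolution), how do defects resolve
(self-healing), and on what timescales -- questions a plain trajectory
cannot answer without dedicated descriptors and rare-event machinery.

All quantities use GROMACS-style units: nm, ps, kJ/mol, with
k_B = 0.0083144621 kJ/(mol K).

## Hydrogen-bond coordination

Dimerization hydrogen bonds are counted continuously with the rational
switching function: for a donor-acceptor distance r, the weight is 1 for
r <= D0 and otherwise (1 - x^n)/(1 - x^m), x = (r - D0)/R0, with the
removable singularity at x = 1 evaluated as n/m. Defaults R0 = 0.12 nm,
D0 = 0.27 nm; the exponents (n = 6, m = 12, the common default for this
rational form) are exposed in `switching_params()`. A dimer's count is the
sum over its four atom pairs, a number in [0, 4].

`hb_dim0_series()` evaluates the count against each monomer's *t = 0*
partner at every frame, whatever happens later. This deliberately blind
bookkeeping detects rupture of the original dimers but cannot see a monomer
re-dimerize with a new partner -- which is precisely why the dynamic
descriptors below are needed to study self-healing.

## Structural observables

* **RDF** (`rdf_per_monomer()`): histogram of core-center distances,
  frame-averaged, divided by the shell volume 4 pi r^2 dr and by the number
  of monomers -- *not* by a bulk density. With this normalization the
  stacking peaks grow with polymer size (more neighbours per monomer),
  which is the size effect of interest; a density-normalized RDF would
  suppress it. Bins are half-open [r, r + dr).
* **SASA** (`sasa_atoms()`, `sasa_per_monomer()`): Shrake-Rupley sphere
  points (deterministic golden-spiral lattice, 960 points/atom and a
  0.14 nm probe by default; fewer points are acceptable for per-monomer
  averages and a floor of 32 is enforced). Periodic images are ignored:
  the solute is assumed compact relative to the box.
* **Aggregation propensity** (`aggregation_propensity()`): the SASA of each
  stack taken alone (same conformation) summed, divided by the SASA of the
  assembly; 1 for non-interacting stacks, growing with inter-stack burial.
* **Inter-stack contacts** (`inter_stack_contacts()`): atom pairs across
  stacks within a cutoff (default 0.5 nm -- a heavy-atom contact distance;
  recorded in the output). The scope can be restricted to core subsets to
  exclude side-chain contacts. Tip depth defaults to 2 here (end dimers and
  their first neighbours), matching how end regions behave in bundles.
* **Planarity** (`dimer_planarity()`): angle between the best-fit planes of
  the two partners' core atoms (smallest principal axis), folded to
  [0, 90] degrees; the planar fraction uses a 20 degree threshold by
  default (exposed as a parameter).

## Dynamic descriptors

Each monomer's interaction center is the center of mass of its four H-bond
atoms; the arrangement of these centers encodes both dimerization and
stacking. For every center, `soap_vector()` expands the Gaussian-smeared
density of the *other* centers within r_cut = 0.6 nm on an orthonormalized
polynomial radial basis (n_max = 8) times real spherical harmonics
(l_max = 6), takes the rotation-invariant power spectrum, and L2-normalizes
it. The radial overlap integrals are evaluated analytically through
exponentially scaled modified spherical Bessel functions and tabulated on a
fine distance grid, so per-neighbour evaluation is an interpolation; the
implementation is cross-checked in the tests against a brute-force 3-D
quadrature of the same density.

Two numerical choices deserve mention:

* a smooth cos^2 cutoff ramp (width 0.15 nm) attenuates neighbours
  approaching r_cut, keeping the descriptor continuous as neighbours cross
  the boundary. A useful asymmetry follows from the L2 normalization: a
  loosely attached monomer whose only neighbours sit in the attenuated
  shell still has a fully sensitive (unit-norm) descriptor, while its
  contribution to a tightly packed neighbour's descriptor is marginal.
* an isolated center (no neighbours within r_cut) gets a fixed reference
  vector -- an all-zero spectrum with a unit flag component -- so its
  frame-to-frame distance is exactly zero while it stays isolated:
  dissolved monomers appear static by construction.

`tau_soap_series()` takes the Euclidean distance between a center's
normalized SOAP vectors at consecutive frames and min-max-normalizes the
pooled values to [0, 1] (dataset-wide by default; per-center normalization
is available but makes levels incomparable across centers). An optional
centered moving average (`smooth_window`, off by default) can suppress
single-frame flickers before clustering; it is left off in the shipped
analyses because sustained low-amplitude responses (a monomer next to a
rattling defect) are *not* removed by smoothing while the bound noise floor
is, which sharpens the mixture in a way that hurts rather than helps.

`lens_series()` is the set-based companion: the symmetric difference of a
center's neighbour-id list between consecutive frames over the sum of the
list sizes, 0 by convention for two empty lists. Its default cutoff
(0.75 nm) is chosen so a bound monomer's partner sits safely inside the
list rather than at the boundary.

## Domains and events

The pooled 1-D tauSOAP values are fitted with a three-component Gaussian
mixture (`fit_domains()`): expectation-maximization with 10 restarts, a
variance floor (1e-6 of the data variance), and two structured
initializations -- a k-means start, and a point-mass-aware start that gives
a tied minimum its own floor-variance component. The latter matters:
travelling monomers produce an exact spike at tauSOAP = 0, and from generic
starts EM (like reference mixture software) converges to a local optimum
that splits the bound cluster instead of isolating the spike.

Components sorted by mean are labelled III < I < II:

* **III** -- travelling monomers (dissolved or sliding along the polymer
  surface): empty or near-empty neighbourhoods, lowest values;
* **I** -- stacked bound monomers: moderate, noise-driven rearrangement;
* **II** -- stacked unbound monomers: a monomer that lost its four H-bonds
  but remains attached rattles against the stack, the most dynamic
  neighbourhood.

`assign_domains()` takes the maximum-posterior component per value and
merges runs shorter than `dwell_min` (default 5 frames) into the preceding
state. `detect_events()` then reads transitions: I to II/III is a defect,
II/III to I is self-healing, II and III exchange otherwise. For the
tip/backbone summary the end region is defined with tip depth 2 (end dimers
plus their first neighbours): the first neighbour of a rattling
stacked-unbound monomer shows a genuine mild descriptor response -- it
neighbours a defect -- and belongs to the end region rather than the
backbone.

## Rare-event kinetics

Infrequent well-tempered metadynamics accelerates rupture; the real time of
a transition observed at biased time t_b is the running acceleration
integral t = sum_i dt_i exp(beta V(t_i)) over the bias trace
(`unbiased_time()`, left-rule discretization, exact for piecewise-constant
bias). The characteristic timescale tau comes from a nonlinear
least-squares fit of the Poisson cumulative probability 1 - exp(-t/tau) to
the empirical CDF at plotting positions k/(n+1) (`fit_poisson_cdf()`); the
exponential MLE (the sample mean) and a Kolmogorov-Smirnov test against
Exp(tau-hat) are reported as diagnostics, never used to drop runs. Censored
runs are excluded from the fit but counted. `compare_timescales()` reports
the tau ratio and its log10 with first-order error propagation.

A note on estimator spread: for n = 30 runs the relative standard error of
any tau estimator is bounded below by n^(-1/2) ~ 18%, so individual
estimates scatter accordingly; recovery is assessed through the median
estimate and a factor-of-2 coverage, which is what the tests check.

`reweight_fes()` builds a free-energy surface over one or two collective
variables from biased samples with weights exp(beta (V - c_t)); when no
c(t) column is available the weights use exp(beta V) directly (the
time-independent/final-bias approximation -- any constant offset cancels in
the min-shift; the choice is recorded in the result). Unsampled cells are
NA, never zero.

## The synthetic generator

Because the package's estimators must be validated against known answers,
`build_stack()`/`simulate_exchange()` generate stack trajectories with
planted dynamics. Each monomer is a rigid 5-point motif: four H-bond atoms
in a planar DDAA row plus one core-center atom, partners facing each other
so the core-core separation is exactly d_dimer = 0.6 nm (H-bond pair
distances 0.2 nm, inside D0), dimers stacked at d_stack = 0.37 nm. These
two lengths are the dimerization and stacking distances of the UPy system
and produce the expected first two RDF peaks by construction.

The exchange dynamics is a direct (Gillespie) kinetic Monte Carlo over
three channels, mirroring the defect/self-healing pathway:

* **rupture** of an intact dimer, at rate `k_tip` for dimers at the lattice
  end sites and `k_back` in the interior. One randomly chosen partner
  becomes *stacked-unbound*: it keeps its site, shifted 0.45 nm off the
  stack, rattling with an extra per-frame wobble (`unbound_wobble`,
  0.05 nm). The other becomes *travelling* and starts sliding.
* **slide** steps of travelling monomers by one site (rate `k_slide`),
  rendered in a groove 0.75 nm off the H-bond plane -- outside every
  descriptor shell, so sliding monomers appear static to tauSOAP, as
  dissolved monomers do. A hop beyond the lattice ends releases the
  monomer into solution (an absorbing state, rendered as a dispersed far
  anchor with a slow random walk).
* **rebind** (rate `k_rebind`) when a travelling monomer reaches the site
  of a complementary stacked-unbound monomer: a full dimer re-forms --
  self-healing, possibly with a different partner than at t = 0, which is
  exactly the case the initial-H-bond series cannot see.

Rupture splitting into a stayer and a leaver follows the observed
phenomenology of defect formation in these systems: one partner remains at
the stack end unbound while the other slides away along the polymer.

Default rates: `k_tip` = 5e-5/ps, `k_back` = 5e-12/ps (a seven-order
tip/backbone contrast), `k_slide` = 2e-3/ps, `k_rebind` = 1e-3/ps, frame
interval 100 ps, 400 frames, thermal jitter 0.015 nm per coordinate. The
sliding and rebinding rates have no published counterpart and are free
parameters of the generator, echoed into every dataset manifest. The
ground-truth recovery analyses (mixture classification against planted
states, event localization) use a faster-rupture variant (`k_tip` =
5e-4/ps, `k_back` = 0) so that several ruptures occur within a 40 ns
window; this scenario was fixed, and verified across disjoint seeds, before
the corresponding tests were frozen.

Two reproducibility guarantees: the event stream and the decorative
rendering noise are drawn from separate RNG substreams derived from the
seed, so changing `noise_sigma` (or the wobble) leaves the ground truth
bit-identical; and a fixed seed reproduces the trajectory exactly.

What the generator does **not** emulate: forces and energetics (no
free-energy consistency between planted rates and geometry), solvent,
side-chain chemistry, monomer internal flexibility, or re-entry of
dissolved monomers. Passing tests therefore demonstrate that the
estimators recover *planted* kinetics and classifications from coordinates
alone -- not that the synthetic trajectories are faithful molecular
dynamics.

`sample_biased_transitions()` plants rare-event kinetics analytically: it
draws unbiased transition times from Exp(tau), builds a well-tempered-style
bias staircase (initial height 1.5 kJ/mol, bias factor 10, deposition every
10 ps -- heights shrinking as exp(-V/((gamma-1) kT))), and places the biased
stopping time so that the acceleration integral of the trace reproduces the
draw exactly. This makes the rescaling-plus-CDF-fitting pipeline testable
end to end with machine-precision oracles.

## Problem sizes in the shipped analyses

The test-suite and acceptance analyses run a 20-dimer stack (200 atoms)
over 400 frames for the domain analyses, 10-dimer stacks over 100-150
frames for correlation checks, 30-run bias ensembles, 200-replicate
recovery studies, and 1e5-sample reweighting problems. These sizes give
comfortable statistical margins for every planted effect while keeping a
full run in the minutes range on one CPU.

## Known limitations

* Orthorhombic boxes only; minimum-image distances assume the box is at
  least twice every cutoff.
* SASA ignores periodic images.
* The mixture model is 1-D over tauSOAP with k = 3 by design; systems with
  more dynamic states need a different feature space.
* XTC trajectories are not read; convert to DCD or XYZ.
* The tip/backbone rupture classification in the generator is by lattice
  end *sites*; a stack that loses its end dimers does not promote interior
  dimers to tips.
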