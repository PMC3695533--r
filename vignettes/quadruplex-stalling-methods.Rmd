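---
title: "Two-state quadruplex thermodynamics and stall-escape kinetics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state quadruplex thermodynamics and stall-escape kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadstall)
```

## The scientific problem

A G-rich tract inside the coding region of the human estrogen receptor
alpha (hERα) mRNA can fold into an intramolecular parallel RNA
G-quadruplex. An elongating ribosome must unwind this structure, and the
stall it causes — transient for weak quadruplexes, persistent on the
timescale of minutes for stable ones — propagates all the way to the
protein level: the fraction of hERα cleaved by intracellular proteolysis
grows exponentially with quadruplex stability. `quadstall` implements that
entire quantitative chain: sequence-level analysis of the synonymous
quadruplex variants, two-state van't Hoff thermodynamics from melting
curves, circular dichroism (CD) diagnostics of two-state behaviour, a
kinetic model of stall escape, and the exponential cleavage-ratio model.
A synthetic-data generator emulates every instrument input so the whole
pipeline is testable end to end without instrument files.

## Two-state intramolecular melting

For a unimolecular folding equilibrium with enthalpy $\Delta H$ and
melting temperature $T_m$, the two-state constraint
$\Delta S = \Delta H/T_m$ gives

$$\Delta G(T) = \Delta H\left(1 - \frac{T}{T_m}\right),\qquad
f(T) = \frac{K}{1+K},\quad K = e^{-\Delta G(T)/RT},$$

so $\Delta G(T_m) = 0$ and $f(T_m) = 1/2$ exactly. We use
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and 37&nbsp;°C
$\equiv 310.15$ K, so free energies carry kcal/mol as in the standard
stability tables. The observed melting signal is modelled with linear
folded/unfolded baselines fitted jointly with the thermodynamics:

$$A(T) = f(T)\,(a_f + b_f T) + (1-f(T))\,(a_u + b_u T) + \varepsilon .$$

`fit_two_state()` is a six-parameter nonlinear least-squares fit
($\Delta H$, $T_m$, two baselines) with:

* $T_m$ initialised at the extremum of the smoothed derivative $dA/dT$,
  with a multi-start at $\pm 5$ °C before declaring failure;
* $|\Delta H|$ initialised from $4RT_m^2\,|df/dT|_{T_m}$ on the
  normalised curve;
* sign-agnostic amplitudes — quadruplex melting followed at 295 nm is
  hypochromic (the signal falls on unfolding), but the fit works for
  either sign;
* a "no transition" error when the fitted amplitude at $T_m$ does not
  exceed 5× the residual RMS or $T_m$ falls outside the scanned range.
  This is what flags the quadruplex-free variant as ND while the pipeline
  continues;
* replicate-based uncertainties: each replicate is fitted independently
  and the table reports mean ± SD, the convention used for replicate
  melting profiles. Single-fit covariances are not used.

The entropy is tied to $\Delta H/T_m$ by parameterisation, not by a
penalty: this *is* the intramolecular two-state assumption, and it keeps
the parameter space two-dimensional where the data constrain it.
Heating-rate metadata is carried but not modelled; the analysis assumes
equilibrium melting (slow ramps of order 0.2 °C/min). Whether to fit raw
or normalised signal was an open choice; we fit raw absorbance and
normalise afterwards with the fitted baselines, which avoids committing
to baselines twice.

## CD two-state diagnostics

If melting interconverts exactly two spectroscopic species, every
spectrum is a convex mixture $S(\lambda,T) = f(T)B_f(\lambda) +
(1-f(T))B_u(\lambda)$. Two consequences are implemented as diagnostics:

* **Isosbestic point** — all spectra agree where $B_f = B_u$.
  `isosbestic_point()` returns the argmin over the wavelength grid of the
  cross-temperature variance of the *raw* intensities, with ties broken
  to the lowest wavelength. On noisy data the variance minimum can drift
  into flat spectral tails where both bases are near zero; the diagnostic
  is intended for visible-amplitude series and its zero-spread property
  is exact only in the noiseless two-state case.
* **265/242 nm linearity** — intensities at any two wavelengths are
  affine functions of $f(T)$, hence perfectly collinear ($|r|=1$) across
  temperature. A third species breaks both properties, and the tests
  construct exactly such a counterexample.

The parallel-topology signature (positive band near 265 nm, negative
near 240 nm) uses a 2 mdeg amplitude threshold; no field-standard numeric
cutoff exists, so the threshold is exposed as an argument.

## Stall-escape kinetics

The synchronized-translation experiment releases ribosomes from a defined
halt site at $t=0$ and follows three bands: halted (H), stalled at the
quadruplex (I), and full-length (F). We model it as deterministic
first-order kinetics (band intensities are ensemble averages, so no
stochastic simulation is needed): a fraction $\phi$ of mRNAs carries a
folded quadruplex and goes H → I (rate $k_{fast}$) → F (rate $k$); the
rest goes H → F at $k_{fast}$. Assuming the activation energy for escape
is proportional to quadruplex stability,

$$k = k_0\,e^{\alpha \Delta G^{\circ}_{37}/RT},$$

which reduces to $k_0$ when there is no quadruplex and decreases
exponentially with stability. All closed forms conserve H + I + F = 1
exactly. The stall position (two codons upstream of the
quadruplex-encoding region) is metadata, not simulated at nucleotide
resolution, and $k_{fast}$ defaults to 1 s$^{-1}$ with the constraint
$k_{fast} \ge 10 k_0$ so the stall is rate-limiting; the sampled times
(tens to hundreds of seconds) do not resolve the fast step, so it is held
fixed in fitting. `fit_escape()` estimates $(k_0, \alpha)$ and a $\phi$
per variant by least squares on the I and F trajectories, starting from
per-variant single-rate estimates regressed on $\Delta G^{\circ}_{37}/RT$.
Confidence intervals come from the numerical Hessian over
$(\log k_0, \alpha)$ with the $\phi$ held at their estimates — the full
Hessian is singular whenever a $\phi$ sits at a boundary (fully folded or
quadruplex-free variants), while the rate block stays well conditioned.

No printed rate constants exist for this assay, so the kinetic module is
validated by parameter recovery: noiseless recovery to well under 1%, and
a median relative error on $\alpha$ below 15% at 5% multiplicative band
noise over 20 simulation seeds.

## The exponential cleavage model

Cleaved/full-length band ratios are normalised replicate-wise to the
quadruplex-free standard (which therefore has relative ratio $\rho = 1$
and covariate $x = -\Delta G^{\circ}_{37} = 0$), making $\rho$ invariant
to per-lane rescaling. The default fit is the anchored single exponential
$\rho(x) = e^{bx}$, which passes through $(0,1)$ exactly — the natural
form when the standard *defines* $\rho = 1$; an affine form
$c + a e^{bx}$ is provided for sensitivity analysis. Fitting is least
squares on the $\rho$ scale (uncertainties are reported on $\rho$, not
$\log\rho$), optionally inverse-variance weighted by the replicate SDs.
The published figures give no fitted coefficient, so validation is again
parameter recovery at the actual five-point stability design
$x \in \{0, 0.47, 4.77, 5.15, 5.86\}$ kcal/mol. The partially folded
U-mutant enters with its measured $\Delta G^{\circ}_{37} = -0.47$; its
incomplete folding in cellular buffer is a documented modelling
simplification.

## Sequence utilities

The five 69-nt antisense primers and the 49-nt first-round template are
bundled as data functions; reverse complement, transcription and
translation delegate to Biostrings. The reading frame of the
primer-derived sense windows is determined programmatically — the frame
in which all variants are synonymous (frame 0) — rather than hard-coded,
since the frame is not machine-readable from the printed sequences. The
quadruplex-forming-potential scanner reports maximal chains of ≥ 4
G-tracts (maximal G-runs of length ≥ `min_tract`) separated by loops of
1–7 nt, greedily left to right with 0-based half-open coordinates on the
scanned strand only; callers reverse-complement explicitly. The default
`min_tract = 2` admits mixed-tetrad candidates such as the U-mutant;
`min_tract = 3` gives the strict canonical contrast (wild-type hit,
quadruplex-free mutant clean). Extinction coefficients use the Cantor,
Warshaw & Shapiro (1970) RNA nearest-neighbour table (bundled in code and
swappable); peptide masses use average (not monoisotopic) residue masses,
matching gel/MALDI-scale molecular weights. The canonical 595-residue
hERα protein sequence ships as plain-text FASTA for the truncation-mass
worked examples; `stall_truncation_length()` locates the stall-site
truncation (two codons upstream of the quadruplex-encoded motif, residue
271), whose mass — like that of the 251-residue fragment ending after the
DNA-binding domain — reproduces the reported molecular weights at 0.1 kDa
rounding.

## Synthetic data: what it emulates, and what it does not

`make_table1_scenario()` encodes the study conditions: five synonymous
variants at the published stabilities (enthalpies back-derived from each
printed ($\Delta G^{\circ}_{37}$, $T_m$) pair), five melting replicates
per variant on a 20–95 °C, 0.5 °C grid, a CD series built from two basis
spectra crossing exactly at 250 nm, stall time courses at
0/20/60/120/300/600 s, and a three-replicate cleavage table following
$\rho = e^{bx}$ with $b = 0.3$ (a representative exponent; the published
fit prints none). Noise models: additive Gaussian on absorbance
(SD 0.002) and CD (0.3 mdeg); multiplicative log-normal (5% CV) on band
intensities, since gel densitometry error is multiplicative. The stall
defaults $k_0 = 0.03$ s$^{-1}$, $\alpha = 0.6$ were chosen so the
simulated time courses reproduce the qualitative band pattern —
persistent intermediate for the stable variants over 600 s, a 20 s
transient for the weakly folded variant — and are stated here once, not
tuned per test. One master seed spawns per-file sub-seeds, so bundles are
byte-identical for a given configuration.

The generator emulates the *statistical structure* the analysis assumes
(two-state melting with linear baselines, exact two-basis CD mixtures,
first-order kinetics, exponential dose–response). Passing tests therefore
demonstrate correctness of the estimators under their own assumptions,
not robustness to real-instrument pathologies: baseline curvature,
heating-rate hysteresis, spectral drift, partially resolved gel bands and
non-two-state folding intermediates are all outside the generator.

## Numerical choices and degenerate inputs

* $f(T)$ is computed as $1/(1+e^{\Delta G/RT})$, the overflow-safe form.
* Identical baselines make normalisation ill-posed and raise an error,
  as do empty grids, non-increasing temperatures and curves shorter than
  20 points.
* All-equal cleavage ratios return $b = 0$ with a warning rather than a
  degenerate fit; a missing standard lane is an error.
* The affine exponential fit starts slightly off the anchored solution:
  an exact-fit start leaves the optimiser a degenerate gradient.
* Problem sizes throughout the test-suite simulations (50 noiseless
  recovery draws, 20–100 noise seeds, 151-point melting grids) were
  chosen as the smallest designs that exercise the estimators across
  their parameter ranges.

## Known limitations

* Strictly intramolecular two-state analysis: no multi-state or
  concentration-dependent (intermolecular) melting, no crowding-agent
  correction model.
* The kinetic model has no codon-resolution elongation, tRNA abundance
  or mRNA-surveillance (no-go decay) branch.
* The isosbestic locator is a raw-variance argmin and is meaningful on
  low-noise series only (see above).
* Quadruplex calling is tract/loop counting, not a folding-propensity
  score; no secondary-structure prediction is attempted.
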