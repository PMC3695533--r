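# quadstall

Quantitative analysis of RNA G-quadruplex mediated ribosome stalling.

A guanine-rich tract in the coding region of an mRNA — here the one in
the human estrogen receptor alpha (hERα) message — can fold into an
intramolecular parallel G-quadruplex that the elongating ribosome must
unwind. `quadstall` implements the full quantitative chain linking that
structure to its phenotype, for RNA biochemists and structural
bioinformaticians analysing melting, CD, synchronized-translation and
band-intensity data:

* **Two-state van't Hoff thermodynamics.** For an intramolecular
  equilibrium, ΔS = ΔH/Tm, so ΔG(T) = ΔH·(1 − T/Tm) and the fraction
  folded is f(T) = 1/(1 + exp(ΔG/RT)). `fit_two_state()` fits
  (ΔH, Tm) jointly with linear folded/unfolded baselines to UV (or CD)
  melting curves and reports ΔG°₃₇ with replicate-based mean ± SD;
  transition-free curves are flagged "ND".
* **CD two-state diagnostics** (`isosbestic_point()`,
  `two_state_linearity()`, `topology_signature()`): exact two-state
  series have a zero-spread isosbestic point and |r| = 1 between the
  265 and 242 nm bands.
* **Stall-escape kinetics** (`escape_rate()`, `simulate_timecourse()`,
  `fit_escape()`): first-order escape from the quadruplex stall with
  rate k = k₀·exp(α·ΔG°₃₇/RT) — exponential in quadruplex stability.
* **Cleavage model** (`relative_ratios()`, `fit_exponential()`): the
  cleaved/full-length protein ratio, normalised to the quadruplex-free
  standard, follows the anchored single exponential ρ(x) = exp(b·x)
  with x = −ΔG°₃₇.
* **Sequence utilities**: the printed antisense primers and their sense
  windows, synonymy checking, a quadruplex-forming-potential scanner,
  nearest-neighbour extinction coefficients, average peptide masses, and
  the canonical hERα protein sequence.
* **Synthetic data** (`make_table1_scenario()`, `generate_bundle()`):
  reproducible instrument-free inputs with the statistical structure the
  analysis assumes, and `run_pipeline()` to run every stage end to end.

## Worked example

Generate a synthetic study bundle at the published stabilities and run
the whole pipeline:

```r
library(quadstall)
dir <- tempfile()
generate_bundle(make_table1_scenario(seed = 42), dir)
run_pipeline(dir)
#> == thermodynamic stabilities (two-state UV melting fits) ==
#>   A_mutant   ND
#>   C_mutant   dG37  -4.96 +- 0.13 kcal/mol   Tm  72.2 +- 0.4 C
#>   G_mutant   dG37  -5.83 +- 0.16 kcal/mol   Tm  81.2 +- 0.8 C
#>   U_mutant   dG37  -0.48 +- 0.04 kcal/mol   Tm  40.0 +- 0.2 C
#>   wild_type  dG37  -5.14 +- 0.19 kcal/mol   Tm  76.7 +- 0.4 C
#> == CD: isosbestic 306 nm (spread 0.0366), r(265,242) = -0.973266, parallel-like ==
#> == stall: k0 0.02735 1/s, alpha 0.593 ==
#> == cleavage: rho = exp(b x), b = 0.302 (kcal/mol)^-1 ==
```

The thermodynamic table recovers the generating stabilities (wild-type
−5.15, C −4.77, G −5.86, U −0.47 kcal/mol) within the replicate scatter
of the simulated noise; the quadruplex-free A-mutant is correctly flagged
ND. The stall fit recovers the generating (k₀ = 0.03 s⁻¹, α = 0.6) and
the cleavage fit the generating exponent b = 0.3. (On this noisy bundle
the raw-variance isosbestic locator wanders into the flat spectral tail;
on a zero-noise series it returns exactly 250 nm — see the methods
vignette.)

Sequence-level checks on the printed primers:

```r
w <- qfp_sense_windows()
translate_seq(w$wild_type, frame = 0)
#> "LFINKKIHLGKDGEGRGEVGSKK"   # identical for all five variants
scan_qfp(w$wild_type, min_tract = 3)[[1]]$tracts
#>   start length
#> 1    36      4
#> 2    41      3
#> 3    46      4
#> 4    56      4
peptide_mass(substr(hera_protein(), 1, 251))
#> peptide of 251 residues: average mass 27587.1 Da (27588.1 Da [M+H]+)
```

The 251-residue N-terminal hERα fragment (activation function 1 plus the
DNA-binding domain) weighs 27.6 kDa; the product truncated at the
ribosome stall site two codons upstream of the quadruplex-encoding
region (271 residues, `stall_truncation_length()`) weighs 30.0 kDa.

## Documentation

The methods vignette
(`vignettes/quadruplex-stalling-methods.Rmd`) describes the models, the
fitting and initialisation strategy, the synthetic-data generator's
assumptions and known limitations.
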