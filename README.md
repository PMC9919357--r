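# xecest

Analysis of hyperpolarized ^129^Xe hyperCEST z-spectra of
cryptophane-tagged membrane receptors, and of MD trajectories of the same
tagged systems.

Hyperpolarized xenon reversibly occupies a cryptophane-A cage attached to
a receptor (here a GPCR tagged at an extracellular-loop cysteine).
Saturating RF at the resonance of cage-bound xenon depletes the signal of
freely dissolved xenon through exchange; stepping the saturation
frequency yields a **z-spectrum** whose dips report the chemical
environments the cage visits. `xecest` implements:

- the exponential-Lorentzian multi-resonance z-spectrum model
  `S(x) = A ∏ᵢ exp(−Bᵢ aᵢ²/(aᵢ² + (bᵢ−x)²))`, its linearized weak-signal
  form, and the mechanistic mapping from xenon exchange rates
  (k_on, k_off) and bound-pool relaxation (R₂) to resonance amplitude and
  width — `B = t·k_on·ω₁²/(ω₁² + k_off² + k_off R₂)`,
  `a² = (ω₁² + k_off(k_off+R₂))·(k_off+R₂)/k_off`;
- weighted nonlinear least-squares fitting with standard errors, and
  resonance-count selection by BIC with a deterministic seeded
  multi-start strategy;
- per-scan spectrum integration (7 ppm window, trapezoid) and z-spectrum
  assembly and normalization;
- xenon contact statistics from MD trajectories: per-residue contact
  counts at an 8.5 Å heavy-atom cutoff, per-frame environment categories
  (just lipid / just protein / lipid and protein / no contacts), and
  site-cluster contact probabilities (top-3 residue averaging);
- internal Cα–H order parameters `S² = (3/2)Σ⟨u_α u_β⟩² − 1/2` after
  Kabsch alignment of the receptor, plus RMSD utilities;
- seeded synthetic-data generators with analytic ground truth for every
  stage (reference z-spectrum parameter sets, scan series, Markov
  site-hopping contact trajectories, wobble-in-cone bond-vector
  trajectories).

See the vignette `vignettes/xecest-methods.Rmd` for the models,
assumptions and numerical choices.

## Worked example

Generate a noiseless synthetic z-spectrum from the bundled 5-resonance
apo-state parameter set and fit it blind:

```r
library(xecest)

acq <- acquisition_params()        # 2*pi*99 rad/s, 20 s, 91-point grid
z   <- gen_zspectrum("apo", acq)   # forward model on the grid
fit <- fit_zspectrum(z, 5, initial_guess(z, 5, acq), acq = acq)
fit
#> 5-resonance z-spectrum fit (converged), rss = 6.105e-32, BIC = -6878.81
#> A = 1 (+/- 5.8e-18)
#>          b_ppm               B   width_hz
#>  103.3 +/- 0.0 0.069 +/- 0.000  820 +/- 0
#>   91.9 +/- 0.0 0.077 +/- 0.000  947 +/- 0
#>   77.5 +/- 0.0 2.300 +/- 0.000  573 +/- 0
#>   67.2 +/- 0.0 0.163 +/- 0.000  242 +/- 0
#>   58.8 +/- 0.0 0.092 +/- 0.000 1570 +/- 0
```

The five recovered rows are the generating parameters: position in ppm
(referenced to xenon gas), exponential amplitude B (on-resonance dip depth
is `1 − exp(−B)`), and half-width a/π in Hz. On noiseless data the
residual sum of squares sits at the machine-precision floor and the
standard errors collapse to zero.

The trajectory arm runs the same way from generated ground truth:

```r
hm  <- hop_model(matrix(c(0.8, 0.1, 0.1,
                          0.2, 0.7, 0.1,
                          0.3, 0.2, 0.5), 3, 3, byrow = TRUE),
                 list(list(name = "lipid",
                           targets = data.frame(segcat = "lipid", resid = 501L)),
                      list(name = "protein",
                           targets = data.frame(segcat = "receptor", resid = 40L)),
                      list(name = "bulk", targets = NULL)))
sim <- gen_hop_trajectory(hm, n_frames = 10000, seed = 5)
tab <- build_contact_table(sim$traj, discard_ns = 0)
round(category_probabilities(tab), 3)
#>        just lipid      just protein lipid and protein       no contacts 
#>             0.542             0.294             0.000             0.164
round(sim$stationary, 3)   # analytic stationary distribution of the chain
#> [1] 0.542 0.292 0.167
```

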