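# lysedpa

Forward and inverse modeling of dual-wavelength photoacoustic (PA)
measurements on partially lysed blood.

Hemolysis releases hemoglobin from ruptured red cells into the suspending
medium. That simultaneously removes scatterers, index-matches the remaining
cells to their surroundings, and makes the medium absorbing — and all three
effects imprint on PA signals. `lysedpa` models the full measurement chain
for a blood state (initial hematocrit `H0`, lysis level `LL`, oxygen
saturation `SO2`, PBS or plasma medium) and inverts simulated or measured
signals back into the clinically interesting quantities. It is aimed at
researchers in biomedical optics and PA spectroscopy who want a
reproducible, scriptable model of hemolysis experiments.

The chain, stage by stage:

1. **Chromophore optics** — intracellular absorption
   `mua_RBC = 2.303 (C_HbO e_HbO + C_Hb e_Hb) + 0.66 mua_W`, complex
   refractive indices of cell and lysed medium
   (`nr = nr_M (B c + 1)`, `ni = mua lambda / 4 pi`), the lysed-medium
   mixing rule, and bulk coefficients from single-cell efficiencies
   (`mua = H/V Qabs pi aeff^2`, `mus = H/V (1-H)^2 Qsca pi aeff^2` with the
   current hematocrit `H0 (1-LL)`).
2. **Cell geometry** — analytic Evans–Fung biconcave profile from
   (D, t, h, d), voxelized to a cubic dipole lattice.
3. **Dipole scattering** — discrete dipole approximation with LDR
   polarizability, FFT-accelerated BiCGSTAB, far-field efficiencies, S11
   angular patterns, orientation averaging, and a Lorenz–Mie oracle for
   validation on spheres.
4. **Photon transport** — voxel Monte Carlo (hop–drop–spin,
   Henyey–Greenstein, Fresnel top surface, Russian roulette) producing
   fluence maps.
5. **Acoustics** — `p0 = Gamma mua F`, k-space propagation to a focused
   spherical-cap transducer (317 grid points at the reference geometry),
   aperture summation, 5 MHz / 70% Gaussian band-pass, 40 dB Gaussian
   noise.
6. **Quantification** — gated peak-to-peak amplitudes, the closed-form
   dual-wavelength inversion for THB and SO2, hematocrit calibration, lysis
   level `LL = |H_init - H_cur| / H_init * 100`, and paired t-test
   distinguishability matrices.

## Worked example

Closed-form optics for a half-lysed-series sample, then a scaled-down
simulated lysis series with the dual-wavelength inversion:

```r
library(lysedpa)

state <- blood_state(H0 = 0.5, LL = 0.06, SO2 = 0.68, medium = "PBS")
opt <- blood_optics(state, 700)
round(c(mua_rbc = opt$mua_rbc, mua_lm = opt$medium$mua_lm,
        nr_lm = opt$medium$nr_lm, mua_bs = opt$mua_bs), 4)
#>  mua_rbc   mua_lm    nr_lm   mua_bs
#>   9.0639   0.5329   1.3359   4.5425
```

The intracellular coefficient is 9.06 cm^-1 at 700 nm; 6% lysis raises the
medium absorption from 0.021 to 0.53 cm^-1 and its refractive index to
1.336, while the whole-sample absorption stays at the conserved 4.54 cm^-1
(total hemoglobin does not change with lysis).

```r
ser <- lysis_series(ll_pct = c(0, 6, 14, 20, 30), lambda_pair = c(700, 905),
                    medium = "PBS", seed = 1)
ser[, c("ll_pct", "est_so2_pct", "est_h_pct", "est_ll_pct")]
#>   ll_pct est_so2_pct est_h_pct est_ll_pct
#> 1      0    67.61919  50.00000   0.000000
#> 2      6    66.10275  45.92029   8.159417
#> 3     14    67.23623  41.98268  16.034635
#> 4     20    67.33678  39.21066  21.578676
#> 5     30    67.46280  32.83712  34.325755
```

Each row is one simulated sample: ten forward runs (five lysis levels at
two wavelengths) through Monte Carlo fluence, k-space acoustics and the
band-limited transducer. The inversion holds SO2 near the nominal 68%
across the whole series, while the recovered hematocrit falls linearly with
lysis — PA amplitude only sees hemoglobin still enclosed in cells — which
is what makes the lysis level recoverable from a hematocrit calibration
(estimated 0/8/16/22/34% against nominal 0/6/14/20/30%).

A thin command-line wrapper over the same functions ships in
`inst/cli/lysedpa.R` (subcommands `optics`, `tables`, `mc`, `pipeline`,
`quantify`).

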