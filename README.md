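# synthcest

Quantification of the NOE(−1.6 ppm) CEST signal at low field (4.7 T, 1 µT
continuous-wave saturation) using partially synthetic training data and a
small 1D-convolutional regressor, benchmarked against six-pool Lorentzian
fitting on Bloch–McConnell tissue-mimicking spectra with analytic ground
truth.

## The problem and who this is for

CEST (chemical exchange saturation transfer) MRI encodes dilute solute pools
in the water Z-spectrum Z(Δω) = S/S₀. The nuclear Overhauser enhancement
resonance at −1.6 ppm is a small, narrow peak squeezed between direct water
saturation, the NOE(−3.5) band and the broad semi-solid MT background;
Lorentzian decomposition of such a peak is noise-sensitive and biased. This
package is for quantitative-MRI researchers who want (a) a clean reference
implementation of the steady-state CEST algebra and a multi-pool
Bloch–McConnell simulator, and (b) the partially-synthetic-training approach:
learn the mapping from R₁obs/Z to the NOE(−1.6) amplitude A and width W from
data whose background is *measured* (Lorentzian-fit components of real
spectra) and whose NOE(−1.6) content is *analytic*, so the training target is
exact.

## The model in brief

A solute pool contributes the rotating-frame rate (all rates 1/s, offsets
rad/s)

    Rex(Δω) = fs·ksw·ω₁² / (ω₁² + (R2s+ksw)·ksw + (Δω−Δ)²·ksw/(R2s+ksw))

with analytic FWHM W ≈ 2√(ω₁²(R2s+ksw)/ksw + (R2s+ksw)²). Water relaxes with
Reff = R₁obs·Δω²/(ω₁²+Δω²) + R₂w·ω₁²/(ω₁²+Δω²). A partially synthetic
Z-spectrum is the inverse summation

    Z = R₁obs / (Reff + [Rex^NOE16 + r₃₅·Rex^NOE35 + r_ag·Rex^ag]/(1+r_MT·fm)
        + r_MT·Rex^MT) · Δω²/(ω₁²+Δω²)

where the three background components are tabulated from a six-pool
Lorentzian fit (AREX metric R₁obs(1/Z_lab − 1/Z_ref)(1+fm)), scaled by r
factors, and B₀ shifts are injected by Δω → Δω + Δω_shift. Each sample's
targets are A = Rex(Δ) and the analytic W, computed without the shift. The
regressor (three ELU 1D-conv layers, dropout, dense 256/128, Adam on MSE) is
trained with curriculum denoising: one clean pass, then three passes with
fresh Gaussian noise (sd 0.005) added to the clean spectra.

## Worked example

```r
library(synthcest)

grid  <- offset_grid()          # 89 offsets, 0.125 ppm fine / 1.25 ppm coarse
sat   <- saturation(b1_uT = 1, t_sat = 5)
model <- default_tissue_model() # 7-pool rat-brain-like tissue

# ground truth for this tissue
noe16_ground_truth(model, sat)
#> $A  0.03944877        # 1/s, Rex at -1.6 ppm
#> $W  0.6775096         # ppm, analytic FWHM

# simulate, then quantify by six-pool Lorentzian fitting
zs  <- simulate_zspectrum(model, sat, grid)
fit_noe16(zs)
#> <noe16_estimate> A = 0.02908 1/s, W = 0.425 ppm
```

The Lorentzian fit recovers A = 0.029 against a true 0.039 1/s — the
systematic underestimate of a narrow peak leaning on the water shoulder,
and the bias the learned approach removes. Building training data from this
single spectrum and checking the reconstruction:

```r
comp <- extract_components(b0_correct(zs))
rec  <- reconstruct_zspectrum(comp, model$pools[model$pools$name == "NOE16", ],
                              water_params(model$r1obs, model$water$r2w),
                              grid = grid, include_amide = TRUE)
max(abs(rec$z - zs$z))
#> 0.0109                # round trip within |dz| <= 0.02 on all 89 offsets

train <- sample_partial_synth(comp, 10000, seed = 1)
mod_A <- train_noe_regressor(train, target = "A", seed = 1)
predict(mod_A, add_noise(zs, snr = 75, seed = 2))
```

`emulate_regime()` + `evaluate_methods()` reproduce the tissue-mimicking
method comparison (partially synthetic vs measured vs augmented vs fully
simulated training vs the Lorentzian baseline) and `snr_sweep()` the
noise-robustness comparison; `autoplot()` methods draw Z-spectra, fits and
loss distributions. See the vignette
(`vignettes/noe16-quantification.Rmd`) for the full methods account.

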