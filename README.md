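# driftknn

Fiducial-free drift correction for single-molecule localization microscopy
(SMLM), in R.

Long SMLM acquisitions (dSTORM, DNA-PAINT) drift by tens to hundreds of
nanometers — more than the localization precision — smearing the
super-resolution reconstruction. `driftknn` corrects this without fiducial
markers by exploiting the blinking of the fluorophores themselves: repeated
localizations of the same emitter should coincide once drift is removed.
The package provides

* **`drift_correct_knn()`** — the post-processing corrector. It fits, per
  dataset (a contiguous block of frames), a polynomial drift in frame
  number, and then constant shifts between datasets, by minimizing the
  thresholded sum of nearest-neighbor distances

  ```
  sumNND = Σ_i min(d_i, l),   l = l_intra (1 px) or l_inter (2 px)
  ```

  with a derivative-free simplex (Nelder–Mead) search. The threshold
  saturates pairings too distant to come from the same emitter, so sparse
  blinking data cannot poison the cost. Corrected table and the fitted
  `drift_model` are returned; `corrected = observed − model`, exactly.

* **`register_once()` / `register_iterative()`** — 3D brightfield z-stack
  registration: per-slice sum scaling, whitening, overlap-scaled full 3D
  cross-correlation via FFTs, and sub-voxel 3-point parabola peak fits,
  iterated against a (simulated) stage until residual motion is below
  5 nm laterally / 50 nm axially.

* **`smlm_sim`** generators — uniform / star-shaped / 3D ring-pair emitter
  fields, exponential on/off blinking (`K_on`, `K_off`), constant /
  polynomial / cubic-spline drift curves, Gaussian localization scatter,
  and analytic synthetic brightfield scenes with exact sub-voxel ground
  truth.

* **evaluation harness** — drift-curve RMSE / max-error metrics
  (`drift_error()`), rate-recovery and pairs–RMSE sweeps, dataset
  re-segmentation studies.

## Worked example

Simulate a star-shaped field of blinking emitters drifting at
0.3 / 0.4 nm per frame over five 1000-frame datasets, then correct it:

```r
library(driftknn)
set.seed(1)

field  <- gen_star_emitters(6400, 1e-4)            # ~2000 emitters
traces <- gen_blink_traces(nrow(field), 5000,
                           K_on = kon_for_lambda(1.28, 1000))
curve  <- gen_drift_constant(5000, c(0.3, 0.4))    # nm/frame
sim    <- render_localizations(field, traces, curve,
                               noise_sigma_nm = 10,
                               frames_per_dataset = 1000)
sim$table
#> <loc_table> 20531 localizations, 2D, 5 dataset(s), 100 nm/px

fit <- drift_correct_knn(sim$table, registration_used = FALSE)
round(recovered_rate(fit$model), 4)
#>   x   y
#> 0.3 0.4
drift_error(fit$model, curve)
#> <drift_error> per-axis RMSE (nm): x=1.38 y=1.55 | max |err| 3.09 nm | pooled RMSE 2.08 nm
```

The recovered rate matches the imposed 0.3/0.4 nm/frame drift to four
decimals, and the estimated drift curve tracks the truth to a few
nanometers — on data whose raw drift spans 2 µm (1.5 and 2.0 µm in x and
y over the 5000 frames).

The same workflow runs from the shell via the installed `exec/driftknn`
script (`simulate`, `correct`, `register`, `evaluate`, `landscape`
subcommands); every run writes its parameters as JSON next to its outputs.

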