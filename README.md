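# t1sens

Sensitivity of mono-exponential T1 mapping to the underlying
magnetization-transfer parameters.

## Why

Reported T1 values for human brain white matter at 3 T range from about
0.6 to 1.1 s. Much of that spread is not noise but physics: longitudinal
magnetization exchanges between a free (liquid) proton pool and a
semi-solid (macromolecular) pool with very different relaxation times, so
the "T1" a sequence reports depends on how that sequence and its fitting
procedure project the two-pool dynamics onto a mono-exponential model.
`t1sens` is for quantitative-MRI researchers who want to know *which*
tissue parameters a given T1-mapping method actually responds to.

## What it computes

The two-pool MT model describes a tissue by six parameters: the semi-solid
pool fraction `m0s` (with `m0f + m0s = 1`), the free-pool relaxation times
`T1f`, `T2f`, the inverse exchange rate `Tx`, and the semi-solid relaxation
times `T1s`, `T2s`. For each pulse sequence `j` the package treats the
whole acquisition-plus-fitting chain as a scalar map

    T1o = f_j(m0s, T1f, T2f, Tx, T1s, T2s)

and computes the gradient `∂T1o/∂p` by 5-point central finite differences,
for every sequence in a 25-protocol suite (12 variable flip angle, 8
inversion recovery, 1 saturation recovery, 2 Look-Locker, 2 MP2RAGE) and
every region of a 9-ROI brain cohort. Each sequence is simulated with
propagator matrices (matrix exponentials of the Bloch–McConnell generator,
RK4 for shaped pulses, complete spoiling) and fitted with its native
procedure: the three-parameter IR fit, `A(1−e^{−TS/T1})` for SR, the
Look-Locker apparent-T1 correction, the DESPOT1 linearization
`S/sin α ~ S/tan α`, and the MP2RAGE ratio-lookup.

The variability of each derivative over the (ROI × sequence) grid is then
decomposed with a linear mixed-effects model — fixed effects: the six MT
parameters; random intercepts: ROI, sequence type, individual sequence —
into Nakagawa–Schielzeth R² components satisfying

    R²_full = R²_fixed + R²_ROI + R²_seqtype + R²_indseq

exactly, and `R²_fixed` is attributed to the individual MT parameters by
Shapley regression over all 2⁶ fixed-effect subsets.

## Worked example

```r
library(t1sens)

run <- run_t1_sensitivity(t1_run_config(seed = 1))
pretty_table(run$summary)
```

```
  param sensitivity   cv n_records r2_fixed r2_roi r2_seqtype r2_indseq r2_full
1   m0s        0.40 0.33       225     0.46   0.02       0.32      0.04    0.84
2   T1f        0.69 0.51       225     0.81   0.00       0.14      0.03    0.98
3   T2f        0.00 1.09       225     0.09   0.00       0.53      0.05    0.67
4    Tx        0.08 0.76       225     0.17   0.00       0.47      0.06    0.70
5   T1s        0.39 0.45       225     0.63   0.01       0.20      0.05    0.88
6   T2s        0.10 1.12       225     0.11   0.00       0.69      0.05    0.85
```

Reading this: `sensitivity` is the mean absolute derivative
`|∂T1o/∂p|` over all 225 (ROI, sequence) cells, normalized by the
cohort-mean parameter value, in seconds — the observed T1 responds most
strongly to the free-pool T1 (0.69 s per unit relative change), with the
pool size and the semi-solid T1 close behind (0.40 and 0.39 s), while
`T2f`, `Tx`, and `T2s` matter far less. `cv` is the coefficient of
variation of those derivatives: even the strong sensitivities vary by
30–50% across regions and sequences, so no single correction factor exists.
The R² columns decompose each derivative's variability: for `T1f` and `m0s`
mostly the MT parameters themselves (`r2_fixed`), for `Tx` and `T2s`
mostly the sequence (`r2_seqtype + r2_indseq`) — variable-flip-angle
protocols are systematically more exchange-sensitive than
inversion-recovery ones — and for no response the ROI identity
(`r2_roi ≈ 0`).

`run$shapley` splits each `r2_fixed` over the six parameters,
`run$coefficients` gives the fixed-effect slopes on both the standardized
and the natural scale, and `autoplot(run)` draws the stacked R²
decomposition. Individual pieces are exported too:

```r
p  <- mt_params(m0s = 0.25, T1f = 1.84, T2f = 0.065,
                Tx = 0.05, T1s = 0.34, T2s = 1e-5)
pr <- default_protocol_suite()$vfa01
observed_t1(pr, p)
#> <t1_fit> variable_flip_angle  T1o = 1.010128 s  converged = TRUE ...
```

A white-matter-like tissue with `T1f = 1.84 s` is reported as
`T1o ≈ 1.01 s` by this VFA protocol and as `T1o ≈ 0.80 s` by an IR
protocol — the method dependence the package exists to quantify.

## Package layout

* `R/mt-model.R` — two-pool generator, propagators, lineshapes, pulses
* `R/sequences.R` — protocol objects, YAML I/O, signal simulation
* `R/t1-fitting.R` — the five native T1 estimators
* `R/sensitivity.R` — finite-difference engine and derivative tables
* `R/effects.R` — mixed models, Nakagawa R², Shapley, AIC scan
* `R/cohort.R` — synthetic ROI cohort and mixed-model data generators
* `R/pipeline.R` — end-to-end orchestration and CSV/JSON outputs
* `vignettes/t1-mt-sensitivity.Rmd` — models, assumptions, design choices
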