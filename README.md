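# stpdual

Inference of short-term synaptic plasticity (STP) dynamics from
postsynaptic-current (PSC) peak amplitudes recorded during
constant-frequency, DBS-like extracellular stimulation.

Electrical stimulation of a nucleus activates its afferents on every
pulse, so stimulation times can be treated as presynaptic spikes. The
per-pulse PSC peaks then facilitate or depress according to the synapse's
STP, and fitting a plasticity model across several stimulation frequencies
recovers the underlying dynamics. This package is for experimenters and
modelers who have such multi-frequency peak series (or raw PSC traces) and
want the parameters of the extended four-parameter Tsodyks–Markram (TM)
model, together with the machinery to validate the estimator on synthetic
ground truth.

## Model and estimator

The TM model tracks utilization `u` (release probability; jumps by
`f(1−u)` at each pulse, relaxes to `U` with time constant `F`) and
resources `R` (depleted multiplicatively, recovers to 1 with time constant
`D`). The per-pulse peak is `I[n] = I[n−1]·e_τ + A·u[n]·R[n]`. Under
constant-interval stimulation at frequency ν (with `e_X = exp(−1/(νX))`)
the peaks settle at the closed form

    u∞ = (f + (1−f)·U·(1−e_F)) / (1 − (1−f)·e_F)
    R∞ = (1 − e_D) / (1 − (1−u∞)·e_D)
    I∞ = A·u∞·R∞ / (1 − e_τ)

The estimator — *dual optimization* — splits the response into its
steady-state level (analytic in θ = {f, U, F, D}; fitted by a bounded
trust-region method with an analytic Jacobian) and its transient onset
(first ≤ 20 pulses; fitted by Nelder–Mead), and alternates the two stages,
each warm-starting the other. A frozen-U variant handles under-determined
recordings with only three stimulation frequencies, and a conventional
full-series least-mean-square-error (LMSE) fit is included as the
comparison baseline. See `vignette("dual-optimization")` for the methods
account.

## Worked example

```r
library(stpdual)

truth <- tm_params(f = 0.1, U = 0.2, F = 0.5, D = 0.2)   # mixed STP synapse
d <- generate_dataset(truth, c(5, 10, 20, 30, 50, 100, 130, 200),
                      n_pulses = 100, noise_sd_frac = 0.05, seed = 1)
fit <- dual_optimize(d, dual_config(seed = 7))
fit
#> TM fit (dual): final cost = 0.00217616
#> TM model parameters
#>   f = 0.1242  U = 0.1861  F = 0.4253 s  D = 0.1938 s
#>   A = 0.9805  tau_syn = 0.003 s
#>   history: 17 stage records
parameter_distance(fit$params, truth)
#> [1] 0.07994679
```

Under 5% measurement noise the estimate lands within ~0.08 (L2 over
[f, U, F, D]) of the generating parameters: facilitation magnitude and
time constant, release probability and depression time constant are each
recovered to within a few hundredths/tens of milliseconds. The fitted
parameters predict the response at any frequency:

```r
steady_state_response(fit$params, c(10, 50, 130))
#>   frequency     u_inf     R_inf      I_inf
#> 1        10 0.5146847 0.5674188 0.28634513
#> 2        50 0.8009083 0.1194892 0.09395275
#> 3       130 0.9086962 0.0426486 0.04116813
```

A shell front end wraps the same functions:

```sh
Rscript inst/cli/stpdual-cli.R generate --preset facilitation \
    --freqs 10,20,130 --pulses 50 --noise 0.05 --seed 3 --out demo.csv
Rscript inst/cli/stpdual-cli.R fit --data demo.csv --mode dual-frozen-u \
    --seed 4 --out demo_fit.json
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's quantitative headline
claim from scratch: it draws 200 seeded TM parameter sets, simulates
100-pulse trains at 8 stimulation frequencies, applies the 5%
relative-change settling criterion to every series, and reports the
maximum detected transient length (which the theory bounds by ~20 pulses).

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON output maps the target id to its recomputed value and the number
of series scanned.
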