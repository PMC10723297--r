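# activecall

Belief-based simulation and analysis of contact-call exchanges.

Animals that keep in touch with out-of-sight group members through
antiphonal contact calls face a policy choice on every call: produce the
duration most likely to draw a partner's response (**vocal
accommodation**), or the duration most likely to *teach them something*
about the partner's response behavior (**active sampling**). `activecall`
implements both as Bayesian agents and provides the statistical pipeline
used to compare their simulated sessions with real or synthetic
call-event tables.

## The model

A call of duration *x* draws a response with probability

&nbsp;&nbsp;&nbsp;&nbsp;Υ(θ′, x) = V<sub>max</sub> · exp(−(x − θ′)² / 2σ₁²)

peaking at the optimal duration θ′ (defaults σ₁ = 0.9 s, V<sub>max</sub> =
0.5, θ′ = 1.5 s on durations 0–5 s). Each agent holds a belief
p<sub>t</sub>(θ) over candidate optima on a 101-point grid, starts uniform,
and updates by the binary-response Bayes filter p<sub>t+1</sub>(θ) ∝
Υ(θ,x) p<sub>t</sub>(θ) after a response (1 − Υ(θ,x) otherwise). The
accommodation policy samples its next duration from the belief itself,
χ ~ p<sub>t</sub>(θ). The active policy samples from the normalized
**Expected Information Density**

&nbsp;&nbsp;&nbsp;&nbsp;EID(x) = ∫₀¹ p(V|x) · (S[p<sub>t</sub>] −
S[p<sub>t+1</sub>(θ|V,x)]) dV,

the expected Shannon-entropy reduction of the belief after a hypothetical
noisy response-likelihood measurement V = Υ(θ,x) + ε, ε ~ N(0, σ₂²),
σ₂ = 0.3.

The analysis side mirrors the standard bioacoustic workflow: syllables
separated by < 1 s merge into calls; a call counts as *responded* when a
different caller starts within 12 s; durations after the first quarter of
a session are clustered by 1-D Gaussian mixtures with the component count
chosen at the BIC elbow; duration variability is tracked as a time-binned
coefficient of variation with a sigmoid fit; and the trend in binned
response proportions is tested with a within-session case-resampling
bootstrap of its OLS slope.

## Worked example

```r
library(activecall)

sim <- run_simulation(simulation_config("accommodation",
                                        n_iterations = 1500, seed = 1))
duration_clusters(sim, seed = 1)
#> clustering_report: 2275 calls clustered; elbow k = 2 (BIC-min k = 2)
#> components (mean / sd / weight):
#>     mean     sd weight
#> 1 1.4516 0.0998 0.5089
#> 2 1.6542 0.1392 0.4911
```

After discarding the exploratory first quarter, the accommodation dyad's
call durations concentrate in two clusters hugging the 1.5-s optimum — the
policy has converged on the duration it believes maximizes responses. The
same pipeline applied to an active-sampling run
(`simulation_config("active_sampling", ...)`) instead finds modes flanking
the optimum on either side, where calls are most informative.

Synthetic sessions exercise the empirical pipeline end to end:

```r
synth <- generate_session(synth_config(seed = 1))
response_proportion_trend(synth$calls, seed = 1)
#> trend_report: slope 0.0001916 per s over 10 bins; one-sided bootstrap p = 0.005 (1000 replicates)
fit_sigmoid(binned_cv(synth$calls))
#> cv_series: 10 retained bins (min 3 calls each)
#>   sigmoid: floor 0, ceiling 0.671, midpoint 1562, steepness 0.003293
```

The generated session has a rising response rate (positive slope, small
one-sided p) and call durations that become more stereotyped as the
session progresses (falling CV traced by the sigmoid).

One-command scenario runs, with a pass/fail summary per check:

```r
cmd_reproduce("fig3-accommodation", seed = 1, out_dir = "out")
```

or from a shell: `Rscript inst/cli/activecall.R reproduce fig3-accommodation --seed 1 --out out`.

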