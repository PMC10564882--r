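# rhisusc

Bayesian hierarchical ordered-probit modelling of **rubber hand illusion
(RHI) susceptibility** and its modulation by **cardiac interoceptive
accuracy (CIA)**.

## The problem

In the classic RHI paradigm each participant gives one Likert-type
ownership rating ("the fake hand felt like my hand") after a
synchronous and one after an asynchronous stroking block, and a CIA
score from the heartbeat tracking task. The question is whether people
who perceive their heartbeat accurately are less susceptible to the
illusion. The traditional analysis — correlating CIA with the
synchronous-minus-asynchronous difference of raw ratings — treats
ordinal data as continuous and hides the (large) uncertainty of a
per-person estimate built from two ratings.

`rhisusc` is for researchers who want the model-based alternative:
ratings are ordinal outcomes of a latent normal intensity, each
participant's condition effect is a random slope, and that slope is
regressed on CIA inside the model. For participant *i* and condition
`cond` (0 = asynchronous, 1 = synchronous):

```
IHO*_i  =  (β1 + r_i)·cond + β2·CIA_i + β3·cond×CIA_i + ε,   ε ~ Normal(0, 1)
rating  =  k   iff   τ_{k-1} < IHO*_i ≤ τ_k,                 r_i ~ Normal(0, σ_r²)
```

with K−1 ordered cutpoints τ and no intercept (location lives in the
cutpoints). A participant's **susceptibility** is `β1 + β3·CIA_i + r_i`;
`β3` is the slope of susceptibility on CIA; and two effect sizes
summarize the modulation: **standardized β3** (= β3/σ_r per posterior
draw, a Cohen's-d-like contrast between hypothetical CIA = 0 and
CIA = 1 populations) and the **Bayesian R²**
(= Var(β3·CIA)/(Var(β3·CIA) + σ_r²) per draw).

The package covers the whole pipeline: CSV readers/writers and an
adapter for externally formatted tables, CIA scoring from raw trial
counts, the probit model (likelihood/prior/posterior as plain
functions), a self-contained adaptive Metropolis-within-Gibbs sampler
with split R-hat diagnostics and HPDI/equal-tailed summaries, the
derived effect sizes and per-participant susceptibility tables, and a
synthetic-data generator with exactly the model's structure. Default
priors are weakly informative (Normal(0, 2.5) coefficients,
half-Cauchy(0, 2.5) on σ_r) and the default MCMC protocol is 4 chains ×
4000 iterations with 2000 warmup.

## Worked example

```r
library(rhisusc)

data  <- simulate_dataset(generator_config(n_participants = 50, seed = 2024))
draws <- sample_posterior(data, config = mcmc_config(seed = 2024))
convergence_report(draws, parameters = c("beta1", "beta2", "beta3", "sigma_r"))
make_report(draws, data)
```

```
<rhi_convergence> 4 parameter(s), threshold R-hat <= 1.1
  overall: PASS (max R-hat = 1.035)
== Parameter summary (posterior median, 95% CrI) ==
  beta1     0.255  [-2.055, 2.680]
  sigma_r   2.654  [1.648, 4.029]
  beta2     0.073  [-1.380, 1.594]
  beta3     1.380  [-2.001, 4.740]
== Effect sizes ==
  standardized_beta3    0.517  [-0.759, 1.88] (equal_tailed)
  bayes_r2              0.008  [2.18e-08, 0.0588] (hpdi)
== Susceptibility ==
  29 of 50 participants include 0 in the 95% CrI (21 exclude it)
```

Reading this output: the fifty simulated participants carry a true
interaction of β3 = 0.33, yet its credible interval spans almost seven
latent-scale units and comfortably includes zero — at this sample size
the design simply cannot pin down the modulation, which is the
uncertainty regime real RHI datasets of this size live in. The R²
median of 0.008 with an HPDI hugging zero says CIA explains essentially
none of the between-person variance in susceptibility here, and 29 of
50 participants have susceptibility intervals spanning zero. The
convergence line reports the split R-hat gate (accepted at ≤ 1.1) for
the four focal parameters.

Real data enter through `read_ratings()` / `read_heartbeat_trials()` /
`read_cia_scores()` (native CSV layouts) or `read_external_ratings()`
(column-mapping adapter for open datasets), then `cia_scores()` and
`assemble_dataset()`; the fitting and reporting calls are identical
from there.

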