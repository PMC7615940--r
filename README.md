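# mrfocus

Focused instrument selection and post-selection inference for
two-sample summary-data Mendelian randomization (MR).

## The problem

MR estimates the causal effect θ₀ of a risk factor on an outcome from
per-variant GWAS summary statistics: exposure associations β̂_Xj ± σ_Xj
and outcome associations β̂_Yj ± σ_Yj from two non-overlapping samples,
under the model β_Yj = β_Xj·θ₀ + τ_j, where τ_j ≠ 0 marks an invalid
(pleiotropic) instrument. Investigators often trust a **core** set S₀ of
instruments (e.g. variants in a biologically justified gene region) and
are unsure about many **additional** candidates S. Using S may be worth
a little bias for a large variance reduction.

`mrfocus` implements:

* **LIML estimation** on any instrument subset, with many-weak-instrument
  variance corrections:
  θ̂ = argmin_θ Σ_j (β̂_Yj − β̂_Xj θ)² / (σ²_Yj + σ²_Xj θ²);
* **Focused selection** between the Core and Full (or k-means-derived
  candidate) instrument sets by estimated asymptotic MSE:
  Ŵ = max(b̂² − Δ̂_B, 0) + Δ̂_F − Δ̂_C, selecting Full iff Ŵ ≤ 0,
  where b̂ is an asymptotically unbiased estimate of the Full
  estimator's bias under locally invalid instruments;
* **Post-selection confidence intervals**: standard Core/Full, the
  naive interval (a baseline that can collapse), the 1-step and 2-step
  constructions, and the **focused interval**, which simulates the
  mixture limit Λ(b) of the post-selection estimator and picks the
  single plausible bias value whose interval keeps at least
  1 − α₂ − γ mass of Λ(b″) for every plausible b″ — guaranteeing
  asymptotic coverage of at least 1 − α − γ while staying inside the
  2-step envelope;
* a **simulation harness** (calibrated concentration parameters,
  uniform local direct effects, fixed-effects τ) reproducing the RMSE,
  coverage and length experiments, and a **CLI**.

## Worked example

A synthetic 110-variant dataset (10 core variants, moderate invalidity)
ships with the package:

```r
library(mrfocus)
dat <- read_summary_table(system.file("extdata",
  "example_summary_synthetic.tsv", package = "mrfocus"))
sel <- focused_estimate(dat)
print(sel)
#> Focused instrument selection
#>   theta_core = 0.187995 (se 0.04993)   theta_full = 0.226326 (se 0.01556)
#>   b_hat = 0.0387094   W_hat = -0.00225119
#>   AMSE: core 0.00249344, full 0.000242259 -> selected: full
#>   theta_focused = 0.226326
interval_standard(sel$est_core, 0.05)
#> core 95.0% CI: [0.0901255, 0.285865]
interval_focused(sel, alpha = 0.05, gamma = 0.2, seed = 1)
#> focused 95.0% CI: [0.124436, 0.30264]  (gamma = 0.2, b* = -0.03748)
```

Reading: the Full estimator's estimated AMSE (0.00024) undercuts the
Core estimator's variance (0.0025), so the additional instruments are
kept (Ŵ ≤ 0) and θ̂ = 0.226 with a much smaller standard error than the
core-only fit. The focused 95% interval accounts for the selection step
(the naive interval here would just be the Full Wald interval); γ = 0.2
caps the worst-case asymptotic coverage loss at 0.2.

The same analysis from the shell:

```sh
Rscript inst/cli/mrfocus.R ci inst/extdata/example_summary_synthetic.tsv \
  --method focused --alpha 0.05 --gamma 0.2 --seed 1 --out report.txt
```

## Documentation

The methods vignette
(`vignettes/focused-instrument-selection.Rmd`) describes the model and
assumptions, every tunable parameter, the Monte-Carlo conventions
(shortest-mass windows, shared draws, PSD policy), what the synthetic
generator does and does not emulate, and known limitations.
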