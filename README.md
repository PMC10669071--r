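# baroloop

Closed-loop estimation of baroreflex sensitivity (BRS) from beat-to-beat
heart-period (interbeat interval, IBI) and systolic blood pressure (SBP)
recordings, for researchers in autonomic and cardiovascular physiology.

Heart period and blood pressure regulate each other simultaneously: SBP
fluctuations drive IBI through the baroreflex (feedback, ms/mmHg) while
IBI fluctuations drive SBP back through mechanical effects (feedforward,
mmHg/ms). The classical open-loop BRS estimator,
`alpha_o(f) = S_SBP,IBI(f) / S_SBP,SBP(f)`, ignores the feedforward arm
and mixes the two directions. `baroloop` instead fits a bivariate VAR(p)
model to the preprocessed series, transforms it to the frequency domain,
and factorizes the cross-spectral matrix as `S(f) = H(f) Σ H(f)*`. The
residual covariance is diagonalized, `Σ = D Σ_diag D^T`, which extracts
the instantaneous (same-beat) interaction `b0` along a chosen path
(SBP→IBI by default, the fast vagal limb) and yields *corrected*
closed-loop transfer functions for each arm, e.g.
`alpha_c(f) = A'_12(f) / (1 − A'_11(f))` for the baroreflex. From the
same factorization come the squared spectral coherence, the *causal*
(directed) coherence of each arm, and the percentage of each channel's
spectrum contributed by each noise source. Transfer curves are reduced to
LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) indices by four strategies: band
mean, coherence-threshold mean (0.5 n.u., with explicit N/A when no point
qualifies), Gaussian-weighted mean, and gain at maximal coherence.

Preprocessing follows the standard pipeline: cubic-spline resampling to a
uniform 4 Hz grid, MODWT wavelet detrending with an adaptive dyadic
cutoff (`f_C = f_N / 2^d`, depth chosen from a reference frequency; the
defaults give a six-level decomposition and a 0.03125 Hz cutoff), and an
ADF + KPSS stationarity gate. A seedable closed-loop simulator with known
analytic transfer functions provides ground truth for validation.

## Worked example

Simulate the coupled reference system (one-way SBP→IBI coupling with a
generative instantaneous path `b0 = 0.5`), run the full pipeline, and
read off the band indices:

```r
library(baroloop)
sim <- simulate_closed_loop_var(synthetic_preset("baroreflex",
                                                 n = 4096, seed = 1))
res <- run_full_analysis(analysis_config(sim, detrend = FALSE))
print(res)
#> analysis_result: VAR(2), radius 0.585, b0 = 0.5062
#>          transfer band              method value   units
#>     closed_biased   LF                mean 0.746 ms/mmHg
#>  ...
#>  closed_corrected   LF                mean 1.195 ms/mmHg
#>  closed_corrected   HF                mean 1.317 ms/mmHg
#>  ...
```

The AIC selects the true order 2; the reported zero-lag coefficient
`b0 = 0.5062` recovers the generative value 0.5. The biased (lagged-only)
LF gain of 0.75 ms/mmHg rises to 1.195 ms/mmHg once the instantaneous
path is extracted — matching the analytic corrected gain of the generator
(1.195 ms/mmHg at the LF band centre). The direction of coupling shows in
the causal coherences: `mean(res$causal$sbp_to_ibi$values)` is 0.36
against effectively 0 for the reverse arm, correctly identifying the
one-way SBP→IBI construction.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/baroloop.R simulate --preset baroreflex --n 4096 \
    --seed 1 --out sim.csv
Rscript inst/cli/baroloop.R run --input sim.csv --input-kind uniform \
    --no-detrend --out-dir results/
```

writing tidy CSVs (transfer gains, coherences, noise contributions, band
estimates), the model as JSON, a run log with every effective parameter,
and a summary plot.

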