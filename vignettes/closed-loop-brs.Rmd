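---
title: "Closed-loop baroreflex analysis with baroloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop baroreflex analysis with baroloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(baroloop)
```

## The problem

Spontaneous baroreflex sensitivity (BRS) is the gain, in ms/mmHg, of the
reflex path by which systolic blood pressure (SBP) fluctuations drive
heart-period (interbeat interval, IBI) fluctuations. The classical
frequency-domain estimator treats the system as open loop:

$$\alpha_o(f) = \frac{S_{\mathrm{SBP,IBI}}(f)}{S_{\mathrm{SBP,SBP}}(f)},$$

the ratio of the cross-spectrum to the pressure auto-spectrum. But the
cardiovascular system is a closed loop: SBP drives IBI through the
baroreflex while IBI drives SBP back through mechanical (Starling/runoff)
effects, and both variables are additionally perturbed by noise sources
outside the loop. Open-loop estimators mix the two arms and systematically
misattribute variability; `baroloop` identifies the two arms separately
from a bivariate parametric model.

## The model

Both channels, mean-subtracted and detrended, are described by a bivariate
VAR(p):

$$y_n = \sum_{k=1}^{p} a_{11}(k)\, y_{n-k} + \sum_{k=1}^{p} a_{12}(k)\, x_{n-k} + w_y(n),$$
$$x_n = \sum_{k=1}^{p} a_{21}(k)\, y_{n-k} + \sum_{k=1}^{p} a_{22}(k)\, x_{n-k} + w_x(n),$$

with $y$ = IBI (channel 1), $x$ = SBP (channel 2); entry $(i, j)$ couples
source channel $j$ into target channel $i$, so $a_{12}$ is the baroreflex
arm and $a_{21}$ the feedforward arm. Transforming the lag polynomial,
$A(f) = \sum_k A_k e^{-i 2 \pi f k / f_s}$, gives the noise-to-signal
transfer $H(f) = (I - A(f))^{-1}$ and the spectral factorization

$$S(f) = H(f)\, \Sigma\, H(f)^{*},$$

where $\Sigma$ is the residual covariance. The closed-loop transfer
functions of the two arms are

$$\alpha_c(f) = \frac{A_{12}(f)}{1 - A_{11}(f)} \quad (\mathrm{SBP\to IBI,\ ms/mmHg}),
\qquad
\beta_c(f) = \frac{A_{21}(f)}{1 - A_{22}(f)} \quad (\mathrm{IBI\to SBP,\ mmHg/ms}).$$

### Instantaneous (zero-lag) interactions

A lagged-only VAR pushes any same-beat interaction into the residual
correlation $\sigma_{12}$, which biases the transfer functions. The
correction diagonalizes $\Sigma = D \Sigma_{\mathrm{diag}} D^T$ with a
unit-diagonal triangular $D$ whose single off-diagonal entry
$b_0 = \sigma_{12} / \sigma^2_{\mathrm{source}}$ sits on the user-chosen
path. The fast vagal limb of the baroreflex acts within the same beat, so
the physiologically recommended default routes the zero-lag path from SBP
to IBI. The extraction propagates exactly: $H' = H D$,
$A'_k = D^{-1} A_k$, $A'_0 = I - D^{-1}$, leaving $S(f)$ invariant while
the *corrected* transfer functions now include the $A'_0$ term. The
biased (pre-correction) transfer is kept for comparison.

### Coherence, causal coherence, noise contributions

Squared coherence $|S_{12}|^2 / (S_{11} S_{22})$ measures total coupling.
Because the diagonalized sources are orthogonal, zeroing the single $H'$
entry that feeds one direction's noise into its target and rebuilding $S$
yields the *causal* coherence of the opposite direction — the coupling
attributable to one arm alone. Likewise each channel's spectrum splits
exactly into the shares $|H'_{ij}|^2 \sigma_j^2 / S_{ii} \times 100\,\%$
contributed by its own and by the foreign noise source; the two shares sum
to 100 % at every frequency.

A note on the two open-loop variants: `type_I` is $\alpha_o$ above.
`type_II` is implemented as the noise-path ratio
$H'_{\mathrm{IBI,SBP}} / H'_{\mathrm{SBP,SBP}}$. For a bivariate model
this ratio is algebraically identical to the corrected closed-loop
transfer ($H'$ is the inverse of $D^{-1}(I - A)$, so the ratio of its
first-row entries reproduces $A'_{12}/(1 - A'_{11})$ by the adjugate
identity). It is kept as a separately named output because the two
families are reported separately in the BRS literature; users should be
aware the two curves coincide here, and the package's validated ordering
statement is therefore `type_I >= type_II = closed_corrected` on coupled
simulations.

## Preprocessing: resampling, wavelet detrending, stationarity

Beat series are interpolated onto a uniform 4 Hz grid (cubic spline by
default, linear selectable; the grid never extends past the last beat
because spline extrapolation is unbounded). Windows are half-open
$[t_0, t_1)$ so that tiled windows never double-count a sample.

Very-low-frequency (VLF) drift below 0.04 Hz violates the stationarity the
VAR model needs, so each channel is detrended with the maximal overlap
discrete wavelet transform (MODWT). The dyadic band structure ties the
realized cutoff to the decomposition depth $d$:
$f_C = f_N / 2^d$ with $f_N = f_s/2$, and a user reference frequency
$f_{\mathrm{ref}}$ selects $d = \lceil \log_2 f_N - \log_2 f_{\mathrm{ref}} \rceil$ —
the depth whose deepest detail band $[f_N/2^d, f_N/2^{d-1})$ contains
$f_{\mathrm{ref}}$. At the defaults ($f_s = 4$ Hz,
$f_{\mathrm{ref}} = 0.04$ Hz) this yields a six-level decomposition and a
0.03125 Hz cutoff; $f_{\mathrm{ref}} = 0.07$ Hz yields five levels and a
0.0625 Hz cutoff. The trend is the smooth (approximation) reconstruction
with all detail levels zeroed — no coefficient thresholding — and is
subtracted from the signal.

Numerical choices:

* **Wavelet.** Default is the 16-tap Daubechies wavelet with 8 vanishing
  moments (`"d8"`; called *d16* in some R HRV packages). Compared with the
  Haar wavelet it leaves smaller relative spectral error across the
  0.04–0.4 Hz analysis range on broadband signals, which the test suite
  measures; Haar remains selectable.
* **Border handling.** The MODWT is circular; on a windowed record the
  wrap-around mixes the two record ends. By default each channel is
  extended by reflection (without repeating the edge sample) by the
  level-$d$ filter support, transformed, and cropped back. `border =
  "none"` gives the plain circular transform.
* **Record length.** A depth-$d$ transform needs at least
  $(2^d - 1)(L - 1) + 1$ samples ($L$ = filter length); the six-level
  default with the 16-tap wavelet needs 946 samples, i.e. roughly four
  minutes at 4 Hz. Shorter windows raise an error suggesting a smaller
  depth or a longer window.

Detrended segments must pass a two-test stationarity gate before
modelling: the augmented Dickey–Fuller test must reject a unit root
(p < α) *and* the KPSS test must not reject level stationarity (p > α),
per channel, α = 0.05 by default. The ADF regression includes a constant
but no trend (the series are already detrended and mean-subtracted), with
augmentation order chosen by AIC; p-values use the MacKinnon asymptotic
approximation. KPSS uses a Bartlett-window long-run variance with
bandwidth $\lfloor 4 (n/100)^{1/4} \rfloor$ and table-interpolated
p-values clamped to [0.01, 0.10]. Because each channel's verdict is gated
by a 5 %-size KPSS test, even perfectly stationary two-channel records
pass the conjunction only ~90–95 % of the time; the gate can be
overridden (`force = TRUE`), and every override is logged.

## Model fitting and validation

The VAR is estimated by equation-wise least squares on lags $1..p$ with an
intercept retained as a numerical safeguard (it is ~0 on preprocessed
input). The residual covariance uses divisor $n_{\mathrm{eff}} - p$; this
affects only AIC constants, not comparisons. Order selection minimizes
AIC over $p = 1..p_{\max}$ with all candidates conditioned on the same
$p_{\max}$ initial rows so the likelihoods are comparable; ties break to
the smaller order, and $p_{\max}$ defaults to $\min(20, \lfloor n/40
\rfloor)$ — low orders blur the spectral peaks, high orders invent extra
ones. Validation is two-fold: stability (companion-matrix spectral radius
< 1) and residual whiteness via a multivariate Ljung–Box portmanteau
statistic up to lag $h = \max(12, p + 8)$ with $4(h - p)$ degrees of
freedom. The whiteness criterion in the connectivity literature this
follows is not pinned to a specific test; the portmanteau choice is this
package's documented decision.

## Band indices

Transfer-function curves are reduced to per-band scalars over the
conventional LF ([0.04, 0.15) Hz) and HF ([0.15, 0.4) Hz) bands by four
strategies: the plain arithmetic mean; the coherence-threshold mean
(points with squared coherence > 0.5 n.u. only — the estimate is reported
as an explicit *N/A* when no point qualifies, never silently dropped); a
Gaussian-weighted mean centred at the band midpoint with
$\sigma = (\mathrm{hi} - \mathrm{lo})/4$ truncated to the band (the width
is this package's choice — the original weighting publication emphasizes
the band centre but does not fix a width); and the gain at the frequency
of maximal coherence, ties breaking to the lowest frequency for
determinism.

## The synthetic ground truth

Because validation against human recordings requires subject data, the
package ships a generator whose truth is known exactly.

* `synthetic_preset("uncoupled")` — independent AR(1) channels; the null
  reference.
* `synthetic_preset("baroreflex")` — a VAR(2) with one-way SBP→IBI
  coupling (lag-1 gain 0.9, lag-2 −0.4), resonant SBP dynamics, and a
  generative instantaneous path $b_0 = 0.5$ from SBP to IBI. This is the
  coupled reference for parameter-recovery checks: the analytic corrected
  gain is ~1.2 ms/mmHg at the LF band centre.
* `synthetic_preset("bidirectional")` — a closed loop with both arms
  active, positive feedforward (the Starling-type sign convention:
  a longer interval raises the next systolic pressure) and positively
  correlated innovations. Under these conditions the classical open-loop
  estimator over-reads the baroreflex gain relative to the closed-loop
  corrected one — the pattern reported for real cohorts — and mean
  coherence sits near 0.7.

Innovations are Gaussian (the white-noise sources of the model are not
otherwise constrained); 1000 burn-in samples remove initial transients
for spectral radii up to ~0.95; every realization is seed-reproducible
and restores the caller's RNG state. `generate_physio_like()` additionally
emulates the *shape* of a short supine recording (baseline 1000 ms with
~0.1 Hz and ~0.25 Hz rhythms, slow drift, linear IBI→SBP coupling) for
exercising the resample/detrend/window stages; it is not a dynamical
closed-loop model, and a VAR fitted to it will rightly fail the whiteness
gate because its rhythms are deterministic sinusoids.

What passing the simulation tests does *not* show: robustness to ectopy
and artifacts, to respiration as an unmodelled third variable, to
non-Gaussian or time-varying dynamics — all present in real recordings
and all outside the generator's scope.

## Problem sizes used in the test suite

Monte-Carlo checks run at the sizes a desk validation supports: order
selection and gain recovery use 20–50 realizations of n = 4096–8192 at
4 Hz; consistency sweeps use n up to 16384; the spectral-power invariant
uses one n = 65536 realization; detrending fidelity uses 1024–4096-sample
windows. Recovery at these sizes achieves median band-gain errors well
below 15 % against the analytic truth, with ≥ 90 % correct causal
direction classification and ≥ 80 % correct order selection.

## A worked run

```{r worked}
sim <- simulate_closed_loop_var(synthetic_preset("baroreflex",
                                                 n = 4096, seed = 1))
res <- run_full_analysis(analysis_config(sim, detrend = FALSE))
res$freq_model$b0          # generative value: 0.5
subset(res$estimates, transfer == "closed_corrected" & band == "LF")
```

```{r plot, fig.height = 6}
plot_analysis(res)
```

## Known limitations

* Strictly bivariate: respiration, if desired, must be handled upstream.
* Frequency-domain only; no time–frequency (wavelet-core) BRS tracking.
* The `type_II` open-loop output coincides with the corrected closed-loop
  transfer in the bivariate case (see above).
* ADF/KPSS p-values are asymptotic approximations, clamped at the table
  edges for KPSS; verdicts near α should be read with that in mind.
* Beat detection and artifact/ectopy correction are out of scope; the
  reader expects clean beat-to-beat series.
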