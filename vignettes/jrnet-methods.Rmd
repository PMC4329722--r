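---
title: "Methods: stochastic Jansen-Rit networks and cross-frequency power transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic Jansen-Rit networks and cross-frequency power transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jrnet)
```

## The model

`jrnet` simulates a small, homogeneous, all-to-all network of Jansen-Rit
cortical columns. Each column couples three neuronal populations — pyramidal
cells, excitatory interneurons, and inhibitory interneurons — through two
transformations: a linear synaptic impulse response that converts presynaptic
firing rate into postsynaptic membrane potential, and a static sigmoid that
converts mean membrane potential into population firing rate,

$$\mathrm{Sigm}(y) = \frac{2e_0}{1 + e^{r(v_0 - y)}},$$

which saturates at $2e_0$ and passes through $e_0$ at $y = v_0$. Writing the
synaptic convolution in differential form yields, per column $i$, the
six-dimensional system

$$
\begin{aligned}
\ddot y_0 &= A a\,\mathrm{Sigm}(y_1 - y_2) - 2a\dot y_0 - a^2 y_0,\\
\ddot y_1 &= A a\,\bigl(p^i_{\mathrm{exc}}(t) + C_2\,\mathrm{Sigm}(C_1 y_0)\bigr)
             - 2a\dot y_1 - a^2 y_1,\\
\ddot y_2 &= B b\, C_4\,\mathrm{Sigm}(C_3 y_0) - 2b\dot y_2 - b^2 y_2,
\end{aligned}
$$

with the canonical constants $A = 3.25$ mV, $B = 22$ mV, $a = 100$ s$^{-1}$,
$b = 50$ s$^{-1}$, $C_1 = 135$, $C_2 = 0.8\,C_1$, $C_3 = C_4 = 0.25\,C_1$,
$e_0 = 2.5$ s$^{-1}$, $v_0 = 6$ mV, $r = 0.56$ mV$^{-1}$ (`jr_params()`
defaults, all overridable). These canonical values are not free fits here:
they are validated indirectly by reproducing the known bifurcation structure
(Hopf points at 89.83 and 315.70 Hz, see below). The EEG-like observable is
$y_1 - y_2$ of the pyramidal population; for a network the electrode signal
is modeled as the unweighted average across columns.

The total excitatory input to the pyramidal population of column $i$
decomposes as

$$p^i_{\mathrm{exc}}(t) = p_{\mathrm{const}}
  + \frac{1}{N-1}\sum_{j \ne i} K_{j,i}\,\mathrm{Sigm}(y_1^j - y_2^j)
  + p_{\mathrm{osc}}(t) + \xi^i_{\mathrm{OU}}(t),$$

i.e. a constant level, afferent-normalized coupling from the other columns,
a deterministic periodic drive common to all columns, and an independent
Ornstein-Uhlenbeck (OU) noise stream per column. The input may transiently
go negative under noise; no rectification is applied, since the $y_1$
equation is linear in its input and the reference dynamics specify none.

## Noise: convention and calibration

The background noise obeys
$\dot\xi = -\xi/\tau + (\sqrt{2D}/\tau)\,\xi_w(t)$ with unit-intensity white
noise $\xi_w$. Under this amplitude convention the stationary standard
deviation is $\sqrt{D/\tau}$, which evaluates to 48.3 Hz at the default
$D = 350$ Hz, $\tau = 0.15$ s — the dispersion the model is designed to
operate at, large enough for the input to straddle the first Hopf point at
89.83 Hz when the mean sits near 90 Hz. The alternative reading
$\sqrt{2D/\tau}\,\xi_w$ would give $\sqrt{D} \approx 18.7$ Hz and is
rejected on that evidence. The OU value is initialized from the stationary
distribution, which avoids introducing an artificial noise transient on top
of the discarded mechanical transient.

Each column's white-noise stream comes from a dedicated substream with seed
$(s + 1000003\,i) \bmod (2^{31}-1)$ derived from the master seed $s$, so the
noise a column sees depends only on $s$ and its own index — never on how
many other columns are simulated. A `shared_noise` test mode feeds every
column the same stream, under which identically initialized columns remain
bit-identical indefinitely (a symmetry check of the integrator).

## Driving signals

Two deterministic drives are provided. A pure sine
$\tilde A \sin(2\pi f t)$ (defaults $\tilde A = 45$ Hz, $f = 0.25$ Hz, the
slow-rocking condition) and a composed multi-sine

$$f(t) = \tilde A' \sum_{n = n_{\min}}^{n_{\max}}
  10^{-\frac{n f_{\mathrm{step}} - f_{\min}}{f_{\max} - f_{\min}}}
  \sin\bigl(2\pi (n f_{\mathrm{step}} t + X_n)\bigr),$$

with frequencies every $f_{\mathrm{step}} = 0.05$ Hz from 0.05 to 4 Hz,
exponentially decaying weights, and random phases $X_n \in [0, 1)$. The
amplitude $\tilde A'$ is calibrated so the phase-averaged mean power equals
that of the pure sine: $\tilde A' = \tilde A / \sqrt{\sum_n w_n^2}$, giving
10.76 Hz for $\tilde A = 45$ Hz on the default grid
(`calibrate_composed_amplitude()`). A brute-force long-time average of the
generated signal confirms the match to within a few percent, and the power
is insensitive to the particular phase draw.

## Integration

The joint column/noise system is advanced with the stochastic Heun scheme:
an Euler predictor followed by a trapezoidal corrector, with the *same*
white-noise increment entering both stages. With $D = 0$ this reduces to the
deterministic Heun method, and the global error on a deterministic
trajectory scales as $O(h^2)$ (verified against a tolerance-$10^{-12}$
Runge-Kutta reference). The default step is $h = 10^{-3}$ s; halving it
changes the alpha-band power of a 10-run ensemble by well under 5%, so the
default step is adequate for the spectral statistics of interest. The
compiled kernel (Rcpp) makes a 1000-s four-column run a sub-second
operation; a plain-R stepper with identical arithmetic is kept as a
cross-validation oracle.

Initial conditions default to the zero state (the reference dynamics do not
specify them); the configurable initial transient — 10 s by default —
absorbs the settling and is discarded before any analysis. Runs are
bit-reproducible from the master seed.

## Bifurcation analysis

At an equilibrium the system reduces to a scalar fixed-point equation in
$y = y_1 - y_2$, solved by a dense sign-change scan plus bisection and
lifted back to the full state. The equilibrium curve is S-shaped: three
equilibria coexist below the fold near 113.6 Hz, a single branch persists
above it. Linear stability uses the analytic Jacobian with
$\mathrm{Sigm}'(y) = r\,\mathrm{Sigm}(y)(1 - \mathrm{Sigm}(y)/2e_0)$
(cross-checked against finite differences). `hopf_scan()` follows the upper
branch — the one that exists at every input level — and bisects sign changes
of the leading complex pair's real part, recovering the two Hopf points at
89.83 Hz (cycle frequency ~10.4 Hz, in the alpha band) and 315.70 Hz.

Attractors of deterministic runs are classified from the trajectory:
`fixed_point` below 0.1 mV peak-to-peak; otherwise `spiky_cycle` when the
dominant spectral frequency is below 6 Hz *and* the peak-to-peak amplitude
exceeds 8 mV; otherwise `alpha_cycle`. The thresholds sit between the two
regimes' simulated characteristics — the alpha cycle runs at ~10 Hz and a
few mV, the spiky cycle at ~3-5 Hz and >10 mV — and are overridable. The
spiky/alpha coexistence window is located by simulation-based bisection on
the *existence* of the spiky attractor: each probe input is tested from a
library of initial conditions (all equilibria, ±2/±10 mV perturbations of
$y_1$, the origin) plus a continuation state carried over from the nearest
input where the spiky orbit was confirmed. Continuation is what finds the
branch reliably near its fold, where its basin shrinks. Probes are 40-s
deterministic runs with 15 s settling; classification uses the final 25 s.
With a 0.05 Hz bisection tolerance the window comes out as
[113.60, 137.28] Hz against the published [113.58, 137.38] Hz; residual
discrepancies of this size are expected from the finite probe length near
the fold (where transients slow critically) and are reported, not rounded.

## Spectral estimation

`welch_psd()` averages modified periodograms over Hann-windowed segments of
20 s with 10 s overlap (0.05 Hz resolution — exactly the composed drive's
frequency grid). Each segment's mean is removed before windowing; without
detrending the 0 Hz bin dominates every low-frequency comparison. The
one-sided density is normalized per Hz so that its integral equals the
signal variance; all headline comparisons are ratios, which any consistent
normalization leaves unchanged. Band powers are trapezoidal integrals with
optional notches (a ±0.1 Hz notch, two Welch bins, is used to exclude the
drive line when comparing the 0-5 Hz band). Relative change maps are
$10\log_{10}(\mathrm{PSD}_{\mathrm{driven}}/\mathrm{PSD}_{\mathrm{stat}})$,
with zero-density bins flagged `NA` rather than infinite.

## Experiments and their defaults

The pipelines mirror the reference computational designs: a single noisy
column at $p_{\mathrm{const}} = 90$ Hz; the coupled $N = 4$, $K = 15$,
$p_{\mathrm{const}} = 75$ Hz network (whose mean effective pyramidal input
self-consistently lands near 90 Hz, with coupling-input coefficient of
variation near 1); sine and power-matched composed driving with a
10-realization phase ensemble; and response maps sweeping drive amplitude
(`0, 15, 30, 45, 60, 90` Hz), drive frequency
(`0.1, 0.25, 0.5, 1, 2, 5, 10, 15, 20, 25` Hz), and network size
(`2, 4, 8, 16`). The sweep grids are package defaults chosen to span the
published axes at desk scale; they are not printed anywhere in the source
material. Driven and stationary runs of a comparison share the same noise
seed: matched pairing reduces the variance of the dB maps without biasing
the expected ratio.

## What the simulations do and do not show

The generator *is* the study system — there is no external data. Runs used
by the test suite are deliberately desk-scale: 100-310 s of simulated
activity and 3-10 replicates instead of the reference 1000 s, which leaves
roughly ±0.5 dB of seed-to-seed variability in band-averaged dB changes.
The robust findings at this scale are the 1/f^b-like broadband spectrum
with an embedded alpha peak, the ~1.8x alpha-band power increase under slow
sine driving, the low-frequency power increase under composed driving (vs a
decrease outside the drive line for the pure sine), and the 1:1 response
ridge. The *decrease* of alpha power at high driving frequencies is a weak
effect at this scale (a fraction of a dB); the suite therefore tests the
loss of the alpha increase rather than its strict sign reversal. Full-length
settings remain a configuration choice away (`sim_config(duration = 1010)`).

Known limitations: homogeneous columns only (one shared parameter set, as in
the reference network); no conduction delays, plasticity, or spatial
embedding; no limit-cycle continuation (Floquet) machinery — cycle existence
is probed by simulation; and the OU intensity parameter $D$ is stored under
its conventional label (Hz) without resolving its dimensional status, the
dynamics being fully defined by the stated SDE convention.

## A worked call

```{r, eval = FALSE}
hopf_scan(80, 100)                      # first Hopf point: p = 89.832 Hz
coexistence_boundaries(tol = 0.05)      # spiky window: 113.60 - 137.28 Hz
rd <- run_driven(duration = 210, seed = 1)
band_power(rd$psd_sine, 8, 12) /
  band_power(rd$psd_stationary, 8, 12)  # alpha-band increase, ~1.8
```
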