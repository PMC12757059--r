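---
title: "normnet: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{normnet: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`normnet` simulates a two-layer spiking circuit model of visual cortex and
the analysis pipeline used to study the neuronal heterogeneity of divisive
normalization: why neurons in higher visual areas differ so widely in how
sublinearly they combine responses to two stimuli, what circuit quantity
that heterogeneity tracks, and what it buys the population code. This
vignette documents the model, the parameters, the numerical choices, and
the places where the design was genuinely open and we had to decide.

## The model

**V1 front end.** 5000 linear-nonlinear-Poisson neurons on a uniform grid
covering the sheet $\Gamma = [0,2]\times[0,1]$. Neurons on the left half
(population V1$_1$) share a receptive-field centre at $(0.5, 0.5)$, those
on the right half (V1$_2$) at $(1.5, 0.5)$. Each neuron's receptive field
is a Gabor filter at its preferred orientation $\theta_i$, with envelope
SD $\sigma = 0.2$ and wavelength $\lambda = 0.6$ (domain units), matching
the stimulus Gabors. The instantaneous rate is the half-rectified filter
response to the noisy image,
$r_i(t) = g\,[F_i \cdot (m + \nu\,\xi(t))]_+$, and spikes are drawn as an
inhomogeneous Poisson process by per-bin Bernoulli thinning on the
integrator clock (dt = 0.05 ms).

Pixel noise $\xi$ is an Ornstein-Uhlenbeck process per pixel,
$\tau_n\,d\xi = -\xi\,dt + \sigma_n\,dW$ with $\tau_n = 40$ ms and
$\sigma_n = 3.5$, so the stationary pixel variance is
$\sigma_n^2/(2\tau_n)$.

**Orientation maps.** Preferred orientations come from superimposed-
plane-wave pinwheel maps: $z(x,y) = \sum_{j<n} \exp(i\frac{2\pi}{\Lambda}
l_j[\cos(j\pi/n)x + \sin(j\pi/n)y] + i\phi_j)$ with $n = 30$ waves,
column spacing $\Lambda = 0.125$, random signs $l_j = \pm 1$ and uniform
phases. We take $\theta = \arg(z)/2$ wrapped into $[0, \pi)$ — the
standard half-angle convention for orientation maps. (The original description of this map
also admits a $\arg(z)/(2\pi)$ form, which would compress
orientations into a quarter turn and is dimensionally inconsistent with
the $\cos\theta$ in the Gabor filters; we treat it as a typesetting
artifact and do not reinterpret it elsewhere.) V1 and V4/MT maps are
generated independently.

**V4/MT layer.** 20 000 excitatory and 5000 inhibitory exponential
integrate-and-fire neurons:
$C_m \dot V = -g_L(V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} + I(t)$,
with $\tau_m$ = 15/10 ms (E/I), $E_L = -60$, $V_T = -50$,
$V_{th} = -10$, $V_{re} = -65$ mV, $\Delta_T$ = 2/0.5 mV, and
$\tau_{ref}$ = 1.5/0.5 ms. At threshold crossing the membrane is clamped
(we hold at $V_{th}$; whether the clamp sits at $V_{th}$ or $V_{re}$ is
not observable downstream) for $\tau_{ref}$, then reset. Synapses are
current-based double exponentials normalised to unit integral, rise/decay
1/5 ms (E), 1/8 ms (I); feedforward synapses mix a fast (1/5 ms) and a
slow (2/100 ms) component with weights 0.2/0.8. Forward Euler at
dt = 0.05 ms; synaptic filters use exact exponential state updates; no
transmission delays.

**Connectivity.** Each presynaptic neuron makes exactly $K^{out} =
\bar p\,N_{target}$ contacts per projection (repeats allowed): 200 (E to
E), 800 (I to E), 150 (E to I), 200 (I to I), 1000 (V1 to E), 250 (V1 to
I). 85% of the connections follow a wrapped-Gaussian distance profile
(widths $\sigma_e = \sigma_i = 0.2$, $\sigma_{ffwd} = 0.1$); for
excitatory-source projections onto excitatory neurons (both recurrent and
feedforward) the remaining 15% are drawn uniformly from similarly tuned
neurons, $\cos(\theta_i - \theta_j) \ge 0.6$, anywhere on the sheet. The
cosine rule is used as stated; an orientation-doubled variant
$\cos(2(\theta_i-\theta_j))$ is available as a configuration switch.
Weights are $J_{ee} = 80$, $J_{ei} = -240$, $J_{ie} = 40$, $J_{ii} =
-300$, $J_{eF} = 160$, $J_{iF} = 140$ mV.

**Weight scaling** was an open point: the model's written convention scales weights
as $1/N$, but the stated mV weights under $1/N$ ($N = 25\,000$) give
microvolt synapses and a silent network, while balanced-network theory —
the regime this model lives in — requires $1/\sqrt N$, which yields
physiological ~0.5 mV unitary inputs. We implement $J/\sqrt N$ with
$N = N_e + N_i$.

**Control variants.** The matched-in-degree network fixes every neuron's
in-degree at the population mean of the default network for each input
type (out-degrees free, same spatial/tuning sampling distributions) — it
removes most in-degree-driven heterogeneity. The random network has no
spatial or tuning structure, and its two feedforward source populations
project onto target sets sharing a configurable overlap fraction.

## Calibration

Two front-end scales are free: the rate gain $g$ and a noise scale $\nu$
multiplying the noise contribution to the filter response. They are
solved jointly and analytically so that (i) with an image of reference
contrast 0.5 the driven population's mean rate is 10 Hz and (ii) with
noise alone it is 5 Hz. With $a_i = F_i \cdot m$ and $s_i$ the stationary
SD of $\nu F_i \cdot \xi$, the rectified-Gaussian mean
$a_i\Phi(a_i/s_i) + s_i\varphi(a_i/s_i)$ gives both constraints in closed
form up to one scalar root find. This reproduces the feedforward-drive
ratio $((10+5)+(5+10))/(10+10) = 1.5$ that anchors the mode of the
normalization-index distribution.

The stimulus contrast for the headline normalization experiments is not part of the
stated parameter set; we expose it as a configuration value with default
0.5 (the contrast used in the information protocol and in the
experimental data conventions) and report it with every result.

## Stimuli

Gabor images (25 x 25 pixels) use the same $\sigma$ and $\lambda$ as the
filters. The pixel lattice spans a square patch of side 0.5 domain units
centred on the receptive-field centre (about $\pm 1.25\sigma$); the patch
extent is not part of the stated parameter set, so it is a configuration knob fixed
once — all calibration happens after fixing it. Plaids are pixelwise sums
of two orthogonal Gabors at one centre, without clipping.

**Plaid presentation.** The stated protocol leaves open whether superimposed
stimuli are shown at one or both receptive-field locations. We present
each stimulus at both locations (the plaid experiment's "stimulus 1" is
the $\theta$ Gabor at both centres, "both" is the plaid at both centres),
which keeps both feedforward pathways engaged as in the main protocol.
The one-location variant gives very similar rotation-stability values in
our hands.

**Naturalistic surrogates.** The capacity experiment calls for grayscale
photographs downsampled so that 15 x 15-pixel patches tile the V1 grid at
stride one (114 x 64 pixels at full scale). The package generates
spectrally shaped Gaussian noise ($1/f^2$ power spectrum, per-image
distinct, pixel SD matched to the Gabor contrast range) instead of
shipping photographs; the capacity analysis is property-based, so nothing
downstream depends on photographic content. V1 rates for these images are
the rectified patch responses normalised to a 10 Hz population mean; no
pixel noise is added (trial-to-trial variability comes from Poisson
spiking and the recurrent dynamics).

## Analysis conventions

- Firing rates for indices are post-burn-in means; the first 1 s of every
  simulation is excluded everywhere.
- Normalization index $(FR_1 + FR_2)/FR_{both}$; units with
  $FR_{both} \le 0$ are excluded. Current normalization indices use
  time-averaged signed currents per type, so the inhibitory index is a
  ratio of negative quantities and reported positive.
- Unit inclusion for correlation/index analyses: mean rate within one
  population SD of the population mean in all three conditions.
- Spike-count correlations: 200-ms windows stepped by 50 ms, pooled
  across simulations of a condition, Pearson per pair. The windows
  overlap and are autocorrelated; no decorrelation correction is applied,
  by design (fidelity to the standard analysis over statistical
  nicety). A disjoint-window path exists via the window/step arguments.
- NI binning: heatmap bins of width 0.25 over [1, 3]; the |dNI| curve
  conditions on mean NI 1.5 +- 0.25; "similar" pairs have |dNI| < 0.5
  (0.6 for the covariance decomposition), matching the reference analyses.
- Tuning curves: Gabor at location 1, orientations 0-170 deg in 10-deg
  steps; tuning similarity is the Pearson correlation of curves.

## Fisher information

The ON/OFF protocol holds image 1 fixed while image 2 alternates 200-ms
ON and 300-ms OFF intervals; during OFF, V1$_2$ fires independent Poisson
spikes at 5 Hz. Per ON interval the probed parameter is $c \pm \delta c/2$
(c = 0.5, $\delta c$ = 0.01) or $\theta \pm \delta\theta/2$
($\theta = \pi/2$, $\delta\theta$ = 0.02 rad). Counts are taken from
excitatory units in ON windows; the first count of each simulation is
dropped. The bias-corrected estimator
$$\hat I_{bc} = \frac{(f_2-f_1)^\top}{\delta x}
  \Big(\tfrac{Q_1+Q_2}{2}\Big)^{-1}\frac{(f_2-f_1)}{\delta x}
  \cdot\frac{2N_{tr}-N-3}{2N_{tr}-2} - \frac{2N}{N_{tr}\delta x^2}$$
is the standard finite-trial-corrected form (alternative renderings of this
estimator differ in grouping; this form reproduces the exact trivial case
$f_2 = f_1 \Rightarrow \hat I_{bc} = -2N/(N_{tr}\delta x^2)$ exactly and
is validated against a Gaussian oracle in the tests). Ridge
regularisation ($10^{-6}\,\mathrm{tr}(Q)/N$) is applied only when the
pooled covariance is numerically singular, and warned about.

**Desk-scale caveat.** The reference full-scale protocol accumulates ~300 000 counts;
with the reference $\delta c = 0.01$ the estimator's sampling noise at
desk-scale trial counts (tens of simulations) swamps the signal — the
correction term alone is $2N/(N_{tr}\,\delta x^2)$. The package therefore
keeps the reference offsets as defaults but the desk-scale directional
test (heterogeneous vs matched-in-degree information) probes with
$\delta c = 0.2$, where the secant estimate is stable at a few hundred
trials. Reported trial counts always accompany estimates.

The analytic V1 input information uses
$f' = gT\,F\,\partial m/\partial s$ and
$\Sigma = (g\nu)^2\,\mathrm{Var}(\xi_T)\,FF^\top + \mathrm{diag}(gTFm)$
with $\mathrm{Var}(\xi_T) = \sigma_n^2[T - \tau_n(1 - e^{-T/\tau_n})]$ —
the unique grouping consistent with the OU integrated-noise asymptotics
($\to \sigma_n^2 T$ for $T \gg \tau_n$), verified against brute-force OU
integration in the tests. Rectified-silent units (zero mean response)
are dropped: they carry no information in the linearised model and make
the Poisson diagonal singular.

The $1/N$ extrapolation fits $1/I_N = (1/a)(1/N) + 1/I_\infty$ by
ordinary least squares; a non-positive intercept is reported as
$I_\infty = \infty$ (information not saturating), not an error.

## Manifold capacity

Each image's trial-by-trial population responses (100-ms spike-count
windows, $M = 0.2N$ trials for $N$ sampled units) form one manifold.
After global mean subtraction, each manifold is embedded in the affine
span of its own trials (centre = trial mean, basis from the SVD of the
centred trials, rank capped at $M-1$, coordinates scaled by the centre
norm; column signs are canonicalised so the embedding is invariant to
global rotations of response space). For each Gaussian sample
$(\vec t, t_0)$ the anchor point is the KKT solution of the projection
onto the manifold's convex hull — a small nonnegative quadratic program
solved by cyclic coordinate descent on the dual (tolerance $10^{-10}$);
identical Gaussian samples are reused across manifolds for variance
reduction. Capacity composes per-manifold inverse capacities by their
mean, $\alpha = 1/\langle F \rangle$.

The manifold dimension is implemented as
$D_M = \langle(\vec t\cdot\hat s)^2\rangle$ — the squared-average form of
the underlying mean-field formalism — rather than the unsquared average that
is sometimes written; the squared form passes the calibration
cases ($D_M \to D$ and $R_M \to r$ for a $D$-ball of radius $r$;
$R_M = 0$ and $\alpha \to 2$, the Cover limit, for point manifolds),
which we verify against a brute-force linear-program separability oracle
(random dichotomies, Gordan's-theorem feasibility via a Frank-Wolfe
minimum-norm point) in the test suite.

## Desk scaling

`scale_factor` shrinks all population sizes (grids rescale as
$\sqrt{scale}$ per axis) and with them the out-degrees, preserving the
mean connection probabilities and the $J/\sqrt N$ scaling. Defaults:
1 is the full model; 0.25 is the desk configuration used by the
acceptance script (5000 E, 1250 I, 1250 V1 neurons); the test suite uses
0.05-0.1 for directional checks. Consequences to keep in mind:

- Synapses are relatively stronger and the balance residual larger at
  small scale; the excitation/inhibition cancellation test therefore runs
  at scale 0.5, the largest desk-affordable size.
- The normalization-index mode stays near the feedforward-drive anchor of
  1.5 at scale 0.25 but drifts lower at 0.1; criteria about the NI
  distribution are tested at 0.25.
- Correlation estimates attenuate with simulation time: with 2 x 10 s per
  condition the inhibitory current-NI correlation reads about -0.45; with
  3 x 20 s it reaches the full-scale value near -0.7. The acceptance
  script uses 3 x 20 s.
- The plaid-rotation stability of normalization indices comes out near
  0.8 at desk scales (0.1-0.25) — higher than the full-scale reference of
  0.61. We report the desk value as computed; we did not find a desk-scale
  protocol that reproduces the full-scale number, and treat this as a
  known scale limitation rather than tuning it away.

## What a green test does and does not establish

The synthetic world exercises every pipeline stage with the stated
parameters, but: the naturalistic images are spectral surrogates, not
photographs; desk-scale simulations have stronger finite-size effects
than the full model; and the monkey-recording conventions
(`empirical_data_conventions`) are validated on constructed count
matrices, not on the original recordings, which are not shipped. Green
tests establish internal consistency with the stated model and the
direction and rough magnitude of the population-level effects at desk
scale, not a quantitative replication of every full-scale figure.
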