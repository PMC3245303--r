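---
title: "Dynamics of a periodically forced Jansen-Rit neural mass model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics of a periodically forced Jansen-Rit neural mass model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(photicnmm)
```

## The model

Photic driving — the entrainment of the EEG alpha rhythm by rhythmic light
flicker — is modeled here with a normalized Jansen–Rit neural mass model of a
single cortical area: pyramidal cells (PCs) coupled to an excitatory and an
inhibitory interneuron population through mean postsynaptic potentials (PSPs)
and sigmoidal potential-to-rate conversion. Both interneuron populations
receive the same excitatory synaptic kernel from the PCs, so their incoming
PSP is carried by one combined state. The state vector is
$(x_{03}, x_{31}, x_{32}, y_{30}, y_{31}, y_{32})$ — PSPs $x_{ba}$ at
population $b$ caused by population $a$, and their time derivatives
("currents") — plus the stimulus phase $\theta$.

All quantities are dimensionless: potentials are scaled by the sigmoid slope,
time by the excitatory dendritic time constant $\tau$ ($\kappa = t/\tau$).
Each synapse obeys a critically damped second-order kinetic; the excitatory
branches have unit normalized time constants, the inhibitory branch is scaled
by $\beta = \tau_e/\tau_i$:

$$\ddot{x}_{03} = O(x_{31}+x_{32}+x_{3T}) - 2\dot{x}_{03} - x_{03}$$
$$\ddot{x}_{31} = \alpha_{31}\,O(\alpha_{13}x_{03}+x_{1T}) - 2\dot{x}_{31} - x_{31}$$
$$\ddot{x}_{32} = \alpha_{32}\,O(\alpha_{23}x_{03}+x_{2T}(\theta)) - 2\beta\dot{x}_{32} - \beta^2 x_{32}$$

with the sigmoid $O(x) = 1/(1+\gamma e^{-x})$. The coupling gains derive from
the physiological constants by
$\alpha_{ba} = 2e_0\,r\,c_{ba}H_{e,i}\,\tau^2/\tau_{e,i}$ and
$\gamma = \exp(\upsilon_0 r)$; the canonical set is $\alpha_{13} = 12.285$,
$\alpha_{23} = \alpha_{13}/4$, $\alpha_{31} = 4\alpha_{13}/5$,
$\alpha_{32} = -11\alpha_{13}/13$, $\beta = 0.5$, $\gamma = 28.7892$,
$x_{1T} = 0$, $x_{3T} = 3.36$. We verified this normalization end-to-end: the
Jansen–Rit constants ($c = 135, 108, 33.75, 33.75$; $H_e = 3.25$ mV,
$H_i = 22$ mV, $2e_0 = 5\,\mathrm{s^{-1}}$, $r = 0.56\,\mathrm{mV^{-1}}$,
$\tau_e = 10$ ms, $\tau_i = 20$ ms) reproduce every default exactly, and the
unforced system oscillates at normalized frequency $0.108$, i.e. a 10.8 Hz
alpha rhythm at $\tau = 10$ ms. $\tau$ is pure metadata: it converts
frequencies by $f = \eta/\tau$ at I/O boundaries and never enters the
dynamics.

Two conventions deserve an explicit note, since they are choices rather than
forced by the equations. First, the combined interneuron state $x_{03}$ has
unit synaptic gain, with $\alpha_{13}$ and $\alpha_{23}$ applied inside the
sigmoid arguments; the alternative (folding $\alpha_{13}$ into $x_{03}$) is
an exact rescaling of that state and leaves the observer untouched. Second,
the extrinsic inputs $x_{bT}$ are summed into the axonal-hillock potential
before the sigmoid, consistent with treating them as afferent PSPs.

### The stimulus

The flicker input drives the inhibitory interneurons (thalamic feed-forward
inhibition) as a periodic pulse train
$x_{2T}(\theta) = \zeta\,\exp(-2\delta\cos^2\theta)$ with
$\dot{\theta} = \pi\eta$, so the train repeats with normalized frequency
$\eta$ (period $1/\eta$ in $\kappa$). $\zeta \in [0, 4.1]$ covers the
effective input range of the inhibitory population, $\eta \in (0, 0.19]$
brackets the intrinsic frequency, and $\delta = 110$ sets the pulse width
(the qualitative charts are robust for $\delta$ between about 109 and 130).
The pulse-train variance, used as the signal power in stimulus
signal-to-noise definitions, has the closed form
$\sigma^2 = \zeta^2 e^{-2\delta}\big(I_0(2\delta) - I_0(\delta)^2\big)$,
which the tests pin against direct quadrature to $10^{-6}$ relative error.

### The observer

M/EEG is modeled as a linear read-out of the PC membrane potential:
the observer is $x_{31} + x_{32}$, the summed PSP on the pyramidal cells. No
forward model beyond this linear map is attempted (single source,
fully-illuminated retina driving much of V1 in parallel).

## Numerics

* **Trajectory integration** uses an adaptive Dormand–Prince 4(5) scheme
  (compiled) with relative tolerance $10^{-11}$ by default, resampled at
  $\Delta\kappa = 10^{-2}$. Steps never cross an output sample, which also
  makes piecewise-constant stimulus noise exact. The default initial state is
  the unforced equilibrium (a scalar root problem, solved by `uniroot`)
  perturbed by a fixed $10^{-3}$ offset — deterministic and reproducible.
* **Lyapunov spectra** come from fixed-step classical RK4 integration of the
  state jointly with a set of tangent vectors, reorthonormalized by modified
  Gram–Schmidt QR (default every 10 steps of $\Delta\kappa = 10^{-3}$ to
  $5\cdot10^{-3}$; growth between renormalizations is at most a few percent,
  far from overflow). The stimulus phase is explicit time dependence, so six
  fiber exponents are reported and the trivially zero drive-direction
  exponent is implicit. Exponent accuracy is tracked as trailing-window
  drift (full-window vs second-half estimates); the analytic Jacobian is
  verified against finite differences to $10^{-6}$, and the exponent sum is
  checked against the state-independent divergence
  $\mathrm{tr}\,J = -4 - 2\beta$ to 1%.
* **Analysis window**: downstream spectra and histograms use the final 20%
  of the resampled trajectory by default (configurable). A fixed sample
  count would tie the window to the sampling interval; what matters is a
  transient-free window of adequate spectral resolution.
* **Spectra** are plain (untapered) one-sided periodograms normalized so the
  ordinates sum to the series variance; analysis windows are trimmed to
  5-smooth lengths because mixed-radix FFT degrades badly on lengths with
  large prime factors.
* **Histograms** use the Freedman–Diaconis bin rule as the "optimal bin
  count" (the originally cited rule is not reproduced here; FD is the
  standard robust choice).
* **Characteristic mean frequency** is the time-averaged polar-angle
  velocity about the attractor centroid in the $(x_{32}, y_{32})$ projection
  plane — an interpretive choice ($x_{32}$ is the bifurcation-diagram
  coordinate); it agrees with the spectral peak to 2% on the unforced cycle.

### Desk-scale problem sizes

The full-resolution charts in the source study used a $106 \times 69$
stimulus grid with $\kappa \approx 1.07\cdot10^{6}$ per cell on a cluster.
This package defaults to desk-scale sizes — grids of order $12 \times 24$
and spans of $5\cdot10^{3}$ to $3\cdot10^{4}$ with explicit convergence
flags — chosen so every analysis script and the full test suite run on one
CPU in minutes. All qualitative conclusions (regime charts, dimension
bounds, entrainment intervals) are stable at these sizes; the boundary
*positions* carry a one-grid-step uncertainty that the acceptance checks
state explicitly. Finer grids are plain configuration changes.

## Regime classification and its tolerances

A mode-locked (entrained) state of the forced system has all six fiber
exponents negative — the only zero is the implicit drive direction — so the
classifier counts that implicit zero: no positive exponent and no fiber zero
is "periodic" (locked); one fiber zero is "quasi-periodic" (a two-torus,
i.e. two zeros counting the drive); one positive exponent is "chaotic". The
Kaplan–Yorke dimension
$D_{KY} = k + \sum_{i\le k}\lambda_i / |\lambda_{k+1}|$ is evaluated on the
fiber exponents (with $D_{KY} = 0$ when $\lambda_1 < 0$): including the
drive zero would push every chaotic cell above dimension two and contradict
the dissipation bound the charts themselves show.

The default zero tolerance is $10^{-3}$ — below typical negative exponents
(order $10^{-1}$), above estimator noise at short spans. Near the two-torus
onset this is too coarse: the competing weakly attracting locked states have
converged exponents of only a few $10^{-4}$ (drift $<10^{-5}$ at span
$10^{5}$). Torus-onset detection therefore uses longer spans
($2\cdot10^{4}$) and a tolerance of $2.5\cdot10^{-4}$, a few times the
estimator drift at that span.

Entrainment intervals combine two signals: a clearly negative largest
exponent ($\lambda_1 < -5\cdot10^{-5}$) marks a locked cell on its own,
because deep inside a tongue the locking order $p{:}q$ can be high; at the
tongue edge $\lambda_1 \to 0^-$ continuously, so near-zero cells count as
locked only if the spectral response sits on a low-order rational multiple
($q \le 6$) of the stimulus frequency within half a spectral bin. Interior
runs of positive exponents are the chaotic islands that interrupt, but do
not terminate, an entrainment range. Tongue-edge exponents are of order
$10^{-6}$–$10^{-5}$, genuinely unresolvable in sign at desk-scale spans;
this is the dominant uncertainty in the reported interval endpoints.

## Surrogate photic-driving data

No EEG from the original experiment is available, so the `synthetic_data`
stage generates surrogate subjects with the statistical structure the
analysis assumes: 15 stimulus frequencies at ratios 0.4–1.6 of an individual
alpha frequency (9.5–11.8 Hz), one occipital channel, 62.5 s at 200 Hz
(12 500 samples) per condition. For each ratio the forced model is simulated
at $\eta = \mathrm{ratio}\times\eta_{\mathrm{int}}$ with $\tau$ chosen so
the intrinsic rhythm lands on the subject's alpha frequency; the PC observer
is rendered to physical time by cubic interpolation and white Gaussian
measurement noise is added at a controllable SNR (signal power = variance of
the noise-free rendered series). Integration tolerance for rendering is
$10^{-9}$, an accuracy/throughput balance for the 300-record test ensembles.
The experimental train structure (20 trains of 40 flashes with rest periods)
is *not* reproduced — the analysis operates on contiguous 12 500-sample
segments, so continuous stimulation is generated. The surrogates contain no
1/f background, eye blinks or line noise; robustness conclusions transfer to
real EEG only to the extent that white measurement noise is the dominant
nuisance.

## Wolf exponent estimation

The empirical largest Lyapunov exponent uses the Wolf fixed-evolution-time
algorithm on a Takens delay embedding with the study's settings: dimension
16, delay 9 samples (~50 ms), evolution 5 samples (~25 ms) at 200 Hz. The
neighbor-selection scales are not prescribed by the study and are
data-driven here: the temporal exclusion window is one embedding-window
span; the upper distance bound is 10% of the embedding extent (doubled on
exhaustion); the lower bound is three times the raw median nearest-neighbor
distance. That factor matters: the median nearest-neighbor distance of a
noisy embedding estimates the measurement-noise ball radius, and admissible
neighbors must sit *above* that ball — pairs chosen inside it measure noise
decorrelation instead of deterministic separation and invert the
exponent-vs-frequency profile on noisy records. With the factor of three,
surrogate profiles at SNR 17 dB correlate above 0.8 with their noise-free
profiles and degrade gracefully toward 0 dB, reproducing the
profile-stability behavior reported for the original recordings. On exactly
periodic noise-free series the raw floor collapses to machine roundoff, so
an absolute floor of $10^{-5}$ of the extent applies. Estimates are in
natural-log units per second, metric-scale invariant by construction.

## Model-to-data fitting

Empirical exponents (all positive under noise) are compared with model
exponents through a shift–scale map $u + v\lambda_1$ ($v > 0$) whose image
range equals the model row's exponent range, followed by a nearest-neighbor
relative error: for each of the 15 subject points, the four nearest model
frequencies are taken; Euclidean distances in the (frequency-ratio,
normalized exponent) plane are divided by the maximum attainable distance
(substituting the exponent bound farther from the query, i.e. the lower
bound when the query exceeds the bound midpoint); the minimum of the four
relative errors is kept and averaged over points. The best-fitting stimulus
amplitude minimizes this mean error (ties toward the smaller amplitude).

Which model cells define the normalization bounds is genuinely open (the
exponent map also contains positive, chaotic cells, yet the reference bounds
are negative). The package normalizes per candidate amplitude, to the range
of the non-positive exponents of that amplitude's row: normalizing every
row's comparison to one global range structurally favors the rows with the
widest exponent span and erases the amplitude information the fit is after.
The axes of the Euclidean distance are deliberately left unscaled, as in the
source procedure.

Significance uses Pearson correlation with a two-sided t-test at the
Bonferroni-corrected level $0.05/(4\,N_\zeta)$ (four neighbors times the
amplitude count), and a permutation ("bootstrap") test: shuffling the
empirical exponents along the frequency axis, refitting, and reporting the
fraction of shuffled fits with smaller error.

At desk scale the recovery of a known generating amplitude from 12 500-sample
surrogate records is weak-signal statistics: single-subject profiles at
10 dB measurement noise carry only a faint image of the model's
exponent-vs-frequency pattern, and the analysis relies on the ensemble
(median over subjects) rather than any individual fit.

## Known limitations

* Exponent boundaries (periodic-branch end, torus onset, entrainment
  endpoints) inherit one-grid-step uncertainty plus the tongue-edge
  sign-resolution limit described above.
* On surrogates the Wolf profile is nearly binary (locked records saturate
  near zero, chaotic records at a few nats per second), while the model
  row's locked exponents spread over the whole negative band. Amplitude
  recovery survives this (it integrates the error landscape across rows),
  but a frequency-permutation test on single-subject surrogate profiles
  does not separate matched from shuffled alignments; that separation needs
  exponent profiles that vary smoothly across frequency, as real EEG
  profiles do.
* The Wolf estimator compresses strongly contracting dynamics (separations
  cannot shrink below the admissible floor), so locked-state estimates
  saturate near zero rather than tracking the variational exponent's
  magnitude; comparisons rely on profile shape, not absolute values.
* The surrogate generator emulates the analyzed data segments, not the
  experiment's train/rest micro-structure, and only white measurement noise.
* No thalamo-cortical feedback dynamics: the drive is an independent signal
  generator, as in the source model.
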