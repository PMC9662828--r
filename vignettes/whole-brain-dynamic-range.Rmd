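---
title: "Whole-brain neural mass dynamics, dynamic range, and decision capacity on weighted connectomes"
author: "conndyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain neural mass dynamics and dynamic range}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conndyn)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices
made where the underlying procedures left them open, and the known
limitations. No empirical claim is made here beyond what the package's
tests and acceptance script themselves compute.

## The scientific question

A brain's structural connectome — the weighted matrix $A_{ij}$ of
connection strengths between cortical regions — constrains the dynamics
that can unfold on it. Comparing species (or individuals) at the level of
raw graphs is informative but indirect; the sharper question is how wiring
differences change each region's *operating characteristics* when the
whole network is driven through a range of excitability levels, and what
those changes imply for the network's capacity to integrate evidence and
reach decisions. `conndyn` operationalizes this with four linked layers:
neural mass simulation, response-function characterization (dynamic
range), haemodynamic/functional readouts, and a networked decision model.

## The neural mass models

### Reduced Wong-Wang (dynamic mean-field)

Each region carries one synaptic gating variable $S_i \in [0,1]$ (the
fraction of activated NMDA channels, a proxy for activity):

$$\dot S_i = -\frac{S_i}{\tau_s} + \gamma_s (1 - S_i)\, H(x_i) + D\,\nu_i(t),$$
$$H(x) = \frac{a x - b}{1 - \exp[-d\,(a x - b)]}, \qquad
  x_i = w J S_i + G J \sum_j A_{ij} S_j + I_0 .$$

Defaults (`wwParams()`): $\tau_s = 0.1$ s, $\gamma_s = 0.641$,
$D = 0.003$, $a = 270$ (V nC)$^{-1}$, $b = 109$ Hz, $d = 0.154$ s,
$J = 0.2609$ nA, $G = 0.2$, $I_0 = 0.33$ nA. The global scaling $G$ is
held fixed when comparing connectomes, so that all dynamical differences
are attributable to $A_{ij}$. The recurrent strength $w$ is the swept
control parameter, interpreted as a brain-wide excitability modulation.

$H$ has a removable singularity at $a x = b$; the implementation switches
to a series expansion there, so the transfer function is smooth
(`firingRate(109/270)` returns exactly $1/d$).

Two confirmatory variants modify the input term: conduction delays
($A_{ij} S_j(t - D_{ij}/v)$, $v = 10$ m/s by default, delays rounded to
integration steps, ring-buffer history initialized at the initial
condition), and heterogeneous excitatory input, which replaces $I_0$ by a
linear function of the region's strength rank from $I_{max} = 0.33$ nA
(weakest region) down to $I_{min} = 0.28$ nA (strongest region), ties
sharing averaged ranks.

### Wilson-Cowan replication model

To show that conclusions do not hinge on one biophysical form, an
excitatory–inhibitory Wilson-Cowan model is provided: sigmoidal activation
$H(x) = 1/(1+e^{-a(x-\mu)})$, couplings $w_{EE} = 16$ (swept),
$w_{EI} = 12$, $w_{IE} = 15$, $w_{II} = 3$, $G = 2$, drive
$G_E P_E = 0.5$, time constants $\tau_E = 2.5$ ms, $\tau_I = 3.75$ ms,
noise $D_E = D_I = 5\times10^{-5}$. As the equations place the noise
inside the $1/\tau$ bracket, the implemented increment is
$(D/\tau)\sqrt{dt}\,\xi$ — deliberately literal to the model definition.

### Numerical scheme and its choices

Both models are integrated with Euler-Maruyama (C++ cores). Points the
model definitions leave open, and the package's choices:

* **Initial conditions**: $S(0) = 0.001$ (Wong-Wang) and
  $S_E(0)=S_I(0)=0.1$ (Wilson-Cowan) — near the low branch, standard
  mean-field practice; both configurable.
* **State clamping**: $S$ is a channel fraction, so states are clamped to
  $[0,1]$ after every step; this prevents rare noise-driven escapes and
  is invisible in the bulk of the dynamics.
* **Transient removal**: the models' time averages are taken "after
  removing transients" — the window length being unspecified, the package
  discards the first 20% of the simulated interval by default
  (configurable via `transientFrac`).
* **Noise/reproducibility model**: all stochastic kernels draw standard
  normals from R's global RNG in a fixed region-major order, so any
  simulation is bit-reproducible from `set.seed()`; the zero-delay code
  path and a delay specification that rounds to zero steps are the same
  path, hence bit-identical.
* **Verification**: with $D=0$ the Euler core tracks a deSolve RK4
  reference (10× finer step) to about $10^{-3}$ sup-norm over 10 s at
  $dt = 5$ ms, and uncoupled steady states match independent root-finding
  oracles to $10^{-6}$ (`wwFixedPoint()`, `wcFixedPoint()`).

## Response functions and neural dynamic range

Sweeping $w$ over a grid (default $0$–$1$ in steps of $0.01$ for
Wong-Wang; $w_{EE}$ $0$–$20$ in steps of $0.2$ for Wilson-Cowan) and
averaging $S_i$ after the transient yields the per-region response
function $\bar S_i(w)$. Its **dynamic range** is

$$\mathrm{dr} = 10 \log_{10} \frac{w_{90}}{w_{10}},$$

where $w_x$ is the recurrent strength at which the curve first reaches
$\bar S_x = \bar S_{min} + (x/100)(\bar S_{max} - \bar S_{min})$.
Implementation decisions:

* $\bar S_{min}/\bar S_{max}$ are the observed sweep extremes, not
  asymptotic model limits — the statistic is defined on the measured
  curve, which also makes it invariant to affine rescaling of $\bar S$
  and to horizontal stretching of $w$ (both tested).
* $w_x$ is located at the *first upward crossing*, by linear
  interpolation between grid points. First-crossing is deterministic on
  noisy, non-monotone curves; an optional 3-point running median
  (`smooth = TRUE`, off by default) suppresses spurious early crossings.
* A flat curve, or a 10% crossing at or before $w = 0$, leaves the
  dynamic range undefined: such regions are reported `NA` with a warning
  and *excluded* from the distribution's $\sigma$ (their count is kept in
  `nDefined`) rather than imputed.

The distribution of regional dynamic ranges — particularly its standard
deviation $\sigma$ — is the species-contrast summary: a cortex whose
regions recruit over similar excitability windows has small $\sigma$;
a strongly graded cortex has large $\sigma$.

## Haemodynamics and functional connectivity

Neural activity drives the Balloon-Windkessel model per region
(vasodilatory signal $z$, inflow $f$, volume $v$, deoxyhemoglobin $q$;
$\kappa = 0.65$ s$^{-1}$, $\gamma = 0.41$ s$^{-1}$, $\tau = 0.98$ s,
$\alpha = 0.32$, $\rho = 0.34$, $V_0 = 0.02$, $k_1 = 4.1$, $k_2 = 0.58$,
$k_3 = 0.53$), integrated by Euler at the neural step from resting
equilibrium $z=0, f=v=q=1$. The BOLD signal is the standard *algebraic*
readout $Y = V_0[k_1(1-q) + k_2(1-q/v) + k_3(1-v)]$ — an ODE reading of
the readout would grow without bound under any sustained drive, which is
unphysical and contradicts the steady-state behaviour the rest of the
analysis relies on. The integrator is validated against the closed-form
constant-drive steady state ($f = 1 + c/\gamma$, $v = f^\alpha$, $q$ from
the extraction-balance equation) to $10^{-4}$.

$Y$ is decimated to TR $= 0.72$ s by nearest-sample decimation (the
target resolution is specified; the resampling method is the package's
choice), FC is the pairwise Pearson correlation after transient removal,
and within-network FC averages the off-diagonal entries inside each
partition block. Note that the haemodynamic model low-pass filters the
signal severely: the effective number of independent BOLD samples is far
smaller than the sample count, which is why the uncoupled-network test
pools pairs within networks before asserting near-zero FC.

## Intrinsic timescales

At fixed $w = 0.45$ (a biologically plausible, low-firing and not fully
synchronized regime), each region's normalized autocorrelation (biased,
divide-by-$N$ estimator — monotone-decaying and standard for fitting) is
fitted with $c_1 e^{-t/\tau} + c_2$ by bounded Levenberg-Marquardt
(start $(1, 0.1, 0)$; $\tau \in [dt, \text{window}]$; window 1 s by
default — the original fitting window being unstated). A fit pinned at a
bound or with negligible decay amplitude is flagged non-converged and the
region reported `NA` rather than returning a meaningless number. A
double-exponential variant reports the amplitude-weighted effective
timescale; on genuinely single-exponential inputs the two components are
only weakly identified, which is why the weighted mean (not the larger
amplitude's $\tau$) is the robust summary. Parameter recovery is
validated on exact Ornstein-Uhlenbeck signals: the generator uses the
exact discretization $x_{t+1} = \phi x_t + \sqrt{1-\phi^2}\,\xi$,
$\phi = e^{-dt/\tau}$, and recovery tests span $\tau \in \{0.12, 0.2,
0.5\}$ s with the signal duration scaled to at least 3000 correlation
times so that estimator variance, not duration, sets the 10% tolerance.

## The networked drift-diffusion decision model

Evidence accumulates per region on the connectome Laplacian
$L = \mathrm{diag}(s) - A$, $s_i = \sum_j A_{ij}$:

$$\dot y_i = \beta_i + \lambda y_i - \sum_j L_{ij} y_j + D \nu_i(t),$$

with $\beta_i = 1$, $D = 1$, boundaries $\theta = \pm 1$ ($+\theta$ is
the correct decision), $dt = 0.01$ s, horizon 5 s, ensembles of 1000
trials. A region's decision is fixed by its *first* grid point at or
beyond a boundary (no sub-step interpolation). What happens to a region
after absorption is not specified by the model statement; the package
clamps it at the boundary value, where it keeps driving its neighbours
through $L$ — this keeps the network equation well-defined after first
hits — and also implements the alternative (`absorb = "free"`: the
region keeps diffusing, only the first hit is recorded). Both give
closely similar accuracy curves; clamped is the default. Accuracy uses
all trials in the denominator (undecided trials count as not-yet-correct),
so regional curves are nondecreasing by construction.

The single-region case has a closed form — absorption at $+\theta$ with
probability $1/(1+e^{-2\beta\theta/D^2})$ — used as the acceptance oracle
(0.8808 at the defaults). `matchExcitation()` sweeps the self-coupling
$\lambda$ with common random numbers across the grid and the reference,
so that identical connectomes need $\lambda^\ast = 0$ exactly and the
Monte-Carlo comparison is paired rather than independent.

## Graph metrics

* **Clustering**: the Onnela geometric-mean triangle intensity on
  max-normalized weights. The variant matters (several weighted
  clusterings exist); a brute-force triple-enumeration oracle in the test
  suite pins the semantics.
* **Path length**: Dijkstra on distances $1/w$; regional value is the
  mean distance to all other regions; disconnected input is an error
  naming the components (the metric is undefined there, and the
  synthetic generator guarantees connectivity instead of silently
  dropping pairs).
* **Modularity**: best Newman weighted $Q$ over Louvain restarts
  (resolution 1, 100 restarts by default, maximum reported) — a stated
  selection rule for a stochastic heuristic.
* **Small-world propensity**: $\phi = 1 - \sqrt{(\Delta_C^2 +
  \Delta_L^2)/2}$ with clustering/path deviations measured against
  weight-preserving lattice and random null ensembles (10 of each by
  default, Muldoon-style: the lattice null packs the strongest weights
  nearest the diagonal in ring order, the random null scatters the same
  weight multiset uniformly), each deviation clipped to $[0,1]$. Because
  the nulls preserve the weight multiset and clustering normalizes by the
  maximum weight, $\phi$ is invariant to global weight rescaling.
* **Directed connectomes** (tract-tracing species) are symmetrized as
  $(A + A^\top)/2$ for undirected metrics; simulations keep the directed
  matrix.

Group handling follows the conventions of the respective data types:
consistency-thresholded averaging (an edge is kept iff present in at
least the threshold fraction of subjects — 60% by default) with the
retained weight averaged *over the subjects possessing the edge*; the
alternative (zeros included) is available via `includeZeros = TRUE`. The
present-only default avoids deflating weights as a side effect of the
consistency level; "present" means weight $> 0$ exactly, with no epsilon,
since the matrices are sparse by construction. Nonzero-mean averaging
(`averageNonzero()`) is the tract-tracing convention. Density matching
removes the weakest edges to a target count with a deterministic
(row, column) tie-break.

## The synthetic connectome generator

`syntheticConnectome()` emulates the statistical structure the analyses
assume: ~114 regions, ~13% density, symmetric and max-normalized,
heavy-tailed (log-normal, $\sigma = 1$) weights, 7 modules mirrored
across two hemispheric blocks (within-module affinity ×4, within-
hemisphere ×2), centroids on two parallel anterior-posterior rows
(~140 mm extent, 30 mm apart) so delay and gradient analyses are
possible, and a controllable strength gradient: edge $(i,j)$ is scaled by
$\sqrt{g_i g_j}$, $g_i = e^{\text{gs}\,(x_i - 1/2)}$ with $x_i$ the
normalized anterior-posterior position. Edges are sampled *exactly* to
the target count (affinity-weighted sampling without replacement), so the
realized density is within one edge of the request; disconnected draws
are resampled (up to 100 times) and, as a last resort, bridged by
minimum-weight edges with the weakest dispensable edges removed to keep
the count.

One subtlety: after max-normalization, the *absolute* SD of regional
strengths can decrease as the gradient grows (the gradient inflates the
maximum weight, shrinking all rescaled weights), while every scale-free
measure of spread — SD/mean of strengths, and the dynamic-range $\sigma$
downstream — increases monotonically. The property tests therefore assert
monotonicity of the relative spread, which is the only scale-meaningful
reading under max-normalization.

`syntheticCohort()` adds subject-level structure (shared skeleton,
multiplicative log-normal weight noise, a dropped-edge fraction so
consistency thresholding is exercised); `ouSignal()` provides exact
ground-truth timescale inputs.

What the generator does **not** emulate: the true degree sequence or
geometry of any real connectome, distance-dependent weight decay,
long-tailed degree hubs, or realistic inter-hemispheric homotopy. Passing
tests on synthetic data therefore demonstrate that the *pipeline*
computes its statistics correctly and that the gradient→spread→accuracy
mechanism operates as designed — not that any particular species
comparison would come out quantitatively the same on deposited data.

## Problem sizes used by the tests and the acceptance script

Analyses in the test suite and `scripts/acceptance.R` use the full
114-region connectome with sweeps of 51 grid points at 60 s per grid
point, 240–480 s single-w simulations for timescales, and 1000-trial
decision ensembles; oracle checks run on 8–25-region fixtures. These
sizes put every Monte-Carlo tolerance comfortably inside its bound while
keeping a full run in tens of seconds; the defaults baked into the
functions themselves (720 s simulations, 0.01-step sweeps, 100 Louvain
restarts) are the full-study settings.

## Known limitations

* $G$ (and all biophysical constants) are taken as fixed; no fitting of
  the coupling to empirical FC is provided, by design.
* The dynamic-range statistic depends mildly on the sweep grid through
  the first-crossing interpolation; the dense-grid oracle test bounds
  this at one coarse-grid step.
* The decision model is two-alternative with homogeneous drift; no
  reaction-time distribution fitting or multi-alternative extension.
* Delays are a single global conduction speed over Euclidean
  centroid distances — no tract-length or myelination-dependent speeds.
* The small-world propensity null models are stochastic; the reported
  value carries ensemble noise that shrinks with `nNull`.
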