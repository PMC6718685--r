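---
title: "Controlling chaotic and stochastic resonance in a discrete neural map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling chaotic and stochastic resonance in a discrete neural map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrochaos)
```

## The model

The package simulates the Sinha discrete neural system: an excitatory unit
$x(t)$ and an inhibitory unit $y(t)$ coupled through piecewise-linear
activations,

$$x(t+1) = F_a(w_{EE}\,x - w_{EI}\,y), \qquad
  y(t+1) = F_b(w_{IE}\,x - w_{II}\,y),$$

where $F_g$ saturates at $\pm 1$ outside the activation threshold $1/g$
and is linear with slope $g$ inside it.  Under the weight-ratio constraint
$w_{EI}/w_{EE} = w_{II}/w_{IE} = k$ the pair closes exactly on the
*effective neural potential* $z = x - k\,y$:

$$z(t+1) = F(z(t)) = F_a(z(t)) - k\,F_b(z(t)).$$

Throughout, the inhibitory gain and inhibition ratio are fixed at
$b = 3.42$, $k = 1.3811$, and the excitatory gain $a$ is the internal
control parameter (the studied regime is $a \approx 5.95$–$6.03$).

$F$ is odd, bounded by $1+k$, and has an interior local maximum at
$z = 1/a$ whose *value* is $f_{\max} = 1 - kb/a$ (and, by symmetry, a
local minimum value $f_{\min} = -f_{\max}$).  Because the peak value is
itself the next iterate of an orbit touching the peak, the fate of the
positive sub-attractor is decided by the *image of the peak value*:

* if $F(f_{\max}) > 0$ and $F(f_{\min}) < 0$, each orbit is trapped on one
  side of $z = 0$ (two separated chaotic sub-attractors);
* if $F(f_{\max}) < 0$ and $F(f_{\min}) > 0$, the orbit hops between the
  two regions — *chaos–chaos intermittency* — and the attractor is merged.

At $K = 0$ this flips in closed form at $a^* = (kb)^2/(kb-1) \approx
5.9919$, which `critical_a()` recovers by bisection on the numerically
located extrema:

```{r}
critical_a()
```

### RRO feedback

The reduced-region-of-orbit (RRO) feedback term

$$u(z) = -(z - z_d)\, e^{-(z-z_d)^2 / 2\sigma^2}$$

is an odd, Gaussian-localized deformation about the merging point
$z_d = 0$, with width $\sigma = 1/a$ (the distance from the merging point
to the extremum).  The iterated map becomes $F(z) + K\,u(z)$.  Positive
$K$ shrinks $|f_{\max}|$, $|f_{\min}|$ and separates a merged attractor;
*negative* $K$ enlarges them and merges a separated attractor.  The
critical strength `critical_K()` satisfies the merging condition exactly
at the boundary:

```{r}
sapply(c(5.95, 5.96, 5.97), function(a) critical_K(map_params(a)))
```

A weak sinusoidal signal $S(t) = A \sin 2\pi\Omega t$ and additive
Gaussian noise $D\,\xi(t)$ complete the full update

$$z(t+1) = F(z(t)) + K u(z(t)) + S(t) + D\,\xi(t).$$

## Indices

* **Signal response** `cross_correlation()`: the normalized delayed
  correlation $C(\tau) = C_{SZ}(\tau)/\sqrt{C_{SS} C_{ZZ}}$ between the
  drive $S$ and the binarized state $Z = \mathrm{sign}(z)$ (with $z = 0
  \mapsto +1$), maximized over integer delays.  The delay grid defaults to
  64 evenly spaced delays spanning one drive period $[0, 1/\Omega)$: the
  index is used with periodic drives, for which one period of delays
  exhausts the distinct phases.  Means and variances are taken over the
  full retained window, lagged products over the overlap.  A constant $S$
  or $Z$ (no intermittency at all) raises a typed
  `rro_undefined_correlation` condition, which sweep drivers record as a
  missing value — the white regions of a response surface.
* **Chaos** `lyapunov_exponent()`: $\lambda = \frac{1}{\tau M} \sum_k \ln
  (d^k(\tau)/d_0)$, the average log growth over $M$ restarts of a $d_0$
  perturbation evolved $\tau$ steps alongside the base orbit.  Defaults
  $d_0 = 10^{-8}$, $\tau = 1$, $M = 10^5$; for the noise-free map with
  $\tau = 1$ this equals the orbit average of $\ln|$slope$|$ across the
  map's branches, which the test suite uses as an independent oracle.
  Under noise the perturbed copy sees the *identical* noise realization
  (common-noise convention), so $\lambda$ measures state-space divergence
  only.  A separation that collapses exactly to zero — possible on the
  saturated flat branches, where the local slope is zero — is floored at
  $d_0\,\varepsilon_{\text{mach}}$ with a warning.
* **Intermittency** `intermittency_probability()`: $P_t = f_{cc}/T$ with
  $f_{cc}$ the number of sign changes of $Z$ between consecutive retained
  samples — the simplest operational event count for attractor hopping.

## Initial conditions and the saturated period-2 cycle

For $|z| > 1/b$ both activations saturate, so the map is flat at
$\mp(k-1) = \mp 0.3811$.  These branches carry a *superstable alternating
period-2 cycle* $(+0.3811 \leftrightarrow -0.3811)$ that coexists with
the chaotic attractor, which occupies only $|z| \lesssim f_{\max} \approx
0.21$.  Any initial state beyond roughly $1/(kb) \approx 0.212$ risks
capture by this cycle and never reaches the chaotic attractor.  The
package therefore defaults to $z_0 = 0.1$, and trial replication draws
$z_0$ with random sign and magnitude uniform in $[0.1, 0.2]$ — inside the
chaotic basin, on either side of the merging point.  Trials differ in
their $z_0$ draw and (when $D > 0$) in their noise stream, each derived
from one base seed.

## Simulation conventions

* **Clock.** The drive phase uses the absolute iteration index starting at
  $t = 0$, *before* transient removal, so the retained window's phase is
  well defined and $S$ and $Z$ share one clock.
* **Lengths.** Default transient $10^4$, retained window $T = 2\times
  10^5$: twenty periods of the slowest default drive $\Omega = 10^{-4}$.
  Bifurcation scans use $T = 10^5$ per initial sign (the intermittency
  onset needs hop *detection*, not phase resolution).  The acceptance
  script uses $T = 10^6$ for the noise-merging onset, where a single hop
  in a long run defines the threshold.
* **Extrema.** `find_extrema()` works on the *full* map $F + Ku$ — the map
  actually iterated — not on $F$ alone, since feedback shifts both the
  extremum locations and values; it scans $10^4$ grid points per half-axis
  of $[-(1+k), 1+k]$ and refines by golden-section search to $10^{-10}$.
  The extrema are interior and unique per half-axis throughout the
  studied parameter range; a degenerate configuration (extremum at the
  interval edge) raises an error rather than returning a boundary value.
* **Bisection.** `critical_a()`/`critical_K()` bisect the boolean merging
  condition to $10^{-6}$ and require a bracketing interval on which it
  flips.

## Drive amplitudes for the resonance experiments

The resonance curves need a fixed weak drive, and the choice matters:

* **Chaotic resonance** (`response_curve("K", ...)`): $A = 10^{-2}$,
  $\Omega = 10^{-4}$ — a clearly sub-threshold signal (half the merging
  margin $|F(f_{\max})| \approx 0.02$ at $a = 5.96$), in the middle of the
  high-response amplitude band.  The curve is unimodal with its peak just
  beyond the critical feedback strength, at the *slightly merged*
  settings.
* **Stochastic resonance** (`response_curve("D", ...)`): $A = 2\times
  10^{-2}$, $\Omega = 10^{-4}$ — at the merging margin, the lower edge of
  the high-response amplitude band.  This is the regime in which the
  noise-free drive can cause occasional, unsustained switching while an
  optimal noise level locks the switching to the signal period: exactly
  the qualitative sequence seen in the time series as $D$ grows.  Well
  above the margin (e.g. $A = 5\times 10^{-2}$) the drive alone sustains
  switching and the $D$-curve loses its interior peak — that amplitude is
  still useful as a *representative point* of the stochastic-resonance
  band at $D = 4\times 10^{-3}$, but not for locating the noise optimum.

Response surfaces annotate, per first-axis value, whether merging occurs
*without* the drive (analytically for the $K$ axis, by an undriven noisy
run from both initial signs for the $D$ axis).  The *resonance region* of
a surface — where the comparison between the two resonance modalities is
made — is the part merged without the drive; outside it, high correlation
can also arise from drive-induced switching of a separated attractor,
which is a different (non-resonant) synchronization mechanism.

## What the package computes versus what the tests show

All data are generated by the model itself; there is no external data.
The test suite checks the implementation against independent oracles
(brute-force correlation by direct transcription of its definition,
orbit-averaged branch derivatives for $\lambda$, dense-grid scans for the
extrema and critical parameters) and checks the physics against the known
regime boundaries (merging onset $a^* \approx 5.99$, chaos onset
$a \approx 5.72$, critical feedback $-0.068/-0.051/-0.035$ for
$a = 5.95/5.96/5.97$, noise-merging onset $\approx 2\times 10^{-3}$).
Quantities that depend on trial averaging are computed in the tests on
reduced grids (fewer grid points and trials, $T = 10^5$); the acceptance
script `scripts/acceptance.R` runs the full-size versions.

Two caveats on interpretation.  First, the noise-merging onset is a
stochastic first-passage quantity: it decreases slowly with run length
(a longer run gives a rare hop more opportunities), so its value is tied
to the stated $T$.  Second, the absolute height of the delay-maximized
correlation at the resonance peaks depends on conventions that published
figures rarely pin down (window length, delay grid, trial pooling); peak
*locations* and threshold *positions* are robust to these choices, and
the qualitative contract — unimodal resonance curves, response bands,
and a chaotic-resonance maximum exceeding the stochastic-resonance
maximum — is insensitive to them.

## Known limitations

* The model is the simplest neural system exhibiting chaos–chaos
  intermittency; nothing here addresses continuous-time or
  high-dimensional networks.
* The merging condition is analytic only through numerically located
  extrema; for maps outside the studied family (multiple extrema per
  half-axis) `find_extrema()` would need a different search strategy.
* Lyapunov estimates under noise use the common-noise convention; with
  independent noise streams the estimate would include a noise-induced
  component and is not what the chaos index intends to measure.
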