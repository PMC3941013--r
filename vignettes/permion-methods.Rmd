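---
title: "From steered pulling to channel conductance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From steered pulling to channel conductance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permion)
```

permion post-processes the output of steered and equilibrium
molecular-dynamics simulations of hexameric membrane channels (connexin
hemichannels and gap junction channels are the motivating system). It
covers four analyses that are usually scattered across ad-hoc scripts:

1. building a potential of mean force (PMF) from a constant-velocity
   pulling log;
2. converting a full-channel PMF into a unitary conductance via
   mean-first-passage-time (MFPT) theory, with a Debye-screening
   multi-ion correction;
3. quantifying the departure of a hexameric pore from six-fold symmetry;
4. detecting rupture (detachment) events in force-ramp pulling traces.

Because trajectories of this kind are rarely redistributable, the package
also ships generators that emulate each input with known ground truth, and
the test suite exercises every stage against that truth. Units are fixed
package-wide: nm, ns, K, kJ/mol, kJ mol^-1 nm^-1 for force, pS for
conductance.

## 1. PMF from steered pulling

A tagged ion is tied to a harmonic spring (stiffness $k$, zero rest
length) whose free end moves along the pore axis at constant velocity
$v$. When the spring is stiff and the pulling slow, the spring force
balances the systematic force of the channel on the ion, and the work
profile

$$W(z) \;=\; \int_0^{z} \bar F(\zeta)\, d\zeta$$

is the free-energy profile of permeation. `window_average_force()`
averages the instantaneous spring force over fixed time windows (40 ps by
default, matching common practice for this type of log); the window's $z$
coordinate is the mean *trap* position, because the trap is the
controlled variable (binning on the ion position is available via
`bin_on = "ion"`). `integrate_pmf()` accumulates the trapezoid integral
and anchors $W = 0$ at the cytoplasmic entry; since the PMF is defined up
to a constant and all downstream rates are gauge invariant, the anchor is
a pure convention. A full (two-hemichannel) profile is produced by
`reflect_pmf()`, mirroring the hemichannel PMF about its extracellular
end — the docked channel is assumed head-to-head symmetric.

Two biases are worth knowing about. First, steering at finite speed drags
the ion through a viscous medium, adding a constant force
$\gamma_f v$ with $\gamma_f = k_B T / D$; at the slow speeds used here
($v \le 0.1$ nm/ns) this is $\lesssim 0.1$ kJ mol$^{-1}$ nm$^{-1}$ and is
*not* subtracted by default (an optional `friction_correction` argument
exists). Second, thermal force noise survives window averaging with a
standard deviation of roughly
$\sqrt{k\,k_B T}\sqrt{2\tau_c/\Delta t_{win}}$ per window
($\tau_c = k_B T/(kD)$ is the trap relaxation time), and accumulates
along the profile as a random walk. The synthetic recovery test (20
kJ/mol Gaussian barrier, $k = 2000$ kJ mol$^{-1}$ nm$^{-2}$, $v = 0.02$
nm/ns, 40 ps windows) was sized from this budget so that the barrier
height is recovered well within 1 $k_BT$.

### The steering generator

`gen_smd_log()` integrates an overdamped (Euler–Maruyama) Langevin
equation for the ion in a prescribed profile plus the moving trap:

$$z_{n+1} = z_n + \frac{D}{k_B T}\,F_{tot}(z_n)\,\Delta t +
  \sqrt{2 D \Delta t}\;\xi_n .$$

The friction is set by the Einstein relation; the scheme requires
$k\,\Delta t\,D/k_B T < 0.1$ and refuses to run otherwise (an unstable
trap spring oscillates numerically instead of relaxing). Steering is
strictly one-dimensional: the lateral confinement of a real stiff spring
(sub-0.05 nm off-axis excursions) is not emulated because only the axial
force enters the work integral. With `noise = FALSE` the generator
produces the deterministic drift limit, which is convenient for exact
tests (the spring force then settles at the drag value $\gamma_f v$).
The integrator is compiled code driven by R's RNG, so a fixed seed
reproduces logs bitwise.

## 2. Conductance from the PMF

Permeation is modelled as 1-D diffusion in the full-channel profile. The
mean first passage time from one end to the other (absorbing far end,
reflecting near end) is the standard double integral

$$\tau = \frac{1}{D}\int_l^r e^{\beta U(y)}
  \int_l^y e^{-\beta U(z)}\,dz\,dy ,$$

with the mirrored expression for the reverse direction. `mfpt()`
evaluates it by trapezoid quadrature with the inner integral accumulated
once as a prefix sum (O(n) instead of O(n^2)); the mid-range of
$\beta U$ is factored out of the exponentials first, so barriers of
100+ kJ/mol do not overflow. A membrane potential enters as a linear tilt
(`tilt_potential()`): $U(z) = W(z) + q\,\Delta V\,(L - z)/L$, with
$q\,\Delta V$ converted at 0.0964853 kJ/mol per e·mV.

`compute_conductance()` computes forward and reverse rates
$\kappa = 1/\tau$ for each applied potential, forms the net single-ion
current $I = q(\kappa_{l\to r} - \kappa_{r\to l})$, and fits the I–V line
by ordinary least squares with a free intercept. The intercept must come
out at numerical zero; a large intercept flags a quadrature asymmetry
bug, so it is checked and warned about rather than suppressed.

Two numerical choices deserve explanation:

* **Voltage list.** The default is $\pm 5, \pm 10, \ldots, \pm 25$ mV.
  The exact I–V relation of a barrierless channel,
  $I \propto g(a) - g(-a)$ with $a = \beta q \Delta V$ and
  $g(a) = a^2/(a - 1 + e^{-a})$, carries a cubic term that depresses a
  fitted slope by $(\sum V^4/\sum V^2)\,(\beta q e)^2/180$ — about 1.4%
  for a $\pm 10\ldots\pm 50$ mV design but only 0.37% for the default.
  Since the slope at the origin *is* the unitary conductance, the
  smaller span is the better estimator; wider spans remain available
  through `dV_list`.
* **Grid.** All quadrature happens on the profile's own grid. For smooth
  profiles $\gamma_0$ moves by well under 0.5% between 512 and 1024
  points, which the tests pin down.

For a flat profile the small-signal conductance has the closed form
$\gamma_0 = 4 q^2 D / (3 k_B T L^2) \approx 54.7$ pS at the package
defaults ($D = 1.957\times 10^{-9}$ m$^2$/s, $T = 300$ K, $L = 17.2$ nm,
$q = +1$); the pipeline reproduces it within 1%, and the tests also
verify gauge invariance (adding a constant to $W$ changes nothing),
oddness of $I(\Delta V)$ for symmetric profiles, and monotone loss of
conductance as a barrier grows.

### Multi-ion correction

A single-occupancy model underestimates the current of a long channel.
Ions further apart than one Debye diameter barely interact, so a channel
of length $L$ can carry $N_I = L/(2\lambda_D)$ ions at once, and the
corrected conductance is $\gamma = N_I\,\gamma_0$. `debye_length()`
implements
$\lambda_D = \sqrt{\varepsilon_0 \varepsilon_r k_B T / (2 e^2 N_A c)}$;
at 300 K, 0.15 M and $\varepsilon_r = 78.4$ (water near room
temperature; the value is exposed as a parameter) this gives 0.79 nm, so
$N_I \approx 10.9$ for a 17.2 nm channel. `ion_count()` offers two
rounding conventions: `"printed"` quotes $\lambda_D$ to two decimals
before doubling (so $17.2/1.58 = 10.89$, the arithmetic used when these
numbers are quoted at two-decimal precision), and `"none"` divides
directly ($17.2/1.5748 = 10.92$); the half-percent difference documents
the sensitivity to intermediate rounding. Note that the correction
cancels in any ratio of two conductances — comparisons between channel
variants are unaffected by it.

Absolute $\gamma_0$ values for a *real* channel require its measured PMF
curve as input; the package computes conductances from whatever profile
it is given and makes no claim of predicting a PMF itself.

## 3. Hexamer symmetry

For each residue, the alpha carbons of the six protomers form a hexagon.
`hexagon_metrics()` projects the six vertices onto their least-squares
plane (an exact no-op for planar input, and the natural channel frame
when the pore axis is not pre-aligned), takes the three main diagonals —
opposite-vertex distances $(i, i+3)$, *not* all 15 pairwise distances,
which would include edges — and reports the eccentricity
$E = D_{max}/d_{min}$ together with the six interior angles. $E = 1$
iff the three diagonals are equal; for a planar convex hexagon the
angles sum to 720°.

`eccentricity_series()` evaluates one $E$ per (residue, frame) pair. Two
aggregations are provided because the choice genuinely matters for the
standard error: the default averages residues within a frame and takes
the s.e.m. across frame means (frames are closer to independent than
residues within a frame, which share the same protomer displacement);
`"pooled"` treats each (residue, frame) value as an observation. Neither
is claimed to be canonical; report which one you used.

The generator `gen_hex_traj()` places vertices at
$0°, 60°, \ldots, 300°$ on a circle, scales the x axis by an anisotropy
factor $a \ge 1$, and adds i.i.d. Gaussian noise per coordinate per
frame. The noiseless eccentricity is analytic,
$E(a) = a/\sqrt{a^2/4 + 3/4}$ (`hex_eccentricity_aniso()`), which gives
the worked value $E(1.2) = 1.139$. Two caveats about realism: vertex
noise alone inflates the *expected* $E$ above 1 (the maximum of three
noisy diagonals is biased upward), so a noisy estimate of $E$ is not an
unbiased estimate of the noiseless shape; and real protomer fluctuations
are correlated in time and between neighbours, while the generator's
frames are independent. Recovery tests therefore compare seed ensembles
against a long reference run *at the same noise level*, not against the
noiseless value.

Condition comparisons use the Mann–Whitney U test (`mann_whitney_u()`),
since the $E$ distributions are skewed: exact enumeration for small
samples without ties ($n_1 + n_2 \le 12$), tie-corrected normal
approximation with continuity correction otherwise. The implementation
wraps `stats::wilcox.test` (mapping W to U); the test suite checks it
against an exhaustive enumeration oracle.

## 4. Detachment forces

In a force-ramp experiment the pull force rises with slope $k v$ until
the attachment breaks, then drops abruptly. Two estimators are provided
because published analyses use both readings:

* `per_trace_drop`: the first *sustained* drop — force below
  `1 - drop_fraction` (default 30%) of the running peak for at least
  `dwell` (default 0.1 ns) — marks the rupture; the reported force is
  the pre-drop peak. On a clean ramp with rupture at 105
  kJ mol$^{-1}$ nm$^{-1}$ and $kv = 100$ per ns this reads exactly 105
  at 1.05 ns.
* `mean_trace_divergence`: given the smoothed mean traces of two
  conditions, the detachment force of the weaker condition is read off
  the reference trace at the first time the two traces separate by more
  than `n_sd` pooled local standard deviations for at least `dwell`.

The noise scale for the divergence rule is the *within-window* standard
deviation returned by `running_average()` — the local (temporal) noise
of the smoothed estimate. The across-trace pointwise spread is retained
by `mean_pull_trace()` but is deliberately not used as the divergence
threshold: in the region where some traces have ruptured and others have
not, that spread explodes and would push detection far past the true
separation point. `n_sd` defaults to 4, calibrated on the synthetic
two-condition ensemble (ruptures 105 vs 260, noise sd 5): at lower
thresholds detection fires on the earliest rupture in the averaged set
and systematically underestimates the rupture mean by several
kJ mol$^{-1}$ nm$^{-1}$, while at 4 the reading is centered on it. Both
parameters are plain arguments, not constants.

The smoothing window is a free parameter as well. Published figures of
this kind sometimes quote sub-picosecond running averages, which cannot
reduce noise on traces sampled at picosecond strides; the examples here
use 0.02 ns, about 20 samples at the generator's default stride.
A trace with no qualifying event yields a `detected = FALSE` result
rather than an error, since "no detachment within the simulated span" is
a legitimate finding (the stronger condition in a short run).

## File formats

Numeric traces (pulling logs, PMFs, pull-force sets) use a plain
whitespace-separated dialect with `#` comment lines and `@ key value`
metadata, as emitted by common MD tooling; the writers record units and
column roles, and round-trips are bit-comparable at the printed
precision. Hexamer trajectories travel as multi-model PDB (six chains,
one CA per residue; Angstrom on disk, nm in memory, converted only at the
boundary). Chain order is taken as the cyclic pore order, overridable
where that assumption fails. Results serialize to JSON.

## Problem sizes and limitations

The shipped tests run the steered-pulling recovery at $v = 0.02$ nm/ns
over 8.6 nm ($\approx 10^7$ integrator steps, a few seconds in compiled
code), the eccentricity recovery over 20 seeds of 100 frames times 13
residues against a 2000-frame reference, and the detachment recovery
over 20 paired ensembles of 6 traces; these sizes put the statistical
checks at roughly 3-sigma margins.

Out of scope by design: running molecular dynamics itself; umbrella
sampling, WHAM, Jarzynski or bidirectional work estimators;
Poisson–Nernst–Planck or Brownian-dynamics currents; ion–ion
interactions beyond the Debye count; binary trajectory formats
(XTC/TRR/DCD); pore-radius profiling and RMSD/RMSF diagnostics. The MFPT
model treats the diffusion coefficient as position independent, which is
optimistic inside a narrow pore; because conductance ratios between
variants are insensitive to a common $D$, relative statements are the
robust output of this pipeline.
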