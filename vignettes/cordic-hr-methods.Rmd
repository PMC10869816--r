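---
title: "A multiplier-free CORDIC Hindmarsh-Rose neuron: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiplier-free CORDIC Hindmarsh-Rose neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordichr)
```

## The model

The Hindmarsh-Rose neuron is a three-variable ODE system

$$
\begin{aligned}
\dot X &= Y + X^2(3 - X) - Z + I\\
\dot Y &= 1 - 5X^2 - Y\\
\dot Z &= r\,\bigl(4[X + 1.6] - Z\bigr)
\end{aligned}
$$

with membrane potential $X$, fast ionic current $Y$, slow adaptation
current $Z$, stimulation current $I$ and slow-variable rate $r$ (all
dimensionless). Depending on $(I, r)$ the neuron spikes tonically, bursts,
or fires chaotically; the inter-spike-interval (ISI) sequence is the
observable used to characterize these regimes.

The package provides two implementations of the same first-order Euler
discretization (step $\Delta t = 1/256$):

* `simulate_hr(..., model = "reference")` — double-precision floating
  point, the ground truth;
* `simulate_hr(..., model = "cordic")` — a bit-exact emulation of a
  multiplier-free fixed-point datapath in which $X^2$ and $X^3$ are
  computed by linear-mode CORDIC blocks and every constant multiplication
  is a shift-and-add schedule.

Both are deterministic: identical inputs give bit-identical traces.

## The fixed-point datapath

**Number format.** State variables span roughly $(-2, 2.5)$ and
intermediate sums stay below $\pm 16$, so the register format is
Q(15,1,10): 15 bits total, 1 sign bit, 4 integer bits, 10 fractional bits
(LSB $2^{-10} \approx 9.8\times10^{-4}$). `quantize()`, `shift_mul()` and
`const_mul()` expose the primitive operations; right shifts are arithmetic
(truncation toward $-\infty$), exactly as a hardware shift register behaves,
and out-of-range results saturate by default.

**Constant multiplication.** Every model constant ($3$, $5$, $4r$, $6.4r$,
$r$, $\Delta t$) is quantized and decomposed into canonical signed digits
(CSD), so a multiplication is a short signed sum of shifted copies of the
operand — at most one LSB of error per nonzero digit, and no general
multiplier anywhere. $\Delta t = 1/256$ is a single right shift by 8.

**CORDIC power blocks.** In linear rotation mode, CORDIC computes $x\cdot z$
by driving $z$ to zero through the shift schedule
$2^{-i_0}, 2^{-i_0-1}, \dots$ while accumulating $d\, x\, 2^{-i}$ into $y$,
with $d = \mathrm{sign}(z)$ and $\mathrm{sign}(0) = +1$. We use
$i_0 = 0$ and 11 iterations, giving convergence for $|z| \le 2 - 2^{-10}$
and a residual error of $|x|\,2^{-10}$. Squaring sets $y = 0$, $z = x$.
Because $X$ exceeds the $(-2,2)$ operand range, the extended block halves
its input, squares, and rescales by 4 ($x^2 = 4(x/2)^2$); the cubing block
chains a squaring and a linear multiply
($x^3 = 8\,[(x/2)^2 \cdot (x/2)]$). Three numerical choices matter here:

* *Shift placement.* The halving and scaling shifts belong to the block
  interior and run at the block's internal width; only the output register
  truncates back to Q(15,1,10). Re-truncating after the input halving
  would add a systematic negative bias of order one LSB that measurably
  distorts the neuron's bifurcation boundaries.
* *Guard bits.* The iteration loop carries 16 guard bits below the I/O
  fraction so that every scheduled shift is representable and
  per-iteration truncation does not accumulate; this also permits
  schedules longer than the fraction width (used by the convergence test
  at 24 iterations / 20 fractional bits).
* *Tie-break.* $\mathrm{sign}(0)=+1$ makes the zero-operand case walk the
  full schedule and land one ulp away — the documented error bound, not a
  special case.

The test suite verifies $\max |{\rm POW2}(x) - x^2| < 2^{-9}\,\max x^2$
and the cubic analogue over $10^4$-point grids, sign symmetry up to the
residual bound, and that errors shrink monotonically with more iterations.

**State accumulators.** The Euler updates accumulate into wide registers
with 26 fractional bits (31-bit payloads), truncated to Q(15,1,10) only at
the power-block input register. This width is forced by the slow variable:
its per-step increment $\Delta t \cdot r \cdot O(1) \approx 4\times10^{-5}$
is far below the 15-bit LSB, so a 15-bit accumulator would freeze $Z$ and
destroy bursting and the entire bifurcation structure. A hardware
implementation needs the same separation between datapath width and
accumulator width.

With these choices the fixed-point neuron tracks the reference trace at
$I = 0.5$, $r = 0.0021$ with $X$-correlation $\approx 0.9994$ and mean
absolute error $\approx 1.1\times10^{-3}$ over 1000 time units after a
200-unit transient (computed by the acceptance script); a high-precision
configuration (24 iterations, 20 fractional bits) agrees with the
reference to $\sim 10^{-5}$, confirming that the residual error is
quantization, not model error.

## Spike detection and ISI classification

Spikes are upward crossings of $X$ through 1.0 separated by at least one
time unit — the threshold sits between the resting level near $-1.6$ and
spike peaks near $2$. For regime classification (`classify_period()`),
steady-state ISIs are grouped by single-linkage clustering at a 2%
relative gap; a firing pattern is *periodic* when there are at most 8
clusters and the cluster-label sequence repeats cyclically (95% of
positions, absorbing edge effects), and the reported period is the number
of distinct ISI clusters — the number of branches a bifurcation diagram
shows. Anything else is *chaotic*. The cyclicity condition matters:
chaotic ISI sets can chain into few clusters under single linkage, and
only their aperiodic ordering betrays them.

Sweeps (`bifurcation_sweep()`) simulate 2000 time units per parameter
value from the fixed initial state $(0.1, 1, 0.2)$ and discard the first
half; 2000 units yield $\ge 25$ steady ISIs in the slowest regimes while
keeping a 61-point sweep under half a minute.

### What the sweeps show

Versus $r$ at $I = 3$: chaotic firing at $r \le 0.006$, period 4 at
$r = 0.007$, period 2 at $r = 0.018$, period 1 from $r \approx 0.04$ — and
the float reference produces the identical label sequence at these points.

Versus $I$ at $r = 0.005$ (step 0.05): the neuron is quiescent below
$I \approx 1.3$, then a period-adding cascade $3 \to 4 \to 5$ unfolds,
interrupted by a narrow chaotic window at $I = 2.8$, with dense chaos from
$I \approx 3.0$ to $3.35$ and a collapse to simple period-1/2 spiking
around $I = 3.5$. Two honest caveats, both reproduced identically by the
floating-point reference and therefore properties of the model rather than
of the fixed-point datapath: the cascade reaches a genuine period-5 band
(at $I = 2.85$–$2.95$, plus a period-5 point at 2.75) before sustained
chaos, and the first chaotic window under this scan protocol appears near
$I = 2.8$, well before the dense chaotic band that a coarse reading of the
diagram would place near 3.2. Narrow inter-band chaotic windows are a
standard feature of period-adding cascades; whether one calls the cascade
"up to period 4" or "up to period 5" depends on scan resolution and on
whether those windows are resolved.

## Nullclines, equilibria and phase space

With one variable clamped, `hr_nullclines()` samples the two nullclines of
the X–Y plane ($Y = X^3 - 3X^2 + Z - I$ against $Y = 1 - 5X^2$) or the X–Z
plane ($Z = -X^3 + 3X^2 + Y + I$ against $Z = 4X + 6.4$); the CORDIC
variants replace the cubic and quadratic by the power blocks.
`find_equilibria()` intersects them — exactly (cubic roots) for the
reference, by sign-change scanning at block resolution for the CORDIC
curves, merging crossings within one quantization plateau (0.05 in $X$)
because a staircase-valued difference curve can graze zero repeatedly near
a root. The models agree on equilibrium count and coordinates to a few
times $10^{-4}$, and steady-state phase portraits agree to a Hausdorff
distance below 0.1.

## The random network

`build_random_network()` wires $n = 1000$ neurons with independent
directed connections at probability 0.2 (about 200,000 synapses), 80%
excitatory / 20% inhibitory assigned by shuffled index block, unit weight,
sign set by the presynaptic neuron. The membrane equation of the coupling
is this package's own modeling choice (nothing canonical exists for it):
each presynaptic spike injects a current step $\mathrm{sign}\cdot w\cdot g$
into its targets, decaying exponentially with $\tau_{\rm syn} = 10$ time
units. The scale $g = 0.002$ keeps a 1000-neuron population at $I = 0.5$
spiking without saturation. The synaptic accumulator is floating point and
is quantized on injection; the neuron datapath itself remains
multiplier-free. Tests verify that a weightless network reproduces $n$
independent single-neuron simulations bit-exactly, that synapse counts
follow binomial moments across seeds, and that reference and CORDIC
populations produce closely matching per-neuron spike counts.

## Spike-frequency gates

Boolean values are frequency-coded: rates in $[0, 5)$ Hz mean logic 0,
rates in $[5, 20]$ Hz mean logic 1 (the boundary belongs to the one-band),
with canonical carriers of 2 Hz and 10 Hz and one model time unit mapped
to 1 ms, so model ISIs of 50–200 units land in the one-band.

A gate is a single CORDIC neuron receiving a bias current plus its inputs
through current synapses. Getting this to work exposed three properties of
the neuron that fix the design:

1. *Sharp rate threshold.* With slow adaptation the steady firing rate is
   0 up to $I \approx 1.3$ and 6–20 Hz just above — a clean decision
   boundary for mean-drive logic.
2. *Change detection.* Step discontinuities in the drive trigger
   adaptation-rebound bursts regardless of the mean, so the synapses are
   double-exponential (rise 60, decay 120 time units), which keeps the
   drive continuous; and the gate neuron uses $r = 0.01$ so its adaptation
   tracks the residual slow bumps from 2 Hz carriers instead of bursting
   through them.
3. *Startup transient.* From a cold start the unadapted neuron fires a
   burst for hundreds of time units, so gates run a 1000-unit settling
   period and measure their output rate on the following 1000-unit
   steady-state window — a streaming device sampled in equilibrium.

Because the rate threshold is sharp, the mapping from input *rate* to mean
drive cannot tolerate band-edge inputs (a 5 Hz "one" produces half the
drive of a 10 Hz "one"). Gates therefore restore logic levels first, as
electronic gates do: each input train is decoded to its band and the
canonical carrier of that band regenerated before the synapse. The
calibration constants, found once by a coarse grid scan over weights and
bias and frozen in the package, are

| gate | weights | bias | measured rates (00, 10, 01, 11) |
|------|---------|------|---------------------------------|
| AND  | 0.50, 0.50 | 0.50 | 2, 2, 2, 10 Hz |
| OR   | 0.46, 0.46 | 0.75 | 2, 6, 6, 10 Hz |
| NOT  | −0.90      | 1.90 | 7, 0 Hz |

All truth tables hold with every output inside its band, and the
De Morgan composition `NOT(AND(a,b)) == OR(NOT a, NOT b)` holds on all
four input pairs through actual gate chaining.

## Cellular-logic image filters

Three binary morphological filters are built from AND/OR/NOT over the
4-neighborhood, with edge-replication padding (the border policy is a
package choice; it keeps solid regions touching the frame solid):

* **Edge detection** — `f = g AND NOT(up AND left AND down AND right)`:
  keeps exactly the foreground pixels with at least one background
  4-neighbour, so `f <= g` pointwise.
* **Magnification (3x)** — each source pixel is placed at the anchor of a
  3x3 block of an upsampled zero grid and each output pixel is the OR of a
  3x3 window; with the anchor at the block's last row/column every window
  sees exactly one anchor, and the result is exact block replication
  (equal to `kronecker(g, matrix(1,3,3))`, which the tests assert).
* **Noise removal** — an OR of nine three-term AND clauses over the
  4-neighborhood: isolated pixels are deleted, solid regions preserved.
  The clause set is asymmetric: a convex corner supported only from above
  and the right matches no clause and is shaved by one pixel per
  application, so the filter is idempotent on full-width bands but not on
  free-standing rectangles. The tests pin the filter to an independently
  coded clause table on all 512 neighborhood patterns.

Grayscale images are handled by decomposing into 8 bit planes, filtering
each, and recombining — a package interpretation, chosen because it makes
the binary filter's guarantees carry over plane-wise.

Every filter runs on two interchangeable backends. `backend = "logic"`
evaluates the Boolean expressions directly. `backend = "spiking"` routes
every gate through the frequency-coded CORDIC neuron gates; since the
gates are deterministic, each distinct (gate, input combination) is
simulated once and memoized, so a megapixel filter costs the same ten
neuron simulations as its truth tables. The tests assert pixel-for-pixel
equality of the two backends — the logic semantics is the oracle, the
spiking path is the implementation under test.

Noise generators (`add_noise()`) provide seeded salt-and-pepper
(probability 0.10 by default, half salt / half pepper), additive scaled
zero-mean Poisson ($\lambda = 1$, scale 32, clipped to 8 bits) and
additive Gaussian noise; `mse_psnr()` scores reconstructions. On the
synthetic shapes fixture, one pass of the noise filter raises PSNR of a
10% salt-and-pepper corruption from about 13.5 dB to about 22.5 dB
(computed in the test suite). Absolute MSE/PSNR values on photographic
material depend entirely on the test image and are out of scope.

## Problem sizes and reproducibility

Default study sizes, chosen to keep the full suite and the acceptance
script within a few minutes of one CPU while leaving ample steady-state
data: 2000 time units (512,000 Euler steps) per bifurcation point with the
first half discarded; a 61-point current sweep; 1200 units for
trace-matching metrics (200 discarded); 2000 units per gate evaluation;
network demonstrations at $n \le 1000$. All randomness (wiring, noise,
subsampling) flows through explicit integer seeds; the simulations
themselves are integer-exact and seed-free.

## Known limitations

* The synaptic models (network coupling and gate synapses) are documented
  stand-ins; the qualitative network claims (tonic population regime,
  reference/CORDIC equivalence) are robust to their details, but absolute
  population rates are not.
* The ISI classifier's 2% cluster tolerance and the chaos cutoff at 8
  clusters are tunable conventions; near bifurcation boundaries the label
  of a single scan point can depend on them.
* The synthetic image fixtures are binary-dominated geometric shapes;
  performance figures on them do not transfer to natural images.
* Fixed-point emulation targets the documented register widths; other
  accumulator-width choices would need their own validation against the
  reference model.
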