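---
title: "Planning and dosimetric QA for dynamically collimated proton scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning and dosimetric QA for dynamically collimated proton scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Pencil-beam-scanning (PBS) proton therapy scans a narrow beamlet
magnetically across the target in energy layers. At shallow depths the
lateral penumbra of each spot is several millimetres wide, and a sliding-bar
dynamic collimation system (DCS) — four independently moving trimmer blades
(X1, X2, Y1, Y2) that re-position per spot — can sharpen the field edge
considerably. `dcpt` implements a desk-scale version of the full planning
and verification chain for such a system: an analytic collimated beamlet
library, planar test targets with peripheral normal-tissue rinds, dose-ratio
beamlet selection, collimation-level assignment, nonnegative least-squares
weight optimization to a uniform prescription, rind-sparing
characterization versus depth and trimmer-to-surface distance (TSD), 2D
gamma and registration QA, and emission of layered delivery (PLD) files
extended with per-spot trimmer coordinates.

```{r, eval = FALSE}
library(dcpt)
beam <- beam_from_table(78.3)              # 5 cm depth, no range shifter
lib  <- build_kernel_library(beam, tsd = 5)
bean <- make_kidney_bean_target("large")
pair <- dc_plan_pair(bean, beam, tsd = 5, library = lib, t_coll = 40)
pair
```

## The analytic beamlet model

The production workflow this package emulates obtains its beamlet dose
planes from Monte Carlo particle transport. Those kernels are not published
in functional form, so `dcpt` generates them analytically; the analytic
model is the package's own construction, chosen to reproduce the
*qualitative* structure of collimated beamlets (Gaussian core, light broad
halo, erf-shaped trimmed edges) rather than any measured machine.

An uncollimated beamlet at the evaluation plane is a radially symmetric
double Gaussian on a 1 mm node-centered lattice,

$$K(x, y) = A\left[\,0.95\, g_\sigma(x)g_\sigma(y) + 0.05\,
g_{3\sigma}(x)g_{3\sigma}(y)\right],$$

with the core sigma broadened in water in quadrature,
$\sigma(d) = \sqrt{\sigma_\mathrm{air}^2 + (k d)^2}$, $k = 0.35$ mm/cm, and
$d$ the plane depth in cm. $\sigma_\mathrm{air}$ comes from the machine
beam table (`beam_table()`); the peak is normalized to a configurable
calibration of $10^{-9}$ Gy/proton (absolute calibrations are
machine-specific). The 5% halo at three core sigmas stands in for the
nuclear/large-angle dose envelope; it is what makes rind doses nonzero and
hence reductions measurable. Real Monte Carlo kernels carry a considerably
larger and longer-ranged low-dose envelope, which is why the absolute rind
metrics here are not comparable to measured values (see *Limitations*).

Trimmer collimation multiplies the kernel by the transmission of each
engaged blade: a unit step at the configured offset (1 or 2 mm from the
beamlet axis, toward the field interior; X2/Y2 block the positive side,
X1/Y1 the negative side), blurred by the edge-spread sigma

$$\sigma_\mathrm{edge} = \sqrt{\big(10\,\theta_\mathrm{eff}\,
(\mathrm{TSD} + d)\big)^2 + (k d)^2},$$

with $\theta_\mathrm{eff} = 2$ mrad without and $12$ mrad with the range
shifter. The blur is applied to the transmission rather than to the
trimmed product: this separable fluence-times-transmission approximation
guarantees exactly that collimation never increases dose anywhere, and
places the 50% crossing of the trimmed profile at the trimmer edge. The
large range-shifted $\theta_\mathrm{eff}$ makes the RS penumbra — and so
the benefit of a small TSD — strongly TSD-dependent, while NRS plans are
nearly TSD-independent; the 4 cm physical trimmer thickness has no
analytic consequence because engaged trimmers are treated as fully
attenuating.

A per-energy library holds one uncollimated kernel plus the eight
collimated base configurations (X/Y offsets from \{1 mm, 2 mm, Out\},
positive-side convention). Trimmer symmetry lets each base kernel be
mirrored about either axis to model the opposing blade; the four axis
flips applied to the eight base kernels give the conventional count of 32
trimmed entries. Single-trimmer entries are pairwise mirror-degenerate, so
a strict distinct-state count would be 24; the library keeps all 32
entries to preserve the counting convention and exposes the 24 distinct
kernels through `library_configs()`.

## Targets, rinds and spot maps

Five planar test shapes are provided at the 0.5 mm analysis resolution:
circles of 3, 5 and 8 cm diameter and two kidney-bean crescents in the
spirit of treatment-planning QA test patterns. The bean parameterization
is declared, not inferred from any drawing: an outer 45 × 25 mm
semi-axis ellipse minus an inner 40 × 22 mm ellipse displaced 15 mm along
the minor axis; the small variant is scaled by 0.4, which is also why it
uses a 1 mm spot spacing instead of the standard 2.5 mm. Peripheral rinds
of 10 and 30 mm are Euclidean-distance dilations of the target minus the
target itself, computed by exact distance transform (isotropic widths, not
square structuring elements).

Spot lattices cover the target bounding box plus a 10 mm margin, aligned
so one node sits on the target centroid; the margin keeps candidate spots
outside the target available to the optimizer, which needs them to build
up the field edge.

## Selection, collimation level and weight optimization

Each spot/configuration pair is scored by the dose ratio
$\mathrm{DR} = 100\,D_\mathrm{in}/D_\mathrm{out}$, the beamlet dose
integrated inside versus outside the target on the analysis grid; a spot
is kept when its best available configuration reaches the selection
threshold. A beamlet depositing nothing outside the target scores
$+\infty$: it passes any threshold and is never collimated. Spots are
assigned a trimmed configuration when their uncollimated DR falls below
the collimation level $T_\mathrm{coll}$; the assigned configuration
maximizes DR, with ties broken toward fewer engaged trimmers, then smaller
offsets. This operational rule reproduces the two behaviours that define
the threshold: raising $T_\mathrm{coll}$ monotonically increases the
number of trimmed beamlets, and collimation concentrates at the target
edge.

Weights minimize a per-node-normalized quadratic objective,

$$f(w) = \frac{1}{n_T}\sum_{i \in T} (D_i - R_x)^2 +
\frac{\lambda}{n_R}\sum_{i \in R} \max(D_i - L, 0)^2, \qquad w \ge 0,$$

over the target $T$ and the 30 mm rind $R$, with prescription
$R_x = 5$ Gy, rind limit $L = 0$ Gy and default rind weight
$\lambda = 0.05$. With $L = 0$ the one-sided penalty is a plain quadratic
(doses are nonnegative) and the problem is a single nonnegative
least-squares solve; positive limits re-estimate the active rind set in an
outer loop. The solver is a hand-written active-set Lawson–Hanson on the
normal equations with deterministic pivoting (largest gradient, first
index on ties), warm-started from the positive part of the unconstrained
solution, gradient tolerance $10^{-10}$ relative. The influence matrix is
sampled every other analysis node (1 mm effective) during optimization;
coverage metrics are always reported on the full 0.5 mm grid.

### The plan-equivalence protocol

Uncollimated and collimated plans are compared only when equivalent: D98
and D2 over the target within 3% of the prescription (4.85–5.15 Gy) and
the paired D98/D2 within 1% of each other. The tuning that achieves this
is deterministic and proceeds in three stages:

1. *Coverage tuning* — per variant, the rind weight is halved (up to 20
   steps, last step zero) until D98 and D2 are within 0.5% of the
   prescription, half of the paired budget.
2. *Coverage rescue* — if a variant cannot reach the 3% window even with
   the rind penalty fully relaxed, its selection threshold is lowered in
   5-point steps (floor 5%), admitting more beamlets outside the target.
   Under the defaults this triggers only for the deepest (22.5 cm) beam,
   whose kernels are broadest. The default thresholds of 30%
   (uncollimated) and 16% (collimated) are the values under which matched
   coverage is attainable for the rest of the beam table, mirroring the
   asymmetry expected from the sharper collimated penumbra: collimated
   plans need *more* beamlets outside the target, never fewer.
3. *Pair matching* — when the paired criteria still fail, the variant with
   the better achievable coverage is detuned toward the other by a
   log-space bisection on its rind weight that balances the paired D98 and
   D2 mismatches (both move monotonically with the rind weight, so the
   minimax sits at their crossing).

## Rind metrics, trends and QA

Rind sparing is summarized as the reduction in mean rind dose between the
paired plans, as a percentage of the prescription; the "mean dose"
label is implemented as the arithmetic mean over rind nodes, with the
percentile D50 available separately through `dose_area_percentile()`.
Depth trends are least-squares linear or quadratic fits
(`fit_depth_trend()`), reporting the slope and the smallest real root
beyond the last data point — the extrapolated depth at which the
collimation benefit vanishes.

Gamma analysis uses global normalization (dose criterion as a percentage
of the reference maximum, the clinical QA convention), a 10% low-dose
threshold, and a discrete search on a dta/10 sub-grid out to three dta,
which bounds the discretization error of the pass rate well below 0.1% in
oracle tests; relative mode rescales the evaluated dose by the
least-squares factor over above-threshold nodes before comparison. Rigid
registration maximizes normalized cross-correlation over a coarse
±10 mm / ±5° grid followed by simplex refinement; the chamber-averaged
central-axis dose uses a 10 mm disk footprint by default (a vendor-nominal
value — the exact chamber dimensions are a configuration parameter, not a
reproduced quantity).

## Delivery files

PLD files are layer-structured text: a version line, a beam header, one
layer block per (single-energy) plan and one element line per spot. The
extension over the legacy dialect appends the four trimmer coordinates to
each element line, `Out` marking parked blades. The dialect — comma
separators, mm with three decimals, MU with six significant digits — is
self-consistent and round-trips byte-identically, but is not a
vendor-verified machine format. Optimized proton weights convert to MU
through a per-energy protons/MU factor (`protons_per_mu()`); the default
calibration is synthetic.

## What the synthetic scenario does and does not show

The default scenario suite (the five shapes, the ten beam-table rows, TSDs
of 5–15 cm) exercises every stage of the chain under realistic geometry
and produces the expected qualitative physics: collimated plans need more
beamlets than uncollimated ones at matched coverage; the 10 mm rind
reduction decreases monotonically with depth for NRS beams
(34.6 → 14.2% of prescription from 5 to 22.5 cm at
$T_\mathrm{coll} = 70\%$); RS sparing degrades steadily as the TSD grows
while NRS sparing changes by under 1%.

Because the analytic kernels carry only a light 5% halo, absolute rind
doses and reductions are not comparable to Monte-Carlo-based values, and
two published orderings invert here: the measured studies find *larger*
reductions over the 30 mm rind than the 10 mm rind (their low-dose
envelope dominates the far rind), whereas this model, with its thin halo,
spares the near rind most. Likewise the 30 mm reduction is non-monotone at
the deepest beam, where the threshold-rescued uncollimated selection
admits extra peripheral beamlets that raise the far-rind baseline. The
package therefore asserts ordering properties on the 10 mm rind and treats
30 mm values as descriptive output.

Problem sizes were chosen for interactive desk-scale use: 0.5 mm analysis
grids of roughly 300 × 260 nodes, kernel grids of six core sigmas
half-width, a few hundred to a thousand candidate spots per plan, and
full-precision solves throughout; a complete paired scenario fits in a few
seconds to a few tens of seconds on one core.

## Known limitations

- No particle transport: depth dose, nuclear halo shape, range-shifter
  material effects beyond one divergence parameter, and LET effects are
  out of scope; all dosimetry is a single plane per beam.
- Single energy layer per plan; no spread-out Bragg peak composition, no
  robustness optimization, no trimmer motion sequencing.
- The collimation-level rule and kidney-bean dimensions are declared
  package conventions where the source workflow leaves them unspecified.
- Measured-hardware quantities (chamber central-axis doses, film/array
  gamma tables) are emulated structurally (the QA operations exist and are
  oracle-tested) but their published values are not reproduction targets.
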