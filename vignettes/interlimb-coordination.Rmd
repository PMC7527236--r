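---
title: "Interlimb coordination analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interlimb coordination analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadgait)
```

## The measurement model

Quadrupedal locomotion is described here entirely by footfall events:
for each limb, ordered paw-contact and paw-lift times within a
locomotor pass. A stride is contact-to-next-contact of the same paw;
its ground-contact portion (stance) runs to the intervening lift and
the airborne remainder is swing. Only complete strides are analysed —
the terminal partial cycle of a pass is discarded, and a pass needs at
least `min_cycles` (default 3) complete reference strides to enter the
coordination analyses. Units are seconds, centimetres and degrees
throughout.

The coupling of a limb pair for one reference stride is the phase

$$\varphi = \frac{t_{\text{paired contact}} - t_{\text{ref contact}}}
{T_{\text{stride}}} \in [0, 1),$$

with the paired limb's *first* contact in the half-open window
$[t_{\text{ref}}, t_{\text{ref}} + T)$ — half-open so a contact is
never assigned to two strides. $\varphi = 0.5$ is alternation,
$\varphi = 0 \equiv 1$ is synchrony. Contact (not lift) is the phase
event; it is the standard footfall convention and is exposed should a
different event be preferred upstream. When the paired limb makes no
contact in the window the sample is skipped and counted, since it
marks a departure from 1:1 stepping that the stepping index
($100 \times$ hind/fore step counts) is designed to catch.

### Folding

Animals differ in preferred lead limb, so $\varphi$ and $1 - \varphi$
describe the same coupling pattern. Phases are folded onto a single
half-scale, $\mathrm{fold}(\varphi) = \max(\varphi, 1 - \varphi) \in
[0.5, 1]$, making e.g. the two gallop configurations 0.25 and 0.75
coincide at 0.75. The upper half was chosen as the canonical one;
keeping both halves would only double the bookkeeping. Folding is
idempotent and reflection-symmetric, which the test suite checks as an
invariant.

### Control bands and altered steps

Folded phases from all control timepoints of the same task and surface
are pooled into one band per limb pair: mean $\pm k \cdot$ SD (sample
SD, $k = 2$ by default), clipped to $[0.5, 1]$. A step whose folded
phase falls outside its band is an *altered step*. The band is
two-sided before clipping; since control means sit near 0.5 the lower
limit usually clips to 0.5, so the distinction from a one-sided
threshold is minor in practice. With a tight control distribution the
$k = 2$ band admits roughly 95–98% of a fresh control draw, so a
nominal false-positive rate of a few percent is expected and is
accounted for wherever altered fractions are predicted.

## Statistics

**Proportions.** Altered/total counts are compared with the two-sample
proportion z statistic using the *unpooled* standard error and no
continuity correction, two-tailed. The unpooled form is the one that
reproduces published altered-step comparisons of this design from
their count tables (the pooled form is available behind a flag, and
visibly disagrees — e.g. 10.07 vs 11.31 on the hindlimb overground
comparison).

**Circular distributions.** Phase samples are compared with the
two-sample Watson U² test, chosen because coupling distributions are
neither uniform nor unimodal with a common concentration, which rules
out the usual parametric circular tests. The statistic is computed
from the difference $d = F - G$ of the empirical cumulative fractions
at the $N$ pooled ordered points,
$U^2 = \frac{n_1 n_2}{N^2}\left(\sum d^2 - (\sum d)^2 / N\right)$.
At tied pooled values every member of the tied block takes the ECDF
difference evaluated at the tie; averaging the running cumulative
instead would depend on the arbitrary within-block order and break the
statistic's sample symmetry. The p-value defaults to a seeded random
permutation of pooled labels (10,000 by default; the seed is stored in
the result), with the asymptotic series
$P(U^2 > u) = 2\sum_{m \ge 1} (-1)^{m-1} e^{-2 m^2 \pi^2 u}$
available for larger samples. Public interfaces keep phases on the
0–1 scale; radians are internal.

**Speed relations.** Spearman rank correlation (average ranks on ties)
plus an ordinary least-squares fit — matching the "line of best fit"
reading of such analyses — relate stride time, stance time, swing time
and stride length to body speed; slopes are compared with
$t = (b_1 - b_2)/\sqrt{SE_1^2 + SE_2^2}$ on $n_1 + n_2 - 4$ degrees of
freedom.

## Gait taxonomy

Gaits are defined by the left-right coupling at each girdle on the
folded scale. No numeric band edges are standard, so the package
centres three zones on the canonical patterns with equal guard bands:
alternation $[0.5, 0.65)$, phase-shifted $[0.65, 0.85)$, synchronous
$[0.85, 1.0]$ — all configurable. Walk-trot requires both girdles
alternating (walk and trot are deliberately not distinguished); gallop
is an intermediate pattern at either girdle with non-synchronous
hindlimbs; half-bound is synchronous hindlimbs with non-synchronous
forelimbs; full-bound is synchrony at both girdles. Combinations
matching no definition (e.g. alternating hindlimbs under synchronous
forelimbs) are reported as unclassified rather than forced into a
class. The 5 Hz step-frequency threshold used in the phase-frequency
tabulation marks the usual walk-trot-to-gallop transition zone.

## Kinematics

The intralimb model is three segments (iliac crest–hip, hip–ankle,
ankle–toe) and two angles, with vertices at the hip (proximal) and
ankle (distal) — the vertex assignment follows from the segment list
and is configurable. All angles are arccosines of normalised dot
products, clamped to $[-1, 1]$ against rounding, which makes every
angle operation exactly invariant under translation, rotation and
uniform scaling (tested to $10^{-9}$). Range of motion is the global
peak-to-trough excursion within a stride; peak timing uses the global
maximum with ties resolved to the earliest frame and no smoothing by
default. Base-of-support is the angle at the groin between the caudal
extension of the shoulder-to-groin axis and the groin-to-paw ray,
evaluated at initial contact only (paw rotation drifts through
stance). The swim trunk angle is the acute angle between the iliac
crest–hip line and the water-surface line, averaged per frame within
each stroke cycle, a per-frame mean being the natural reading of
stroke-by-stroke sampling.

## The synthetic generator

The generator exists so that every pipeline stage can be validated
against known ground truth. A scenario fixes a cohort (default
6 animals × 8 passes × 10 strides = 480 reference strides, the size of
a typical curated control dataset), a per-pass speed drawn from
`speed_range`, and the temporal laws:

* stride time $T = 2.6\,v^{-0.55}$ s (v in cm/s) with multiplicative
  log-normal noise (CV 0.05). The exponent is the usual shallow power
  law; the coefficient was calibrated so walking speeds of 20–90 cm/s
  give 2–4.6 Hz step frequencies, keeping essentially all control
  steps at or below the 5 Hz walk-trot ceiling, as observed in control
  rats;
* duty cycle falling linearly from 0.70 at 20 cm/s to 0.45 at
  120 cm/s;
* phase noise that is von Mises on the circle — the canonical
  unimodal circular noise model; the reference right hindlimb lays
  down contacts at the accumulated stride times, the left hindlimb is
  offset by draws around the left-right hindlimb mean, the right
  forelimb around the homolateral mean, and the left forelimb is
  placed relative to the right forelimb so the diagonal pair comes out
  in-phase by composition;
* with probability `disruption_rate` a stride's left-limb phases are
  redrawn, uniformly on the circle (`uniform_phase`) or shifted by
  0.25 (`shifted_phase`), emulating decoupled steps.

Every limb emits the same number of contacts, so generated passes step
in a strict 1:1 ratio and the stepping index is exactly 100 unless
disruption is configured to drop steps. Marker tracks (default 200 Hz)
move the body at the pass speed and hold each paw through stance,
making stride length and speed recoverable to within interpolation
error. One master seed drives everything; per-pass substreams are
derived deterministically from it, so a pass can be regenerated in
isolation.

Preset concentrations were fixed once: κ = 12 per left-right pair
(κ = 14 homolateral) for controls, so that essentially only walk-trot
is expressed (>95% of strides), matching what control animals do; the
silenced preset lowers left-right κ to 4 and sets a 0.25 disruption
rate while leaving the stride-speed laws untouched, reproducing the
signature dissociation — decoupled left-right phases with intact
rhythm. These values favour the qualitative structure of the
conditions over matching printed per-animal variability magnitudes,
which depend on per-animal averaging the generator does not model.

What the generator does *not* emulate: per-animal idiosyncrasies
(lead-limb preference, animal-level random effects), speed-dependent
gait *transitions* within a pass, autocorrelated stride-to-stride
drift, and measurement artefacts of video digitisation. Passing tests
therefore show that the pipeline recovers what it is pointed at under
clean 1:1 stepping with independent circular noise — not that every
property holds for arbitrarily messy video-derived data.

## Numerical choices and degenerate inputs

* Folding and band edges use closed intervals; a zero-variance band
  degenerates to a point and anything off the mean is altered.
* Fewer than two contacts yields an empty cycle table (logged, not an
  error); fewer than two control samples, a zero standard error in a
  proportion test, a flat angle trace, constant speed, or coincident
  geometric points raise errors naming the violated contract.
* The circular mean direction is undefined at zero resultant length
  and is reported as `NA` with $R = 0$; a mean direction landing
  numerically at the 0/1 wrap point canonicalises to 0.
* Permutation p-values use the add-one estimator
  $(1 + \#\{U^2_\pi \ge U^2\})/(B + 1)$, which cannot return 0.
* Von Mises sampling uses the Best–Fisher rejection algorithm with the
  uniform and point-mass limits handled explicitly.

## Problem sizes

The test suite validates the Watson U² implementation against a
brute-force double-sum oracle on 100 random small instances, checks
its null rejection rate over 200 seeded permutation-test simulations
($n_1 = n_2 = 15$, 199 permutations), and recovers generator
parameters from cohorts of 480–1000 strides; these sizes were chosen
to match the study-scale datasets the package targets (hundreds of
steps per condition) while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* Event-based phase only; continuous relative phase from angle traces
  is out of scope by design.
* The gait band edges are a modelling choice, not an estimated
  boundary; sensitivity to them should be checked when classifying
  borderline strides.
* The asymptotic U² p-value is a large-sample approximation; below
  roughly 50 points per sample the permutation mode is preferred.
* Watson U² p-values for any particular dataset depend on its raw
  per-step phases; printed test statistics from other laboratories'
  datasets cannot be reproduced from summary tables alone, and the
  package makes no attempt to.
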