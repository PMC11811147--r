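---
title: "Black-box models of overall biomass yield on multiple nutrients"
author: "multiyield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Black-box models of overall biomass yield on multiple nutrients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiyield)
```

## The model

When a batch culture is left to grow until every available substrate — and
every secreted byproduct — has been consumed, the biomass produced over the
whole curve, $\Delta B$, typically rises linearly with the initial amount of
the carbon source: $\Delta B = Y_{X/D}\, N_D$. The slope $Y_{X/D}$ is the
*overall biomass yield*, and a thermodynamic "black box" description predicts
it from an energy balance: catabolism of the nutrient releases Gibbs free
energy, anabolism consumes it, and a fixed dissipation per unit biomass is
lost. `multiyield` stores every energy term as a non-negative magnitude
(kJ/g), so the balance reads *catabolic supply = dissipation + anabolic
cost* and the single-nutrient yield is

$$Y = \frac{g_{cat}}{g_X + g_{an}}.$$

Under the usual signed thermodynamic convention the catabolic and overall
dissipation terms would be negative; working with magnitudes keeps every
invariant of the package (supplementing a biomass precursor raises the
yield, a positive catabolic interaction raises $\Delta B$) associated with a
positive parameter, and avoids committing to a sign convention that the
ratio form cannot express unambiguously.

With two nutrients and no interaction the model is additive,
$\Delta B = Y_1 N_1 + Y_2 N_2$: the yield of each nutrient is independent of
the availability of the other. Titration experiments contradict this, so the
model couples the nutrients phenomenologically: each growth reaction's energy
term is multiplied by a linear *mutual-effect function* of the other
nutrient's availability.

**Two degradable nutrients.** With
$f_{cat,1}(N_2) = 1 + m_{cat,1} N_2$, $f_{cat,2}(N_1) = 1 + m_{cat,2} N_1$
and $f_{an}(N_1,N_2) = 1 + m_{an,1} N_1 + m_{an,2} N_2$, the produced biomass
has the closed form

$$\Delta B \;=\; \frac{g_{cat,1} N_1 + g_{cat,2} N_2 +
  \Delta m_{CAT}\, N_1 N_2}{g_X + g_{an} f_{an}(N_1, N_2)},
\qquad \Delta m_{CAT} = g_{cat,1} m_{cat,1} + g_{cat,2} m_{cat,2}.$$

The interaction appears as a bilinear term: a positive catabolic coupling
makes the yield of the measured nutrient *increase linearly with the base
amount* (slope $\Delta m_{CAT}/(g_X + g_{an})$ when $m_{an} = 0$), a
negative one decreases it.

**Degradable nutrient plus a non-degradable biomass precursor.** A
precursor (e.g. methionine for a strain that cannot degrade it) carries no
catabolic energy; supplying it externally alleviates its biosynthesis cost
$g_{bsyn}$ in proportion to the utilisation fraction
$M_{utl} = \min(1, M / (q_{req}\,\Delta B))$, where $q_{req}$ (µg precursor
per µg biomass, default 0.02) is the requirement ratio. The mutual-effect
functions are linear in $M_{utl}$ ($f_{cat}$, the $M$-part of $f_{an}$) or in
$N$ ($f_{bsyn}$, the $N$-part of $f_{an}$). On the *unsaturated* branch
($M_{utl} < 1$, all precursor incorporated, $M' = M/q_{req}$) the balance is
quadratic in $\Delta B$:

$$G_A\,\Delta B^2 - \Delta B\!\left[N g_{cat} - g^{excl}_{an} m^M_{an} M' +
  g_{bsyn}(1 + m_{bsyn} N) M'\right] - N g_{cat}\, m_{cat}\, M' = 0,$$

with $G_A = g_X + g^{excl}_{an}(1 + m^N_{an} N) + g_{bsyn}(1 + m_{bsyn} N)$.
Deriving this from the energy balance fixes the sign of the $m^N_{an}$ term
inside $G_A$ as positive — the self-consistent form is what the package
implements. The solver takes the larger real root (the branch continuous
with the $M \to 0$ limit, where the roots are $0$ and $N g_{cat}/G_A$) and
accepts it if the implied $M_{utl} \le 1$; otherwise it solves the
*saturated* branch ($M_{utl} = 1$), on which the biosynthesis term vanishes
and the solution is linear. A negative unsaturated discriminant falls back
to the saturated branch when the available precursor covers its
requirement; any remaining inconsistency raises a structured validity error
rather than a clamped value. `solve_energy_balance_numeric()` solves the
same balance by sign-scan and bisection for the largest root, with no
algebra shared with the quadratic; the two agree to better than $10^{-6}$
relative error across randomised valid draws, and the test suite enforces
this.

### A structural caveat: monotonicity in the precursor amount

Writing the unsaturated solution as
$x(M') = [b + \sqrt{D}]/(2 G_A)$ with $b = N g_{cat} + \beta M'$ and
$D = b^2 + 4 G_A N g_{cat} m_{cat} M'$, the condition $x'(M') = 0$ reduces
to $m_{cat}(G_A m_{cat} + \beta) = 0$ — independent of $M'$. The derivative
therefore never changes sign except at one degenerate parameter tuning, the
saturated branch is constant in $M$, and the only possible discontinuity is
a downward jump where the discriminant vanishes. Consequently, **within this
model family $\Delta B(M)$ at fixed $N$ is weakly monotone**: a sweep can
decrease (strong negative catabolic coupling, $m_{cat} < -\beta/G_A$),
increase, or decrease onto a constant saturated plateau — but it cannot dip
and then recover. A genuinely non-monotone titration curve (produced
biomass falling at low precursor amounts and rising again at higher ones,
as batch data for methionine on glucose suggest) is *outside the solution
space* of this closed form; capturing it would require mutual-effect
functions of the raw precursor amount rather than of $M_{utl}$, which would
break the quadratic structure above. `map_solution_space()` therefore
labels strongly negative catabolic settings as `yield_decrease`, and the
package's solution-space tests assert the monotone behaviour the model
actually has. This is stated prominently because a user may expect such
cells to be labelled `non_monotone`.

### Identifiability and the fitted reduced form

Produced-biomass data determine the model only up to an overall energy
scale, so `fit_mutual_effects()` estimates *reduced* parameters and never
raw magnitudes:

* two-degradable: $Y_1$, $Y_2$, $\delta = \Delta m_{CAT}/(g_X+g_{an})$ and
  $\alpha_i = g_{an} m_{an,i}/(g_X+g_{an})$; the two catabolic coefficients
  enter only through $\Delta m_{CAT}$ and are deliberately not offered
  separately.
* precursor: $y_N = g_{cat}/G_{A0}$, $m_{cat}$ (dimensionless, unchanged by
  reduction), $\beta_M = (g_{bsyn} - g^{excl}_{an} m^M_{an})/G_{A0}$,
  $\alpha_N = (g^{excl}_{an} m^N_{an} + g_{bsyn} m_{bsyn})/G_{A0}$ and
  $\beta_{MN} = g_{bsyn} m_{bsyn}/G_{A0}$, with
  $G_{A0} = g_X + g^{excl}_{an} + g_{bsyn}$.

A design with a single base amount confounds the interaction with the
single-nutrient yields; the fitter refuses it with an explicit
identifiability error. Estimation is Levenberg–Marquardt least squares on
the replicate means, with five starts: a least-squares-initialised start,
two sign probes on $m_{cat}$ (the only parameter with a plausibly large
negative value), and seeded log-uniform ±50 % perturbations. Standard
errors come from the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$. Qualitative labels
(`classify_mutual_effect()`) use a two-standard-error rule: an effect is
called positive or negative only when its estimate is more than 2 SE from
zero — a deliberate, conservative convention.

## From growth curves to endpoints

The curve pipeline follows standard plate-reader practice:

* **Calibration** (`calibration_model()`): an optional monotone
  piecewise-linear OD linearisation (identity by default, since instrument
  calibrations are lab-specific), the dry-weight factor 0.396 g DW per litre
  per OD unit, and a 200 µl well volume, so OD 1.0 ≙ 79.2 µg per well.
  Readings outside the calibration range are extrapolated with the end
  segments and a warning — never silently clipped.
* **Endpoint** (`produced_biomass_from_curve()`): final biomass is read a
  fixed window after the curve maximum (default 4 h, the midpoint of a
  3–5 h stationary window) minus the inoculum biomass; the nearest sample
  is used rather than interpolation, matching the 10-min discrete sampling.
* **Growth rate** (`estimate_growth_rate()`): the best log-linear sliding
  window (default 7 points ≈ 1 h), ties to the earliest window; a best
  window with $R^2 < 0.95$ flags the estimate unreliable.
* **Diauxic segmentation** (`segment_diauxic_phases()`): the stationary
  tail is trimmed at the first sample reaching 99.5 % of the smoothed
  maximum, the log-biomass is smoothed with a centred 5-sample moving
  average (10-min noise suppression), and an exhaustive, deterministic
  two-changepoint search on its derivative minimises within-segment
  variance. The curve is called diauxic only when the middle segment's mean
  specific rate is clearly below the first phase's and a distinct second
  phase follows; otherwise the curve is flagged single-phase.

## Yield estimation

Fits use unweighted ordinary least squares on the triplicate means.
`detect_linear_region()` enumerates every contiguous window (≥ 4 points)
and returns the longest run with $R^2 \ge 0.9$, ties broken by higher
$R^2$, then leftmost — a convention, stated as such.
`fit_segmented_two_phase()` searches the breakpoint exhaustively over the
observed amounts with per-segment OLS; SSE ties go to the **larger**
breakpoint, because on exactly continuous piecewise-linear data the kink
point lies on both segment lines, so the kink and the preceding grid point
tie at zero SSE and the larger choice names the amount at which the slope
actually changes. Each segment is also tested against a constant model
(F-test, α = 0.05), and the two slopes agreeing within two combined
standard errors flags the fit as effectively linear.

## What the synthetic data emulate — and what they do not

`generate_endpoint_table()` realises a chosen model variant on a titration
design with multiplicative Gaussian noise on $\Delta B$ (truncated at
−90 % to preserve positivity), the error structure of plate readers, whose
noise scales with signal. `generate_diauxic_plate()` wraps each endpoint in
a phenomenological two-exponential trajectory (growth at $\mu_1$ to a
fraction `phase_split` of the target gain, a flat lag, growth at $\mu_2$ to
the target, then stationary phase) and converts it to raw OD through the
inverse calibration. The defaults — triplicates, 10-min sampling,
$\mu_1 = 0.9\,h^{-1}$, $\mu_2 = 0.35\,h^{-1}$, 3.5 h lag, 2 µg inoculum,
2 % noise, measured amounts up to 240 µg and base amounts up to 160 µg —
mirror plate-scale batch experiments on sugars and organic acids. The
trajectories are *not* mechanistic: there is no substrate depletion, no
Monod kinetics, no byproduct dynamics, no evaporation or edge effects, and
replicate noise is independent across wells. Passing round-trip tests
therefore demonstrates that the pipeline is self-consistent — that
endpoints, phases and coefficients programmed into the generator are
recovered — not that real cultures obey the two-exponential form.

Problem sizes used by the tests and the acceptance script: endpoint designs
of 18–65 conditions in triplicate, plates of 10–30 wells at 10-min sampling
over 24–40 h, 200 randomised draws for the oracle comparison and 1000 for
the analytic identities. These sizes make every statistical check
well-resolved while keeping a full run in the order of seconds.

**Precursor study design.** The reduced parameters $\beta_M$ and $m_{cat}$
are separately informative only on the unsaturated branch, which at the
default settings ends below roughly 0.4–1.4 µg of precursor (saturation at
$M = q_{req} \Delta B$). The packaged precursor design therefore titrates
densely there — `c(seq(0, 0.5, 0.05), 0.7, 1, 1.5, 2, 3)` µg against base
amounts of 40, 80 and 160 µg — the design a practitioner would run after
the same identifiability reasoning; a sparse uniform grid over 0–4 µg
leaves $\beta_M$ essentially undetermined at 2 % noise.

## Known limitations

* Nutrients that are both degradable and usable as biomass precursors
  (e.g. aspartate) are outside the model; for such data only the
  descriptive segmented fit applies.
* The monotonicity result above: genuinely non-monotone precursor
  titration curves cannot be represented, only approximated by a decrease
  onto a saturated plateau.
* $q_{req}$ must be supplied; it is not identifiable from endpoint data
  (it rescales $M$) and the 0.02 µg/µg default is a methionine-like order
  of magnitude, not a measured constant.
* Endpoint fits use replicate means without weighting; heteroscedastic
  designs with very unequal replicate counts would need the per-replicate
  records that `generate_endpoint_table()` also returns.
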