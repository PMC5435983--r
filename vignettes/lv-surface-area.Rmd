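---
title: "Modeling the left-ventricular surface area as a truncated prolate spheroid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the left-ventricular surface area as a truncated prolate spheroid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvtps)
```

## The model

The normal left ventricle (LV) is well approximated by an ellipsoid of
revolution cut by a plane at its base: a *truncated prolate spheroid* (TPS).
`lvtps` implements the exact lateral area of that surface and uses it to turn
two routine echocardiographic measurements into an LV surface-area estimate.

The TPS is the revolution of $x(z) = a\sqrt{1 - z^2/c^2}$ about the polar
$z$-axis, restricted to $z \in [\sigma, c]$ with semi-axes $c \ge a > 0$ and
truncation coordinate $\sigma \in [-c, c)$. Its lateral area is

$$A_\sigma(S) \;=\; \pi a\left[
  \frac{c^2\!\left(\arcsin\frac{\sqrt{c^2-a^2}}{c}
        - \arcsin\frac{\sigma\sqrt{c^2-a^2}}{c^2}\right)}{\sqrt{c^2-a^2}}
  \;+\; a \;-\; \sigma\sqrt{1 + \frac{(a^2-c^2)\,\sigma^2}{c^4}}\,\right],$$

computed by `tps_area()`. Only the curved surface is counted: complementary
pieces of a spheroid then add up exactly to the full prolate-spheroid area
(`prolate_spheroid_area()`, the classical arcsine closed form), which is both
a correctness check and the semantics a ventricular surface needs — the open
mitral base contributes no wall. An `include_base` flag adds the planar cut
disk for users who want a closed surface.

```{r}
split_prolate(10, 3, -2)       # two complementary pieces of S(10, 3, 3)
sum(split_prolate(10, 3, -2))
prolate_spheroid_area(10, 3)
```

The exact value of the smaller piece is `r round(tps_area(3, 10, 2), 4)`
cm². Published tabulations of this worked example sometimes show 115.90,
which is inconsistent with their own total (115.894 + 190.833 = 306.727
rounds to the quoted 306.73); we report the exact value. The same
tabulations also label the two pieces with swapped truncation subscripts;
`tps_area()` follows the formula literally, so $\sigma=-2$ names the larger
piece spanning $[-2, 10]$.

### Mapping echocardiographic measurements to axes

Two standard LV dimensions feed the model: the short-axis diameter $D$
(taken at or below the mitral leaflet tips) and the long axis $L$, combined
into the ratio $\delta = D/L$, which lies in $[0.45, 0.62]$ in normal
subjects. With the base plane at the point dividing $L$ in $1/3 : 2/3$
proportion (the standard basal-third convention),

$$a = b = \tfrac{D}{2}, \qquad L = \tfrac{D}{\delta}, \qquad
  c = \tfrac{2D}{3\delta}, \qquad \sigma = -\tfrac{D}{3\delta}.$$

`lv_axes()` performs this closed-form arithmetic; `lv_surface_area()`
composes it with `tps_area()`. Because $D$ is an internal end-diastolic
diameter, the result is an estimate of the *internal* (endocardial) surface
at end diastole. $\sigma$ is stored negative — base below the equator, apex
at $z = +c$ — and reports quote $|\sigma|$. A ratio outside the normal band
warns but still computes (design choice D-range: dilated ventricles are a
primary application of a surface-area parameter, so normality is a flag,
not a constraint).

Two consequences of the arithmetic drive the whole cohort analysis:
the area scales exactly as $D^2$ at fixed $\delta$, so (i) male/female
area ratios at the same $\delta$ depend only on the diameter ratio, and
(ii) Pearson correlations of area with any covariate are invariant in
$\delta$. `delta_invariance_check()` verifies both numerically.

## The cohort analysis

`lv_area_model()` is the central fit. Its default data are the bundled
sex- and age-stratified MRI averages for 107 normal Brazilian adults
(`builtin_reference_cohort()`: end-diastolic short-axis diameter $D_d$ in
cm and end-diastolic volume normalized by body surface area $V_{dn}$ in
mL/m², a `total` row plus five decade groups per sex). Default axis ratios
are the normal-range endpoints and the mid value 0.50 widely used in
ventricular-mass formulas.

```{r}
fit <- lv_area_model()
fit
```

The fit holds the long-form area table (`fit$table`), per-age-group
male-vs-female percentage differences ($100\,|A_m - A_f|/A_f$,
$\delta$-invariant by construction), the signed comparison of aggregate
areas against an external reference area (151 cm², a published
nuclear-imaging estimate of the mean LV surface; configurable via
`lv_config()` or the `reference_area` argument), and per-sex correlations
of area against $V_{dn}$ across the five age groups.

The correlation layer uses Pearson's $r$ with the small-sample Student
significance $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2 = 3$ degrees of freedom
(two-tailed by default; one-tailed via `tails = 1`). Aggregate `total` rows
are excluded from correlations so the five decades are the sampling units.
For the male groups this reproduces $r = 0.8520$, $R^2 = 0.7260$,
$p = 0.0668$ at every $\delta$. For the female groups direct computation on
the bundled values gives $r = 0.9576$ ($p = 0.0104$); the value 0.9810
printed alongside the source tables cannot be recovered from those same
tables and is reported here as computed, with the discrepancy noted.

`summary(fit)` renders the blocked per-$\delta$ table. All computation is
kept in full precision; rounding (default 2 digits) happens only at the
display layer, because the published tables were evidently produced with
intermediate rounding (±0.01 cm² wobble). One column of those tables — the
men's $|\sigma|$ — conflicts with the axis relations that the men's own
printed areas satisfy (e.g. 3.70 vs the consistent 3.63 at $D=4.9$,
$\delta=0.45$); we treat it as a typesetting error and print the consistent
values.

Methods follow the usual modelling idiom: `coef()` returns the per-sex
regression coefficients of area on $V_{dn}$, `predict()` predicts either
geometrically (from `D_d` and `delta`) or from the fitted regression (from
`V_dn` and `sex`), `residuals()` gives the regression residuals, `plot()`
draws the per-sex dispersion/regression panels, and `simulate()` draws
synthetic cohorts.

## The synthetic-cohort generator

`simulate_cohort()` emulates the *structure* of the reference table: within
each sex × age-group cell it draws per-subject diameters
$D \sim N(\mu_g, \mathrm{sd}_D^2)$ (truncated positive), couples the
normalized volume linearly to the squared diameter,
$V_{dn} = \alpha + \beta D^2 + \varepsilon$, $\varepsilon \sim N(0,\tau^2)$
— the structure the area–volume correlation analysis presumes, since the
area itself is proportional to $D^2$ — and by default returns per-group
averages, as reference tables do. All randomness flows through one seed.

Defaults were chosen once from the bundled table and are not tuning knobs:
group means are the ten age-group diameters; regressing the table's
$V_{dn}$ on $D_d^2$ gives $\alpha = 20.6$ mL/m², $\beta = 2.14$ mL/m² per
cm², residual sd $\tau = 2.1$ mL/m²; $\mathrm{sd}_D = 0.4$ cm is a typical
reported within-group spread of the end-diastolic diameter; and
`n_per_group = 10` matches 107 subjects spread over ten cells.

With group means fixed, the population correlation across $G$ groups is
the attenuation value
$r = \beta s_x \big/ \sqrt{\beta^2 s_x^2 + \tau^2/n}$ with $x = D^2$;
the test suite verifies (500 seed-fixed replicates) that recovered
correlations bracket this value and that group averaging ($n$ large)
drives $r$ toward 1.

What the generator does *not* emulate: measurement error in $D$ correlated
with error in $V_{dn}$ (both come from the same images in real studies),
non-Gaussian tails, age trends within a decade, or any systematic
$\delta$ variation across subjects. Passing tests therefore certify the
pipeline's arithmetic and its statistical calibration under the stated
generative model, not the clinical accuracy of the TPS geometry itself.

## Numerical choices

* **Elliptic integrals.** The general-ellipsoid area (`general_ellipsoid_area()`)
  is the classical amplitude/modulus closed form with
  $\phi = \arcsin(\sqrt{a^2-c^2}/a)$ and
  $k^2 = a^2(b^2-c^2)/(b^2(a^2-c^2))$ — the unique modulus for which the
  formula collapses to the prolate arcsine form at $b = c$. It is evaluated
  in the algebraically identical Carlson symmetric form
  $S = 2\pi c^2 + 2\pi ab\,R_F - \tfrac{2\pi}{3}\tfrac{(a^2-c^2)(b^2-c^2)}{ab}R_D$
  (arguments $c^2/a^2$, $c^2/b^2$, $1$), which has no $0/0$ at coincident
  axes, so prolate, oblate and spherical degeneracies need no branching.
  $R_F$ and $R_D$ use the standard duplication algorithm (argument spread
  contracts 4× per step; terminated at relative spread $10^{-14}$ plus a
  fifth-order tail series).
* **Sphere limit.** The arcsine closed forms for the prolate spheroid and
  the TPS are $0/0$ at $a = c$. When the squared relative eccentricity
  $(c^2-a^2)/c^2$ falls below $10^{-9}$, both switch to a three-term series
  in it (truncation error below $10^{-18}$ there), reproducing $4\pi r^2$
  and the spherical-zone limit $2\pi c(c-\sigma)$ with no precision
  blow-up down to $|c-a|/c = 10^{-12}$ and beyond.
* **Quadrature oracle.** `tps_area_quadrature()` integrates the defining
  surface-of-revolution integral after the substitution $z = c\sin\theta$,
  which removes the $x'(z)$ singularity at the apex; the integrand becomes
  the smooth $2\pi ac\cos\theta\sqrt{\cos^2\theta+(a/c)^2\sin^2\theta}$.
  It exists purely as an independent check on the closed form (default
  relative tolerance $10^{-10}$) and fails loudly on non-convergence.
* **Problem sizes.** Randomized property checks use on the order of 100
  geometries per property and 500 Monte-Carlo replicates for parameter
  recovery — generous for closed-form arithmetic at these scales while the
  whole suite stays interactive.
* **Labels.** Age groups are opaque strings matched exactly across sexes;
  the reader normalizes dash variants and maps the `">=60"`/`"60+"`
  aliases to `"60-69"`, reconciling the two labelings that appear in
  published tables.

## Limitations

The axis association fixes the basal plane at exactly one third of the long
axis and assumes perfect rotational symmetry ($a = b$); both are
conventions, not measurements, and real ventricles deviate. The reference
comparison treats 151 cm² as a single external constant with no uncertainty.
Correlations rest on five group *averages* per sex — the significance
arithmetic is exact, but $n = 5$ summaries of ~10 subjects each cannot
support individual-level inference. Volumes, masses and ejection fractions
are deliberately out of scope.
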