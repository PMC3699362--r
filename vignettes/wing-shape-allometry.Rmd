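---
title: "Wing-shape allometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wing-shape allometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`calomorph` implements a comparative analysis of wing-shape allometry in
territorial calopterygid damselflies.  This vignette is the package's
account of the science: the quantities it computes, the assumptions
behind them, the tunable parameters, and the choices made where the
design was genuinely open.  It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The RSM: a univariate wing-shape summary

For a wing of length $R$ (base to apex) and area $S$, write
$\hat r = r/R$ for the non-dimensional distance from the wing base along
the wing axis and $\hat c(\hat r) = c(\hat r)\,/\,(S/R)$ for the local
chord (the wing width perpendicular to the axis) normalised by the mean
chord.  By construction $\int_0^1 \hat c \, d\hat r = 1$.  The
non-dimensional radius of the $k$-th moment of wing area is

$$\hat r_k(S) \;=\; \Bigl(\int_0^1 \hat c\,\hat r^k \, d\hat r\Bigr)^{1/k},$$

and the package's central quantity is the second-moment radius
$\hat r_2(S)$, the **RSM**.  In quasi-steady aerodynamics of flapping
flight the RSM is proportional to the mean lift force; lower values mean
wing area concentrated toward the base, which is less energetically
demanding and widens the range of usable flight speeds.  The first three
moment radii are strongly correlated and satisfy
$\hat r_1 \le \hat r_2 \le \hat r_3$ (power-mean monotonicity); the
package computes all three but analyses the second.

**Computation.**  `chord_profile()` takes the wing as an ordered simple
polygon with designated base and apex, rotates the base→apex segment
onto the x-axis, and partitions the wing into `n_strips` strips
perpendicular to that axis; the chord of a strip is its area divided by
its width.  Strip areas are evaluated *exactly* through the divergence
identity $A(t) = \oint \min(x, t)\,dy$ for the area of the polygon left
of $x = t$, so the only discretisation error left in
`moment_radius()` — which integrates $\hat r^k$ exactly against the
piecewise-constant chord — is the piecewise-constant representation
itself, $O(n_\text{strips}^{-2})$ for smooth outlines.  The default
`n_strips = 500` reproduces the closed-form RSM of a rectangle
($\sqrt{1/3}$), base- and tip-tapered triangles ($\sqrt{1/6}$,
$\sqrt{1/2}$) and a Beta(2,2)-density chord ($\sqrt{0.3}$) to well
inside $10^{-3}$.  The wing axis is the base→apex chord, not a principal
axis, matching how $r$ is measured in the strip-counting protocols this
mirrors; fore- and hindwings are always processed separately because in
damselflies the two pairs do not form a common lifting surface.

## Geometric morphometrics

Twelve landmarks per wing (ten fixed, two semilandmarks on the wing
margin) are superimposed by Generalized Procrustes Analysis
(`gpa()`): translate to the centroid, scale to unit centroid size,
rotate to minimise summed squared deviations from the consensus,
iterate.  Semilandmarks lack point-to-point homology along the margin,
so when `slide = TRUE` each is displaced along its discrete tangent (the
chord between its neighbouring points; end points use the single
adjacent chord) by the projection of its residual from the consensus —
the sliding criterion that minimises Procrustes distance, not bending
energy.  Two open details were resolved as follows:

* **Sliding target.**  Sliding uses the consensus of the current
  iteration, alternating slide and re-superimposition, rather than a
  one-shot slide against a final consensus.  Each pass restarts from the
  originally digitised configurations, so the slid state is a
  deterministic function of the current consensus and the iteration is a
  genuine fixed-point scheme.  Because the likelihood is nearly flat
  along the tangent direction, this fixed point is approached linearly;
  the iteration cap is therefore 500 (tolerance $10^{-10}$ on the
  consensus RMS change), and typical cohorts converge in roughly 100
  passes.
* **Species-mean shapes** are means of aligned coordinates, with shape
  variables recomputed from those means (the alternative — averaging
  shape variables — differs only at second order in the variation).

Shape is expressed in the standard $2k-4$ tangent-space variables:
$2k-6$ partial-warp scores (projections on the non-null eigenvectors of
the consensus bending-energy matrix, ordered by decreasing bending
energy) plus the two-dimensional uniform component, built here as the
orthonormal complement of the similarity directions inside the affine
deformations of the consensus.  A purely affine deformation loads only
on the uniform columns.  Residuals are orthogonally projected onto the
tangent space at the consensus before scoring.  With $k = 12$ this gives
20 variables, which is exactly the numerator df the shape-component
MANCOVA carries at the full design.

Thin-plate-spline deformation grids (`tps_grid()`, kernel
$U(r) = r^2\log r^2$) visualise shape change; the interpolation property
(landmark images exact) and agreement with a direct solve of the
bordered kernel system are tested.  Allometric **shape scores**
(`shape_scores()`) regress each tangent coordinate on a covariate and
project every specimen's shape onto the unit regression vector,
summarising all landmarks in one value while retaining the residual
variation along that direction of shape space.

## Comparative statistics

Species are the unit of replication: per-specimen RSM and log centroid
size are averaged per taxon and wing.  The raw-scale analyses are
ordinary least squares (linear and quadratic regressions of RSM on log
centroid size), a MANCOVA of the shape variables on wing identity and
the RSM (Wilks' $\Lambda$ per term, partial hypothesis SSCP, Rao's F
approximation — for 74 species-wing means and 20 variables the covariate
test carries df 20 and 52), an ANCOVA layout for comparing RSM across
odonate groups with body length as covariate, and a general linear model
of the RSM on coloration group (six levels) plus size and size² with
partial (SPSS Type-III-style) sums of squares; with 37 taxa its error df
is 29.  The non-allometric RSM is the residual of the quadratic size
regression.

**Independent contrasts.**  Felsenstein's recursion produces
$n_\text{tips}-1$ standardized contrasts; regressions on contrasts are
forced through the origin (df $= (1, n_\text{contrasts}-1)$, $R^2$ about
the origin, with the about-the-mean $R^2$ also reported), and contrast
pairs are positivized on the size axis, which provably changes neither
slope nor $R^2$.  The through-origin contrast slope equals the
generalized-least-squares slope under Brownian covariance; the tests
verify this equality on random trees to $10^{-8}$.  Branch lengths can
be transformed to pass the $|$contrast$|$-versus-SD diagnostic; the
exponential transform was named but not defined in the protocol this
follows, so the package defines it as: rescale the tree to unit height,
then $b \mapsto e^{b}$ per edge.  Every transformed edge then lies in
$(1, e]$, compressing relative branch-length differences — the usual
reason this transform passes the diagnostic.  `"log"` and `"sqrt"` are
provided untouched by any rescaling; `"log"` warns if it produces
non-positive lengths.  Polytomies are a hard error everywhere; nothing
is silently resolved.

**Phylogenetic ANOVA.**  The conventional one-way F of a trait on group
labels is referred to a null distribution obtained by simulating the
trait under Brownian motion on the study tree (`brownian_simulate()`:
independent normal increments per edge, variance $\sigma^2 \times$
branch length).  The Brownian rate defaults to the contrasts-based REML
estimate $\hat\sigma^2 = \sum \text{pic}_i^2/(n-1)$; since F is
scale-invariant the rate affects nothing but is reported.  The p-value
uses the $(b+1)/(N+1)$ plug-in estimator so that finite simulation never
reports zero; the plain proportion is available via
`p_method = "proportion"` for strict replication of implementations that
use it.  Type-I error at the Brownian null is verified by simulation to
sit near the nominal 5%.

## The synthetic-data generator

No raw specimen data accompany the study this package re-implements
(museum photographs, no deposited measurements), so
`simulate_wing_dataset()` generates cohorts with the statistical
structure the analysis assumes.  What it emulates:

* **Tree** — 37 taxa; the root splits a small basal clade
  (`n_basal = 4` tips, the size of the early-diverging,
  wing-base-coloured group in the study family) from the main
  radiation; each side is a Yule tree, grafted to give total height 1.
  A plain Yule tree was rejected because its smaller root child is
  nearly half the taxa in about half of all replicates, which produces
  two size clouds rather than the hump the generator must emulate.
* **Size** — log wing centroid size evolves by Brownian motion
  ($\sigma^2 = 0.04$ per unit height, i.e. tip SD $\approx 0.2$,
  roughly a two-fold size range) from a root value of $\log 60$ (mm);
  the basal clade is shifted by $-0.55$ log units, because the basal
  genus of the study family is also its smallest.
* **RSM** — $\text{RSM} = 0.56 - 0.12\,(\log\text{size} - \log 60) -
  0.07\,[\text{basal}] + \varepsilon$, $\varepsilon \sim N(0, 0.005^2)$
  per wing.  The negative slope is the evolutionary-level signal; the
  basal offset produces the raw-scale hump.  These effect sizes were
  fixed once by a power study at the study design (200 replicates):
  with them, the species-mean regression selects the quadratic term
  *and* the contrast regression recovers a significantly negative slope
  in ~88% of replicates, which is what the acceptance property asserts
  (threshold 80%).
* **Geometry** — each taxon-wing's chord profile is a Beta density with
  fixed concentration 4, chosen because its RSM is closed-form
  ($\hat r_2 = \sqrt{m(1-m)/(\nu+1) + m^2}$ for mean $m$), giving an
  exact oracle for the whole outline→RSM stage; `rsm_to_beta()` inverts
  the map by monotone root finding.  This is a modelling convenience,
  not a biological claim about chord shapes.  Specimens get small RSM
  jitter (SD 0.004), 2% length jitter, and landmarks placed at fixed
  arc-length fractions with isotropic digitising noise (SD 0.5% of wing
  length); specimen counts are uniform on 5–10.
* **Coloration groups** — random in 1–6 by default, deliberately
  independent of the phylogeny and the RSM; `link_color_to_clade = TRUE`
  ties group 1 to the basal clade to mimic the real study's confounding
  of basal status with wing-base coloration.

What the generator does **not** emulate: vein topology, pigmentation
imagery, outline asymmetry, measurement error correlated across
landmarks, or non-Brownian trait evolution.  Passing tests therefore
show the machinery is correct and the design has power against the
generator's world — not that real wings satisfy these models.

Note one consequence of the generator's structure worth knowing when
reading pipeline reports: the basal-clade RSM offset is real structure
that the quadratic size regression absorbs only partially, so when a
randomly drawn coloration group happens to capture basal taxa, the
coloration-group GLM and the phylogenetic ANOVA can rightly flag it.

## Numerical choices and degenerate inputs

* Strip integration: exact slab areas; wing tissue projecting beyond
  base or apex along the axis is folded into the end strips so the
  normalisation invariant $\int \hat c = 1$ holds exactly.
* GPA: full-Procrustes scaling each iteration; reflections disallowed
  by default (single body side); convergence at $10^{-10}$ consensus
  RMS change, cap 500 iterations, hard error with diagnostics on
  non-convergence.  The Gower objective is tracked and is
  non-increasing.
* TPS: singular bordered systems (collinear landmarks) are a hard error
  naming the cause.
* Degenerate inputs error early and loudly: zero-area outlines,
  base = apex, coincident landmarks, constant covariates, empty groups,
  trees without branch lengths, duplicate tip labels.
* Monte-Carlo seeds are explicit arguments everywhere; the pipeline
  derives every stage seed from one config seed, and two runs with the
  same config are byte-identical.
* Problem sizes used by the checks: 37 taxa, 5–10 specimens, 500
  strips, 12 landmarks; the phylogenetic-ANOVA size check uses 500 null
  replicates of 500 simulations, and the reversal property 200
  replicates — sizes at which the whole suite runs in minutes on one
  core.

## Known limitations

* The MANCOVA requires more error df than response dimensions; with
  fewer than 13 species-wing means per wing the pipeline truncates to
  the highest-variance shape variables and says so in the result object
  (`p` column).  The full design never triggers this.
* The uniform component uses the linearised (small-deformation)
  construction; for very large shape differences the affine/non-affine
  split is only approximate, as in all tangent-space morphometrics.
* `"log"` branch transforms can produce non-positive lengths on trees
  with edges shorter than 1; the package warns rather than silently
  rescaling.
* The RSM integral assumes a simple (non-self-intersecting) outline
  polygon; self-intersections are not detected, only zero area is.
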