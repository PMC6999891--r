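---
title: "Detecting neighborhood preferences of CD30-positive cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting neighborhood preferences of CD30-positive cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd30nbhd)
```

# The question and the model

Classical Hodgkin lymphoma is unusual among tumors: the malignant
Hodgkin/Reed-Sternberg (HRS) cells make up only a small percentage of
the affected lymph node, embedded in a reactive microenvironment.
CD30 immunostaining marks HRS cells — and, in inflamed but non-tumorous
nodes (lymphadenitis, LA), strongly activated lymphocytes.  Whole slide
images of such stainings yield, after segmentation, tens of thousands of
cell profiles per slide: centroid positions plus shape descriptors.

`cd30nbhd` asks a simple question of such data: *does the morphology of a
cell predict the morphology of its nearest neighbor?*  The analysis
proceeds in five stages.

**1. Profile classes.**  Each segmented cell carries an area $A$
(µm²), an eccentricity $e$ (of the ellipse with the same second central
moments), and a solidity $s$ (fraction of the convex hull filled).
Objects of 109 µm² or less are discarded — the size of an 11.8 µm disk,
below the plausible size of a CD30-positive cell.  The survivors are
classified into eight *profile classes* by a 3-bit code

$$\mathrm{PC} = [A \ge A_L] + 2\,[e \ge e_E] + 4\,[s < s_F],$$

so PC 0 is small/round/solid and PC 7 large/elongated/frayed.  The
original study defined its thresholds empirically with pathologists and
did not publish the values; the package defaults are documented
stand-ins — $A_L = 100\pi \approx 314.16$ µm² (a 20 µm disk, the lower
end of the reported HRS size range of 20–60 µm), $e_E = 0.75$,
$s_F = 0.90$ — and every threshold is configuration-exposed and echoed
into the run log, so results are reproducible under any stated values.
The boundary conventions (large means $\ge$, elongated means $\ge$,
frayed means $<$; the small-object filter removes "or less", i.e. keeps
strictly greater) are fixed and asserted by tests.

**2. Neighborhood table.**  For every classified cell the nearest other
cell by Euclidean centroid distance is found, subject to a cutoff of
175 µm (700 px at 0.25 µm/px — roughly ten average cell diameters, the
range over which cytokine/chemokine-mediated interaction is plausible).
Cells whose nearest neighbor lies beyond the cutoff are excluded from the
table but counted, and still contribute to the class frequencies.  The
relation is directional: $a$'s nearest neighbor being $b$ does not make
$b$'s nearest neighbor $a$, and the table never assumes symmetry.
Distance ties (possible in rasterized coordinates) break to the lowest
neighbor id, making the table deterministic.  The default spatial search
buckets cells on a grid of the cutoff width; it is contract-tested to be
identical to the all-pairs scan.

**3. Significance per image.**  Under the null hypothesis that the
nearest neighbor's class is a random draw, the count $k$ of
(PC $=i$, NPC $=j$) pairs among the $n_i$ class-$i$ cells with a
neighbor is $\mathrm{Binomial}(n_i, p_j)$, where $p_j = f(j)$ is the
relative frequency of class $j$ among **all** classified cells of the
image (the focal class included — with 3,435 of 10,860 cells in class 0,
$p_0 = 0.316$).  A two-sided exact prediction interval at level
$\alpha = 1\%$,

$$k_{low} = \max\{k : P(X \le k) \le \alpha/2\}, \qquad
  k_{up} = \min\{k : P(X \ge k) \le \alpha/2\},$$

is computed by exact tail evaluation (regularized incomplete beta, no
normal approximation; endpoints are verified against exhaustive
term-by-term summation for all $n \le 200$).  Counts strictly above
$k_{up}$ are *significantly high* (sh), strictly below $k_{low}$
*significantly low* (sl), anything else — including the endpoints —
*non-significant* (ns).  No multiple-testing correction is applied
across the 64 combinations, matching the published procedure; an
optional Benjamini–Hochberg switch exists but is off by default.

**4. Cohort scores and networks.**  Within a diagnosis group the integer
score of a combination is (number of images called sh) − (number called
sl), normalized to a percent of the group size (rounded half away from
zero, so 31/35 → 89% and 26/35 → 74%).  A directed preference network
draws an edge $i \to j$ whenever the absolute percent strictly exceeds
50% of the maximum; sign encodes favored (green) versus unfavored (red),
self-loops are allowed, and the two directions of a pair are independent
entries.

**5. Diameter background subtraction.**  "Diameter" is always the
maximal Feret diameter.  Relative diameter histograms use half-open
2.5 µm bins anchored at 0.  The identifying assumption of the tumor-cell
proportion estimate is that the reference bin [12.5, 15) µm contains
activated-lymphocyte background only.  Scaling the LA histogram by
$c = \mathrm{disease}(\mathrm{ref})/\mathrm{LA}(\mathrm{ref})$ and
subtracting leaves the tumor component; the estimated HRS proportion is
$1 - c$.  Negative corrected bins are clipped to zero (the clipped mass
is recorded) and the corrected distribution is renormalized before
moments are computed over bin centers.  Renormalization-before-moments
is a package choice where the original procedure is silent; it makes the
corrected distribution a proper distribution and the moments
mixture-consistent, and is exercised by a planted-mixture recovery test.

# Shape descriptors from label masks

For workflows starting from segmentation masks rather than feature
tables, the package computes the four descriptors from labeled rasters:
area as pixel count × resolution², centroid as the mean of pixel-center
coordinates, eccentricity from the eigenvalues
$\lambda_{1,2}$ of the pixel-center covariance as
$e = \sqrt{1 - \lambda_{min}/\lambda_{max}}$ (the
moment-equivalent-ellipse convention of the common region-properties
toolchains), solidity as region pixels over filled-convex-hull pixels,
and the maximal Feret diameter as the largest pairwise distance between
convex hull vertices.  Regions are 8-connected; hulls are taken over
pixel centers.  Whether the original measurement tool used pixel centers
or corners is not stated; the difference is below one pixel and all
fixture tests carry a ±1 px tolerance.  A single-pixel region has
eccentricity 0 and Feret diameter of one pixel width by convention.

# The synthetic cohort generator

The study's 35 whole slide images are not public, so the package ships a
marked-point-process generator whose defaults emulate the cohort
structure the analysis assumes:

* **Window and intensity** — a 10 × 10 mm tissue window at
  8×10⁻⁵ cells/µm², i.e. ≈8,000 cells per image, within the study's
  10³–10⁴ cells per slide.
* **Class fractions** — near the reported cohort averages
  (38.6% PC 0, 25.5% PC 4, 0.8% PC 3, …).
* **Clustering** — every class a Thomas process (Poisson parents, mean
  5 offspring, Gaussian spread σ = 60 µm).  Under these defaults the
  mean nearest-neighbor distance is ≈42 µm against a CSR mean of
  ≈56 µm at equal intensity — inside the reported per-diagnosis range of
  37.9–48.3 µm and, like the real images, clearly left-shifted relative
  to complete spatial randomness.  Parents are sampled in a window
  dilated by 4σ so clusters straddle the boundary without bias.
* **Morphology** — descriptors drawn uniformly inside the threshold cell
  of the target class with a 5% margin of each threshold, so generated
  cells are classified as their target class with zero error; the Feret
  diameter follows from the equal-area ellipse of the drawn
  eccentricity.  Large-cell areas extend to a 60 µm disk, the top of the
  reported HRS size range.

Ground truth is planted by two mechanisms:

* **Attraction** (shared parents): class $b$ reuses a stated fraction of
  class $a$'s cluster parents, placing the two classes in common
  clusters.  This was chosen over pairwise Gibbs interactions because it
  gives direct, cheap, exactly-sampled control over nearest-neighbor
  composition.
* **Repulsion** (hard-core thinning): class $b$ points within a stated
  radius of any class $a$ point are deleted (the later-sampled point of
  a violating pair dies).  In the shipped repulsion scenario the
  repulsed class is left unclustered: at study densities, a 50 µm hard
  core around a *clustered* class still leaves most of the window
  vacant, so enough repulsed cells survive for the significantly-low
  call to be testable, whereas thinning against an unclustered class of
  the same intensity would delete nearly everything (vacant-area
  fraction $e^{-\lambda \pi r^2} \approx 0$) and make the question
  degenerate rather than significant.

A fixed seed makes cohorts bit-identical.  What the generator does *not*
emulate: staining artifacts, segmentation errors, anisotropy, tissue
compartments (follicles, sinuses), inhomogeneous intensity, or any
correlation between a cell's morphology and its local density beyond
class membership.  Tests passing on synthetic cohorts therefore validate
the statistical machinery — calibration, power, bookkeeping — not the
biological conclusions on real tissue.

# Calibration, power, and a known limitation

On null cohorts (CSR positions, class labels independent of positions)
the overall rate of sh+sl calls at $\alpha = 1\%$ stays below 1.5%
(the exact intervals are conservative on discrete counts), and planted
attraction/repulsion are recovered as sh/sl in ≥90% of images — both
checked by the acceptance suite at 500 and 50 images respectively.

One genuine limitation of the binomial model surfaces in calibration:
for *same-class* combinations (PC = NPC = $i$) the pair-count variance
exceeds the binomial variance, because the two cells of a mutual
nearest-neighbor pair contribute the *same* event twice (about 62% of
cells in a CSR pattern are in mutual pairs).  Same-class false-call
rates can therefore reach a few percent at nominal 1% while off-diagonal
combinations stay conservative.  The acceptance script reports the
pooled, off-diagonal, and diagonal rates separately.  Practically this
means isolated same-class sh calls near the interval boundary deserve
more caution than cross-class calls; the strong effects the method is
meant to find (counts several intervals away from the boundary) are
unaffected.

A second documented discrepancy: for the published worked example
($n = 3435$, $p \approx 0.316$, $\alpha = 1\%$) the interval printed in
the original report, [1047, 1125], is substantially narrower than what
the report's own interval definitions produce under exact evaluation
([1016, 1158]; a normal-approximation interval at $z = 2.576$ gives the
same width).  The package implements the stated definitions; the
worked example's sh call ($k = 1217$) holds under either interval.

# Numerical and degenerate-input choices

* $p = 0$ gives $k_{low} = -1$ and $p = 1$ gives $k_{up} = n + 1$:
  that side can then never fire, so single-class images yield all-ns
  rows rather than spurious calls.
* Rows with $n_i = 0$ (no class-$i$ cell has a neighbor) are all ns.
* The enrichment strength used for the distance–preference correlation
  is $-\log\left(q/(1-q)\right)$ with $q = P(X \ge k)$, clamped at
  $\pm\log 10^{15}$; the original report used a "log-odd value" without
  defining it, so only monotonicity in $k$ is relied upon.
* The distance–preference Pearson correlation requires ≥3 images with
  defined values and flags zero-variance input as undefined instead of
  returning a number.
* Empty diameter bins in the background's reference bin are an error,
  not a silent division by zero.
* Percent scores round half away from zero, matching the published
  integer percentages.

# Problem sizes used by the tests

The suite and the acceptance script size their simulations to the study
scale where that matters and to miniatures where only structure is
checked: calibration uses 500 null images of ≈2,000 cells; recovery uses
50 images per scenario at the full ≈8,000-cell default; the CSR
closed-form check pools ≈30,000 nearest-neighbor distances from
realizations of ≈5,000 points; mixture recovery uses 5×10⁴ cells;
the interval oracle sweeps all $n \le 200$ against term-by-term
summation.  Structural pipeline tests run three miniature images of a
dense 0.8 × 0.8 mm spec.

# Limitations

* The classification thresholds are stand-ins, not the original values;
  conclusions about specific classes on real data require the original
  (or locally calibrated) thresholds.
* The binomial test treats neighbor choices as independent; see the
  same-class variance inflation above.  A Monte-Carlo label-permutation
  test would calibrate the diagonal exactly but is intentionally not the
  primary method, to stay faithful to the published procedure.
* No edge correction is applied to nearest-neighbor distances; at study
  densities the boundary bias on the mean is well below sampling noise,
  but very sparse images in small windows would inflate distances.
* The background-subtraction estimate of the tumor proportion is exactly
  as good as its identifying assumption (no tumor mass in the reference
  bin); if tumor cells of 12.5–15 µm exist, the proportion is
  underestimated.
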