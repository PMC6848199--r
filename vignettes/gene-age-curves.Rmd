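---
title: "Comparing evolutionary age distributions of gene classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing evolutionary age distributions of gene classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(geneage)
library(dplyr)
```

## The setting

Phylostratigraphy assigns each gene an *evolutionary age*: the oldest
branch point of the focal lineage whose genomes still contain a
detectable homolog. On the human lineage this package uses a linear,
16-taxon timeline from Cellular Organisms down to *H. sapiens*, each
taxon carrying a divergence time in million years (Ma). The age bucket of
a gene is a taxon index; the taxon's divergence time is a *lower bound*
on when the gene arose, because the gene may have appeared anywhere along
the branch leading to that taxon.

Given a catalog of gene classes (housekeeping genes, oncogenes, tumor
suppressors, differentiation genes, cancer/testis antigens, ...), the
scientific questions are:

1. How is each class's origination spread along the timeline, and what is
   its representative (median) age?
2. Which classes have indistinguishable age distributions, and how do the
   classes group (clusters of curves)?
3. Is one class *stochastically younger* than another — a distributional
   ordering, not merely a difference in means?
4. Do class memberships overlap more than chance?

## Cumulative origination curves and medians

For a class with per-taxon origination counts $n_1, \dots, n_k$
(oldest to newest, $n = \sum_s n_s$), the cumulative origination curve is

$$C(s) = \frac{1}{n}\sum_{t \le s} n_t .$$

$C$ is the CDF of the origination step. Writing $A$ for the age of a
random gene of the class, $P(A \ge a_s) = C(s)$, so *the class whose
curve lies everywhere lower has the stochastically larger age CDF and is
the younger class*. Curves are plotted against the Ma axis, which runs
right to left.

The **median age** is the point where the curve, linearly interpolated on
the Ma axis between taxon breakpoints, reaches 50%. Interpolation is what
lets a median fall between divergence times; a step-function median could
only ever return a breakpoint age. Two conventions are involved, both
deliberate and config-overridable:

* a left anchor $(\text{root\_age}, 0)$ — default 4200 Ma — so classes
  with half their mass in the oldest bucket still receive a finite
  median. The oldest bucket is open-ended ("at or before this branch
  point"); `age_of()` reports it at `root_age` while the bucket keeps its
  own breakpoint age (default 3900 Ma) for curve geometry;
* when the interpolated curve is flat at exactly 0.5, the oldest crossing
  time is reported.

`median_age()` is tested against an independent oracle that evaluates the
polyline on a $10^6$-point grid (augmented with the exact breakpoints so
no grid cell spans a kink) and inverts the first 0.5 crossing; agreement
is required to $10^{-9}$ Ma.

Divergence times for Opisthokonta (1368), Bilateria (910), Chordata
(797) and Homininae (6) are fixed study values; the other twelve taxa
ship as editable TimeTree-style defaults. Deuterostomia defaults to 860
Ma so that it sits between the fixed Bilateria and Chordata anchors even
though newer compilations place it younger; internal monotonicity wins
over any single external source.

```{r curves}
tl <- default_timeline()
study <- simulate_study(study_scale_spec(), tl, seed = 1)
ca <- join_ages(study$catalog, study$age_table)
dist <- age_distributions(ca, tl)
median_age(dist, tl) |> arrange(desc(median_ma))
```

## Distances, tests and clustering

Classes are compared with the Kolmogorov-Smirnov distance
$d(A, B) = \max_s |C_A(s) - C_B(s)|$; on a common 16-point support the
breakpoint maximum is the full supremum distance. Pairwise inference uses

* the two-sample KS test. Gene ages are heavily tied (16 support
  points), and the asymptotic KS p-value is conservative under ties, so a
  **permutation p-value** (relabelling genes between the two classes;
  implemented as fixed-margin table resampling, default 9999 draws) is
  the headline number, with the asymptotic value reported alongside;
* Pearson's chi-square homogeneity test on the class-by-taxon count
  table. All-zero taxon columns are dropped first (they would zero the
  expected counts); degrees of freedom are $(r-1)(c_\text{used}-1)$, so a
  three-cluster table over 16 occupied taxa carries 30 df. No continuity
  correction is applied on 2x2 tables;
* Holm's step-down adjustment for multiple testing — chosen as the
  least-assumption method since nothing about the dependence structure of
  the pairwise tests is known.

Classes are clustered by complete linkage on the KS distance matrix
(`stats::hclust`); complete linkage is monotone, so merge heights never
decrease toward the root. Trees serialize to ultrametric Newick with leaf
depth equal to the root merge height. Bootstrap reliability resamples
every class at its own size (multinomial resampling of its count vector,
which is identical in law to resampling the age multiset), rebuilds the
tree, and reports for each original node the fraction of replicate trees
containing the same leaf set as a clade — topology-only comparison, the
standard clade-support convention. Default 10000 replicates; module tests
use a few hundred for speed.

## The stochastic-order test

The central inference: is class $A$ stochastically younger than class
$B$? The statistic is the maximum standardized curve difference

$$T = \max_s \frac{|C_A(s) - C_B(s)|}{\hat\sigma_s}, \qquad
\hat\sigma_s = \sqrt{\hat p_s (1 - \hat p_s)\left(\tfrac{1}{n_A} +
\tfrac{1}{n_B}\right)},$$

with $\hat p_s$ the pooled cumulative proportion. The centered difference
of two empirical CDFs converges to a Brownian bridge with covariance
$p_i(1 - p_j)$ for $i \le j$; the null distribution of $T$ is therefore
the maximum modulus of a correlated Gaussian vector, evaluated by Monte
Carlo (default $10^6$ replications, seeded). The $(1-\alpha)$ quantile
$c_\alpha$ yields a *simultaneous* confidence band
$D_s \pm c_\alpha \hat\sigma_s$ over all breakpoints, and the same Monte
Carlo sample gives the two-sided max-modulus p-value.

Design choices that were genuinely open:

* **Pooled covariance.** The bridge covariance is estimated from the
  pooled curve, the null-consistent choice for a test of
  equality/ordering (separate-curve estimates would target a different
  null).
* **Degenerate breakpoints.** Breakpoints with pooled proportion 0 or 1
  carry no information (zero asymptotic variance) and are excluded rather
  than regularized; the final breakpoint is always excluded since both
  curves end at 1.
* **Verdict rule.** "A younger" requires both a simultaneous rejection
  and *signed, band-supported* evidence: at least one breakpoint whose
  band excludes zero, and all such breakpoints with $C_A < C_B$.
  Significant deviations of both signs give "crossing". This keeps the
  verdict interpretable as stochastic ordering rather than mere
  difference.
* **Scheffé alternative.** A chi-square-based closed-form calibration
  $c_\alpha = \sqrt{\chi^2_{k,1-\alpha}}$ is available behind
  `method = "scheffe"` for sensitivity analysis; it is conservative
  (never narrower than the max-modulus band) and is tested as such.

```{r order}
parts <- split(dist, dist$class)
fit <- stochastic_order_test(parts$ct_x, parts$housekeeping,
                             n_mc = 1e5, seed = 2)
glance(fit)
```

Bootstrap order rates complement the test: each replicate pair of
resampled curves is classified as strictly lower, strictly higher, or
neither (curves crossing, or exactly tied — ties carry no strict order
and are counted under "crossing", reported separately as `tied`).

## Overlap analysis

Class overlaps are assessed on 2x2 contingency tables over a gene
universe: observed joint membership against the expectation
$N \cdot \frac{|A|}{N}\cdot\frac{|B|}{N}$ under independent attendance,
with plain chi-square and two-sided Fisher exact p-values (the
point-probability two-sided rule; a zero margin returns $p = 1$ by
convention). The universe defaults to the genes detected in the age
table, not the full annotated gene count — expected counts are
universe-sensitive, so the universe is explicit and overridable.
Derived subclasses (intersections `A x B`, differences `A - B`) re-enter
every other analysis stage as first-class classes, and triple/quadruple
intersections report counts plus per-member shares.

## The synthetic generator

No gene database ships with the package. `simulate_study()` generates
studies with the statistical structure the analysis assumes: a universe
of genes (default 19911, the scale of a detected human protein-coding
set) with a stylized genome-wide origination profile, plus classes drawn
i.i.d. from their own multinomial profiles, with optional pairwise
sharing of members (a shared gene has one age, drawn from the first
declaring class's profile and honored by both classes — the simplest
model consistent with single-valued gene ages).

`study_scale_spec()` provides ten classes at the detected sizes of the
study databases (6789, 3697, 984, 231, 224, 121, 109, 78, 60, 53) in
three stylized profile families — old, intermediate, young — echoing the
three clusters such studies report. The profiles are step-up inventions,
**not** digitized curves; passing tests on this structure demonstrates
that the machinery recovers planted multinomial structure at realistic
sizes, not that any biological claim is reproduced. Real data differ in
ways the generator deliberately omits: ages are not i.i.d. within a
class (gene families share histories), class membership is curated and
error-prone, and identifier mapping across databases loses genes.

## Calibration, problem sizes and limitations

The test suite and the acceptance script verify, at the package's chosen
problem sizes:

* type-I error of the stochastic-order test under a shared profile
  ($n_A = n_B = 500$, $10^5$ Monte-Carlo replications per test) within
  [0.03, 0.07] at $\alpha = 0.05$;
* power $\ge 0.9$ against a two-taxon rootward profile shift at the same
  sizes;
* simultaneous null coverage of the joint band $\ge 93\%$
  ($n = 200$ per side);
* recovery of planted three-group structure with near-unanimous
  bootstrap support for every complete group clade ($n = 300$ per class).
  The order in which whole groups merge above those clades is *not*
  asserted: when two between-group distances are close, the middle group
  may join either neighbor across replicates, which is a property of the
  merge ordering, not of group separation;
* closed-form identities (bridge covariance, KS breakpoint maximum,
  Fisher enumeration, Holm by hand, normal quantile at one breakpoint).

Known limitations: ages live on a linear lineage (no tree structure
beyond the human path); the exact small-sample null of the max-modulus
statistic under heavy ties is not computed (the Monte-Carlo Gaussian
limit is used); identifier matching is exact-string; and the non-coding
age rule consumes already-thresholded homology hits — a single E-value
cutoff (default $10^{-3}$), with bit-score filtering out of scope.
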