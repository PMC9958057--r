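---
title: "Reduced reverse degree indices: models, closed forms and QSPR diagnostics"
author: "rrtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced reverse degree indices: models, closed forms and QSPR diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrtopo)
```

## The model

A molecular graph here is the hydrogen-suppressed skeleton of a molecule:
vertices are heavy atoms, edges are bonds, and the graph is simple and
undirected. A degree-based topological index assigns the graph the number

$$TI(G) = \sum_{uv \in E(G)} w\big(\ell(u), \ell(v)\big),$$

where $w$ is a symmetric weight and $\ell$ a vertex labeling. For the
classical indices $\ell(v) = d(v)$, the vertex degree. The reduced reverse
family instead labels each vertex

$$\mathcal{RR}(v) = \Delta(G) - d(v) + 2,$$

with $\Delta(G)$ the maximum degree of the graph. The label is smallest (2)
exactly at maximum-degree vertices and grows toward the periphery, so these
indices emphasise terminal and low-coordination atoms — the opposite
weighting to plain-degree indices. `rrtopo` always computes $\Delta$ on the
graph actually supplied, never on a wider chemical family; disconnected
graphs are accepted and $\Delta$ is taken over the whole graph.

The catalog (`indexCatalog()`) holds 26 weight rules: ten reduced-reverse
indices (first/second Zagreb, first/second hyper-Zagreb, forgotten,
atom-bond connectivity, geometric-arithmetic, and Randic type with exponents
$-1$, $1/2$, $-1/2$) and sixteen classical comparison indices (Zagreb,
hyper-Zagreb, forgotten, ABC, Randic and its exponent variants, GA, harmonic,
Gourava and hyper-Gourava). The classical formulas are the standard
literature definitions for those families. Two catalog notes:

* the reduced-reverse Randic index with exponent $1$ is pointwise identical
  to the second reduced-reverse Zagreb index, so it is not duplicated as a
  catalog entry; `randicSpec(1, "reduced_reverse")` constructs it and a
  property test asserts the identity;
* the classical `R` and `R_-0.5` entries are numerically the same rule under
  two conventional names, and both are kept.

The ABC-type weight at the degenerate label pair $(1,1)$ is defined as 0
(its numerator vanishes), not an error.

## Edge partitions and closed forms

Because the weight depends only on endpoint labels, an index is a linear
functional of the *edge partition*: the table of edge counts per unordered
label pair (`edgePartition()`). For a polymer family $G_n$ whose class
counts are linear forms $s \cdot n + c$ in the repeat count $n$, every index
is therefore itself linear in $n$; `closedForm()` weights slopes and
intercepts separately and returns the pair as a `LinearForm`. The
equivalence of the three evaluation routes — direct edge summation, numeric
partition summation, and symbolic closed form instantiated at $n$ — is
enforced by property tests over seeded random graphs.

The packaged example is the hyaluronic-acid–paclitaxel conjugate
$(HAP)_n$, a drug-delivery copolymer whose reduced-reverse edge partition
(nine classes, 96 edges per repeat unit) ships as a JSON fixture:

```{r}
hapPartition()
closedForm(hapPartition(), "RRM1")
```

A useful consistency check inverts the partition: mapping a reduced-reverse
label $a$ back to a degree $d = \Delta + 2 - a$ and summing
$1/d(u) + 1/d(v)$ over all edges counts each vertex once
(`impliedVertexForm()`). For the HAP partition with $\Delta = 4$ this gives
$87n + 1$ vertices. The published per-unit coefficient (87) is reproduced;
the $+1$ constant disagrees with the published pure $87n$ count and is
reported as-is — with only the printed partition available the discrepancy
cannot be resolved, so only the per-unit coefficient is asserted anywhere.

Two published HAP closed forms — RRGA and Randic type with exponent $-1/2$ —
cannot be reconciled with direct summation over the printed partition
(`hapClosedFormReport()` tabulates computed against published values and
flags them). The package reports both and never forces agreement; these two
forms are excluded from every reproduction check. A third, minor case: the
published Randic($1/2$) slope `326.571942` carries a one-unit slip in its
final digit (exact summation gives `326.5719413931...`), so that coefficient
is compared at one unit in the last printed digit rather than half a unit.

## Benzenoid systems

`hexagonalSystem()` builds fused-hexagon (benzenoid) skeletons from axial
lattice coordinates. Corner positions are scaled to exact integer lattice
points, so shared corners of adjacent rings unify by identity — there is no
floating-point merging tolerance to tune. Degrees are always 2 or 3, and
catafused chains of $h$ rings obey the counting law $4h + 2$ vertices and
$5h + 1$ edges, which the tests check for $h = 1..6$.

## The QSPR study data

The regression study covers 26 unnamed benzenoid hydrocarbons with twelve
properties (boiling point BP, critical temperature/pressure/volume, GE,
LogP, molar refraction, Henry's law constant HL, PI, molecular weight,
exact mass, heavy atom count). The molecules are identified only by ordinal,
so their structures cannot be rebuilt and their index values cannot be
regenerated; the study's printed reduced-reverse Randic($-1$) column is
therefore packaged as data (`loadFixture("benzenoid_ti")`) and regression
reproduction is anchored on printed index values plus printed model
coefficients. (The printed column itself is at odds with a literal per-graph
$\Delta$ labeling — e.g. the value 2.2778 for the naphthalene-mass molecule
equals the plain degree-product Randic($-1$) sum — suggesting the study
computed $\Delta$ per family rather than per molecule. The package
implements the definition literally and treats the column as data.)

Two reproduction paths are deliberately separate:

* **published coefficients** (`printedModels()`, `polynomialModel()`):
  evaluate the rounded printed equations to rebuild prediction and residual
  tables (`reproduceTables()`);
* **fresh fits** (`fitPolynomial()`): ordinary least squares via `lm()`,
  whose unrounded coefficients and $R^2$ are compared against the printed
  summaries.

## Diagnostics and their conventions

* **Chi-square goodness of fit** is the residual statistic
  $\sum (O_i - P_i)^2 / O_i$ over molecules — not a counts-based Pearson
  test — compared against the tabulated critical value 37.652
  (25 d.o.f., 5% level), which ships both as a fixture constant and via
  `chisqCritical()` (`qchisq(0.95, 25)`). Degrees of freedom follow the
  study's usage: number of records minus one.
* **Average residual percent** is the mean of $100\,|O_i - P_i| / O_i$.
* **RMSE** exposes both denominator conventions because the study does not
  state one. On predictions from the printed BP coefficients, the residual
  degrees-of-freedom convention ($n - p$, $p$ = number of coefficients)
  reproduces the printed 23.2957; the plain-$n$ convention gives 22.38.
* **Model screening** (`selectBestModels()`) admits only fits with
  $R^2 \ge 0.8$ (the IAMC recommendation the study adopts), picks the
  maximum-$R^2$ survivor, breaks exact ties by fewer coefficients then
  lexicographic name, and flags properties with no survivor or a constant
  (degenerate) response instead of erroring.

Worked reproduction, all from packaged data:

```{r}
props <- loadFixture("benzenoid_properties")
ti <- loadFixture("benzenoid_ti")[["RRR_-1"]]
pred <- predict(printedModels(1, "BP")[[1]], ti)
c(chi2 = chiSquareGof(props$BP, pred),
  res.pct = avgResidualPercent(props$BP, pred),
  rmse.np = rmse(props$BP, pred, "n-p", p = 2))
fit <- fitPolynomial(ti, props$BP, degree = 1)
round(c(coef(fit), r2 = diagnostics(fit)$r.squared), 4)
```

`reproduceTables()` rebuilds the per-molecule prediction tables and the
statistics rows for every published model whose index column is packaged
(the Randic($-1$) column serves BP, LogP and CP linearly, BP and LogP
quadratically); the remaining properties' index columns were never published
and are not reproducible from data.

## The random-graph generator

`randomMolecularGraph(nVertices, maxDeg, seed)` exists to exercise the
oracle equivalence (direct sum vs partition sum) across index specs, not to
emulate chemistry. It draws a random recursive tree under the degree cap and
adds random capacity-respecting extra edges, giving connected simple graphs
with heterogeneous label pairs — the property the equivalence tests need.
Caps of 2–5 and sizes of 8–40 vertices cover the label ranges the packaged
partitions use. It makes no attempt at chemical realism (no valence rules,
no rings-vs-chains statistics), so passing oracle tests demonstrates
algebraic correctness of the index machinery, not fidelity to real
molecules. The generator is deterministic for a fixed seed and leaves the
caller's RNG state untouched.

The property suite runs 200 such graphs against all 26 specs; the catafused
law is checked for chains of up to 6 rings; closed forms are verified
against instantiated partitions for $n = 1..5$. These sizes keep the whole
suite near-instant while exhausting every label class the fixtures contain.

## Numerical choices

* Closed-form coefficients accumulate in double precision; reproduction
  tests compare at the precision each published value was printed with
  (half a unit in the last digit, except the one-ulp case noted above).
* `buildGraph` canonicalizes each edge (larger label first for partitions;
  lexicographic pair for deduplication) and rejects self-loops naming the
  offending pair.
* Fits require at least degree + 2 observations and a non-constant
  predictor; a constant predictor is a rank-deficient design and errors,
  while a constant *response* in model selection is flagged, not an error.
* Graphs with isolated vertices warn on index evaluation (such vertices
  contribute nothing); an empty edge set yields index 0.

## Limitations

* Only degree- and reduced-reverse-degree-based indices: no distance,
  eccentricity or spectral descriptors; no bond orders, charges or 3D
  geometry.
* The 26 benzenoid molecules are data, not structures; nothing in the
  package guesses their identity.
* The HAP family is represented solely by its published partition; the
  package does not reconstruct the conjugate's molecular graph.
* Regression is univariate linear/quadratic as in the study — no
  cross-validation, regularization or multiple-testing correction.
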