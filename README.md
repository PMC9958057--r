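# rrtopo

Reduced-reverse-degree topological indices and curvilinear QSPR for
molecular graphs.

Degree-based topological indices summarise a hydrogen-suppressed molecular
graph as a single number, `TI(G) = Σ_{uv ∈ E} w(ℓ(u), ℓ(v))`, and are the
workhorse descriptors of quantitative structure–property relationship
(QSPR) modelling. The classical indices label each vertex with its degree
`d(v)`; the *reduced reverse* family instead uses

```
RR(v) = Δ(G) − d(v) + 2,
```

where `Δ(G)` is the maximum degree — weighting peripheral, low-coordination
atoms most heavily. `rrtopo` provides, for chemists and cheminformaticians
working with these descriptors:

* **Graphs and partitions** — edge-list and hexagonal-lattice (benzenoid)
  graph builders, degree and reduced-reverse labelings, and edge partitions
  (edge counts per unordered label pair), on which every such index is a
  linear functional.
* **Index engine** — a catalog of 26 indices (10 reduced-reverse, 16
  classical: Zagreb, hyper-Zagreb, forgotten, ABC, Randić variants, GA,
  harmonic, Gourava families), evaluated by direct edge summation, from
  numeric partitions, or — for polymer families whose edge-class counts are
  linear in the repeat count `n` — as closed-form polynomials `a·n + b`.
  The packaged example is the hyaluronic-acid–paclitaxel conjugate
  `(HAP)_n`, an anticancer drug-delivery copolymer, represented by its
  nine-class reduced-reverse edge partition (96 edges per repeat unit).
* **QSPR toolkit** — linear and quadratic least-squares property models
  with the study diagnostics (R², residual chi-square, average residual %,
  RMSE under both denominator conventions), R² ≥ 0.8 screening, best-model
  selection, and a reduced-reverse vs classical comparison report, together
  with the packaged 26-molecule benzenoid hydrocarbon study data (twelve
  physico-chemical properties, the published Randić(−1) index column, and
  the published model coefficients).

## Worked example

Build naphthalene on the hexagonal lattice, partition its edges under the
reduced-reverse labeling, and evaluate indices:

```r
library(rrtopo)

naph <- hexagonalSystem(rbind(c(0, 0), c(1, 0)))
naph
#> MolecularGraph: 10 vertices, 11 edges, max degree 3

edgePartition(naph, "reduced_reverse")
#> EdgePartition (reduced_reverse labeling), 3 classes, 11 edges
#>   (3,3): 6
#>   (3,2): 4
#>   (2,2): 1

indexValue(naph, "RRM1")                    # 60
indexValue(naph, getIndexSpec("RRR", -1))   # 1.583333
```

Closed forms for the HAP conjugate come straight from the packaged
partition — here the reduced-reverse ABC index as a polynomial in the
number of repeat units:

```r
closedForm(hapPartition(), "RRABC")
#> LinearForm: 62.60092n - 0.1081835
```

The benzenoid QSPR study reproduces from packaged data alone. A fresh OLS
fit of boiling point on the published Randić(−1) column:

```r
props <- loadFixture("benzenoid_properties")
ti <- loadFixture("benzenoid_ti")[["RRR_-1"]]
fitPolynomial(ti, props$BP, degree = 1, property = "BP", index = "RRR_-1")
#> QsprFit degree 1: BP ~ RRR_-1
#>   P = 129.008(TI) -75.2619
#>   R2 0.9587 | chi2 44.7368 | avg residual 5.3017% | RMSE 22.3818 (n) / 23.2957 (n-p)
```

and the published rounded coefficients (BP = 129·TI − 75.26) evaluated
against the observed boiling points give the study's table statistics:

```r
pred <- predict(printedModels(1, "BP")[[1]], ti)
round(c(chi2 = chiSquareGof(props$BP, pred),
        res.pct = avgResidualPercent(props$BP, pred),
        rmse.np = rmse(props$BP, pred, "n-p", p = 2)), 4)
#>    chi2 res.pct rmse.np
#> 44.7293  5.3008 23.2957
```

The chi-square value exceeds the tabulated critical value 37.652 (25
d.o.f., 5% level), so the linear boiling-point model is the one model the
screening rejects; `reproduceTables()` rebuilds the full prediction and
statistics tables.

A command-line wrapper is installed at `inst/cli/rrtopo`:

```sh
inst/cli/rrtopo index closed-form --partition hap --index RRM1
# slope 664 intercept 4
inst/cli/rrtopo qspr fit --degree 1
```

See `vignettes/rrtopo-methods.Rmd` for the model conventions, the two
published HAP closed forms that direct summation does not reproduce (they
are reported, never forced), and other documented discrepancies.

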