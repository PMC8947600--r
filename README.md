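# ngmcs

Nutrient-genetic minimal cut sets for constraint-based metabolic models.

## The problem

Synthetic lethality in metabolism is usually framed genetically: a set of
genes whose joint loss blocks biomass production while any proper subset
is viable. But whether a gene set is lethal depends on the growth
environment — a nutrient in the medium can feed an alternative pathway
that rescues an otherwise lethal knockout, and conversely a cell whose
endogenous biosynthetic route is silenced becomes dependent on the
external supply of its product (an auxotrophy). `ngmcs` treats genes and
nutrients uniformly: it enumerates **nutrient-genetic minimal cut sets
(ngMCSs)** — minimal combinations of gene losses and/or nutrient
deprivations whose simultaneous occurrence blocks flux through the
biomass reaction of a genome-scale metabolic model. Gene-only solutions
(gMCSs) are the classical case.

## The method

For a stoichiometric matrix `S` with irreversible fluxes `v ≥ 0`, biomass
is *blocked* exactly when `{S v = 0, v ≥ 0, v_target ≥ 1}` is infeasible,
which by Farkas duality is certified by a vector `u` with
`(Sᵀu)_j ≥ 0` for every reaction `j` that can still carry flux and
`(Sᵀu)_target ≥ 1`.

The knockout structure lives in a binary **G matrix**: each row is a
minimal knockout unit — a minimal gene set falsifying some reaction's
gene-protein-reaction (GPR) boolean rule, or a single nutrient whose
deprivation closes its input exchange reaction — and marks the reactions
that unit disables. Selecting row `i` (binary `z_i`) relaxes the dual
constraint of each covered reaction through a big-M slack, so a minimal
selection of rows admitting a Farkas certificate is a minimal cut set.
The MILP objective counts *elements* (genes via indicators `y_g ≥ z_i`,
nutrients via their row binaries), so cut sets come out by increasing
size; after each solution an integer cut excludes the found element set
and all its supersets. Every solution is re-verified with plain flux
LPs (one blocking LP, plus one leave-one-out LP per element) before it
is reported.

Downstream, expression data contextualise the structural cut sets: a
gene or nutrient is *essential for a sample* when it is the only active
element of at least one cut set (gene active = expression ≥ 1 TPM by
default; nutrient active = present in the medium). Applied across
samples this yields a binary nutrient-dependency (auxotrophy) matrix.

## Worked example

The built-in two-medium toy network has one carbon source `M1` feeding
the growth precursor through two gene-dependent branches; the second
medium adds a nutrient `M2` with a gene-less salvage route.

```r
library(ngmcs)

cm2 <- toy_network("CM2")
g <- build_g_matrix(cm2$model) |>
  extend_with_nutrients(cm2$model, cm2$medium)
res <- enumerate_cutsets(cm2$model, g)
tidy(res)
#> # A tibble: 3 × 7
#>   cutset   classification  size n_genes n_nutrients verified_cut verified_minimal
#>   <chr>    <chr>          <int>   <int>       <int> <lgl>        <lgl>
#> 1 M1;M2    ngMCS              2       0           2 TRUE         TRUE
#> 2 M2;g3    ngMCS              2       1           1 TRUE         TRUE
#> 3 M2;g1;g2 ngMCS              3       2           1 TRUE         TRUE
```

Every cut set here involves `M2`: no purely genetic knockout is lethal
while the gene-less route from `M2` is fed. `{M2, g1, g2}` reads in
three directions — if `g2` is silenced and `M2` is absent, `g1` is
essential; if both genes are silenced, the cell is auxotrophic for `M2`.
The essentiality rule makes those calls from data:

```r
expr <- matrix(c(5, 0.2, 3), 3, dimnames = list(c("g1","g2","g3"), "s1"))
presence <- matrix(c(TRUE, FALSE), 2, dimnames = list(c("M1","M2"), "s1"))
ctx <- activity_context(expr, threshold = 1, nutrient_presence = presence)
essential_elements(res, ctx, "s1")
#> # A tibble: 3 × 5
#>   sample element kind     essential witness
#>   <chr>  <chr>   <chr>    <lgl>     <list>
#> 1 s1     M1      nutrient TRUE      <list [1]>
#> 2 s1     g1      gene     TRUE      <list [1]>
#> 3 s1     g3      gene     TRUE      <list [1]>
```

With `M2` absent and `g2` silent, `g1` is essential (witness
`{M2, g1, g2}`), `g3` is essential (witness `{M2, g3}`), and `M1` is an
essential nutrient (witness `{M1, M2}`).

A command-line front end (`inst/scripts/ngmcs`) wraps the same
functions: `ngmcs compute`, `ngmcs essentiality`, `ngmcs fixtures`, and
`ngmcs reproduce` (pinned configurations for user-supplied genome-scale
models; nothing is downloaded or bundled).

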