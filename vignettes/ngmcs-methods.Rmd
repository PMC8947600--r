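---
title: "Methods: enumerating nutrient-genetic minimal cut sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enumerating nutrient-genetic minimal cut sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngmcs)
```

## The model and its conventions

A constraint-based metabolic model is a stoichiometric matrix `S`
(metabolites × reactions), flux bounds `lb ≤ v ≤ ub`, a boolean
gene–protein–reaction (GPR) rule per reaction, and a designated biomass
reaction whose maximal steady-state flux (`max v_biomass` subject to
`S v = 0` and the bounds) proxies proliferative capacity. Conventions
used throughout:

* **Exchanges are written as exports** (`metabolite → ∅`); uptake is
  negative flux, and closing a nutrient's import means raising the
  exchange's lower bound to 0. The export direction is never touched,
  so secretion stays possible. Models written the other way round are
  handled by detecting the import direction per exchange.
* **Unbounded flux is encoded as ±1000 mmol·gDW⁻¹·h⁻¹**, the
  conventional big bound. Medium concentrations in mM are used directly
  as uptake bounds. The toy fixtures use 10 mmol·gDW⁻¹·h⁻¹ per
  nutrient, a round value in the millimolar range typical of defined
  media; for blocking questions only the open/closed distinction
  matters, not the magnitude.
* **A reaction with no gene association has GPR = TRUE** and can never
  be disabled by a gene knockout; if it is an input exchange it can
  still be cut through its nutrient row.
* **A task counts as blocked when its LP maximum falls below
  ε = 1e-6** (configurable). The tolerance separates solver noise from
  genuine leak fluxes at the 1000-bound scale.

Reversible reactions are split into forward/backward copies with
swapped stoichiometry and the same GPR before the duality construction,
so that a knockout removes both directions; flux optima are preserved
exactly (property-tested on random models).

## GPR semantics and the G matrix

AND joins complex subunits (losing any one disables the reaction), OR
joins isozymes (all must be lost); rules are monotone, so the *minimal
falsifying gene sets* of a rule are well defined — they are the prime
implicants of the negated rule. They are computed by structural
recursion: an AND is falsified by falsifying any argument (union of the
children's families), an OR by falsifying all arguments
(cross-product), with subset pruning after every step. Exhaustive
truth-table enumeration is kept in the package as an independent
cross-check (`falsifying_sets_exhaustive()`), and the two agree on
hundreds of random rules in the test suite. A combinatorial guard
(default 10,000 sets) aborts pathological rules with a clear error
instead of exhausting memory.

The **G matrix** collects one row per distinct minimal gene set, with
support equal to *every* reaction that set disables (recomputed by
direct GPR evaluation after merging, so the incidence invariant —
entry (i, j) = 1 iff knocking row i disables reaction j — holds by
construction). A row is pruned only when another row has a member
subset *and* a support superset; anything weaker could remove genuine
cut sets from the search space, so dominance must be total. An optional
`scope` restricts rows to a predefined gene list, which is how focused
searches (all partners of one gene of interest) are run.

Nutrient deprivations enter as artificial knockout units: one row per
open input exchange in the medium, with that exchange as its only
support. After this extension the same search returns gene-only cut
sets (gMCSs) and mixed or nutrient-only ones (ngMCSs) in one pass.

## The duality MILP

For the irreversible model, biomass is blocked exactly when
`{S v = 0, v ≥ 0, v_target ≥ 1}` is infeasible, certified via Farkas'
lemma by a dual vector `u` with

* `(Sᵀu)_j ≥ 0` for every reaction `j` that can still carry flux,
* `(Sᵀu)_target ≥ 1`.

(The mirrored orientation — all signs negated, target `≤ −1` — is the
same certificate; this package uses the `≥` form consistently.)
Reactions with no forward capacity under the applied medium impose no
dual constraint. Selecting G row `i` (binary `z_i`) adds
`big_M · Σ_i G[i,j] z_i` to reaction `j`'s constraint, relaxing it when
covered; `big_M` defaults to 1000.

Two further choices shape the enumeration:

* **The objective counts elements, not rows.** Gene indicator
  variables `y_g ≥ z_i` (for every row containing `g`) are minimised
  together with the nutrient-row binaries, so the reported size is the
  number of distinct genes plus nutrients. Minimising selected rows
  instead can return a three-gene single-row solution before a
  two-gene two-row one, breaking size-ordered enumeration.
* **Integer cuts are element-level.** After a solution with element
  set `E`, the constraint `Σ_{g∈E} y_g + Σ_{n∈E} z_n ≤ |E| − 1`
  excludes `E` and every superset — exactly the antichain semantics of
  minimal cut sets. Candidates that fail LP verification (possible
  under time limits or big-M artifacts) are excluded by a row-level
  cut on that exact selection only, which cannot discard genuine
  solutions, and the search is re-posed.

The MILP is solved by depth-first branch and bound on the `z` binaries
over an exact two-phase simplex with Bland's rule; both are implemented
in the package and sized for the dense, small systems this produces
(tens of variables). The solver is deterministic, so enumeration
output is reproducible; element and family orderings are canonicalised
(byte-order sorts) to be locale-independent. A per-solution wall-clock
limit (default 60 s) returns the incumbent when the search is cut
short; an incumbent is accepted only if it passes verification.

**Verification policy.** Every candidate is re-checked against the
primal model: one LP with all covered reactions knocked must leave the
target below ε (`verified_cut`), and one LP per element must restore it
(`verified_minimal`). Non-minimal candidates are flagged and excluded,
never silently shrunk. This keeps the reported list clean regardless of
big-M artifacts or time-limit truncation.

**The exhaustive oracle.** `brute_force_cutsets()` enumerates element
sets arising from all subsets of G rows in order of increasing
cardinality with LP blocking tests through direct GPR evaluation — a
route that shares no code with the duality encoding. It is exponential
in the row count (guarded at 20 rows) and exists as ground truth: the
acceptance suite asserts exact agreement with the MILP enumeration on
50 seeded random networks.

## Fixtures

`toy_network()` builds the didactic two-medium example: nutrient `M1`
feeds growth precursor `C` through two redundant branches (`r1`/`r3`
gated by `g1`/`g3` and `r2`/`r4` gated by `g2`/`g3`); the second medium
adds nutrient `M2` with a *gene-less* salvage route `r5`. The drawing
this reconstructs fixes the species counts and the lethality facts but
not the coefficients, so all coefficients are 1 — the smallest network
consistent with every stated fact. `r5` carries no gene precisely so
that no purely genetic cut set exists under the richer medium; the
wiring is isolated in one function so it can be swapped if the example
is ever read differently. Whether nutrient-only sets (like `{M1}`
under the first medium) are listed alongside mixed ones is a
presentation choice; the enumeration returns them and flags them by
classification.

`random_network()` generates property-test inputs: 2 nutrients with
input exchanges, 3 branching pathways of up to 3 reactions converging
on one precursor, GPRs drawn from a shared 6-gene pool (≤ 3 genes per
rule, 15% gene-less, 15% reversible), uptake 10 mmol·gDW⁻¹·h⁻¹, and at
most 12 knockout units in total so the exhaustive oracle stays instant.
Generation is deterministic per seed, regenerates on the rare
non-growing draw, and restores the caller's RNG state. These networks
emulate the *structural* features that make cut sets non-trivial —
redundant routes, shared genes across pathways, gene-less rescues —
but not the scale, flux coupling, or GPR depth of genome-scale
reconstructions; passing tests show correctness of the algorithms, not
performance at genome scale.

## The context-essentiality rule

Cut sets are structural; expression contextualises them. A gene is
*inactive* in a sample when its TPM is below the threshold (default
1 TPM, a conservative floor for "not expressed" in RNA-seq
quantifications); a nutrient is inactive when absent from the (global
or per-sample) medium. **A gene or nutrient is essential for a sample
iff it is the only active element of at least one cut set**, and those
witnessing cut sets are attached to every call. Applied across samples
to the nutrient elements this yields the binary auxotrophy matrix.

Choices worth knowing:

* **Genes absent from the expression matrix count as active.** This is
  the conservative direction — it can only suppress essentiality
  calls, never fabricate them; `unmeasured_genes()` reports them.
* **The "most limiting gene" of a nutrient** takes, within each cut
  set containing the nutrient, the best-expressed partner gene (the
  strongest genetic backup of that route), and across cut sets the
  maximum of those values (the strongest backup overall). A sample is
  auxotrophic when even that value sits below the threshold. A cut set
  with no gene partners contributes 0 — the nutrient has no genetic
  backup there. This aggregation is an inference from the auxotrophy
  definition rather than a uniquely forced choice; it is the one under
  which "limiting value < threshold" coincides with the essentiality
  rule.
* **Threshold monotonicity holds for nutrient calls**: raising the
  threshold silences more genes, so nutrient dependencies can only
  grow. Gene calls are *not* globally monotone — a threshold high
  enough to silence the witness gene itself removes its call, since an
  inactive element is never called essential. The tests assert the
  sound forms of both statements.
* **Regulatory couplings** that GPRs do not carry (a knockout whose
  metabolite accumulation shuts down further enzymes) are modelled
  either by `apply_linked_knockouts()` — knock the gene and its linked
  reactions up front — or by `link_gene_reactions()`, which ANDs the
  gene into the linked reactions' GPRs so the coupling is visible to
  the search, the verification LPs and the oracle alike.

## Numerical choices and degenerate inputs

* LP pivot tolerance 1e-9; blocked-flux ε 1e-6; MILP integrality
  tolerance 1e-6. With integral objectives the branch-and-bound bound
  is tightened to the ceiling of the relaxation.
* A wild type that does not grow yields an empty enumeration with a
  warning (the empty set already "cuts" biomass — there is nothing to
  enumerate).
* Ties among equal-size cut sets are broken by the deterministic
  solver; outputs are then sorted by size and byte-order key, so
  comparisons are stable as set families.
* `max_solutions = 0` returns an empty table; a size cap restricts the
  element count, not the row count.

## Problem sizes and limitations

The bundled analyses and tests run on networks of ≤ ~15 reactions and
≤ 12 knockout units (50 random networks in the oracle-equivalence
campaign, 200 random GPR rules in the truth-table campaign) — sizes at
which every quantity can be verified against an exhaustive, independent
route within seconds. The built-in simplex/branch-and-bound solver is
written for this dense, desk-scale regime; genome-scale reconstructions
(thousands of reactions) are supported structurally by every interface,
but enumeration there would want a large-scale MILP back end and the
time-limit heuristics exposed in `engine_options()`. No thermodynamic
or loopless constraints, no flux-variability analysis, and no automatic
biomass construction are attempted.
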