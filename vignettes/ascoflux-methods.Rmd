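---
title: "Methods: constraint-based overexpression-target prediction with ascoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based overexpression-target prediction with ascoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascoflux)
```

# The problem

Ascomycin (FK520) is a 23-membered polyketide macrolide made by
*Streptomyces hygroscopicus* var. *ascomyceticus*.  Its chain extension
consumes unusual extender units — ethylmalonyl-CoA and
methylmalonyl-CoA — so production titre is often limited by precursor
supply rather than by the synthase itself.  Given a genome-scale
metabolic reconstruction of the producer, `ascoflux` asks: *which single
enzyme, if overexpressed, would redirect flux toward the product with
the least collateral damage to growth?*

The package implements the standard constraint-based answer to that
question, end to end:

1. **Model derivation** (`apply_edit_script()`, `remove_subsystems()`,
   `complete_emc_pathway()`): a product-specific model is derived from a
   base reconstruction by removing irrelevant secondary-metabolite
   clusters, adding the product-synthesis reactions, and applying a
   small set of curated bound constraints.
2. **Wild-type reference** (`fba()`, `reference_flux()`): flux balance
   analysis maximizes the biomass flux subject to the steady-state
   constraint $S v = 0$ and the flux bounds; a deterministic
   parsimonious refinement picks one reference vector $v^{\mathrm{wild}}$
   out of the (generally degenerate) optimal set.
3. **Perturbation** (`moma()`): overexpression of reaction $j$ is
   simulated by forcing $v_j = k\,v_j^{\mathrm{wild}}$ and re-solving by
   minimization of metabolic adjustment — the quadratic program
   $\min \sum_i (v_i - v_i^{\mathrm{wild}})^2$ over the feasible set of
   the perturbed network.  MOMA models the short-term response of a cell
   whose regulation has not yet re-optimized for the perturbation.
4. **Scoring and ranking** (`scan_targets()`, `compute_fph()`): each
   perturbed solution is scored by
   $$f_{\mathrm{PH}} \;=\; f_{\mathrm{biomass}} \times f_{\mathrm{ascomycin}}
   \;=\; \frac{v_{\mathrm{biomass}}^{\mathrm{over}}}{v_{\mathrm{biomass}}^{\mathrm{wild}}}
   \cdot \frac{v_{\mathrm{product}}^{\mathrm{over}}}{v_{\mathrm{product}}^{\mathrm{wild}}},$$
   the product of the growth ratio and the production ratio.  A target
   with $f_{\mathrm{PH}} > 1$ improves the growth–production trade-off;
   candidates are ranked by decreasing $f_{\mathrm{PH}}$.

A companion analysis (`parse_hits()` → `best_hit_per_query()` →
`call_conservation()` → `summarize_conservation()`,
`classify_nonhomologs()`) quantifies how conserved the base model's
enzymes are across related strains, which is what justifies porting a
reference reconstruction to a close relative in the first place.

# Assumptions

* **Steady state.**  All solvers operate on $\{v : S v = 0,\;
  lb \le v \le ub\}$.  Units are mmol·gDCW⁻¹·h⁻¹ throughout (the
  biomass flux is in h⁻¹).  Note that some published tables label these
  rates "mM/g DCW/h"; a molar concentration per biomass per time is
  dimensionally a molar amount per biomass per time, and all values are
  used as rates, so the package standardizes on the usual
  mmol·gDCW⁻¹·h⁻¹ convention.
* **The wild type grows optimally.**  FBA's biomass maximization is the
  usual proxy for an evolved production host growing on a defined
  medium.
* **A positive product baseline.**  $f_{\mathrm{PH}}$ divides by the
  wild-type product flux, and pure growth maximization would set it to
  zero.  The reference is therefore computed with the product reaction's
  lower bound at a small baseline rate (the curated toy bakes in
  5e-4 mmol·gDCW⁻¹·h⁻¹, the same order as a measured basal synthesis
  rate); during the perturbation the product flux is free above that
  bound.
* **Overexpression forces flux.**  The default perturbation is the
  equality $v_j = k\,v_j^{\mathrm{wild}}$ — the strictest reading of
  "the enzyme now carries $k$-fold flux", and the one that makes the QP
  well-posed.  `mode = "min"` instead only raises the bound in the
  carried direction, the laxer reading; on the bundled toy both modes
  agree on which targets are beneficial.  Reverse fluxes are amplified
  in their carried direction ($-0.3 \to -0.6$).

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 2 | amplification factor; published flux-amplification scans rarely state it, and 2 ("doubling the enzyme") is the conventional middle of the 1.5–3 range.  `scan_targets()` accepts any `k >= 1`, and a sweep over `c(1.5, 2, 3)` is a one-liner; on the bundled toy the ranking's order is insensitive to `k` in that range. |
| `zero_tol` | 1e-9 | a reference flux with `abs(v) <= zero_tol` is "not carried" and skipped; amplifying an exact zero is a no-op. |
| `threshold` (`count_targets()`) | 1 | "potential target" cutoff: better than wild type.  Any other reading of "higher is better" can be substituted. |
| `exclude_subsystems`, `exclude_reactions` | empty | scan exclusions.  Typical choices: exchange pseudo-reactions, inorganic ion transport, nucleotide salvage, ATP maintenance — steps that are not realistic enzyme-overexpression targets.  Exclusions are explicit lists, never pattern matches, so a scan's scope is auditable. |
| conservation thresholds | 40 % identity, 50 % coverage, e < 1e-5 | the standard reciprocal-annotation working point.  Identity and coverage are inclusive (`>=`), the e-value strict (`<`): only the e-value comparator is conventionally printed as a strict inequality, and `>=` is the natural reading of "a threshold of 40 %".  Coverage is `alignment_length / query_length`, the only coverage measure computable from 12-column tabular alignment output (gaps included). |

# Numerical design

**LP.**  No linear-programming backend is available in the package's
dependency footprint, so `ascoflux` ships a dense two-phase
bounded-variable primal simplex (Bland's smallest-index rule, hence
finite termination; fresh dense factorization per pivot).  This is
entirely adequate for the desk-scale networks the package targets —
tens of reactions — and is validated against a vertex-enumeration
brute-force oracle on randomly generated networks in the test suite.
Feasibility tolerances: 1e-6 on $\|S v\|_\infty$, 1e-9 on bounds;
phase-I infeasibility cutoff 1e-7.

**QP.**  MOMA is solved with the Goldfarb–Idnani dual active-set method
(`quadprog`), after eliminating the equality constraints: an SVD of the
equality matrix yields a particular solution anchored at the
unconstrained minimizer plus an orthonormal null-space basis, and the
box-constrained QP is solved in the reduced coordinates.  Working in
the null space keeps every iterate exactly on the steady-state subspace
(no post-hoc re-projection needed) and avoids the spurious
"constraints are inconsistent" failures the dual method exhibits when
degenerate equalities or exactly-opposed inequality pairs are passed
through directly.  Variables pinned by `lb == ub` become equality rows
for the same reason.  Infeasible perturbations are *signalled*
(`status = "infeasible"`), never raised, so a scan can skip them.

**Degenerate FBA optima.**  MOMA needs one reference vector, but FBA
optima are typically a face, not a point.  `reference_flux()` resolves
this in three deterministic stages: (i) the FBA optimum $z^\*$;
(ii) minimum total absolute flux (the parsimonious criterion) subject
to the objective fixed at $z^\*$, via the split-variable LP; (iii) the
unique minimum-Euclidean-norm point of the *entire* L1-optimal set,
found as a strictly convex QP in the split variables with
$\sum(p+q)$ held at the stage-(ii) minimum (ridge 1e-9 for positive
definiteness).  Stage (iii) is the tie-break: two parallel identical
pathways receive equal shares of their combined flux, and repeated runs
are bit-identical.  No randomness exists anywhere in the solve path.

**Ties in the ranking.**  Rows are ordered by $f_{\mathrm{PH}}$
descending, then reaction id ascending, so serialized rankings are
byte-stable.

**Degenerate inputs.**  Duplicate ids, bound inversions
(`lb > ub`), references that do not cover the model, and edits naming
unknown reactions are all rejected with messages naming the offender.
`validate_model()` is report-only: orphan metabolites, bound
violations, and (when formulas are present) elemental imbalances, with
exchange/demand/sink/biomass pseudo-reactions exempt from the element
check.

# What the synthetic generators emulate — and what they do not

`make_core_ascomycin_toy()` is a fixed ~21-reaction network carrying
exactly the features the pipeline exercises: glucose uptake; a lumped
glycolysis to acetyl-CoA; an NAD/NADH couple closed by a respiration
step; the ethylmalonyl-CoA chain `ACACT1r → HACD1 → ECOAH1 → CCCR`; a
methylmalonyl-CoA route (`SUCS`, `MMM`, `MME`); a condensation step
(`ASCS`) draining both extender pools plus acetyl-CoA into the product;
a biomass equation competing for acetyl-CoA and NADH; and an obligatory
overflow drain (`DRAIN`, lower bound 0.05 mmol·gDCW⁻¹·h⁻¹) that stands
in for the by-product secretion every real fermentation shows.  All
non-boundary reactions balance under pseudo-element formulas, so the
element check is exact.  On this fixture the scan reproduces the
qualitative finding that motivates the method: the four
ethylmalonyl-CoA steps score $f_{\mathrm{PH}} \approx 2 > 1$ at
$k = 2$ and outrank the drain ($f_{\mathrm{PH}} < 1$).

`make_toy_model()` generates parameterized branched networks with known
closed-form FBA optima (`uptake * max(branch_yields)`), and
`random_toy_model()` draws random small stoichiometries with finite
bounds containing zero — bounded, usually-feasible polytopes on which
brute-force oracles are tractable.  `make_hit_table()` plants a
per-strain conserved fraction exactly: passing hits sit far inside all
three thresholds (identity 80, full-length alignment, e = 1e-50) and
decoys fail all three simultaneously (identity 30, coverage 0.3,
e = 1e-3), so boundary semantics can never blur the planted truth, and
`planted_fraction * n_queries` must be an integer so recovery is exact
rather than approximate.

What passing on these fixtures does **not** show: genome-scale
performance (the dense simplex and the 3ⁿ-pattern oracles do not scale
to thousands of reactions), the realism of any particular bound
(uptake rates are scenario inputs), regulatory or kinetic effects
(MOMA is a purely stoichiometric response model), or the biological
correctness of a real reconstruction's stoichiometry.  Predictions on a
real model inherit all of that model's curation debt.

# Problem sizes used in validation

The test suite and the acceptance script validate on: 50 random
networks of 3–6 reactions against the LP vertex-enumeration oracle; 50
random perturbed instances against the QP active-set oracle (both
oracles enumerate all 3ⁿ bound patterns, which is why instances stay
small); the 21-reaction curated toy for the scan properties; 200-query
planted hit tables for the conservation pipeline; and a 1166-query
fixture for the non-homolog classification arithmetic
(146 non-conserved, of which 95 isozyme-rescued and 15
annotation-similar, leaving 36 absent).  Everything runs in seconds.

# Known limitations

* The simplex and the dense SVD are O(n³)-per-step; the package is
  deliberately a desk-scale reference implementation, not a
  genome-scale production solver.  Swapping in an industrial LP/QP
  backend behind `fba()`/`moma()` would not change any interface.
* Gene–protein–reaction boolean logic is out of scope: targets are
  reactions, and the gene lists attached to reactions are annotations
  only.
* The conservation analysis consumes alignment output; it never runs
  the aligner, downloads proteomes, or filters plasmids.
* `classify_nonhomologs()`'s isozyme rescue is reaction-membership
  based, not synteny-based, and "similar annotation" is an externally
  curated input flag, not computed text similarity.
* SBML support covers Level 3 + FBC bounds, ids, names, formulas and
  subsystem/gene notes — not the full annotation model.

# A worked desk-scale run

```{r example}
m <- make_core_ascomycin_toy()
ref <- reference_flux(m)
ref$objective_value          # wild-type specific growth rate, 1/h

rk <- scan_targets(m, ref, k = 2, exclude_subsystems = "exchange")
head(as.data.frame(rk), 8)

count_targets(rk, threshold = 1)[c("n_total", "n_primary", "n_secondary")]
```

The four ethylmalonyl-CoA steps (and everything upstream of the
extender-unit supply) come out on top with
$f_{\mathrm{PH}} \approx 2$: doubling their flux doubles production
while costing about 0.1 % of growth.  The obligatory drain scores below
1 — amplifying it wastes precursor.  That separation, not the absolute
scores, is the method's deliverable.
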