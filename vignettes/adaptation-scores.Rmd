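---
title: "Adaptation scores: coupling gene expression to metabolic flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptation scores: coupling gene expression to metabolic flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriscore)
```

## The question the method answers

Adaptive laboratory evolution (ALE) produces pairs of strains — a wild
type and its evolved descendants — whose transcriptomes differ in
hundreds of genes. Most of those expression changes are noise or
side-effects; only a few reflect a genuine rewiring of how the cell uses
its metabolism. This package asks a constraint-based question: *how many
of the measured metabolic genes could convert their entire expression
into steady-state flux, and which genes change status between wild type
and evolved strains?*

## The model

Start from ordinary flux balance analysis over a genome-scale metabolic
model: steady state $S v = b$ (here $b = 0$) with flux bounds
$v_{min} \le v \le v_{max}$. The model is first converted to its
irreversible, without-OR form: every reversible reaction is split into a
forward and a backward column, and every OR in a gene–protein–reaction
rule (an isozyme alternative) becomes a separate copy of the reaction
carrying a single AND conjunct. After conversion, gene $j$ supports the
set $K_j$ of converted reaction columns.

For each measured gene the expression-usage constraint couples
transcript level to flux capacity:

$$\sum_{i \in K_j} v_i + \alpha_j = E_j \, C, \qquad \alpha_j \ge 0,$$

where $E_j$ is the expression level on whatever scale the platform
provides, $C$ (mmol gDCW$^{-1}$ h$^{-1}$ per expression unit) converts
expression to flux capacity, and the slack $\alpha_j$ is the portion of
gene $j$'s capacity *not* realized as flux. A gene with $\alpha_j = 0$
is fully used. A binary indicator $z_j$ with the big-M row
$\alpha_j - U_j z_j \le 0$ classifies genes: $z_j = 0$ forces
$\alpha_j = 0$. Minimizing $\sum_j z_j$ and subtracting from $P$, the
number of mapped measured genes, gives the **adaptation score**

$$\text{score} = P - \min \sum_{j=1}^{P} z_j,$$

the maximum number of genes whose expression the flux distribution can
honour exactly.

Left alone, the minimization would cheat by running reversible
reactions in both directions at once, inflating $\sum_{i \in K_j} v_i$
through futile cycles. Per reversible source reaction a pair of binaries
$w_f, w_b$ with

$$v_{i,f} - U w_f \le 0, \quad v_{i,b} - U w_b \le 0, \quad w_f + w_b = 1$$

forbids simultaneous use of the two directions. Because isozyme
expansion creates several copies per direction, the rows are written for
*every* forward copy against *all* backward copies of the same source
reaction — one $(w_f, w_b)$ pair per source reaction, shared by all its
copies, which blocks every cycle among the copies at once.

### Scoring conditions

* **Unlimited condition.** Exchange reactions for the carbon source and
  the minimal-medium components are open for uptake at
  1000 mmol gDCW$^{-1}$ h$^{-1}$; all other uptakes are closed; every
  secretion is open. No growth or measured rate is imposed: the score
  reflects the program the expression pattern *could* run, not the one
  observed.
* **Conditional score.** To ask how compatible an expression profile is
  with maximal use of a reaction or gene, the target's usage (the summed
  flux of its converted columns, or of $K_j$ for a gene) is first
  maximized over the continuous relaxation with direction exclusivity
  enforced, then fixed at that optimum — as an equality within
  tolerance, not a lower bound — and the score is recomputed. Adding a
  constraint can only raise $\min \sum z$, so a conditional score never
  exceeds the unconditional one.

### Key-gene identification

Reprogramming candidates are selected by two factors: (1) the gene is
fully used by the wild type under the unlimited condition, and (2) the
absolute difference between wild-type expression and the mean over the
evolved strains is large. The table reports, per candidate, whether the
wild-type level is the extreme (minimum or maximum) across all strains —
a genuine origin of reprogramming should have the wild type
differentiated, not sitting inside the evolved range. Conditional scores
for each candidate, correlated against measured growth phenotypes,
complete the evidence.

## Design choices where the formulation was open

* **$b = 0$.** The right-hand side of the steady-state system is in
  principle set by known fluxes, but the unlimited condition uses no
  measured rates, so a pure steady state is the only consistent choice.
  Maintenance constraints present in a source model (nonzero lower
  bounds) are preserved as-is.
* **Per-gene big-M.** Since $v \ge 0$ and the usage equality holds,
  $\alpha_j \le E_j C$ always; $U_j = E_j C$ is therefore the tightest
  valid constant. Tight big-Ms avoid the numerical "z-cheating" that
  loose ones permit and measurably help the branch-and-bound. The
  exclusivity rows use $U = 1000$, the model-wide flux cap.
* **AND conjuncts are not split.** A reaction copy's flux enters the
  usage constraint of every gene in its conjunct, so any member of a
  complex can limit the reaction. OR is eliminated by
  disjunctive-normal-form expansion with a configurable cap (default 32
  disjuncts per reaction); rules deeper than the cap abort loudly rather
  than silently truncating.
* **Witness versus set.** The optimal *score* is unique, but the optimal
  usage pattern rarely is. Solvers return one witness; the reproducible
  set-level answer is the *optimality-preserving set*
  (`full_usage_gene_set()`): every gene $j$ such that forcing $z_j = 0$
  keeps the score optimal. Key-gene selection uses this set by default;
  a flag (`use_witness_sets`) switches to the witness to mimic
  single-solver behaviour.
* **Degenerate genes.** A gene with $E_j C$ below the feasibility
  tolerance keeps its constraint (with a logged warning); its slack is
  pinned to zero, so it counts as trivially fully used — consistent with
  the limit $C \to 0$, where the score is exactly $P$.
* **Zero tolerance.** "$\alpha_j = 0$" means
  $\alpha_j \le 10^{-6}$ mmol gDCW$^{-1}$ h$^{-1}$, matched to the
  solver feasibility and integrality tolerances ($10^{-6}$); the three
  move together through `mri_tolerances()`. Conditional targets are
  fixed within a $10^{-6}$ relative band.
* **Expression scale.** Values are consumed as provided (log-scale
  microarray intensities in the motivating datasets); no log/linear
  conversion is applied because $C$ absorbs the scale. The score is
  exactly invariant under $E \mapsto kE$, $C \mapsto C/k$, which the
  test suite asserts.

## Calibrating C

$C$ is the single free parameter. It is fitted per carbon source by
sensitivity analysis: predict growth for every strain by maximizing
biomass flux under the medium bounds, the usage caps
($\sum_{K_j} v_i \le E_j C$) and direction exclusivity, evaluate the
mean relative error against measured growth rates over a grid of $C$
values, and take the minimizer. Predicted growth is non-decreasing in
$C$ (relaxing caps can only help), so the error curve is well behaved
around the crossing point. The default grid is 30 log-spaced values
spanning four decades around (maximum flux bound)/(median total
expression), a scale-free window; `calibrate_C()` accepts any explicit
grid. Growth prediction deliberately shares the direction-exclusivity
machinery with scoring so both analyses explore the same flux space.

## What the synthetic fixtures do and do not show

`random_toy_spec()` generates small networks — an uptake exchange, a
chain of 2–4 internal metabolites with one gene per step, at least one
reversible step, optionally a parallel branch, an isozyme (OR) rule and
a complex (AND) rule, 3–6 genes in total — with wild-type expression
drawn uniformly between 1 and 10. These exercise every structural
feature the MILP must handle, and they are small enough
($\le 8$ genes, $\le 14$ converted reactions) that an exhaustive oracle
can enumerate all $2^P$ usage patterns, deciding each by LP feasibility
with reversible orientations enumerated, through a solver route
(quadprog's dual QP method) entirely independent of the MILP backend
(HiGHS). The validation study runs 70 fixtures at three $C$ values
(0.5, 1, 5) — 210 instances — plus conditional-score monotonicity over
every gene and reaction target of each fixture.

What passing these tests shows: the MILP formulation, the conversion
machinery and the solver bridge are correct on networks with the full
range of structural motifs. What it does not show: performance or
numerical behaviour at genome scale (thousands of reactions, big-M
interactions at the $10^3$ flux cap), biological realism of expression
noise, or anything about mapping probe identifiers to model genes —
real microarray data need a symbol-to-locus-tag mapping supplied by the
user.

```{r toy, eval = FALSE}
model <- make_toy_model("toy1")
conv <- apply_medium(convert_model(model), toy_medium())
wt <- expression_profile("WT", c(g1 = 2, g2 = 4, g3 = 5))
prob <- build_mri_problem(conv, wt, C = 1)
solve_adaptation_score(prob)       # score 2 of P = 3
full_usage_gene_set(prob)          # g1, g2, g3: each fully used in some optimum
conditional_adaptation_score(prob, "R3")  # target max 5, score 2
```

## Known limitations

* Direction exclusivity covers opposite-direction copies of the same
  source reaction only; it is not a general loopless-flux constraint.
  Cycles through *distinct* reactions can still carry flux if the
  network admits them.
* Alternate optima are intrinsic: witness gene sets differ between
  solvers and runs even at a fixed score. Set-level statements should
  use `full_usage_gene_set()`.
* The MILP backend runs HiGHS through Python's scipy; a Python
  interpreter with scipy must be on the PATH. The reported score is
  solver-independent (a proven optimum with zero MIP gap); only the
  witness may vary.
* The exhaustive oracle is exponential in the gene count and refuses
  more than 12 genes.
* At genome scale the full-usage set requires one MILP per candidate
  gene; plan accordingly or use the witness.
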