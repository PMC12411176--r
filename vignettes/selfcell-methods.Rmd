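---
title: "Methods: from flux balance analysis to self-contained growth models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from flux balance analysis to self-contained growth models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfcell)
```

## Scope and units

`selfcell` implements a ladder of steady-state cell models on small,
fully auditable networks. One unit convention holds everywhere: fluxes
in mmol/gDW/h, intracellular concentrations in mmol/gDW, molecular
weights in g/mol, Gibbs energies in kJ/mol, growth rates in 1/h. The
single place where grams meet millimoles is the growth rate
$\mu = w^\top N r / 1000$, and that factor of 1000 is applied only
there and in mass-fraction conversions.

## The mass-balance backbone

A network is a dense stoichiometric matrix $N$ ($l$ compounds $\times$
$q$ reactions, substrates negative). The concentration balance of
compound $j$ is
$\dot c_j = \sum_i \gamma_{ji} r_i - \mu c_j$,
where the dilution term $\mu c_j$ reflects that every cell division
doubles the biomass. Flux analysis works at quasi-steady state and, for
metabolites, drops the dilution term because it is orders of magnitude
below the turnover (`dilutionRatio()` makes the argument quantitative:
a 6 mmol/gDW/h uptake against $\mu c = 0.5 \times 0.03$ gives a factor
of 400). Macromolecular units, in contrast, are *only* diluted, so for
them $r_{syn,j} = \mu B_j$ is exact — this asymmetry is what the later
sections exploit.

Mass conservation of a single reaction column $n$ is $w^\top n = 0$.
`auditMassConservation()` reports the residual of every column;
exchange columns legitimately carry the mass swapped with the
environment (their external partner is not a matrix row), and columns
flagged `massLoss` model an implicit excreted by-product (the toy
network's `r6`, 2A $\to$ D, loses 100 g/mol that way). Only internal,
unflagged, non-biomass columns can be *violations*.

## The toy fixtures

The fixture networks are constructed, not loaded: `toyNetwork()` is the
4×7 matrix over A–D with one input, an internal cycle (`r2`,`r3`,`r4`)
and two exports; `internalNetwork()` is its 4×4 internal block, whose
one-dimensional kernel $(0,-1,-2,1)$ *is* the cycle;
`unitNetwork()` adds macromolecular units in three variants. Molecular
weights (150, 100, 100, 200 g/mol) are fixed as the exact ratios of the
biomass composition on the gram basis (0.35/0.15/0.3/0.2 g/g) to its
molar coefficients — e.g. $0.35/(7/3000) = 150$ — rather than the
rounded $2.33\cdot10^{-3}$.

`randomConservativeNetwork()` supports the property tests: weights are
sampled positive and the last coefficient of every column is solved
from the others, so $w^\top N = 0$ holds to machine precision by
construction. It emulates exactly one feature of real stoichiometry —
elementwise mass closure — and none of the biological structure
(no compartments, no cofactor pairing, no realistic degree
distribution), so a passing property test certifies the linear algebra,
not biological realism.

## Linear programming

All LP-based operations run on an in-package two-phase dense simplex
(Bland's anti-cycling rule as fallback behind Dantzig pricing,
largest-pivot ratio tie-breaking, periodic refactorisation from the
original matrix to cancel pivot drift, row/column equilibration for
badly scaled inputs such as $k_{cat} \sim 10^6$ against enzyme levels
$\sim 10^{-7}$). Problem sizes here are tens of variables, where a
dense tableau is the robust choice. Default flux bounds where a model
gives none are $\pm1000$ mmol/gDW/h for reversible and $[0, 1000]$ for
irreversible reactions.

Degenerate optima are real in these networks (the cycle makes the
export optimum non-unique), so `solveFBA()` tie-breaks by a secondary
minimization of $\sum_i |r_i|$ at the fixed optimal objective and flags
the solution `degenerate` when that step changed the flux map. Pareto
fronts use the ε-constraint method (objective 2 capped on a grid of 20
points by default between the two single-objective optima) rather than
weighted sums, so vertical segments of the front are captured.

## Thermodynamic constraints

For internal reactions, $\Delta G = \Delta G^{0\prime} + RT\, N'^\top x$
with $x = \ln c$, and any running reaction satisfies
$\Delta G_i\, r_i < 0$. The default $RT = 2.4945$ kJ/mol uses
$R = 8.315$ J/mol/K at $T = 300$ K (temperature configurable; standard
condition tables are at 298 K). Within a cycle basis $K$ of the
internal matrix, standard energies are not independent:
$K^\top \Delta G^{0\prime} = 0$, equivalently a multiplicative
equilibrium-constant identity along each cycle
($K_{eq,2} K_{eq,3}^2 = K_{eq,4}$ for the toy cycle). All fixture
parameterisations respect it.

Four mechanisms restrict flux maps:

1. **Loopless FBA** couples each internal direction to the sign of its
   Gibbs energy through a binary $z_i$ ($z_i = 1$: $r_i \ge 0$,
   $\Delta G_i \in [-M, -\varepsilon]$; $z_i = 0$: mirrored) and
   enforces $K^\top \Delta G = 0$. Defaults $\varepsilon = 0.1$ kJ/mol
   and $M = 10^4$ kJ/mol; both are configuration, not physics. The
   mixed-integer program is solved *exactly* by enumerating the $2^n$
   assignments of the $n \le 12$ internal reactions with one LP each —
   at these sizes enumeration is both simple and certifiably optimal. A
   secondary LP then shrinks $\sum_i |\Delta G_i|$ at the pinned
   objective so reported energies do not sit at the artificial big-M
   vertex. Reactions with zero flux inside a cycle are a known blind
   spot of the big-M form (their $\Delta G$ cannot be zero); the
   package therefore re-verifies solutions post hoc with the
   concentration LP below instead of relying on the MILP's claim.
2. **The sign test** $|s_c^\top s_f| < s_c^\top s_c$ needs only signs:
   equality means the flux pattern runs around the cycle. It is both an
   operation (`signLoopTest()`) and the certificate the package attaches
   when a concentration system is infeasible.
3. **Concentration coupling** (`tfbaWithConcentrations()`) takes the
   *direction pattern* of a prior flux map — directions, not
   magnitudes, are what thermodynamics constrains — re-solves the flux
   LP under those directions, and finds a witness $x$ with
   $\mathrm{sign}(r_i)\,\Delta G_i \le -\varepsilon$ within
   concentration bounds. The witness is a plain feasible point, not an
   optimized one, so the MDF comparison below is meaningful.
   Default concentration bounds are $[10^{-6}, 0.1]$ mmol/gDW; exact
   bounds belong to run configuration.
4. **Max-min driving force** (`mdf()`) maximizes the smallest
   $-\mathrm{sign}(r_i)\Delta G_i$ over the running reactions. A
   pattern whose best achievable minimum force is non-positive (any
   in-cycle pattern) is reported infeasible together with the violated
   cycles.

## Enzyme constraints

`capacityFBA()` adds $|r_i| \le k_{cat,i} E_i$, $0 \le E_i \le E_{max}$,
$\sum E_i \le E_{total}$; absolute values are realized by
forward/backward flux splitting, so the LP stays linear. The capacity
constraint binds exactly the reactions that carry a `kcat` — annotating
a reaction is opting it in. `enzymeCostMin()` minimizes
$\sum_i w_i E_i$ under fixed demands; at its optimum every active
enzyme is tight, $|r_i| = k_{cat,i} E_i$. When no turnover numbers are
known, $1.8\cdot10^6$ 1/h is the package default — the order of
magnitude obtained by dividing a standard uptake rate (6 mmol/gDW/h) by
the concentration of ~2000 transporter molecules in a $10^{-12}$ gDW
cell (`copyNumberToConc()`, `estimateKcat()`).

## Kinetics

The reversible rate law is
$$ r = k_{cat} E\,
   \frac{\prod_i s_i^{n_i}\,\bigl(1 - Q/K_{eq}\bigr)}
        {\prod_i (1 + s_i^{n_i}) + \prod_j (1 + p_j^{n_j}) - 1}, $$
with $s = S/K_S$, $p = P/K_P$ and $Q$ the mass-action ratio. The
trailing "$-1$" is implemented literally, and molecularities enter both
the saturation polynomial and $Q$; non-integer orders are rejected
(molecule counts). The law factorizes exactly into capacity
$\eta_c = k_{cat}E$, saturation $\eta_s \in [0,1]$ and thermodynamic
drive $\eta_t = 1 - e^{\Delta G^*}$; `rateDecomposition()` returns the
three factors and the identity $\eta_c\eta_s\eta_t = r$ is tested to
machine precision. The numerator is folded into a single expression so
$S = 0$ with products present evaluates to the correct negative rate
instead of $0 \cdot (-\infty)$. Note the forward rate is capped by
$k_{cat}E$ but the reverse magnitude is capped by the Haldane backward
capacity $k_{cat}E\,K_P/(K_S K_{eq})$ — the tests check both.
`enzymeDemand()` inverts the law; its divergence as $Q \to K_{eq}$ is
the quantitative reason thermodynamically strained reactions are
expensive in proteome.

Kinetic constants share the mmol/gDW concentration convention of the
rest of the package (one convention, applied everywhere, rather than a
mix of mM and specific units).

## Growth without a biomass objective

$\mu = w^\top N r / 1000$: mass-conserving internal columns contribute
nothing, uptake adds, excretion and by-product losses subtract. A
biomass drain column (mass *converted* into biomass, not lost) is
flagged `biomass` and its contribution is counted positive. The
dilution-corrected steady state is $M N r = 0$ with
$M = I - c\,w^\top$ (outer product — the only dimensionally consistent
reading of the growth-coupled form); `buildMMatrix()` applies the
mmol/g factor so $c\,w^\top$ is dimensionless, and with $c = 0$ plain
FBA is recovered.

The two-unit reduced model replaces fluxes by first-order feedback
kinetics: uptake $r_0 = k_1 B_1$ and synthesis capacity $k_2 B_2$, with
$B_1 + B_2$ fixed. The realized growth rate at a given allocation is
the *smaller* of the uptake-limited and machinery-limited branches; the
optimum sits at their crossover, where the overflow vanishes. Defaults
$k_1 = 100$ mmol/gDW/h per g/g and $k_2 = 1.2$ 1/h put the optimal
growth rate near 1.1 1/h, a realistic bacterial scale; the scan grid
default is 401 points on $[0, B_{total}]$, and the tests compare the
grid optimum against a continuous golden-section oracle. In the
heterologous-burden scenario the burden protein still belongs to the
1 g of biomass being synthesized and diluted, which is why growth falls
linearly with the burden instead of staying flat.

## The self-contained model

`solveSelfContained()` maximizes $\mu$ of a cell whose only external
input is the substrate concentration. The model couples the toy
network (kinetic rate laws on all seven metabolic reactions,
loop-consistent $K_{eq}$ values 10, 2, 3, 18, shared
$k_{cat} = 1.8\cdot10^6$ 1/h, binding constants 0.2 mmol/gDW) to three
units: B1, a fixed metabolic sector (0.3 g/g) that also hosts the
enzyme mass; B2, the synthesis machinery, gated by the monomer pool
through $f_M = M/K_M$ (gating metabolite A, $k_{syn} = 20$ 1/h,
$K_M = 0.5$ mmol/gDW); B3, an inert remainder closing the balance
$C + B_1 + E_{mass} + B_2 + B_3 = 1$ g/g. The metabolite budget is
$C = 0.1$ g/g with a concentration floor of $10^{-6}$ mmol/gDW
(concentrations cannot be zero). The enzyme pool default
$E_{total} = 10^{-5}$ mmol/gDW puts the optimal uptake near
10 mmol/gDW/h. Where the machinery's remit was open, the package takes
the capacity reading: B2's gated throughput must cover everything it
sustains, $\mu (B_1 + E_{mass} + B_2) = k_{syn} f_M B_2$, which
determines B2's size (its own steady state alone would only pin
$\mu = k_{syn} f_M$ and leave the size free). The saturating gating
alternative $M/(M+K_M)$ is a one-line change in the units table.

The solver is nested: the outer Nelder-Mead search allocates the enzyme
pool (softmax simplex parameterisation times a usage factor, so
$\sum E_i \le E_{total}$ holds by construction); the inner damped
Newton (numerical Jacobian, backtracking line search) solves six
equations in six unknowns — four log-concentration balances with unit
drains and dilution, the metabolite mass budget, and the machinery
capacity equation. $\mu$ is the fifth unknown; its defining identity
$\mu = w^\top N r$ is *implied* by the weighted sum of the balances and
is therefore re-checked, not imposed, which makes it a genuine
self-consistency test. Infeasible states (negative growth branch,
negative B2/B3, concentrations below the floor) are penalized smoothly
so the outer search can climb back into the feasible region; states
where Newton finds no root at all get a flat penalty. Multistart
default is 17 seeds derived from the master seed by a unit counter;
each start carries its own polish phase, making the best-of-starts
objective non-decreasing in the number of starts. Every accepted
solution is re-verified independently: fluxes re-evaluated through the
rate laws, steady-state residuals below $10^{-6}$, budgets, closure,
and $\mu$ never exceeding the linear-FBA mass bound at the same uptake.

The test suite and examples run the optimizer at 2–3 starts with 60–100
outer iterations on the seven-reaction model — enough for reproducible
optima at this size; the 17-start default is for production runs.
Substrate sweeps at this setting reproduce the expected phenomenology:
growth saturates in the substrate while the self-controlled unit B2
grows and the inert remainder B3 shrinks, and the yield *rises* at low
substrate because less flux is wasted through the by-product branch.

## Elementary flux modes

`enumerateEFMs()` uses the classic null-space tableau: reversible
reactions are split, one metabolite is cancelled per iteration by
pairwise non-negative row combinations, non-minimal supports are pruned
as they arise, and the split is folded back. Every returned mode is
verified support-minimal (the support submatrix has nullity one) and
steady. Normalization is unit uptake when an uptake reaction is in the
support, else $+1$ in the first nonzero coordinate. The guard is
$q \le 20$; beyond that, dedicated EFM tools are the right instrument.
The test oracle is a completely independent exhaustive enumeration over
all column subsets. Comparing biomass-forming modes, the three-unit
model has three times as many as the single-pseudo-reaction model (21
against 7) — the structured biomass is genuinely more flexible. Growth
optima of the kinetic model land *near* but not exactly on a mode,
while the minimal-total-flux solution *is* one; `compareToEFMs()`
quantifies this with direction-normalized distances and flags exact
hits.

## Known limitations

* The loopless enumeration and exhaustive EFM paths are for teaching-
  scale networks (≤ 12 internal reactions, ≤ 20 reactions); nothing
  here is genome-scale.
* $\Delta G^{0\prime}$ estimation (component contribution, ionic
  strength, pH corrections) is out of scope; standard energies are
  inputs.
* The self-contained optimizer certifies feasibility and
  self-consistency, not global optimality; multistart is a heuristic.
* Time-course integration of the concentration ODEs is not provided;
  the package evaluates steady states and their residuals only.
* SBML/COBRA import is deliberately absent; the JSON dialect documented
  in `loadModel()` is the interchange format.
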