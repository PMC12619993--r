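---
title: "Optimum contribution selection and mate allocation: models, algorithms and design choices"
author: "gocsma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimum contribution selection and mate allocation: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gocsma)
```

# The problem

Directional selection consumes the additive genetic variance it feeds on:
concentrating parentage on the few highest-merit individuals raises the mean
of the next generation but also its inbreeding, shrinking future response.
Optimum contribution selection (OCS) resolves the trade-off explicitly. Each
selection candidate $i$ receives a *contribution* $c_i \ge 0$, its fraction
of the next generation's genes, and we solve

$$
\max_{c}\; c^\top \hat u
\quad\text{s.t.}\quad
\tfrac12\, c^\top G c \le \theta,\qquad
c^\top s = c^\top d = \tfrac12,\qquad
c \ge 0 ,
$$

where $\hat u$ are estimated breeding values, $G$ is the genomic
relationship matrix, $s$ and $d$ are the sire/dam indicator vectors, and
$\theta$ caps the expected mean coancestry of the offspring. Using genomic
rather than pedigree relationships matters: $G$ measures the *realized*
proportion of shared genome, including Mendelian-sampling deviations that a
pedigree cannot see.

`gocsma` implements the full two-stage workflow: the OCS program above,
solved by a conic operator-splitting (ADMM) method, followed by *mate
allocation* (MA) among the selected parents, posed as a binary or integer
linear program and solved exactly by branch-and-bound. Around these sit the
standard plumbing: VanRaden method-1 GRM construction with MAF filtering,
plan-evaluation statistics, random-mating baselines, and a seeded synthetic
population generator.

# The genomic relationship matrix

`computeGRM()` uses VanRaden method 1,
$G = Z Z^\top / \big(2\sum_j p_j(1-p_j)\big)$ with $Z = N - P$, $N$ the
0/1/2 dosage matrix and $P_{ij} = 2p_j$. Allele frequencies default to
sample estimates from the supplied matrix, which centers the columns of $Z$
exactly; consequently every row of $G$ sums to zero and negative
off-diagonals (pairs less related than the population average) are a
structural certainty, not an artifact. Supplying external frequencies is
possible and waives that property. Missing genotypes are an error unless
per-locus mean imputation is explicitly requested — silent imputation
changes $G$ and should be a visible decision. `mafFilter()` keeps loci with
minor allele frequency *strictly* greater than the threshold (default
0.05).

# Solving OCS: conic reformulation and ADMM

The coancestry bound is the only non-linear piece. With $G = LL^\top$
(Cholesky), $\tfrac12 c^\top G c \le \theta$ is exactly
$\lVert L^\top c \rVert_2 \le \sqrt{2\theta}$, a second-order-cone
membership. `buildConicForm()` therefore assembles

$$
\min_c\; -\hat u^\top c
\quad\text{s.t.}\quad
Ac + z = b,\qquad
z \in \{0\}^2 \times \mathbb R_+^n \times \mathrm{SOC}_{n+1},
$$

stacking the two sex-sum rows (zero cone), the $n$ nonnegativity rows and
the cone block $[\,0;\,L^\top\,]$ with right-hand side
$(\tfrac12, \tfrac12, 0, \sqrt{2\theta}, 0)$.

Since $G$ built from sample frequencies is singular (zero row sums), the
Cholesky needs a diagonal repair: jitter starts at
$10^{-10}\,\mathrm{tr}(G)/n$ and doubles up to $10^{-6}\,\mathrm{tr}(G)/n$;
the applied value is reported in the solution's diagnostics, and failure
beyond the cap is an error rather than a silent approximation.

`solveOCS()` runs a consensus ADMM on this form. With penalty $\gamma$ and
scaled dual $\lambda$:

1. **c-update** — minimize
   $-\hat u^\top c + \tfrac{\gamma}{2}\lVert Ac + z - b + \lambda\rVert^2$,
   a linear solve against $A^\top A = ss^\top + dd^\top + I + G$, factored
   once and reused every iteration;
2. **z-update** — project $b - Ac - \lambda$ onto the cone product
   (`projectSOC()` handles the second-order block in closed form);
3. **dual update** — $\lambda \leftarrow \lambda + (Ac + z - b)$.

Iteration stops when the primal residual $r^k = Ac^k + z^k - b$ and dual
residual $s^k = \gamma A^\top (z^k - z^{k-1})$ satisfy
$\lVert r^k\rVert_2 \le \epsilon_{abs} + \epsilon_{rel}\max(\lVert
Ac^k\rVert, \lVert z^k\rVert)$ and $\lVert s^k\rVert_2 \le \epsilon_{abs} +
\epsilon_{rel}\lVert \gamma A^\top \lambda^k\rVert$.

Defaults and their meaning (all dimensionless unless noted):

| parameter | default | role |
|---|---|---|
| `epsAbs`, `epsRel` | $10^{-5}$ | residual tolerances |
| `gamma0` | 0.1 | initial ADMM penalty |
| `adaptiveGamma` | TRUE | residual balancing: $\gamma$ doubles when $\lVert r\rVert > 10\lVert s\rVert$, halves in the mirror case, clamped to $[10^{-6}, 10^6]$, with $\lambda$ rescaled to keep the unscaled dual fixed |
| `maxIter` | 20000 | iteration cap; exceeding it returns `status = "max_iter"` with the best iterate, not an error |
| `rhoZero` | $10^{-4}$ | contributions below this are set to exactly zero after solving |
| `feasTol` | $10^{-6}$ | feasibility guaranteed on the reported solution |

Three solver-design points deserve emphasis.

**The reported iterate is the projected one.** ADMM's primal iterate only
satisfies constraints in the limit; the nonnegative-orthant block of $z$,
by contrast, is exactly nonnegative at every iteration. `solveOCS()`
reports that block, and after the residual criteria are met it additionally
verifies the sex sums and the coancestry bound directly at `feasTol`,
tightening the tolerances and continuing if the check fails. Converged
solutions therefore satisfy $|c^\top s - 0.5| \le 10^{-6}$,
$|c^\top d - 0.5| \le 10^{-6}$, $\min(c) \ge 0$ and
$\tfrac12 c^\top G c \le \theta + 10^{-6}$ by construction, not by hope.

**Initialization is feasible and deterministic.** $c^0$ spreads 0.5
uniformly within each sex, $z^0$ is the projected lifted image, $\lambda^0
= 0$. The algorithm contains no randomness; identical inputs give identical
iterates, which the tests assert bitwise.

**Infeasibility is certified, not guessed.** If $\theta$ is below the
minimum coancestry achievable under the sex sums (e.g. one dam and one sire
force $c = (0.5, 0.5)$), no iterate converges. Every 50 iterations the
solver tests the dual-increment direction $v$ as a Farkas certificate —
$v$ in the dual cone, $A^\top v = 0$, $b^\top v < 0$ within $10^{-6}$ after
normalization — and raises a descriptive error when one is found. A
divergence guard on $\lVert\lambda\rVert$ backs this up.

Contributions below `rhoZero` are zeroed and **not renormalized**: the
surviving entries are the solver's optimum, and rescaling them would move
the solution off it. Sums may therefore fall microscopically short of 1.

# Mate allocation

`extractSelected()` splits the thresholded contributions into dams
($c_d$, length $n_d$) and sires ($c_s$, length $n_s$) and slices the
dam-by-sire block $H$ of $G$. The allocation program is

$$
\min_M\; c_d^\top (H \odot M)\, c_s
\quad\text{s.t.}\quad
\textstyle\sum_j M_{ij} \le \kappa_d,\;
\sum_i M_{ij} \ge \kappa_s,\;
M_{ij} \in \{0, \dots, \sigma_d\},
$$

with $\sigma_d = 1$ in binary mode. Because $c_d$, $c_s$ and $H$ are
constants here, the objective is linear in $M$ with coefficients
$C_{ij} = c_{d,i} H_{ij} c_{s,j}$ (`buildCostMatrix()`); the apparent
quadratic form is an integer *linear* program.

Constraint defaults: $\kappa_s = 0$ (a minimum per sire is numerically
treacherous when some contributions are tiny, and 0 usefully prunes
low-value sires; $\kappa_s \ge 1$ is supported), $\kappa_d = 3$ (a typical
per-dam capacity in the litter-bearing settings this model targets; it is
a required, surfaced parameter, not a hidden constant), and
$\sigma_d = \kappa_d$ in integer mode (the loosest per-pair cap consistent
with the row cap; recorded in output metadata).

Three solvers share the problem type:

* `solveMatingGreedy()` — for $\kappa_s = 0$ the rows decouple and each dam
  independently fills her $\kappa_d$ matings with the most negative
  $C_{ij}$ (ties to the lowest sire index, never allocating to
  $C_{ij} \ge 0$, since an allocation can only be worthwhile if it lowers
  the objective). This closed form is provably optimal row by row.
* `solveMatingBnB()` — exact for any $\kappa_s$: depth-first
  branch-and-bound whose node bound is the continuous relaxation
  ($0 \le M \le \sigma_d$ plus the aggregates) solved exactly by a
  successive-shortest-path min-cost flow on the transportation graph
  source → dams → sires → sink. The constraint matrix is totally
  unimodular, so relaxation optima are integral and the search typically
  certifies optimality at the root; the fractional-branching machinery
  (most fractional entry, lowest indices on ties) exists for
  configurations where a bound routine returns fractional values. Cutting
  planes, presolve and primal heuristics of industrial MIP codes are
  deliberately absent — this structure does not need them.
* `enumerateMatings()` — the exhaustive oracle for tiny instances (up to
  $(\sigma_d+1)^{n_d n_s} \le 10^7$ candidates), used throughout the tests
  to certify the other two.

Zero-cost entries are never allocated under $\kappa_s = 0$; this is
deterministic and keeps plans minimal. Integer mode can only do at least
as well as binary mode (its feasible set contains the binary one), and the
tests assert that dominance.

# Evaluating plans and baselines

For any plan $M$ over parents with coancestry block $H$:

* **future coancestry** $\theta_f = \sum_{ij} M_{ij} H_{ij} / \sum_{ij}
  M_{ij}$ — the mating-weighted mean coancestry of mated pairs. Indices
  run over the mating matrix, so only dam-by-sire coancestries enter;
  self- and within-sex terms are excluded.
* **genetic gain** $\Delta\hat u = E(\hat u_{sel}) - E(\hat u_{pop})$,
  where each mating contributes its parental midpoint
  $(\hat u_{dam} + \hat u_{sire})/2$ weighted by its count, and
  $E(\hat u_{pop})$ is the unweighted mean over *all* candidates supplied
  to OCS. The midpoint convention is a genuine choice (a per-parent
  weighting differing by sex would be defensible too); it is the natural
  reading of "weighted by the number of matings" and is applied
  consistently across all schemes, so scheme contrasts are unaffected.

`compareSchemes()` builds the four-scheme table: truncation selection +
random mating (TSRM), OCS parents + random mating (GOCSRM), and the
optimized binary/integer allocations (GOCSMA-bin/-int). Conventions:

* random mating fills dams in order up to $\kappa_d$ each and draws each
  sire uniformly with replacement — uniform, not contribution-weighted,
  among the selected sires;
* TSRM selects the same *numbers* of dams and sires as the OCS solution
  (overridable) and uses the same total matings as the integer plan, so
  the baselines differ from GOCSMA only in *which* parents and pairings;
* random schemes are averaged over `replicates` (default 100) replicates,
  replicate $r$ reseeded deterministically at `seed + r`, making the whole
  table bit-reproducible.

# The synthetic generator: what it does and does not emulate

`simulatePopulation()` draws per-locus allele frequencies uniformly on
`mafRange`, dosages as independent Binomial(2, $p_j$), sexes at a fixed
female fraction (0.6 by default — breeding populations typically carry
more dams than sires), and breeding values additive in the sample-centered
genotypes with standard-normal locus weights plus Gaussian noise at
`noiseRatio` (default 0.25) times the signal variance, i.e. an estimated-BV
accuracy around 0.9. Everything is reproducible from one seed, and fixture
presets (`tiny` 6×10, `small` 40×300, `medium` 200×2000) write the
package's file formats plus a seed manifest.

What this deliberately does **not** emulate: pedigree and family
structure, linkage disequilibrium, and trait architecture (QTL effects,
epistasis, imprinting). Individuals are exchangeable and unrelated in
expectation, so $G$'s off-diagonal dispersion comes from marker sampling
alone. Two practical consequences:

* absolute $\theta$ values from pedigreed datasets do not transfer. The
  package's own experiments therefore scale $\theta$ to the population's
  baseline coancestry $\tfrac12 c_u^\top G c_u$ at uniform contributions
  $c_u$ — 4× baseline as the loose regime and 1.5× as the tight one,
  fixed a priori as the two regimes worth contrasting;
* with no family structure to discriminate against, loose-θ OCS spreads
  contributions widely, and a truncation baseline matched to the OCS
  parent counts keeps most of the population — its gain is then modest.
  Passing tests on synthetic data certify the *algorithms* (feasibility,
  optimality against oracles, formula correctness, reproducibility), not
  the field-data magnitudes of any particular study population.

# Problem sizes and budgets

The test suite works at desk scale by design: OCS oracle comparisons on
$n \le 20$ candidates against an independent convex solver (20 seeded
instances at $10^{-4}$ relative), exhaustive mate-allocation certification
on $n_d, n_s \le 3$ with caps $\le 2$ (50+ seeds), a $10^4$-replicate
Monte-Carlo check of the random-mating expectation, and brute-force GRM
equivalence at 30×200. The acceptance script runs the full pipeline at
200 candidates × 2000 SNPs with 100 evaluation replicates. These sizes
make every independent oracle exact or near-exact; the algorithms
themselves have no dimension-specific code paths.

# Known limitations

* The ADMM solver has no equilibration/preconditioning; badly scaled
  $\hat u$ or $G$ will cost iterations (not correctness). Iteration counts
  depend on the adaptive-$\gamma$ details and should not be compared
  across implementations.
* $\kappa_s \ge 1$ is exact but can be slow if branching were ever needed,
  and can force positive-coancestry matings; it is flagged experimental.
* Single-generation scope: no forward simulation of repeated OCS+MA
  rounds, and no variance reporting beyond replicate means.
* One quantitative trait; multi-objective selection is out of scope.
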