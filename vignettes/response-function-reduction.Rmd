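---
title: "Reducing linear reaction networks to renewal equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing linear reaction networks to renewal equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfekit)
```

## The model

A linear (first-order) reaction network on a finite state set $\Omega$ evolves
as $dn/dt = A n$, where $A_{ij} = \lambda_{ji} \ge 0$ stores the jump rate
from state $j$ to state $i$ and the diagonal makes every column sum to zero,
so the total amount $\sum_i n_i$ is conserved.  rfekit keeps this column
convention everywhere (it avoids a transpose in the master equation); the
JSON interchange format stores the edge list in jump direction so the
orientation can never be misread.

Partition $\Omega$ into compartments $\alpha \in X$.  The compartment totals
$N_\alpha = \sum_{i \in \alpha} n_i$ do not satisfy an autonomous ODE — the
reduction trades the Markov property for memory.  They satisfy instead a
closed system of renewal (Volterra) equations driven by influx and outflux
histories:

$$
N_\alpha' = e^\top S_\alpha - e^\top J_\alpha,\qquad
S_\alpha(t) = S^0_\alpha(t) + \sum_{\beta\ne\alpha}
  \int_0^t G_{\beta\alpha}(t-s)\,S_\beta(s)\,ds,\qquad
J_\alpha(t) = J^0_\alpha(t) + \int_0^t K_\alpha(t-s)\,S_\alpha(s)\,ds,
$$

with matrix-valued kernels computable from the blocks of $A$:

$$
G_{\beta\alpha}(t) = A_{\alpha\beta}\, e^{tA_{\beta\beta}},\qquad
K_\alpha(t) = C_\alpha\, e^{tA_{\alpha\alpha}},
$$

where $C_\alpha$ is the diagonal matrix of total exit rates of the states of
$\alpha$.  When every compartment has at most one *entrance point* (a state
receiving jumps from outside), the system collapses to scalar response
functions $\Phi_{\alpha\beta}(t)$ — the probability density of the waiting
time between entering $\alpha$ and leaving it towards $\beta$.  For a
non-sink compartment these densities sum to a unit total mass,
$\sum_\beta \int_0^\infty \Phi_{\alpha\beta} = 1$, *provided* every state
reachable from the entrance point can also reach an exit; an internal trap
keeps part of the mass forever and `kernel_mass()` reports both the deficit
and the trapped limit $\lim_t e^\top e^{tA_{\alpha\alpha}} e_{i_\alpha}$.

A convention worth stating: a singleton compartment that receives no jumps
has no entrance point in the graph sense, but its entry pathway is
unambiguous (its only state), so `scalar_kernels()` uses that state.
Multi-state compartments without an entrance point get identically zero
scalar kernels; their transient outflow lives entirely in the forcing
functions.

## Numerical choices

**Kernel tabulation.** One matrix exponential `expm(dt * A_bb)` per block
(scaling and squaring, via Matrix), then repeated multiplication along the
grid: the semigroup property holds exactly on the nodes and the cost is
linear in the number of nodes.

**Improper integrals.** For ODE-derived kernels every mass, Laplace
transform and moment is a closed-form resolvent expression.  Because chains
with equal stage rates make the diagonal blocks defective (Jordan blocks),
these are evaluated with the group (Drazin) inverse
$-(A + P_0)^{-1}(I - P_0)$, where $P_0$ is the spectral projector onto
$\ker A$ computed from left/right null bases — never by eigendecomposition,
which fails precisely on the phase-type realizations we care about.
Tabulated kernels fall back to the trapezoid on the grid plus a
single-exponential tail fitted to the last decade of samples; the tail is
reported separately and flagged when the samples do not decay.

**Volterra solver.** Trapezoid convolution quadrature with the implicit
$s = t$ endpoint solved per node — one LU factorization of
$I - \tfrac{dt}{2} G(0)$ reused across the grid.  The scheme is second
order; halving `dt` reduces the error against the matrix-exponential oracle
by about four, which the test suite asserts.  Kernel values at $t = 0$ come
from the closed form ($G(0) = A_{\alpha\beta}$), never from extrapolation.
Impulsive inputs are always realized as initial conditions, not as
discretized delta functions.

**Detailed balance and complete monotonicity.** If $A\mu = 0$ with
$A_{ij}\mu_j = A_{ji}\mu_i$ and $\mu > 0$, the similarity by
$\operatorname{diag}(\sqrt\mu)$ symmetrizes each diagonal block, and the
response kernel out of a compartment becomes a nonnegative mixture of
decaying exponentials
$\Phi = \lambda_{i_\beta i_\alpha}\sum_j \kappa_j^2 e^{-\nu_j t}$ with
$\sum_j \kappa_j^2 = 1$ — a completely monotone function.
`check_detailed_balance()` finds $\mu$ from the null space (SVD); a
reducible network with a multi-dimensional null space is reported as
"non-unique equilibrium" rather than guessed at.  The default tolerance is
$10^{-8}$ relative to the largest equilibrium flux.

**Markovianity.** The reduced dynamics is Markovian exactly when every
kernel is exponential, $\Phi_{\alpha\beta}(t) =
\lambda_{\alpha\beta}e^{-t\sum_\gamma\lambda_{\alpha\gamma}}$.  The theorem
is exact; the test needs a threshold, so `markovianity_test()` reads the
candidate rates off $\Phi_{\alpha\beta}(0)$ and accepts when the sup-norm
misfit is below `tol` (default $10^{-6}$) relative to each rate.

**Long-time behaviour.** With irreducible conservative kernels the matrix
$M(z)$ of Laplace-transformed kernels has spectral radius strictly
decreasing in $z$ and equal to one at $z = 0$; `characteristic_root()`
Brent-solves $\rho(M(z)) = 1$, bracketing by default at $-0.9$ times the
smallest kernel decay rate (from the block spectra, or a tail fit for
tabulated kernels).  The limit profile is the simple-pole residue of
$(I - M(z))^{-1}\hat B^0(z)$ at $z = 0$, computed with the eigenvector
formula $c_0 = u_0^\top \hat B^0(0) / (-u_0^\top M'(0) v_0)$ (left/right
Perron vectors, $u_0^\top v_0 = 1$) rather than small-$z$ extrapolation,
which is badly conditioned near the pole; $M'(0)$ entries are the negated
kernel first moments, exact via squared resolvents for ODE-derived kernels.

## Phase-type approximation

Any waiting-time distribution can be approximated by an Erlang mixture
$f = \sum_j q_j\,\gamma_{M,m_j}$.  The construction used by `erlang_fit()`
is the standard one: bin the target CDF at resolution $1/M$, give bin $j$
the shape $m_j = j - 1$ and the bin's probability as weight, and put the
remainder on the last component (warning when that remainder exceeds half
the mass).  `realize_chain()` turns a mixture into an explicit conservative
network — a start node branching into parallel chains of stages at uniform
rate $M$ — whose first-passage flux equals $f$ exactly, not just in the
limit.

For a whole kernel family, `realize_network()` wires such chains between
entrance points with branch rates $M p_{\alpha\beta} q_j$.  A design choice
departs from the textbook picture here: the per-pair branch node is merged
into the entrance point itself, so the entrance sojourn provides the first
of the $m_j + 1$ Erlang stages and the realized kernel equals
$p_{\alpha\beta} f_{\alpha\beta}$ *exactly* (a separate branch node would
convolve one extra exponential stage into every kernel, an $O(1/M)$ bias).
The price is that all mixtures leaving one compartment must share the same
rate $M$, which the constructor enforces.  Kernel masses
$\int \Psi_{\alpha\beta} = p_{\alpha\beta}$ hold either way; distances to
fit targets are measured with the Kolmogorov–Smirnov statistic (an upper
bound for the Lévy–Prokhorov metric on the line) with a $W_1$ estimate for
diagnostics.

## Age structure

The same reduced dynamics can be Markovianized by adding the time since
entry as an age variable: a transport PDE with exit rate $\Lambda_\alpha(\xi)$
and a renewal boundary condition.  Kernels and rates interconvert by

$$
\Phi_{\alpha\beta}(t) = \lambda_{\alpha\beta}(t)\,
  e^{-\int_0^t\Lambda_\alpha},\qquad
\lambda_{\alpha\beta}(t) = \frac{\Phi_{\alpha\beta}(t)}
  {1 - \sum_\gamma\int_0^t\Phi_{\alpha\gamma}},
$$

and the survival identity $e^{-\int_0^t\Lambda_\alpha} =
1 - \int_0^t\sum_\beta\Phi_{\alpha\beta}$ is asserted internally at
quadrature accuracy.  The inversion needs the denominator bounded away from
zero: if the kernel mass is exhausted inside the grid (bounded support, or
simply a grid much longer than the waiting times) no bounded rate exists
there, and `rates_from_kernels()` raises a "survival exhausted" error with
a configurable floor (default $10^{-8}$) instead of extrapolating.

`spe_solve()` uses a single step $h$ for time and age so transport is exact
along characteristics.  Newborn mass is deliberately *not* written into the
age-density grid: the newborn cohort has a genuine density jump at its
front, and any fixed quadrature rule across that jump costs $O(h)$
globally.  Instead each step's births form a cohort particle (age $h/2$,
mass = trapezoid of the boundary rate over the step, with the earlier-born
members decayed across their birth step), and history point masses are
particles from the start.  Aggregation then sums cohort masses exactly, and
the scheme is second order — step halving shrinks the gap to both the
matrix-exponential oracle and the renewal solver by about four, as the
tests assert.  Smooth tabulated histories stay on the grid part, truncated
where the kernels have decayed to numerical zero.

## Worked biochemical models

*Kinetic proofreading* (Hopfield/Ninio): the five-state scheme with
complex $S$, phosphorylated complex $S^*$, degradation $\mu$ and production
$\lambda$; `Q` measures how far the phosphorylation step is from detailed
balance ($Q = 1$ restores it, which the tests verify on the reaction core).
The response function is $\Phi(t) = \lambda S^*(t)$ under a unit codon
impulse.  Total production and the mean production time are computed both
from printed closed forms and from independent resolvent identities
($(-A_3)^{-1}e_C$ and $A_3^{-2}e_C$) and cross-checked to $10^{-6}$
relative or better; the discrimination ratio
$\bar P_\infty / P_\infty \ge \theta^2$ and its convergence to $\theta^2$
along the scaling family $\alpha = \mu = \varepsilon$,
$\beta = \varepsilon^2$, $Q = \varepsilon^{-2}$,
$\lambda/\eta = \varepsilon^{2+s}$ are exercised numerically down to
$\varepsilon = 10^{-4}$.  The closed form for the mean production time is
stated here as the exact rational expression including the terminal
$1/\lambda$ sojourn term, which is required for agreement with the
first-moment route.  Total-production quadrature resolves the fast initial
transient on the grid and carries the slow tail with the exact resolvent
applied to the final state, so stiffness (rates spread over six orders of
magnitude in the presets) costs no accuracy.

*Adaptation*: the two-species linear circuit with generator
$[[-b, a], [-1, 0]]$, $b^2 > 4a$.  Its kernel has total mass exactly zero —
the signature of perfect adaptation — and the package exposes both the
analytic mass (a cancellation of $C_\pm/|\lambda_\pm|$) and a Simpson
quadrature of the closed-form kernel, which agrees to $10^{-13}$.

*Polymerization*: the linear chain-growth model iterates one fixed
elongation kernel by convolution and develops a size-space front moving at
speed $1/\mu$ with $\mu$ the kernel mean; the front diagnostic is the
half-height crossing of $n_\ell$, which for narrow kernels sits near
$(\ell - \tfrac12)\mu$.  The nonlinear variant couples mass-action binding
to a maturation kernel through a history convolution; the explicit Heun
stepper reproduces the exact monomer mass balance
$d(\sum \ell n_\ell + \sum \ell w_\ell)/dt = S$ to machine precision, the
truncation size is absorbing with the suppressed boundary flux logged, and
a narrow kernel recovers Markovian Becker–Döring-like kinetics against an
independent ODE oracle.

*Coherent feed-forward loop*: the AND-gate motif's output is a quadratic
functional of the signal; the double-convolution kernel is integrated
analytically (no numerical triple integral) and checked against RK4
integration of the ODEs under grid refinement.  In the fast-degradation
limit the kernel degenerates to a Dirac factor, handled analytically as a
one-dimensional convolution: the limit response shows the sign-sensitive
delay — slow saturation after signal onset, instantaneous shut-off after
signal removal.

## Synthetic fixtures

`random_conservative_network()` defines the conditions every stochastic
test runs under.  Rates are uniform on $[0.2, 1]$ (times `rate_scale`) — a
dimensionless order-one band appropriate after nondimensionalizing by a
typical reaction time.  Internal connectivity is a random cycle through
each compartment plus chords, so no compartment hides an internal trap
unless one is built deliberately; `single_entrance` restricts
cross-compartment edges to one designated target state per compartment;
`detailed_balance` constructs rates as $s_{ij}/\mu$ from a symmetric
positive matrix and a random equilibrium, which makes reversibility exact
by construction; `strongly_connected` links compartments in a directed ring
plus extras and verifies strong connectivity of both the state and the
compartment digraphs post hoc, resampling with derived seeds a bounded
number of times.  Problem sizes in the tests (5–9 states, 2–3 compartments,
grids of $10^2$–$4\times10^3$ nodes) are chosen so every identity is
resolved to well below its asserted tolerance at desk scale; what the
passing suite shows is correctness of the reduction machinery on exactly
representable linear kinetics — it says nothing about model misspecification
on real data, where rates are neither constant nor known.

## Known limitations

Laplace analysis is restricted to the real axis (no complex poles, no
oscillatory correction terms to the long-time profile); the decay constants
in the exponential-convergence statements are verified to exist, not
estimated sharply.  Measure-valued kernels beyond tabulated densities plus
finitely many point masses are out of scope, as are stochastic path
simulation of the semi-Markov process, SBML import, and nonlinear
mass-action networks beyond the two worked examples.  Grids are
user-chosen and uniform; there is no adaptive stepping, so stiff kernels
need the user to resolve the fastest scale (the worked models show the
resolvent-tail idiom that avoids paying for the slowest one).
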