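# rfekit

Coarse-graining a linear chemical reaction network usually means *lumping*:
replacing many states by a few and hoping the result is still Markovian.  It
rarely is.  rfekit implements the alternative: keep the compartments as black
boxes and describe the traffic between them exactly, with renewal (Volterra)
integral equations whose kernels — *response functions* — are the waiting-time
densities of transit through each compartment.  The package is for modellers
in systems biology and biochemistry who want to reduce a mechanistic ODE
network to a small non-Markovian input/output description, analyse what such
a description can and cannot look like, and go back again.

## The mathematics in brief

A conservative linear network on states $\Omega$ evolves as $dn/dt = An$,
with $A_{ij} = \lambda_{ji} \ge 0$ (rate of the jump $j \to i$; columns sum
to zero).  For a partition of $\Omega$ into compartments $\alpha$, the totals
$N_\alpha = \sum_{i\in\alpha} n_i$ satisfy

$$N_\alpha' = e^\top S_\alpha - e^\top J_\alpha,\qquad
S_\alpha(t) = S^0_\alpha(t) + \sum_{\beta\ne\alpha}\int_0^t
  A_{\alpha\beta}e^{(t-s)A_{\beta\beta}} S_\beta(s)\,ds,\qquad
J_\alpha(t) = J^0_\alpha(t) + \int_0^t C_\alpha e^{(t-s)A_{\alpha\alpha}}
  S_\alpha(s)\,ds.$$

When each compartment has at most one entrance point this collapses to
scalar kernels $\Phi_{\alpha\beta}(t)$ with
$\sum_\beta\int_0^\infty\Phi_{\alpha\beta} = 1$ for non-sink compartments.
On top of this reduction the package provides:

- **Kernel analysis** — exact (resolvent-based) masses, Laplace transforms
  and moments; sink diagnostics for mass trapped inside a compartment.
- **Volterra solvers** — second-order convolution quadrature for the scalar
  and the generalized (vector-valued) systems, validated against the
  matrix-exponential solution of the original ODEs.
- **Structure theorems as computations** — detailed balance forces kernels
  to be completely monotone (explicit exponential-mixture decompositions);
  the reduced dynamics is Markovian iff all kernels are exponentials (test
  with recovered rates); long-time behaviour via the renewal characteristic
  equation $\rho(M(z)) = 1$ and the residue formula for the limit profile.
- **Phase-type approximation** — Erlangization of arbitrary waiting-time
  distributions and exact realization of kernel families as explicit
  reaction chain networks.
- **Age structure** — conversion between the renewal description and
  structured-population transport equations, both directions, with a
  characteristics-aligned cohort solver.
- **Worked models** — Hopfield kinetic proofreading (discrimination ratio,
  mean production time), a linear adaptation circuit (zero-mean kernel),
  linear and nonlinear (mass-action) polymerization with non-Markovian
  elongation, and the coherent type-1 feed-forward loop with its quadratic
  response kernel.

## A worked example

Reduce a random 6-state network with two single-entrance compartments,
check kernel normalization, solve the renewal system, and compare with the
full ODE:

```r
library(rfekit)

net <- random_conservative_network(6, 2, seed = 42, single_entrance = TRUE,
                                   strongly_connected = TRUE)
net
#> <compartment_network> 6 states in 2 compartments
#>   c1: {s1, s2, s3, s4, s5}  entrance: s2
#>   c2: {s6}  entrance: s6

g <- time_grid(t_end = 12, n_points = 1201)
k <- scalar_kernels(net, g)
kernel_mass(k)$pair_mass        # exit-probability split; rows sum to 1
#>    c1 c2
#> c1  0  1
#> c2  1  0

n0 <- c(1, 0, 0, 0, 0, 0); names(n0) <- net$states
f   <- grfe_forcing(k, n0)      # transient forcing of the initial state
sol <- solve_rfe(k, f)          # Volterra solve of the reduced system
sol
#> <renewal_solution> scalar, 2 compartments, 1201 nodes
#>   N(t_end): 0.75588, 0.24412

max(abs(sol$N - ode_compartment_totals(net, n0, g)))
#> [1] 2.22e-05                  # renewal route vs direct matrix exponential

asymptotic_profile(k, f)        # where the mass ends up, from the residue
#> <asymptotic_profile> c0 = 0.477959
#>   N_inf: c1 = 0.75585, c2 = 0.24415

markovianity_test(k)$is_markovian
#> [1] FALSE                     # a 5-state compartment has memory
```

The totals from the renewal solve agree with the full ODE to the quadrature
order, the kernel masses say every exit from `c1` leads to `c2` and back,
and the long-time profile computed from the Laplace-domain residue matches
where the solver actually converges.  The FALSE Markovianity verdict is the
point of the formalism: the two-compartment description is exact but not
memoryless.

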