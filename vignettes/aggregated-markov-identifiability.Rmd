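---
title: "Aggregated Markov models of ion-channel gating: counting, equivalence and identifiability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated Markov models of ion-channel gating: counting, equivalence and identifiability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggmarkov)
```

## The model class and what is observable

A gating record of a single ion channel is an alternating sequence of open
and closed dwell times. The standard generative model is a continuous-time
Markov chain on states partitioned into an open and a closed class, with
infinitesimal generator

$$Q = \begin{pmatrix} Q_{CC} & Q_{CO} \\ Q_{OC} & Q_{OO} \end{pmatrix},$$

rows summing to zero, off-diagonal entries the non-negative transition
rates (per unit time). Only the class sequence and the dwell durations are
observable; which state inside a class generated a dwell, or whether the
chain hopped between same-class states during it, is invisible. The package
keeps states in closed-first block order throughout, and all block indexing
in the documentation refers to that order.

Everything the package does flows from two classical facts:

1. The dwell time in a class is a (possibly signed) mixture of as many
   exponentials as the class has states. The decay rates are the negatives
   of the eigenvalues of the within-class block; the weights are obtained
   by projecting the *class-entry distribution* onto the eigenbasis.
2. The joint law of a dwell and the following dwell of the other class —
   summarised by coefficient matrices over pairs of exponential components
   — determines the full observable dynamics. Two models with identical
   bivariate structure are *equivalent*: no amount of noise-free dwell data
   can distinguish them.

The entry distribution is not printed in most treatments, so the convention
used here is stated explicitly: the probability of entering a class in
state $j$ is proportional to the stationary flux into $j$ through the
cross block, e.g. $\varphi_C \propto \pi_O\, Q_{OC}$. The test suite
cross-checks this convention against long simulated dwell sequences.

## Counting the topologies

A model topology is a connected graph on $n$ vertices carrying one of two
colours with both colours present. The package counts them exactly:

* the cycle index of the pair group (vertex permutations acting on the
  $\binom n2$ edge slots) is assembled per conjugacy class of $S_n$ from
  the standard induced-cycle rules — within a $k$-cycle, $(k-1)/2$
  edge-cycles of length $k$ for odd $k$, or $k/2-1$ of length $k$ plus one
  of length $k/2$ for even $k$; between cycles of lengths $k,l$,
  $\gcd(k,l)$ cycles of length $\mathrm{lcm}(k,l)$;
* colour is encoded structurally as adjacency to a root that is never
  materialized: each vertex $k$-cycle contributes one extra slot variable
  $t_k$ (a loop) to the rooted cycle index;
* substituting $t_i \mapsto 2$ counts configurations; $t_i \mapsto 1+t^i$
  enumerates by edge count;
* connected counts follow from the inverse Euler transform of the counting
  series. Writing $A_k = k\,a_k$ for the log-series coefficients turns the
  recursion and the subsequent Möbius inversion into pure integer
  arithmetic, which is both faster and sharper: a non-integer or negative
  connected count proves the input series inconsistent, and this is raised
  as an error rather than rounded away. The transform subscript ambiguity
  in some printed statements of the inversion (a $p$ where a $k$ belongs)
  is resolved as $a_{k/d}$; the round-trip against the forward transform
  and the agreement of both routes to $a_k$ are tested exactly.
* finally $M_n = CR_n - 2c_n$ removes, for every connected graph, its two
  single-colour colourings, which correspond to degenerate models with
  only one class.

Counts grow past $2^{53}$ in intermediate quantities well before $n = 12$,
so the module runs on exact big-integer arithmetic throughout (a small
sign/magnitude backend with base-$10^7$ limbs lives in `R/bigint.R`; all
limb operations stay in the exactly-representable double range). The
practical ceiling is `n = 12`: partition counts and polynomial sizes remain
trivial there, and the published reference values certify $n \le 10$. The
output table reports $n$ = number of coloured vertices; the root is never
counted.

For $n \le 5$ (totals) and $n \le 4$ (connected/coloured refinements) the
test suite re-derives every number by brute force — enumerate all labelled
configurations, canonicalize under all $n!$ vertex permutations, count
orbits — a deliberately independent route.

## Equivalence, canonical form, and the parameter bound

Block-diagonal similarity transforms $Q \mapsto S^{-1} Q S$ with
$S = \mathrm{blockdiag}(S_C, S_O)$ preserve the class partition, the
within-class spectra, and the full bivariate dwell structure. For the
transformed matrix to remain a generator, $S$ must fix the all-ones vector;
since eigenvectors are only defined up to scale, the package normalizes by
solving $V c = \mathbf 1$ for the column scalings of the eigenvector matrix
(an explicit choice, as no normalization is canonical). Diagonalizing both
blocks yields the Bauer–Kienker uncoupled (BKU) form, in which every
transition runs between classes and at most $2 n_O n_C$ free rates remain —
which is exactly the identifiability bound: any model with more positive
rates is non-identifiable. Eigenvalues are ordered by descending decay rate
with ties broken by original index, making the canonical output stable.

Two caveats are surfaced rather than hidden. First, the BKU representative
can carry negative rates; it is then flagged `feasible = FALSE`, but all
algebraic operations (spectra, bivariate coefficients, equivalence tests)
still accept it — feasibility and equivalence are deliberately separate
contracts. Second, when the open–closed cross block has deficient rank,
coefficient comparison may be coarser than a rank-refined criterion; the
equivalence test attaches a `rank_deficient` attribute in that case instead
of resolving it.

Defective (non-diagonalizable) or complex-spectrum blocks abort the mixture
machinery with explicit errors; detailed-balance models can never trigger
the complex case.

## The three-state model in full

For two closed states and one open state, the equivalence class of a fully
connected model is pinned by four invariants: the closed decay rates
$\lambda_1 \ge \lambda_2$, the open rate $\lambda_O = q_{31}+q_{32}$, and
the weight $\rho$ of the $\lambda_1$ component of the closed-time density.
Rather than carrying $\rho$ through eigenvector algebra, the implementation
uses elementary-symmetric bookkeeping: with
$T = \lambda_1+\lambda_2$, $D = \lambda_1\lambda_2$ and the coupling
invariant $C = q_{13}q_{31} + q_{23}q_{32}$ (the closed-density value at
zero dwell time scaled by $\lambda_O$; equivalently
$\rho\lambda_1\lambda_O + (1-\rho)\lambda_2\lambda_O$), fixing the free
coordinates $(q_{13}, q_{23})$ makes the invariant equations *linear* in
$(q_{12}, q_{21})$ and in $(q_{31}, q_{32})$. The package therefore solves
the family in closed form — a design choice made after observing the
linearity, where an iterative root-finder had been the obvious default —
and every returned member re-evaluates its invariants as a guard (rejected
above $10^{-8}$ relative error). The spectral definition of the invariants
remains the ground truth the solution is checked against.

The geometry that follows, all of it exercised in tests:

* **Star reduction** `to_star()`: $\tilde q_{13}=\lambda_1$,
  $\tilde q_{23}=\lambda_2$, $\tilde q_{31}=\rho\lambda_O$,
  $\tilde q_{32}=(1-\rho)\lambda_O$ — feasible iff $\rho \in [0,1]$.
* **Chain reduction** `to_chain()` (with detailed balance, so
  $q_{13}=q_{31}=0$): $q_{23}=C/\lambda_O$, $q_{12}=D/q_{23}$,
  $q_{21}=T-q_{12}-q_{23}$, $q_{32}=\lambda_O$.
* **Dichotomy**: star feasible $\iff$ chain feasible $\iff$
  $\rho \in (0,1)$ $\iff$ the closed density is a proper (monotone)
  mixture. In the signed regime the density is non-monotone, both
  reductions require a negative rate, and detailed balance cannot hold
  anywhere in the family.
* **Detailed-balance curve**: inside the $(q_{13}, q_{23})$ family the
  Kolmogorov condition $q_{31}q_{12}q_{23} = q_{13}q_{32}q_{21}$ selects a
  curve from the chain point $(\rho\lambda_1+(1-\rho)\lambda_2,\, 0)$ to
  the star point $(\lambda_1, \lambda_2)$. It is traced by uniform steps in
  $q_{13}$ with a bracketing root-solve in $q_{23}$ (bisection fallback
  when the initial bracket carries no sign change); 50 points by default.
  The chain endpoint at $q_{23} = 0$ is the same detailed-balance chain up
  to swapping the closed labels.

Degenerate spectra ($\lambda_1 = \lambda_2$, e.g. a star with equal exit
rates) leave $\rho$ undefined; the invariants object carries a `degenerate`
flag and downstream reductions refuse to guess a value. Boundary cases
$\rho \in \{0, 1\}$ are classified separately rather than folded into
either regime.

One textual ambiguity had to be resolved by convention: the non-reversible
chain-like variant ("$q_{12}=0$ but $q_{21} \ne 0$") is exposed as
`to_chain(inv, detailed_balance = FALSE)`, returning the $q_{13}=0$ family
member at $q_{23}=\lambda_2$ — one documented point of a one-parameter
family whose printed parametrisation is not fully recoverable.

## Ligand schemes

For a star model whose rates are mass-action ($k\,c$) or constant in the
ligand concentration $c$, the equivalent chain at each $c$ follows from the
same invariants, and crucially the chain rates depend only on $(T, D, C,
\lambda_O)$ — all symmetric in the two closed components. They therefore
stay well defined even at concentrations where the closed eigenvalues
cross (for one activating site, at $c = k_{23}/k_{13}$): the star/family
picture degenerates there, but the chain does not — $\tilde q_{21}$ simply
touches zero, its double root. For this reason `chain_rates_at()` computes
the transformation directly from the symmetric invariants instead of
passing through the (there-undefined) $\rho$, and no spurious error is
raised at the crossing.

`classify_forms()` fits each transformed rate against a five-form library
(constant, $kc$, $kc+K$, $Fc/(H+c)$, $F(c-r)^2/(H+c)$) by exact
interpolation on support points followed by a full-grid relative-residual
check at $10^{-8}$; anything else is reported `unclassified` with its
residuals, never forced. The closed-form constants of the named schemes
(e.g. $\tilde H_{12} = k_{23}k_{32}/(k_{13}k_{31})$ for one activating
site, or $\tilde k_{32}=k_{32}$, $\tilde K_{32}=k_{31}$ for the
activating/inhibitory scheme) serve as oracles in the tests, pinned at
$10^{-9}$ relative tolerance. For the activating/inhibitory scheme only the
internally consistent printed constants are pinned; the offsets of
$\tilde q_{12}$ are classified but not cross-checked against a printed form
whose right-hand side refers to a rate the star model does not have.

The "unexpected dependency" report encodes a sequential-binding reading of
the chain: forward transitions may be ligand-dependent but should vanish at
$c=0$; backward (unbinding-like) transitions should be constant. Deviations
— the mass-action $\tilde q_{21}$ under two activating sites is the
canonical example — are the observable fingerprint of a chain obtained by
reparametrising a star.

## Simulator and empirical cross-validation

`simulate_dwells()` performs exact jump simulation (exponential holding
times, categorical successors; a small C++ kernel keeps $10^5$-event
sequences in milliseconds) and merges same-class sojourns, which preserves
total elapsed time exactly. Sequences start with an open dwell, the initial
state drawn from the open-class entry distribution so the dwell process is
stationary from the first event. Every function that consumes randomness
takes an explicit seed and restores the caller's RNG state; there is no
hidden global state. `mixture_sample()` draws dwell pairs from bivariate
coefficients directly, with rejection sampling against the
$|A|$-mixture envelope when coefficients are signed (an all-pairs density
that goes negative is rejected as non-realizable).

`compare_dwells()` uses per-class two-sample ecdf sup-distances against the
asymptotic critical value $c(\alpha)\sqrt{(n+m)/nm}$,
$c(\alpha)=\sqrt{-\log(\alpha/2)/2}$, at the 1% level by default with
$10^5$ events — enough power, in the test suite, to accept equivalent
reparametrisations and reject a 20% perturbation of the open exit rate.

## Synthetic data: what the generator does and does not emulate

Random fixtures draw rates i.i.d. log-uniform on $[10^{-2}, 10^2]$ — two
decades either side of unit rate, the spread between "fast" and "slow"
gating transitions that motivates multi-state models in the first place —
over full, star, chain or random-connected topologies. Signed-mixture
examples are found by rejection on the classification. This emulates the
*mathematical* situation the theory addresses (well-separated time scales,
arbitrary wiring), not real patch-clamp data: there is no recording noise,
no missed brief events, no sampling discretization, and no modal gating.
Passing tests therefore certify the algebra and the sampling distributions,
not robustness to the artefacts of real recordings, which are explicit
non-goals.

## Numerical choices and problem sizes

* Structural identities (row sums, marginalization constraints) are held to
  $10^{-10}$–$10^{-9}$ relative; spectral comparisons to $10^{-9}$;
  simulation comparisons to 3 standard errors or the stated KS level.
* Signed mixtures are accepted as distributions only if their density is
  non-negative on a 1000-point geometric grid spanning
  $[10^{-3}/\max\text{rate},\, 10/\min\text{rate}]$.
* Rates solved from invariant equations are snapped to exact zero below
  $10^{-12}$ of the rate scale, so topology predicates (edge reversibility,
  tree-ness) see the intended wiring rather than roundoff.
* Equivalence tolerance defaults to $10^{-9}$ relative and is an explicit
  argument everywhere.
* The test suite sizes are chosen to keep the default run around a minute:
  200 fixtures for the three-state dichotomy and invariance sweeps, 100 for
  BKU, 20 random constant sets per ligand scheme, $10^5$-event dwell
  sequences (and $2\times10^5$ for the long-run occupancy check on six
  fixtures). These sizes gave comfortable statistical margins; nothing in
  the methodology depends on them.

## Known limitations

* Enumeration stops at $n = 12$ states and does not split counts by the
  number of open versus closed states, nor construct the topologies it
  counts.
* Equivalence testing assumes diagonalizable within-class blocks and equal
  class sizes after reduction; models with coincident eigenvalues across
  classes are flagged, not resolved.
* The rank-refined identifiability criterion is reported only through the
  interconductance rank itself.
* Fitting models to experimental records (likelihoods, MCMC, missed-event
  corrections) is out of scope; the package analyses models, not data.
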