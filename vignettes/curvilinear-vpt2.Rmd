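---
title: "Anharmonic vibrational energies by VPT2 in curvilinear internal coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anharmonic vibrational energies by VPT2 in curvilinear internal coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvib)
```

## The model

Second-order vibrational perturbation theory (VPT2) computes anharmonic
transition energies from a quartic expansion of the potential around a
stationary geometry.  In the customary Cartesian (rectilinear) formulation
the kinetic-energy operator is diagonal and rotation–vibration interaction
enters through Coriolis terms.  When the expansion is carried out in
curvilinear internal coordinates (bonds, valence angles, dihedrals), the
kinetic operator acquires a coordinate-dependent metric **g** that must be
expanded alongside the potential.  In dimensionless normal coordinates
$q_i$ with conjugate momenta $p_i$ (everything in cm$^{-1}$):

$$
H = \tfrac12 \sum_i \omega_i (p_i^2 + q_i^2)
  + \underbrace{\tfrac16 \sum_{ijk} f_{ijk}\, q_i q_j q_k
  + \tfrac12 \sum_{ijk} g_{ij,k}\, p_i q_k p_j}_{H_1}
  + \underbrace{\tfrac1{24} \sum_{ijkl} f_{ijkl}\, q_i q_j q_k q_l
  + \tfrac14 \sum_{ijkl} g_{ij,kl}\, p_i q_k q_l p_j}_{H_2}
$$

where $f$ are the cubic/quartic force constants and $g_{ij,k}$,
$g_{ij,kl}$ the first and second derivatives of the wavenumber-scaled
metric, which satisfies $g_{ij} = \omega_i \delta_{ij}$ at equilibrium.
The momenta flank the coordinate factors (the symmetrized ordering the
Podolsky construction produces); the test suite demonstrates that the
spectrum is sensitive to this ordering, so the oracle and the closed forms
must — and do — share it.  The purely quantum-mechanical extra-potential
term is a constant to the accuracy relevant here and is dropped; the
zero-point energy cancels from all transition energies and is never
reported.

Second-order Rayleigh–Schrödinger theory then gives state energies of the
customary form
$\epsilon(v) = \sum_i \omega_i (v_i + \tfrac12) + \sum_{i \le j} \chi_{ij}
(v_i + \tfrac12)(v_j + \tfrac12)$.
The anharmonicity matrix $\chi$ is the sum of a potential, a kinetic and a
cross contribution (`chi_components()`).  All closed forms in this package
were (re-)derived symbolically from the Hamiltonian above and are verified
two independent ways in the test suite:

* the *component route* (raw second-order expressions with compound
  denominators) and the *recast route* (below) agree to machine precision
  on random systems;
* both agree with a brute-force sum-over-states oracle
  (`sum_over_states_pt2()`) to better than $10^{-6}$ cm$^{-1}$ for
  potential-only, kinetic-only and mixed couplings.

## The recast: $\eta$, $\sigma$, $\rho$

Partial-fraction decomposition collapses every $\chi$ entry into simple
resonance denominators built from three derived tensors
(`derived_tensors()`):

$$
\rho_{ij;k} = f_{ijk} - g_{ij,k} + g_{ik,j} + g_{jk,i}, \qquad
\sigma_{ijk} = f_{ijk} - g_{ij,k} - g_{ik,j} - g_{jk,i},
$$
$$
\eta_{iikk} = f_{iikk} + g_{ii,kk} + g_{kk,ii} \quad
(\eta_{iiii} = f_{iiii} + 2\, g_{ii,ii}).
$$

$\rho_{ij;k}$ is exactly the amplitude combination coupling a state that
gains one quantum in modes $i, j$ and loses one in mode $k$: it multiplies
every Fermi-resonant denominator
($2\omega_i - \omega_k$ and $\omega_i + \omega_j - \omega_k$) and the
variational interaction elements.  $\sigma$ (fully symmetric) multiplies
the anti-resonant denominators $\omega_i + \omega_j + \omega_k$.  With all
kinetic derivatives zero, $\rho = \sigma = f_3$ and $\eta = f_4$, and the
Cartesian expressions are recovered exactly once the Coriolis term
$\chi^{\mathrm{Cor}}_{ij} = \sum_\alpha B_\alpha^e (\zeta^\alpha_{ij})^2
(\omega_i/\omega_j + \omega_j/\omega_i)$ is added — an identity the
acceptance tests check verbatim.  Because each recast term carries an
explicit resonance identity, deperturbation (DVPT2) is bookkeeping: the
offending terms are removed and registered, and re-adding the registry
restores full VPT2 bit-for-bit.

## Fermi resonances and the variational step

`martin_test()` screens type I ($2\omega_i \approx \omega_k$) and type II
($\omega_i + \omega_j \approx \omega_k$) candidates in two steps: a
detuning filter $\Delta \le \Delta\omega^{1\text{–}2}$ (default 200
cm$^{-1}$) and a strength filter $\rho_{iik}^4/(256\Delta^3) \ge
K^{1\text{–}2}$ (type I; $64$ replaces $256$ for type II; default 1
cm$^{-1}$).  Because the test acts on $\rho$, the same machinery serves
both frames ($\rho = f_3$ in the Cartesian one).  An exactly degenerate
candidate is auto-accepted.  Accepted resonances are deperturbed and the
connected states closed transitively into polyads (`build_polyads()`);
each polyad matrix carries the DVPT2 energies on the diagonal and the
ladder-algebra interaction elements
$\langle v{+}2_i|\tilde H|v{+}1_k\rangle = \tfrac{\rho_{iik}}4
\sqrt{(v_i{+}1)(v_i{+}2)(v_k{+}1)/2}$ (and the analogous type-II element)
off the diagonal; its eigenvalues are the GVPT2 energies, assigned by
dominant eigenvector component with a deterministic low-index tie break.

A second-order contact-transformation correction to these off-diagonal
elements is implemented as an explicit, exact sum over intermediate states
(`interaction_element(aux = TRUE)`); for Fermi-type (odd) couplings it
vanishes identically by parity — two actions of the odd $H_1$ can only
connect states whose total quantum numbers differ by an even number — so
the leading-order elements are complete at this order.  Couplings where
the correction would be nonzero (1–1 and 2–2 Darling–Dennison) are outside
this package's scope.

## From a potential-energy surface to the force field

The pipeline (`gvpt2()`) needs only Cartesian gradients and Hessians from
a pluggable engine adapter (`pes$eval(geometry)`); nothing else is asked
of the electronic-structure side.

1. **Coordinates.** `detect_primitives()` builds the primitive internals
   from the topology (bonds within 1.3 × covalent-radius sum — a standard
   heuristic, configurable).  Valence angles beyond 175° are replaced by a
   pair of orthogonal linear-angle coordinates $p_{1,2} \cdot (\hat u +
   \hat v)$, with the perpendicular axes fixed deterministically from the
   reference geometry (the Cartesian axis least aligned with the a–c
   direction, Gram–Schmidt orthogonalized).  This construction is this
   package's own convention; any smooth non-degenerate pair spans the same
   space.  B and B′ are exact: coordinate values are evaluated in a
   truncated second-order Taylor arithmetic, so their first and second
   Cartesian derivatives are analytic to machine precision for every
   coordinate kind (the test suite checks them against finite differences
   and closed forms).

2. **Harmonic problem.** `gf_solve()` symmetrizes the GF problem by
   diagonalizing G, discarding eigenvalues below $10^{-8}$ of the largest
   (redundancies — the threshold is relative, hence scale-free), and
   diagonalizing $G^{1/2} F G^{1/2}$ on the remainder.  Mode signs are
   fixed so the largest component of each mode is positive; every
   downstream quantity is invariant under sign flips, mode reordering and
   the (arbitrary) orientation of the redundancy-free basis.

3. **Surface.** 2M+1 engine jobs: the reference plus ±δQ displacements
   along each mode, with δQ = 0.02 amu$^{1/2}$ Bohr for all coordinate
   kinds.  Curvilinear displacements are imposed in the internal values
   and back-transformed iteratively (damped with step-halving; residual
   below $10^{-10}$).  Results can be archived as versioned JSON with
   full-precision numbers; reruns skip completed jobs and recompute only
   corrupted entries.  The archive also pins the normal-mode basis: the
   eigenbasis of a redundancy-reduced G matrix with near-degenerate
   eigenvalues is not stable under $10^{-10}$ geometry perturbations, so a
   replay must displace along exactly the archived modes.

4. **Transformation and differencing.**  Displaced Hessians are taken to
   internal coordinates via
   $F = (B^+)^T P (H_x - \sum_i g_{s,i} B'_i) P B^+$ with the symmetric
   projector $P = B^+ B$ (both translations *and* rotations are factored
   out; at non-stationary geometries this choice matters and is validated
   against the analytic internal Hessian of the model surfaces).  Cubic
   constants come from antisymmetric differences of the dimensionless
   normal-coordinate Hessian, averaged over the three displacement roles;
   semi-diagonal quartics from symmetric second differences.  First metric
   derivatives $g_{ij,k}$ are analytic (chain rule through the G′ tensor);
   second derivatives are finite differences of those analytic first
   derivatives over the same displaced geometries — this avoids the
   third-derivative B″ tensor entirely.  All estimates converge as
   $O(\delta Q^2)$; for potentials exactly quartic in a single internal
   coordinate the differences are exact.

## Validation strategy and what it shows

The engine-free model potentials make the full workflow testable at desk
scale:

* **Morse diatomic** (default benchmark parameterized like carbon
  monoxide: $D = 0.4035\,E_h$, $a = 1.2304$ Bohr$^{-1}$, $r_e = 2.132$
  Bohr, giving $\omega_e \approx 2170$, $\omega_e x_e \approx 13.3$
  cm$^{-1}$).  VPT2 is exact for a Morse potential, so the pipeline
  fundamental must equal $\omega_e - 2\omega_e x_e$: it does to
  $10^{-9}$ cm$^{-1}$ with analytic derivatives and to $\sim 0.007$
  cm$^{-1}$ through the δQ = 0.02 finite differences.  The residual is
  pure $O(\delta Q^2)$ truncation and grows with $\omega_e x_e/\omega_e$;
  an HF-like parameterization ($\omega_e x_e \approx 91$ cm$^{-1}$) shows
  $\approx 0.3$ cm$^{-1}$.
* **Synthetic bent triatomic**: a quartic polynomial in the internal
  coordinates of a water-like frame with exact Cartesian derivatives by
  chain rule.  Cartesian- and curvilinear-frame GVPT2 fundamentals agree
  within 0.02 cm$^{-1}$ — far inside the 2 cm$^{-1}$ one can expect for a
  semi-rigid molecule — and the two-mode-restricted curvilinear treatment
  loses less accuracy than the Cartesian one, the motivation for
  reduced-dimensionality variants (`restrict_coupling_order()`).
* **Sum-over-states and FVCI oracles**: explicit Hamiltonian matrices in
  a harmonic-oscillator product basis (default 20 quanta per mode for 2
  modes, 12 for 3; doubling the basis changes the reported oracle
  energies by less than $10^{-8}$ cm$^{-1}$ for the fixtures used).  For a
  weak Fermi pair (detuning 30 cm$^{-1}$, $\rho_{112} = 60$ cm$^{-1}$)
  the GVPT2 polyad eigenvalues track full variational diagonalization to
  better than $0.01$ cm$^{-1}$.

What these fixtures do **not** emulate: electronic-structure noise in the
Hessians, exact symmetry-induced degeneracies of linear/symmetric/
spherical tops (degenerate pairs are caught by the detuning filter as
$\Delta \approx 0$ auto-accepted resonances, but the a posteriori
transformations that restore exact top degeneracy patterns are not
implemented — such results are approximate), large-amplitude motions
requiring non-perturbative treatment, and intensities.  Passing tests
demonstrate the correctness of the perturbative machinery, not the
quality of any particular electronic-structure method.

## Dual-level composition

`add_scheme()` shifts high-level harmonic transition energies by the
low-level anharmonic correction $\nu^L - \omega^L$; `sub_scheme()` re-runs
the entire VPT2/DVPT2/GVPT2 machinery with the high-level frequencies in
every denominator and harmonic term while keeping the low-level force
field and kinetic derivatives.  The Martin test is re-evaluated with the
substituted frequencies — denominator consistency demands it — so the
accepted resonance set may legitimately differ between levels; both
coincide with the low-level result when $\omega^H = \omega^L$ (tested).
Across levels, modes are matched by maximum-overlap optimal assignment
(Hungarian algorithm on the mode-overlap magnitudes), which survives
near-degenerate reorderings that break frequency-order matching.

## Numerical choices and degenerate inputs

* Null-space threshold for redundant G: $10^{-8}$ relative.
* A resonant denominator below $10^{-6}$ cm$^{-1}$ that is not deperturbed
  is a hard error naming the resonance — silent blow-ups are the classic
  VPT2 failure mode.  A vanishing numerator silences the term instead.
* Plain valence angles at 0 or π refuse evaluation and point to the
  linear-angle kind; dihedrals live on $(-\pi, \pi]$ and displaced values
  are unwrapped continuously against the reference so finite differences
  never cross the branch cut.
* Imaginary harmonic frequencies abort the anharmonic treatment.
* The back-transformation of curvilinear displacements damps by
  step-halving on divergence and errors out after 100 iterations.
* All tabulated output is in cm$^{-1}$ at one decimal, in the column
  order $\omega$ / VPT2 / DVPT2 / GVPT2.

## Known limitations

Darling–Dennison (1–1, 2–2) resonances are not treated variationally;
VPT4 and higher-order force fields are out of scope; rotational analysis
is limited to the equilibrium constants the Coriolis terms need; the
reference geometry is assumed stationary (geometry optimization is the
engine's job).  Archives written by future format versions are refused
rather than guessed at.
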