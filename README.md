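# curvib

Anharmonic vibrational transition energies of molecules by generalized
second-order vibrational perturbation theory (GVPT2), formulated either in
the customary Cartesian normal coordinates (with Coriolis couplings) or in
**curvilinear internal coordinates** with a perturbatively expanded
kinetic-energy operator.

The package is aimed at computational spectroscopists who have (or can
model) analytic Hessians and want anharmonic wavenumbers beyond the
harmonic approximation for semi-rigid molecules: fundamentals, overtones
and combination bands, with Fermi resonances detected, deperturbed and
treated variationally, and with dual-level (Add/Sub) composition of a
high-level harmonic description with low-level anharmonic corrections.
Curvilinear coordinates strongly reduce inter-mode couplings, which makes
low-order perturbation theory — and reduced-dimensionality truncations of
it — far more robust, notably for soft torsional modes.

## The model in brief

In dimensionless normal coordinates the vibrational Hamiltonian is

    H = 1/2 Σ ω_i (p_i² + q_i²)
      + 1/6 Σ f_ijk q_i q_j q_k   + 1/2 Σ g_ij,k  p_i q_k p_j
      + 1/24 Σ f_ijkl q_i…q_l     + 1/4 Σ g_ij,kl p_i q_k q_l p_j

where `f` are cubic/quartic force constants and `g_ij,k`, `g_ij,kl` the
derivatives of the wavenumber-scaled Wilson metric (identically zero in
the Cartesian frame, where Coriolis ζ-terms appear instead).  Second-order
perturbation theory yields state energies
`ε(v) = Σ ω_i (v_i + ½) + Σ χ_ij (v_i + ½)(v_j + ½)`.
The χ matrix is assembled from three derived tensors,

    ρ(ij;k) = f_ijk − g_ij,k + g_ik,j + g_jk,i      (resonant combination)
    σ_ijk   = f_ijk − g_ij,k − g_ik,j − g_jk,i      (anti-resonant)
    η_iikk  = f_iikk + g_ii,kk + g_kk,ii

so that the curvilinear theory has exactly the Cartesian form (ρ = σ = f,
η = f₄ when the metric is constant).  Fermi resonances
(2ω_i ≈ ω_k, ω_i + ω_j ≈ ω_k) are screened by the two-step Martin test on
ρ (detuning ≤ 200 cm⁻¹, strength ρ⁴/256Δ³ resp. ρ⁴/64Δ³ ≥ 1 cm⁻¹),
removed from the χ sums (DVPT2), and the coupled states re-diagonalized in
small polyad matrices (GVPT2).  Force fields are assembled from 2M+1
analytic Hessians at geometries displaced by δQ = 0.02 amu^½ Bohr along
the normal modes; metric derivatives come from the analytic Wilson
B/B′/G/G′ tensors, never from a third-derivative B″.

## Worked example

A synthetic bent triatomic with a quartic internal-coordinate potential
(exact Cartesian derivatives by chain rule through B and B′):

```r
library(curvib)
geom <- geometry(c("O", "H", "H"),
                 rbind(c(0, 0, 0), c(1.81, 0, 0), c(-0.45, 1.75, 0)))
pes <- synthetic_polyatomic(geom,
  F2 = matrix(c(0.45, 0.02, 0.01,
                0.02, 0.48, 0.015,
                0.01, 0.015, 0.12), 3, 3),
  cubic = list(list(idx = c(1, 1, 1), value = -0.9),
               list(idx = c(2, 2, 2), value = -0.95),
               list(idx = c(1, 2, 3), value = -0.05)),
  quartic = list(list(idx = c(1, 1, 1, 1), value = 1.4),
                 list(idx = c(2, 2, 2, 2), value = 1.5)))
fit <- gvpt2(pes, geom = geom, frame = "curvilinear")
print(fit)
```

```
GVPT2 anharmonic transitions (curvilinear frame), cm^-1
 assignment  omega   VPT2  DVPT2  GVPT2
        nu1 1435.9 1430.4 1430.4 1430.4
        nu2 3520.4 3462.3 3462.3 3462.3
        nu3 3671.5 3622.3 3622.3 3622.3
       2nu1 2871.9 2853.0 2853.0 2853.0
       2nu2 7040.8 6877.2 6877.2 6877.2
       2nu3 7343.0 7203.1 7203.1 7203.1
    nu1+nu2 4956.4 4892.1 4892.1 4892.1
    nu1+nu3 5107.4 5057.8 5057.8 5057.8
    nu2+nu3 7191.9 7063.7 7063.7 7063.7
0 Fermi resonance(s) accepted by the Martin test
```

`omega` are the harmonic wavenumbers of each transition; the VPT2 column
adds the full second-order anharmonic correction; DVPT2 removes resonant
terms (here none are accepted, so the columns coincide); GVPT2 adds the
polyad variational correction.  The bend fundamental drops by 5.5 cm⁻¹ and
the stretches by ~50–58 cm⁻¹, as expected for the planted cubic/quartic
constants.

VPT2 is exact for a Morse oscillator — a sharp end-to-end check of the
whole finite-difference pipeline:

```r
pm <- morse_diatomic(D = 0.4035, a = 1.2304, r_e = 2.132,
                     masses = c(12, 15.99491462), symbols = c("C", "O"))
fitm <- gvpt2(pm, geom = pm$geom, states = list(1L))
cat(sprintf("Morse: GVPT2 %.3f vs exact %.3f cm^-1\n",
            fitm$table$gvpt2, pm$we - 2 * pm$wexe))
#> Morse: GVPT2 2143.337 vs exact 2143.343 cm^-1
```

Real engines plug in through the adapter contract: any object with an
`eval(geometry)` function returning `energy`, `gradient`, `hessian`
(hartree, Bohr) works, and surfaces are cached in a versioned JSON archive
(`archive =` argument) that supports idempotent restarts and command-line
replay (`inst/cli/gvpt2_run.R`).

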