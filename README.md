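# mtexciton

Collective ultraviolet excitation dynamics in microtubule tryptophan
networks.

## The problem

Tubulin dimers each carry eight tryptophan residues whose $\pi\to\pi^*$
transitions near 280 nm couple through the shared electromagnetic vacuum.
Packed into a microtubule lattice — 13 dimers per circumferential turn,
8 nm axial rise — these chromophores sit far inside the radiative
wavelength ($k_0 r \ll 1$), so they do not emit independently: the network
develops *superradiant* collective modes that dump excitation into the
field faster than a lone tryptophan, and *subradiant* modes that hold it
for orders of magnitude longer.  Whether such networks can transiently
store and route quantum correlations is a live question in quantum
biology.

`mtexciton` is for researchers who want to model this regime
quantitatively: it builds dipole networks from site tables, synthetic
lattice templates or PDB structures, constructs the coupling and
collective-decay matrices from the exact dipole kernels, and follows both
the spectral picture (non-Hermitian eigenmodes, radiative lifetimes) and
the full open-system dynamics (trace-preserving Lindblad evolution with
collective jump operators), together with the quantum-information
measures used to track where coherence goes.

## The model

For sites with positions $\mathbf r_n$ and unit dipoles $\hat\mu_n$
(separation phase $\alpha = k_0 r_{nm}$, $k_0 = 2\pi/\lambda_0$,
$\lambda_0 = 280$ nm), the coherent coupling and collective decay kernels
are

$$\Delta_{nm} = \frac{3\gamma}{4}\left[\left(-\frac{\cos\alpha}{\alpha}
 + \frac{\sin\alpha}{\alpha^{2}} + \frac{\cos\alpha}{\alpha^{3}}\right)
 \hat\mu_n\cdot\hat\mu_m
 - \left(-\frac{\cos\alpha}{\alpha} + \frac{3\sin\alpha}{\alpha^{2}}
 + \frac{3\cos\alpha}{\alpha^{3}}\right)
 (\hat\mu_n\cdot\hat r)(\hat\mu_m\cdot\hat r)\right]$$

$$G_{nm} = \frac{3\gamma}{2}\left[\left(\frac{\sin\alpha}{\alpha}
 + \frac{\cos\alpha}{\alpha^{2}} - \frac{\sin\alpha}{\alpha^{3}}\right)
 \hat\mu_n\cdot\hat\mu_m
 - \left(\frac{\sin\alpha}{\alpha} + \frac{3\cos\alpha}{\alpha^{2}}
 - \frac{3\sin\alpha}{\alpha^{3}}\right)
 (\hat\mu_n\cdot\hat r)(\hat\mu_m\cdot\hat r)\right]$$

with $G_{nn} = \gamma$.  Diagonalizing
$H_{\rm eff} = \mathrm{diag}(H_0) + \Delta - \frac{i}{2}G$ yields complex
eigenvalues $E_j - \frac{i}{2}\Gamma_j$: modes with $\Gamma_j/\gamma > 1$
are bright (superradiant), $\Gamma_j/\gamma < 1$ dark (subradiant), and
$\tau_j = 1/(2\pi c\,\Gamma_j)$ converts rates in cm$^{-1}$ to lifetimes.
Open-system dynamics run on the ground-sink $\cup$ single-excitation
space under the Lindblad master equation whose collapse operators are the
collective channels of $G$.  Metrics: L1 coherence, correlated coherence
between composite subsystems, logarithmic negativity, mutual information,
and the trace-distance backflow measure of non-Markovianity on reduced
two-tubulin subsystems.

## Worked example

```r
library(mtexciton)

net <- make_fixture("pseudo_dimer")   # synthetic 8-Trp dimer template
cs  <- coupling_set(net)              # Delta, G in units of gamma
m   <- eigenmodes(cs)
m
#> mode_set: 8 modes; 4 bright, 4 dark (threshold Gamma/gamma = 1)
#>   Gamma_max/gamma = 3.0291  Gamma_min/gamma = 0.0037195

round(m$ratio, 5)
#> [1] 3.02915 2.44013 1.17967 1.11061 0.13512 0.05560 0.04600 0.00372
```

Eight coupled tryptophans split into four bright modes — the brightest
decays 3.03 times faster than an isolated site — and four dark modes, the
darkest 269 times slower.  A uniform in-phase excitation starts with the
maximal L1 coherence $N - 1 = 7$ and drains its bright component first:

```r
psi0 <- make_initial_state("uniform_coherent", N = 8)
l1_coherence(psi0)
#> [1] 7

traj <- lindblad_propagate(cs, psi0, seq(0, 2, length.out = 81))
proj <- mode_projections(traj, m)
proj$crossover_time      # first time dark weight exceeds bright weight
#> [1] 1.275
```

(time in units of $1/\gamma$).  On a full 13-dimer spiral, preparing
orthogonal states on two tubulins and tracing out the other eleven shows
information flowing back from the structured environment:

```r
sp   <- build_assembly(build_dimer_template(), "spiral", n_spirals = 1)
part <- partition_network(sp, "tubulin")
pair <- contrast_pair_states(part, k = 2, "phase", N = n_sites(sp))
ts   <- seq(0, 0.015, length.out = 121)
t1   <- lindblad_propagate(coupling_set(sp), pair[[1]], ts, rtol = 1e-10, atol = 1e-12)
t2   <- lindblad_propagate(coupling_set(sp), pair[[2]], ts, rtol = 1e-10, atol = 1e-12)
backflow_measure(t1, t2, subsystem = c(part$groups[[1]], part$groups[[2]]))
#> backflow_result: N = 0.72417 over 121 grid points; D(0) = 1
```

The two reduced states start perfectly distinguishable ($D(0)=1$) and
their trace distance revives repeatedly: the accumulated backflow
$N = 0.72$ witnesses non-Markovian memory in the surrounding tubulins,
while the same protocol on the full (untraced) system gives $N = 0$
exactly, as it must for CP-divisible dynamics.

Higher-level drivers (`cmd_build`, `cmd_modes`, `cmd_evolve`,
`cmd_backflow`, `cmd_scan`) run these pipelines from a config list or
JSON file and write tidy CSV outputs plus a run manifest.

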