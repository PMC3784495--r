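# freqresp

Frequency-response analysis of periodically perturbed molecular
dynamics trajectories.

## The problem

Local conformational signals — a flexible loop closing over an active
site, a ligand docking — propagate through a protein via backbone
connectivity and nonbonded contacts, but in an equilibrium trajectory
that propagation is buried under thermal noise. If instead the local
region is *driven periodically* between two conformations (e.g. with a
targeted-MD restraint whose target alternates every half-period), every
variable reached by the signal acquires excess spectral power at the
forcing frequency `f_b`, sitting on top of the `1/f`-like background of
atomic fluctuations. That turns signal-propagation mapping into a
sequence of well-posed statistical operations, which this package
implements for structural bioinformaticians and simulation analysts:

1. **Spectral densities** of atomic variables (coordinates, dihedrals,
   polar-contact distances) via the DFT, normalized so the components
   sum to the mean square fluctuation (Parseval):
   `P_k = 2|X_k|² / N²`.
2. **Detection**: a least-squares line is fitted to the log-log
   spectrum (excluding the lowest components) and a variable is flagged
   as perturbed when its power at `f_b` exceeds the one-sided
   Student-t upper prediction limit
   `L = ŷ(x₀) + t₁₋α s √(1 + 1/n + (x₀ − x̄)²/Sxx)`.
3. **Phase clustering**: each flagged variable's band-reconstructed
   signal `a·cos(2πkn/N + φ)` yields a phase folded to `[0, π)` and
   embedded on the `(cos 2θ, sin 2θ)` plane, where collectively moving
   variables cluster (quadrant bins of width π/4, or seeded k-means).
4. **Collective displacement**: PCA of the band-reconstructed
   coordinate matrix gives one eigenvector `p` and per-atom
   peak-to-peak amplitudes `R_i = 2 a_s ‖p_i‖`, compared with an
   experimental structure-pair displacement `d` by overlap
   `|p·d|/(‖p‖‖d‖)` and Pearson correlation of amplitudes.
5. **Lead-lag (Bode) characterization** across forcing frequencies:
   `AR(ω) = K_p √((τ_z ω)² + 1)/√((τ_p ω)² + 1)`, fitted on the dB
   scale, with breakpoint `ω_c = 1/τ_p` separating transmitted from
   attenuated forcing.

A synthetic-data module (seeded `1/f^β` noise with planted sinusoids,
rotamer-jump circular variables, forcing schedules, and a coarse-grained
restrained-TMD Langevin network simulator) generates every input the
pipeline needs, so everything below runs with no external data.

## Worked example

Drive a 6-bead loop of a 60-bead network between two conformations
every 1.25 ns for 30 ns, then ask which beads received the signal:

```r
library(freqresp)
spec <- toy_network_spec(schedule = target_schedule(2500, 12, 1), seed = 1)
sim  <- toy_tmd_simulate(spec)
sim$traj
#> trajectory_ensemble: 30000 frames x 60 atoms, dt = 1 ps

dens <- lapply(1:60, function(b) power_spectrum_group(
  lapply(c("x", "y", "z"), function(ax) coordinate_series(sim$traj, b, ax)),
  id = sprintf("bead%02d", b)))
tab <- scan_variables(dens, f_b = spec$schedule$f0)   # f_b = 0.4 ns^-1
sum(tab$flag05); sum(tab$flag01)
#> 53 of 60 beads perturbed at alpha = 0.05; 36 at alpha = 0.01
tab[spec$restrained[1:3], c("id", "msf", "excess", "flag05", "flag01")]
#>        id       msf   excess flag05 flag01
#> 28 bead28 0.4673112 3.815322   TRUE   TRUE
#> 29 bead29 0.5390758 4.217239   TRUE   TRUE
#> 30 bead30 0.5277783 4.067738   TRUE   TRUE
```

`excess` is log10 power at `f_b` above the fitted baseline — the driven
beads sit ~4 decades above the 1/f background, and 53/60 beads receive
the signal. The collective in-phase motion, summarized by one
eigenvector, predicts the per-bead displacement; comparing against
"experimental" structure pairs drawn from the two schedule extremes:

```r
k_b <- 12
recon <- do.call(cbind, lapply(1:60, function(b)
  vapply(c("x", "y", "z"), function(ax)
    band_reconstruct(coordinate_series(sim$traj, b, ax), k_b)$series,
    numeric(n_frames(sim$traj)))))
summ <- inphase_summary(recon, k_b, sim$truth$forcing$phase)
summ
#> inphase_summary: 60 atoms, score amplitude 3.729 A,
#>                  phase -0.151 rad, 80.1% explained

sched <- schedule_series(spec$schedule)$values
setA <- lapply(which(sched < 0.02)[seq(1, 600, 20)],
               function(f) structure_model(sim$traj$xyz[f, ]))
setB <- lapply(which(sched > 0.98)[seq(1, 600, 20)],
               function(f) structure_model(sim$traj$xyz[f, ]))
compare_structures(setA, setB, summ)[c("overlap", "correlation")]
#> overlap: 0.902   correlation: 0.89
```

The predicted collective displacement direction agrees with the
end-state structure difference (overlap 0.90) and so does the per-bead
amplitude pattern (r = 0.89). Finally, the frequency dependence of one
driven bead across six forcing periods fits a lead-lag transfer
function:

```r
res <- run_bode(c(100, 250, 500, 1000, 2500, 5000),
                toy_network_spec(schedule = target_schedule(1250, 8, 1),
                                 seed = 1), atoms = 30)
subset(res$fits, id == "atom30.y")
#>         id      K_p    tau_z   tau_p        R2                class
#> 2 atom30.y 1.776684 35.81591 37.4758 0.9613459 leadlag_lag_dominant
```

i.e. this coordinate follows the forcing with a ~37 ps lag constant;
forcing faster than `w_c = 1/τ_p ≈ 27 rad/ns` would be attenuated.

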