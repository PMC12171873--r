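# igmepath

Kinetics of membrane transporters from molecular-dynamics trajectories:
non-Markovian state models plus neural-map detection of ligand egress
pathways.

Conformational changes of transporters (outward-open ↔ inward-open
gating, sidechain rotamer switches that block or open the tunnel) are
slow compared with affordable simulation time, and any practical
discretization of the conformational space is *lumped* — so the observed
state-to-state dynamics carries memory and a plain Markov state model
(MSM) built at short lag times gets the slow kinetics wrong.  This
package addresses both problems for structural biologists analysing
transporter simulations.

## What it computes

**State-model leg.**  Features (χ1 dihedrals of gating residues,
inter-helix distances) → tICA projection → k-means microstates →
microstate MSM → PCCA+ metastable macrostates → an **integrative
generalized master equation (IGME)**, fitted as

> T(t) ≈ A · T̂ᵗ,  t > τk

by elementwise least squares in log-matrix space over the window
t ∈ {τk+1, …, τk+L}.  A is the integrated memory-kernel correction and
T̂ the corrected long-time propagator.  Hyperparameters (τk, L) are
scanned and ranked by RMSE against the estimated transition-matrix
series; the model is validated by a bootstrap Chapman–Kolmogorov test,
and summarized as mean first passage times, free energies
(ΔG = −k_B·T·ln π/π_max at 310 K), and transition-path-theory net-flux
pathways (committors, net flux f⁺ᵢⱼ = max(0, πᵢq⁻ᵢTᵢⱼq⁺ⱼ − πⱼq⁻ⱼTⱼᵢq⁺ᵢ),
bottleneck-ranked path decomposition) from the highest- to the
lowest-free-energy state.

**Pathway leg.**  Capped ligand–residue distances (12 Å cap) train a
10 × 10 non-periodic sheet self-organizing map (SOM, 5000 cycles);
neurons are Ward-clustered with the cluster count chosen by silhouette;
the directed neuron transition network (within-trajectory,
consecutive-frame BMU pairs) is condensed to cluster level, and egress
pathways from the bound to the unbound endpoint are ranked by bottleneck
weight, with per-trajectory pathway assignment and a per-cluster
ligand–residue distance heatmap (contacts < 4 Å flagged).

**Synthetic generators with analytic ground truth** make every stage
testable offline: a lumped hidden Markov chain (two fast-exchanging
pairs bridged by a slow hop — non-Markovian by construction, with exact
stationary/MFPT/timescale oracles), a 2-D Langevin ligand in a
two-branch exit channel with per-trajectory branch labels, and
constructed sidechain fragments with prescribed χ1 angles.

## Worked example

Recover the slow kinetics of a lumped hidden chain (0.1 ns/frame; the
2-state observation of a 4-state chain whose true slow timescale is
analytic):

```r
library(igmepath)

spec <- two_pair_chain_spec(seed = 42)           # hidden 4-state chain
sim  <- generate_hidden_chain(spec, n_traj = 10, n_frames = 100000)
ser  <- tpm_series(sim$trajectories, 60, n_states = 2)
scan <- scan_igme(ser, tau_k_grid = 0:9, L_grid = seq(5, 45, by = 5),
                  lag_unit = 0.1)
scan$best
#> igme_model: tau_k = 1 frames, L = 25 frames, fit RMSE = 5.034e-05
model_timescales(scan$best)[1]                   # IGME slow timescale
#> 10.136
sim$ground_truth$slow_timescales[1]              # analytic truth
#> 10.206
igmepath:::implied_timescales(ser[[1]], 0.1)[1]  # naive lag-1 MSM
#> 10.016
round(mfpt(scan$best), 2)                        # ns (truth: 20.25)
#>       [,1]  [,2]
#> [1,]  0.00 20.07
#> [2,] 20.69  0.00
ck_test(scan$best, sim$trajectories, c(10L, 20L, 40L), n_states = 2,
        seed = 42)
#> ck_report: PASS
#>   lag 10 : fraction inside interval 1
#>   lag 20 : fraction inside interval 1
#>   lag 40 : fraction inside interval 1
```

The IGME estimate (10.14 ns) sits within 0.7% of the analytic slow
timescale where the lag-1 MSM is biased fast, and its MFPTs bracket the
exact 20.25 ns.

Detect egress pathways in the synthetic two-branch channel:

```r
eg  <- generate_channel_egress(channel_spec(seed = 7))   # 200 ligands
ef  <- egress_features(eg)                               # capped, 12 A
som <- train_som(ef$features, cycles = 5000, seed = 7,
                 max_training_frames = 3000)
cl  <- cluster_neurons(som, 2:8)
net <- build_transition_network(som, ef$lengths)
ep  <- identify_endpoints(cl, cluster_heatmap(ef$features, som, cl), net)
extract_pathways(net, cl, som, ep$bound, ep$unbound, n_paths = 2)
#> pathway_set: 2 pathways 2 -> 3
#>    2 -> 1 -> 3  bottleneck 197  support 101
#>    2 -> 4 -> 3  bottleneck 160  support 116
```

Two pathways (bound cluster → one branch arm → unbound cluster), whose
per-trajectory assignments match the simulator's exit-branch labels for
over 95% of exiting ligands.

Both legs can also be driven from a YAML config via `run_state_model()`
/ `run_pathway_detection()` (artifacts written as TSV with provenance
headers), or from the shell through
`inst/scripts/igmepath-run.R`.  Reference parameter sets for the three
transporter systems this workflow targets ship in
`inst/extdata/reference_config.yaml`.

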