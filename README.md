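# ensdist

Distance-geometry analysis of protein conformational ensembles in R.

## What it is for

Peptide-binding modules such as PDZ domains couple ligand recognition to
conformational change, and two limiting mechanisms are commonly
distinguished: *conformational selection* (the apo protein spontaneously
visits bound-like conformations that the ligand selects) and *induced fit*
(the bound conformation becomes accessible only after ligand contact).
Deciding between them — and relating binding-pocket flexibility to binding
promiscuity — requires quantitative statistics over conformational ensembles
from molecular dynamics trajectories or multi-model PDB entries.

ensdist provides those statistics in superposition-free form. Every conformer
is reduced to its Cα–Cα distance matrix `d`, so all quantities are invariant
to rigid-body motion:

* **δ = d^A − d^B** — difference distance matrix localising structural change;
* **dRMSD(A,B) = sqrt(mean over i<j of (d^A_ij − d^B_ij)²)** — a
  superposition-free pseudometric between structures;
* **F** (per-pair distance variance, Å²) and **X** (per-pair distance range,
  Å) — fluctuation and flexibility matrices of an ensemble, with
  F ≤ X²/4 everywhere;
* **Θ = sqrt(mean off-diagonal F)** — overall fluctuation, identically the
  RMS dRMSD of frames to the ensemble mean distance matrix; the size of
  explored conformational space;
* **k-means in distance-matrix space** minimising the within-cluster sum of
  squared dRMSD (cluster centroid = mean distance matrix C_i), with the
  cluster count chosen by the maximal overall silhouette index S_OVER,
  medoids, outliers and classical-MDS 2D maps;
* **Q(k)** — mean dRMSD of the k ensemble frames nearest a ligand-bound
  reference; low Q(1), Q(10) signal conformational selection;
* **Δ** — mean absolute difference distance matrix against a reference over
  its nearest neighbours, localising binding-induced changes;
* cleft-width distance series with **1/2-component Gaussian fits** (BIC
  selection), **open-state fractions**, **dwell-time kinetics** of cluster
  label sequences, and **RMSIP** convergence checks between trajectory
  segments.

Seeded synthetic generators (idealised strand+helix pockets, harmonic and
Markov-switching ensembles, Gaussian-mixture cleft series) make every stage
testable end to end without external data.

## Worked example

```r
library(ensdist)
# idealised closed (6.3 A) and open (9.0 A) pocket references
closed <- make_reference_pocket(cleft_base_distance = 6.3)
open   <- make_reference_pocket(cleft_base_distance = 9.0)
# 2000-frame metastable ensemble switching between them
lab <- generate_two_state(closed, open, switch_prob = 0.02,
                          noise_sd = 0.08, K = 2000, dt = 5, seed = 7)
ens <- lab$ensemble
sel <- residue_selection(1:15, blocks = list(strand = 1:5, helix = 6:15))

overall_fluctuation(ens, sel)
#> Theta = 0.4336 A  (N = 15 residues, K = 2000 frames, scope = all_pairs)

sk <- select_k(ens, sel, k_range = 2:4, seed = 7)
sk$results[[paste0("k", sk$best_k)]]
#> dRMSD k-means: k = 2  sizes = 892/1108  WCSS = 25.36 A^2  S_OVER = 0.816

q_profile(ens, sel, reference = open, ks = c(1, 10, 100, 200))
#> Q profile vs reference pocket
#>     Q1    Q10   Q100   Q200
#> 0.0584 0.0714 0.0825 0.0876

fit_gaussians(cleft_distance_series(ens, "A5", "A6"))
#> 2-component Gaussian fit (n = 2000)
#>   mean 6.306 A  sd 0.113 A  weight 0.446
#>   mean 8.998 A  sd 0.115 A  weight 0.554

cluster_kinetics(sk$results$k2$labels, dt = 5)
#> Mean inter-cluster transition time: 261.6 ps (38 transitions)
```

Reading: the pocket explores a conformational volume of Θ ≈ 0.43 Å and splits
cleanly into two states (high silhouette, S_OVER = 0.82) whose populations
match the generator's hidden labels. Q(1) ≈ 0.06 Å says the ensemble visits
conformations nearly identical to the "open" reference — the
conformational-selection signature. The cleft width is bimodal at 6.3/9.0 Å
(the generator truth), and the mean dwell time of ~260 ps is close to the
dt/p = 250 ps expectation of the switching process.

For real data, `load_ensemble()` reads multi-model PDB or DCD+topology,
`select_binding_site()` resolves author-numbered strand/helix ranges, and
`run_pipeline()`/`report()` (or the thin CLI in `inst/cli/ensdist.R`) run all
stages from a YAML config into a manifest-tracked output directory. See the
vignette in `vignettes/distance-geometry-ensembles.Rmd` for the full model
description and conventions.

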