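---
title: "Distance-geometry analysis of conformational ensembles with ensdist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-geometry analysis of conformational ensembles with ensdist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdist)
```

## The problem

Proteins that recognise peptides — PDZ domains are the motivating family —
often couple binding to conformational change. Two limiting mechanisms are
distinguished: under *conformational selection* the unbound (apo) protein
spontaneously visits bound-like conformations which the ligand then selects;
under *induced fit* the bound conformation only becomes accessible after
initial ligand contact. Whether a binding pocket is rigid or flexible, whether
it interconverts between distinct metastable states, and how closely the apo
ensemble approaches known ligand-bound structures are therefore questions
about the *statistics of a conformational ensemble*, typically sampled by
molecular dynamics (MD) or collected from multi-model PDB entries.

ensdist answers these questions with distance geometry: every conformer is
reduced to its Cα–Cα distance matrix, so all statistics are invariant to
rigid-body motion and no structural superposition is ever needed. This
matters for flexibility analysis because superposition itself distorts
apparent mobility when part of the structure moves.

## Core quantities

For a conformer with residues $i, j$, let $d_{ij}$ be the Cα–Cα distance.
Given two structures $A$, $B$ over $N$ aligned residues:

* **Difference distance matrix** $\delta_{ij} = d^A_{ij} - d^B_{ij}$; positive
  entries mark pairs further apart in $A$.
* **dRMSD** $= \sqrt{\binom{N}{2}^{-1}\sum_{i<j}(d^A_{ij}-d^B_{ij})^2}$ — a
  superposition-free pseudometric (a scaled Euclidean norm on the vector of
  pair distances). The mean is taken over the $N(N-1)/2$ unordered pairs;
  summing over ordered pairs gives the identical value, so only this
  documented denominator choice is a convention.

For an ensemble $S = \{S_1,\dots,S_K\}$:

* **Fluctuation matrix** $F_{ij}$ = *population* variance (divide by $K$) of
  $d_{ij}$ across frames, in Å².
* **Flexibility matrix** $X_{ij} = \max_k d^{(k)}_{ij} - \min_k d^{(k)}_{ij}$,
  in Å — variance can stay small while rare excursions are large, and the
  range captures exactly those extremes. For any bounded variable the
  population variance obeys $F_{ij} \le X_{ij}^2/4$, which the test suite
  checks on every generated ensemble.
* **Overall fluctuation** $\Theta = \sqrt{\mathrm{mean}_{i<j} F_{ij}}$, which
  is *exactly* the root-mean-square dRMSD of the frames to the ensemble mean
  distance matrix. This identity is why $F$ uses the population variance: with
  the $K-1$ denominator the two definitions would disagree by a factor
  $\sqrt{(K-1)/K}$. The identity is asserted to $10^{-12}$ in the tests.
* **Mean absolute difference matrix** $\Delta_{ij}$ = mean over a frame subset
  of $|d^{(k)}_{ij} - d^{\mathrm{ref}}_{ij}|$ — applied to the nearest
  neighbours of a ligand-bound reference it localises which inter-residue
  distances change on binding.

### Binding-pocket scope

Pockets are selected by author residue numbering as two blocks — a β-strand
(canonically 5 residues) and a helix (canonically 10) — via
`select_binding_site()`. Pocket statistics can be restricted to the 5×10
strand×helix cross-submatrix (`cross_submatrix()`, `pair_scope =
"cross_block"` in `overall_fluctuation()`). The default $\Theta$ scope is
*all pairs within the selection*: it includes intra-block rearrangements and
is the more conservative summary; the cross-block scope is available because
pocket opening/closing lives almost entirely in the strand-to-helix
distances.

## Conformational states

Frames are clustered by k-means *in distance-matrix space*: each frame is
assigned to the cluster whose **mean distance matrix** $C_i$ it is closest to
in dRMSD, and the objective is the within-cluster sum of squared dRMSD
(WCSS). The centroid is the arithmetic mean of member distance matrices and
need not correspond to any realisable 3D structure; that is accepted because
the objective is defined in distance-matrix space, where it coincides with
ordinary Euclidean k-means on condensed pair-distance vectors (the test suite
uses `stats::kmeans` on those vectors as an independent oracle).

Numerical choices:

* **Initialisation** — greedy farthest-point seeding from a random first
  frame; `n_init = 10` seeded restarts, best WCSS kept; deterministic given
  `seed`.
* **Convergence** — assignments unchanged, or WCSS improvement below
  $10^{-10}$ Å²; WCSS is non-increasing across iterations and the trace is
  returned for audit.
* **Empty clusters** — re-seeded with the frame farthest from its centroid.
* **k = 1** — allowed as a degenerate summary; its WCSS equals $K\Theta^2$
  exactly, a useful cross-check.

The cluster count is chosen by the silhouette index: $S(i) =
(b(i)-a(i))/\max(a(i),b(i))$ with $a(i)$ the mean dRMSD to the frame's own
cluster and $b(i)$ the smallest mean dRMSD to another cluster;
$S_{\mathrm{OVER}}$ is the mean over frames and `select_k()` returns the $k$
maximising it (ties toward smaller $k$; singleton clusters score 0 by the
Rousseeuw convention — the definition is otherwise undefined there).

Maps of conformational space use classical (Torgerson–Gower) MDS via
`cmds_embed()` (double-centering + eigendecomposition, delegated to
`stats::cmdscale`). Negative eigenvalues are recorded but never used for
coordinates; axis signs are canonicalised (largest-magnitude loading
positive) so repeated runs are bit-identical. Medoids (`medoid()`) are the
members minimising mean dRMSD to the rest, with earliest-frame tie-break;
outliers are frames at dRMSD **greater than or equal to** a threshold from
the medoid — the inclusive comparison is deliberate and tested.

Clustering and the MDS map operate by default on the same strided,
burn-in-trimmed frame subset (`strided_frames()`): frames with time
$\ge$ `burn_in` are kept and then every `stride`-th taken. With 40000
snapshots at 5 ps, a 1 ns burn-in and a 50 ps stride this yields 3981
conformers, the scale the method is routinely used at.

## Binding diagnostics

* **Q(k) profiles** (`q_profile()`): rank frames by dRMSD to a reference
  (typically a ligand-bound crystal structure, mapped onto the pocket
  selection through a sequence alignment); $Q^{(k)}$ is the mean dRMSD of the
  $k$ nearest. $Q^{(k)}$ is nondecreasing in $k$; low $Q^{(1)}, Q^{(10)}$
  mean the apo ensemble visits bound-like pocket conformations
  (conformational-selection signature), high values point toward induced fit.
  Defaults $k \in \{1, 10, 100, 200\}$; ranking ties break by frame order.
* **Cleft-width series** (`cleft_distance_series()`): the Cα distance between
  the strand C-terminal and helix N-terminal residues, i.e. across the base
  of the peptide groove. `fit_gaussians()` fits one- and two-component
  Gaussians (EM through mclust with deterministic model-based initialisation)
  and selects the count by BIC; the per-candidate scores are reported so the
  selection can be audited. `open_fraction()` counts frames with distance
  *strictly greater* than a threshold.
* **Kinetics** (`cluster_kinetics()`): dwell times are the lengths of maximal
  constant-label runs times `dt`. The final run is right-censored and always
  excluded; the first run is included as complete by default
  (`drop_first_run = TRUE` switches to treating it as left-censored — with
  many transitions the two conventions differ negligibly). The mean
  inter-cluster transition time is the mean dwell; on a symmetric Markov
  chain with per-frame switch probability $p$ its expectation is $dt/p$. The
  intra-cluster relaxation time is the time constant of an exponential fitted
  through the origin to the pooled within-run autocorrelation of a per-frame
  signal (canonically the dRMSD to the frame's own cluster centroid); the
  signal is a separate argument because the label sequence alone does not
  determine it. Metastability shows as relaxation ≪ transition time.
* **RMSIP convergence** (`rmsip()`): the ensemble is split (halves by
  default), each segment is superposed to its mean (two fitting passes) and
  the top `n_modes` principal components of the Cα fluctuations are compared
  via $\mathrm{RMSIP} = \sqrt{\tfrac1D \sum_{ij} (\eta_i \cdot \nu_j)^2}$.
  `n_modes = 10` is the field convention for this comparison. RMSIP is 1 for
  coinciding subspaces, 0 for orthogonal ones, and invariant to rotation of
  either mode set within its span. Superposition can be disabled for
  controlled synthetic checks where the fluctuation subspace is constructed
  in coordinates.

Coordinate RMSD after optimal superposition (`superposed_rmsd()`) is provided
for table-style comparisons of aligned structures; it uses the closed-form
least-squares rotation with reflections excluded (determinant correction on
the smallest singular vector).

## Synthetic ensembles: what they test and what they do not

The generators exist so that every stage is testable without downloads:

* `make_reference_pocket()` — a deterministic 15-residue idealised pocket:
  an extended 5-residue strand (3.8 Å Cα spacing) facing a 10-residue ideal
  helix (1.5 Å rise, 100° turn), with the cleft base pair placed at an exact
  requested distance. Two pockets differing only in cleft width serve as
  "closed" and "open" state references.
* `generate_harmonic()` — reference + independent isotropic Gaussian
  displacement per coordinate: a stationary one-state stand-in. For
  well-separated atoms the pair-distance variance tends to $2\sigma^2$
  (delta method), which the tests verify.
* `generate_two_state()` / `generate_markov_states()` — hidden symmetric
  Markov switching between reference conformers plus noise; true labels are
  returned so clustering and kinetics can be scored against ground truth.
* `generate_cleft_series()` — i.i.d. draws from a Gaussian mixture for the
  distribution-fitting path.

Default study conditions used by the pipeline and the acceptance script:
4000 frames at `dt` = 5 ps, switch probability 0.02 per frame (expected dwell
250 ps), per-coordinate noise 0.08 Å, cleft widths 6.3 Å and 9.0 Å. The
widths are typical closed/open pocket values; the noise level puts the
intra-state spread well below the inter-state separation (a regime where
state recovery should be exact, which the tests then require); the frame
count keeps the full map-scale analysis around half a minute on one CPU.
Tests use smaller sizes (stated in each test) chosen so the whole suite runs
in a few minutes.

These generators emulate *statistical* structure only: metastable states,
harmonic fluctuation, unimodal/bimodal cleft distributions. They do not
reproduce force-field physics, anisotropic or correlated fluctuations,
solvent effects, or sequence-dependent geometry. Passing tests therefore
demonstrate that the estimators recover known statistical structure — not
that any particular protein behaves one way or another. All generators take
an explicit seed, restore the caller's RNG state, and are bit-reproducible
per seed on a given platform.

## File handling and conventions

* Multi-model PDB and DCD (+ PDB topology) input via bio3d; XTC/TRR have no
  installed reader and are rejected with a clear error. Models with differing
  Cα counts are rejected. Alternate locations resolve to the
  highest-occupancy atom (alphabetic altloc id as tie-break); insertion codes
  are rejected rather than silently reordered. Multi-model references default
  to model 1.
* Alignments (aligned FASTA, CLUSTAL) via Biostrings;
  `map_equivalent_residues()` keeps only gap-free columns, and
  `pairwise_identity()` divides matches by gap-free aligned columns (the
  denominator is recorded on the result).
* User-facing residue addressing is author PDB numbering, per chain,
  inclusive ranges; internal indices are 1-based, the R convention.
* Distances are Å, times ps. Matrices serialise to labelled TSV at full
  double precision (lossless round-trip), records to JSON. `run_pipeline()`
  writes a manifest with per-file MD5 digests, and reruns with an identical
  config byte-match every numeric output.

## A worked pipeline

```{r pipeline, eval = FALSE}
cfg <- as_run_config(list(
  input = list(kind = "synthetic",
               synthetic = list(generator = "two_state", K = 2000,
                                switch_prob = 0.02, noise_sd = 0.08, seed = 7)),
  stride_ps = 10, burn_in_ps = 50, k_range = c(2, 4), seed = 7,
  output_dir = "run1"))
run_pipeline(cfg)
report("run1")
```

For real data, point `input` at a multi-model PDB or a DCD + topology, give
the pocket ranges under `selection` (e.g. strand `A:27-31`, helix
`A:78-87`), and optionally a ligand-bound `reference` structure for the Q(k)
and Δ stages.

## Known limitations

* Cα-only: side-chain rearrangements, contacts and salt bridges are outside
  the model.
* dRMSD weights all selected pairs equally; very large selections dilute
  localised motions (use the pocket selection, or cross-block scope).
* Cluster centroids are mean distance matrices, not conformations; use
  medoids when a representative *structure* is needed.
* The relaxation-time estimator assumes a single dominant exponential within
  runs and needs runs longer than the correlation time.
* BIC-based component selection considers one or two Gaussians only, matching
  the diagnostic question (one state or two) rather than general density
  estimation.
* Deciding conformational selection vs induced fit from apo sampling alone is
  bounded by sampling: Q(k) not approaching zero may mean induced fit or just
  insufficient simulation time.
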