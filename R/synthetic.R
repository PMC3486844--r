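#' Idealised binding-pocket reference geometry
#'
#' A deterministic Calpha conformer mimicking the canonical peptide-binding
#' pocket: an extended strand trace (3.8 A spacing) facing an ideal helix
#' trace (1.5 A rise per residue, 100 degree turn, 2.3 A radius). The helix is
#' placed so that the cleft base pair -- C-terminal strand residue and
#' N-terminal helix residue -- sits at exactly the requested distance.
#'
#' @param n_strand strand residue count (default 5).
#' @param n_helix helix residue count (default 10).
#' @param cleft_base_distance base-pair Calpha distance in Angstrom.
#' @return a `calpha` conformer of `n_strand + n_helix` residues, chain A,
#'   strand residues numbered first.
#' @export
make_reference_pocket <- function(n_strand = 5L, n_helix = 10L,
                                  cleft_base_distance = 6.3) {
  if (n_strand < 2L || n_helix < 2L) stop("block sizes must be >= 2")
  if (cleft_base_distance <= 0) stop("cleft distance must be positive")
  strand <- cbind(3.8 * (seq_len(n_strand) - 1L), 0, 0)
  j <- seq_len(n_helix) - 1L
  theta <- j * 100 * pi / 180
  helix <- cbind(1.5 * j, 2.3 * cos(theta), 2.3 * sin(theta))
  # translate so helix residue 1 sits cleft_base_distance away from the
  # strand's C-terminal residue, along +y
  target <- strand[n_strand, ] + c(0, cleft_base_distance, 0)
  helix <- sweep(helix, 2L, target - helix[1L, ], `+`)
  labels <- data.frame(chain = "A",
                       resno = seq_len(n_strand + n_helix),
                       resid = c(rep("VAL", n_strand), rep("ALA", n_helix)),
                       stringsAsFactors = FALSE)
  calpha_conformer(labels, rbind(strand, helix), source_id = "reference pocket")
}

labeled_ensemble <- function(ensemble, true_labels, true_parameters) {
  structure(list(ensemble = ensemble, true_labels = true_labels,
                 true_parameters = true_parameters),
            class = "labeled_ensemble")
}

#' @export
print.labeled_ensemble <- function(x, ...) {
  cat("Labeled synthetic ensemble (", x$true_parameters$kind, "): K = ",
      n_frames(x$ensemble), ", states = ", length(unique(x$true_labels)),
      "\n", sep = "")
  invisible(x)
}

frames_from_noise <- function(ref_xyz_rows, noise_sd, labels) {
  # ref_xyz_rows: K x 3N matrix of reference coordinates per frame
  K <- nrow(ref_xyz_rows)
  ref_xyz_rows + matrix(stats::rnorm(K * ncol(ref_xyz_rows), sd = noise_sd),
                        K, ncol(ref_xyz_rows))
}

#' Stationary harmonic-fluctuation ensemble
#'
#' Frames are the reference conformer plus independent isotropic Gaussian
#' displacements (`noise_sd` per coordinate) -- a one-state stand-in for a
#' well-equilibrated trajectory. Bit-reproducible per seed.
#'
#' @param ref a `calpha` conformer.
#' @param noise_sd per-coordinate displacement sd in Angstrom (>= 0).
#' @param K frame count (>= 2).
#' @param dt frame spacing in ps (default 5).
#' @param seed integer RNG seed.
#' @return a `labeled_ensemble` (all labels 1).
#' @export
generate_harmonic <- function(ref, noise_sd, K, dt = 5, seed = 1L) {
  if (K < 2L) stop("K must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  base <- as.vector(t(ref$xyz))
  xyz <- with_seed(seed,
    frames_from_noise(matrix(base, K, length(base), byrow = TRUE), noise_sd))
  labeled_ensemble(calpha_ensemble(xyz, labels = ref$labels, dt = dt),
                   true_labels = rep(1L, K),
                   true_parameters = list(kind = "harmonic", noise_sd = noise_sd,
                                          K = K, dt = dt, seed = seed))
}

#' Metastable multi-state ensemble (hidden Markov switching)
#'
#' A hidden state sequence follows a symmetric Markov chain: at each frame the
#' state switches with probability `switch_prob` (to a uniformly chosen other
#' state when more than two are given). Each frame is the active reference
#' conformer plus isotropic Gaussian noise. Mean dwell time is dt/switch_prob.
#'
#' @param refs list of >= 2 `calpha` conformers sharing residue labels.
#' @param switch_prob per-frame switch probability in (0, 1).
#' @param noise_sd per-coordinate noise sd in Angstrom.
#' @param K frame count.
#' @param dt frame spacing in ps.
#' @param seed integer RNG seed.
#' @param start_state initial state (default 1).
#' @return a `labeled_ensemble` with per-frame `true_labels`.
#' @export
generate_markov_states <- function(refs, switch_prob, noise_sd, K, dt = 5,
                                   seed = 1L, start_state = 1L) {
  m <- length(refs)
  if (m < 2L) stop("need at least 2 reference states")
  key <- residue_key(refs[[1L]]$labels)
  if (!all(vapply(refs, function(r) identical(residue_key(r$labels), key), logical(1))))
    stop("incompatible references: residue labels differ")
  if (switch_prob <= 0 || switch_prob >= 1) stop("switch_prob must be in (0, 1)")
  if (K < 2L) stop("K must be >= 2")
  base <- t(vapply(refs, function(r) as.vector(t(r$xyz)), numeric(3L * nrow(refs[[1L]]$xyz))))
  res <- with_seed(seed, {
    states <- integer(K)
    states[1L] <- as.integer(start_state)
    switches <- stats::runif(K - 1L) < switch_prob
    jumps <- if (m == 2L) NULL else sample.int(m - 1L, K - 1L, replace = TRUE)
    for (t in 2:K) {
      if (switches[t - 1L]) {
        others <- setdiff(seq_len(m), states[t - 1L])
        states[t] <- if (m == 2L) others else others[jumps[t - 1L]]
      } else states[t] <- states[t - 1L]
    }
    list(states = states,
         xyz = frames_from_noise(base[states, , drop = FALSE], noise_sd))
  })
  labeled_ensemble(calpha_ensemble(res$xyz, labels = refs[[1L]]$labels, dt = dt),
                   true_labels = res$states,
                   true_parameters = list(kind = if (m == 2L) "two_state" else
                                            paste0(m, "_state"),
                                          switch_prob = switch_prob,
                                          noise_sd = noise_sd, K = K, dt = dt,
                                          seed = seed, n_states = m))
}

#' Two-state metastable ensemble
#'
#' Convenience wrapper over [generate_markov_states()] for the canonical
#' two-state case.
#'
#' @param ref_a,ref_b `calpha` conformers sharing residue labels.
#' @inheritParams generate_markov_states
#' @return a `labeled_ensemble`.
#' @export
generate_two_state <- function(ref_a, ref_b, switch_prob, noise_sd, K, dt = 5,
                               seed = 1L) {
  generate_markov_states(list(ref_a, ref_b), switch_prob, noise_sd, K, dt, seed)
}

#' Synthetic cleft-distance series from a Gaussian mixture
#'
#' I.i.d. seeded draws from a one- or two-component (or more) Gaussian mixture,
#' emulating unimodal or bimodal binding-cleft width distributions.
#'
#' @param components list of `c(mean, sd, weight)` triples (weights sum to 1),
#'   or a 3-column matrix/data.frame.
#' @param K sample count.
#' @param dt frame spacing in ps.
#' @param seed integer RNG seed.
#' @return a `distance_series` with attribute `true_components`.
#' @export
generate_cleft_series <- function(components, K, dt = 5, seed = 1L) {
  cmp <- do.call(rbind, lapply(components, function(x) as.numeric(x)[1:3]))
  colnames(cmp) <- c("mean", "sd", "weight")
  if (any(cmp[, "sd"] <= 0)) stop("component sds must be positive")
  if (abs(sum(cmp[, "weight"]) - 1) > 1e-8) stop("weights must sum to 1")
  v <- with_seed(seed, {
    z <- sample.int(nrow(cmp), K, replace = TRUE, prob = cmp[, "weight"])
    stats::rnorm(K, mean = cmp[z, "mean"], sd = cmp[z, "sd"])
  })
  out <- structure(list(values = v, frame_times = dt * seq_len(K),
                        residue_pair = c("synthetic", "synthetic")),
                   class = "distance_series")
  attr(out, "true_components") <- cmp
  out
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL per frame, Calpha atoms only; lets the synthetic generators feed
#' the file-based entry points end to end.
#'
#' @param ens a `calpha_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  bio3d::write.pdb(file = path,
                   xyz = ens$xyz,
                   resno = ens$labels$resno,
                   resid = ens$labels$resid,
                   chain = ens$labels$chain,
                   elety = rep("CA", n_residues(ens)))
  invisible(path)
}
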