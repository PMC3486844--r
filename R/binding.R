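#' Q(k) neighbour profile against a reference structure
#'
#' Frames are ranked by dRMSD to a reference (typically a ligand-bound crystal
#' structure); Q(k) is the mean dRMSD of the k nearest frames. Small Q(k) means
#' the apo ensemble spontaneously visits bound-like conformations
#' (conformational-selection signature); large Q(k) points toward induced fit.
#' Ranking ties break by frame order.
#'
#' @param ens a `calpha_ensemble`.
#' @param selection optional `residue_selection` for the ensemble.
#' @param reference a `calpha` conformer.
#' @param ks neighbour counts (default 1, 10, 100, 200).
#' @param ref_selection optional selection applied to the reference (when its
#'   residue indexing differs from the ensemble's).
#' @param frames optional frame subset.
#' @return object of class `q_profile`: `reference_id`, `ks`, `q_values` (A),
#'   `neighbor_frames` (list of the k nearest frame indices per k),
#'   `drmsd_to_reference` (per considered frame).
#' @export
q_profile <- function(ens, selection = NULL, reference, ks = c(1L, 10L, 100L, 200L),
                      ref_selection = NULL, frames = NULL) {
  ks <- sort(unique(as.integer(ks)))
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  if (max(ks) > length(frames))
    stop("k = ", max(ks), " exceeds frame count (", length(frames), ")")
  D <- pair_dists(ens, selection, frames)
  ref <- condensed_dists(reference, ref_selection %||% selection)
  if (length(ref) != ncol(D)) stop("reference does not map to the frame selection")
  d <- sqrt(rowMeans(sweep(D, 2L, ref)^2))
  ord <- order(d, seq_along(d)) # stable: ties by frame order
  q <- vapply(ks, function(k) mean(d[ord[seq_len(k)]]), numeric(1))
  structure(list(reference_id = reference$source_id,
                 ks = ks,
                 q_values = stats::setNames(q, paste0("Q", ks)),
                 neighbor_frames = stats::setNames(
                   lapply(ks, function(k) frames[ord[seq_len(k)]]), paste0("Q", ks)),
                 drmsd_to_reference = stats::setNames(d, paste0("frame", frames))),
            class = "q_profile")
}

#' @export
print.q_profile <- function(x, ...) {
  cat("Q profile vs", x$reference_id, "\n")
  print(round(x$q_values, 4))
  invisible(x)
}

resolve_residue <- function(labels, res) {
  if (is.character(res) && length(res) == 1L) {
    m <- regmatches(res, regexec("^([A-Za-z0-9]):?([0-9]+)$", res))[[1L]]
    if (length(m) == 3L) res <- list(chain = m[2L], resno = as.integer(m[3L]))
    else stop("cannot parse residue spec: ", res)
  }
  i <- which(labels$chain == res$chain & labels$resno == as.integer(res$resno))
  if (length(i) != 1L) stop("residue ", res$chain, res$resno, " absent from structure")
  i
}

#' Binding-cleft distance series
#'
#' Per-frame Calpha-Calpha distance between two residues -- canonically the
#' C-terminal residue of the beta2 strand and the N-terminal residue of the
#' alpha2 helix, a simple measure of the width across the base of the
#' peptide-binding cleft.
#'
#' @param ens a `calpha_ensemble`.
#' @param residue_a,residue_b residue specs: `list(chain=, resno=)` or a string
#'   like `"A31"`.
#' @return object of class `distance_series`: `values` (A), `frame_times` (ps,
#'   may be NULL), `residue_pair`.
#' @export
cleft_distance_series <- function(ens, residue_a, residue_b) {
  ia <- resolve_residue(ens$labels, residue_a)
  ib <- resolve_residue(ens$labels, residue_b)
  ca <- 3L * (ia - 1L) + 1:3
  cb <- 3L * (ib - 1L) + 1:3
  v <- sqrt(rowSums((ens$xyz[, ca, drop = FALSE] - ens$xyz[, cb, drop = FALSE])^2))
  structure(list(values = v, frame_times = ens$frame_times,
                 residue_pair = residue_names(ens$labels)[c(ia, ib)]),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat("Distance series", paste(x$residue_pair, collapse = "-"), ":",
      length(x$values), "frames, mean", round(mean(x$values), 3), "A\n")
  invisible(x)
}

#' Gaussian / two-Gaussian fit of a distance distribution
#'
#' Maximum-likelihood fits with one and two Gaussian components (EM for the
#' mixture, deterministic model-based initialisation via mclust) and selection
#' of the component count by the Bayesian information criterion (lower is
#' better; reported per candidate). A unimodal cleft distribution indicates a
#' single (e.g. permanently closed or open) state; a bimodal one indicates two
#' interconverting cleft widths.
#'
#' @param series a `distance_series` or numeric vector (>= 50 samples).
#' @param candidates component counts to consider (subset of 1:2).
#' @return object of class `gaussian_fit`: `n_components`, `means`, `sds`,
#'   `weights`, `bic` (named, standard -2logL + p log n form), `n`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_gaussians <- function(series, candidates = c(1L, 2L)) {
  x <- if (inherits(series, "distance_series")) series$values else as.numeric(series)
  if (length(x) < 50L) stop("need at least 50 samples")
  if (stats::sd(x) == 0) stop("degenerate (zero-variance) series")
  candidates <- sort(unique(as.integer(candidates)))
  if (!all(candidates %in% 1:2)) stop("candidates must be within 1:2")
  bicv <- mclust::mclustBIC(x, G = candidates, modelNames = "V", verbose = FALSE)
  # mclust reports 2*logL - p*log(n); convert to the standard minimised form.
  bic_std <- stats::setNames(-as.numeric(bicv[, "V"]), paste0("G", candidates))
  g <- candidates[which.min(bic_std)]
  fit <- mclust::Mclust(x, G = g, modelNames = "V", verbose = FALSE)
  ord <- order(fit$parameters$mean)
  structure(list(n_components = g,
                 means = unname(fit$parameters$mean[ord]),
                 sds = unname(sqrt(fit$parameters$variance$sigmasq))[ord],
                 weights = unname(fit$parameters$pro[ord]),
                 bic = bic_std,
                 n = length(x)),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(x$n_components, "-component Gaussian fit (n = ", x$n, ")\n", sep = "")
  for (i in seq_len(x$n_components))
    cat(sprintf("  mean %.3f A  sd %.3f A  weight %.3f\n",
                x$means[i], x$sds[i], x$weights[i]))
  invisible(x)
}

#' Fraction of frames with an open cleft
#'
#' Fraction (and count) of frames whose cleft distance strictly exceeds the
#' threshold.
#'
#' @param series a `distance_series` or numeric vector.
#' @param threshold distance threshold in Angstrom (> 0).
#' @return list with `fraction` and `count`.
#' @export
open_fraction <- function(series, threshold) {
  x <- if (inherits(series, "distance_series")) series$values else as.numeric(series)
  if (length(x) == 0L) stop("empty series")
  if (threshold <= 0) stop("threshold must be positive")
  n <- sum(x > threshold)
  list(fraction = n / length(x), count = n)
}

#' Dwell-time kinetics of a cluster label sequence
#'
#' Dwell times are the lengths (times dt) of maximal constant-label runs. The
#' final run is right-censored and excluded; the first run is included as
#' complete by default (set `drop_first_run = TRUE` to treat it as
#' left-censored). The mean inter-cluster transition time is the mean dwell
#' time. When the per-frame dRMSD-to-own-centroid signal is supplied, the
#' intra-cluster relaxation time is estimated as the time constant of an
#' exponential fit to its within-run autocorrelation; metastable states show a
#' relaxation time much shorter than the transition time.
#'
#' @param labels integer per-frame cluster ids (in time order, >= 2 distinct).
#' @param dt frame spacing in ps (> 0).
#' @param signal optional per-frame numeric signal (e.g. dRMSD to own cluster
#'   mean distance matrix) for the relaxation-time estimate.
#' @param drop_first_run treat the first run as left-censored (default FALSE).
#' @param max_lag maximum autocorrelation lag in frames (default 50).
#' @return object of class `kinetics_report`: `mean_intercluster_transition_time`
#'   (ps), `mean_intracluster_relaxation_time` (ps or NA), `dwell_times`
#'   (ps, named by cluster), `n_transitions`.
#' @export
cluster_kinetics <- function(labels, dt, signal = NULL, drop_first_run = FALSE,
                             max_lag = 50L) {
  if (dt <= 0) stop("dt must be positive")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 distinct labels")
  r <- rle(labels)
  keep <- seq_len(length(r$lengths) - 1L) # drop right-censored final run
  if (drop_first_run) keep <- keep[-1L]
  if (length(keep) == 0L) stop("no complete dwell remains under the chosen conventions")
  dwell <- r$lengths[keep] * dt
  names(dwell) <- paste0("cluster", r$values[keep])

  relax <- NA_real_
  if (!is.null(signal)) {
    if (length(signal) != length(labels)) stop("signal length must match labels")
    run_id <- rep(seq_along(r$lengths), r$lengths)
    relax <- relaxation_time(signal, run_id, dt, max_lag)
  }
  structure(list(mean_intercluster_transition_time = mean(dwell),
                 mean_intracluster_relaxation_time = relax,
                 dwell_times = dwell,
                 n_transitions = length(r$lengths) - 1L),
            class = "kinetics_report")
}

# Pooled within-run autocorrelation, exponential decay fit through the origin:
# log rho(l) = -l*dt/tau over lags before the first nonpositive value.
relaxation_time <- function(signal, run_id, dt, max_lag) {
  runs <- split(seq_along(signal), run_id)
  denom <- 0
  num <- numeric(max_lag)
  cnt <- integer(max_lag)
  for (ii in runs) {
    x <- signal[ii] - mean(signal[ii])
    denom <- denom + sum(x^2)
    L <- min(max_lag, length(x) - 1L)
    if (L < 1L) next
    for (l in seq_len(L)) {
      num[l] <- num[l] + sum(x[seq_len(length(x) - l)] * x[(l + 1L):length(x)])
      cnt[l] <- cnt[l] + length(x) - l
    }
  }
  if (denom == 0 || all(cnt == 0L)) return(NA_real_)
  rho <- num / denom * (sum(vapply(runs, length, 1L)) / pmax(cnt, 1L))
  usable <- which(cnt > 0L & rho > 0)
  if (length(usable) == 0L) return(dt) # decorrelated within one frame
  first_bad <- which(cnt == 0L | rho <= 0)
  if (length(first_bad) > 0L) usable <- usable[usable < min(first_bad)]
  if (length(usable) == 0L) return(dt)
  lag <- usable * dt
  slope <- sum(lag * log(rho[usable])) / sum(lag^2)
  if (slope >= 0) return(NA_real_)
  -1 / slope
}

#' @export
print.kinetics_report <- function(x, ...) {
  cat(sprintf("Mean inter-cluster transition time: %.4g ps (%d transitions)\n",
              x$mean_intercluster_transition_time, x$n_transitions))
  cat(sprintf("Intra-cluster relaxation time: %s\n",
              if (is.na(x$mean_intracluster_relaxation_time)) "not computed"
              else sprintf("%.4g ps", x$mean_intracluster_relaxation_time)))
  invisible(x)
}

# Principal components of Calpha fluctuations for a frame subset: frames are
# superposed to the segment mean (two fitting passes), then the covariance of
# the 3N coordinates is eigendecomposed.
segment_modes <- function(ens, selection, frames, n_modes, superpose = TRUE) {
  idx <- selection_indices(selection, n_residues(ens))
  cols <- as.vector(rbind(3L * (idx - 1L) + 1L, 3L * (idx - 1L) + 2L, 3L * idx))
  X <- ens$xyz[frames, cols, drop = FALSE]
  if (nrow(X) < n_modes) stop("segment has fewer frames than modes requested")
  if (n_modes > ncol(X)) stop("n_modes exceeds 3N")
  as_mat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
  if (superpose) {
    for (pass in 1:2) {
      ref <- if (pass == 1L) as_mat(X[1L, ]) else as_mat(colMeans(X))
      X <- t(apply(X, 1L, function(v) as.vector(t(kabsch_fit(as_mat(v), ref)$xyz))))
    }
  }
  Xc <- sweep(X, 2L, colMeans(X))
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  list(modes = ev$vectors[, seq_len(n_modes), drop = FALSE],
       eigenvalues = ev$values)
}

rmsip_value <- function(U, V) {
  sqrt(sum((crossprod(U, V))^2) / ncol(U))
}

#' RMSIP convergence check between trajectory segments
#'
#' Splits the ensemble into two segments (halves by default), computes the
#' principal components of the Calpha fluctuations of each (after least-squares
#' superposition to the segment mean) and reports the root mean square inner
#' product of the two top-`n_modes` subspaces. RMSIP is 1 when the essential
#' subspaces coincide and 0 when they are orthogonal; values around 0.6-0.7 on
#' trajectory halves are commonly read as adequate sampling convergence.
#'
#' @param ens a `calpha_ensemble`.
#' @param selection optional `residue_selection`.
#' @param n_modes subspace dimension (default 10).
#' @param split `"halves"` or `"custom"` (supply `segments`).
#' @param segments list of two frame-index vectors when `split = "custom"`.
#' @param superpose superpose frames to the segment mean first (default TRUE;
#'   disable only for controlled synthetic checks).
#' @return object of class `convergence_report`: `rmsip`, `n_modes`, `split`.
#' @export
rmsip <- function(ens, selection = NULL, n_modes = 10L,
                  split = c("halves", "custom"), segments = NULL,
                  superpose = TRUE) {
  split <- match.arg(split)
  n_modes <- as.integer(n_modes)
  if (n_modes < 1L) stop("n_modes must be >= 1")
  if (split == "halves") {
    K <- n_frames(ens)
    half <- K %/% 2L
    segments <- list(seq_len(half), (half + 1L):K)
  } else if (is.null(segments) || length(segments) != 2L) {
    stop("custom split needs a list of two frame-index vectors")
  }
  m1 <- segment_modes(ens, selection, segments[[1L]], n_modes, superpose)
  m2 <- segment_modes(ens, selection, segments[[2L]], n_modes, superpose)
  structure(list(rmsip = rmsip_value(m1$modes, m2$modes),
                 n_modes = n_modes,
                 split = if (split == "halves") "halves" else
                   paste0("custom (", length(segments[[1L]]), "+",
                          length(segments[[2L]]), " frames)")),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("RMSIP = %.3f over %d modes (%s split)\n", x$rmsip, x$n_modes, x$split))
  invisible(x)
}
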