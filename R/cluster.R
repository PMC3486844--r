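#' Frame indices after burn-in and striding
#'
#' Frames with time >= `burn_in` (ps) are kept, then every `stride`-th frame
#' starting with the first kept one. With 40000 snapshots at 5 ps (times
#' 5..200000), burn-in 1000 ps and stride 10 this yields the 3981-conformer
#' subset used for map-scale analyses.
#'
#' @param ens a `calpha_ensemble`.
#' @param stride keep every stride-th frame (frames, >= 1).
#' @param burn_in initial time span to discard (ps; needs frame times/dt).
#' @return integer frame indices.
#' @export
strided_frames <- function(ens, stride = 1L, burn_in = 0) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  idx <- seq_len(n_frames(ens))
  if (burn_in > 0) {
    times <- ens$frame_times
    if (is.null(times)) stop("burn-in in ps needs frame times or dt")
    idx <- idx[times >= burn_in]
  }
  if (length(idx) == 0L) stop("no frames left after burn-in")
  idx[seq(1L, length(idx), by = stride)]
}

#' All-pairs dRMSD dissimilarity matrix
#'
#' Computes the pairwise dRMSD between (optionally burn-in-trimmed and
#' strided) frames over the selected residues, optionally appending reference
#' conformers (e.g. ligand-bound crystal structures) as extra rows/columns so
#' they can be projected into the same map.
#'
#' @param ens a `calpha_ensemble`.
#' @param selection optional `residue_selection`.
#' @param stride,burn_in see [strided_frames()].
#' @param extra_refs optional named list of `calpha` conformers; each must
#'   resolve to the same residue count as the selection (use
#'   `ref_selections` when a reference needs its own index set).
#' @param ref_selections optional list of selections, one per reference.
#' @return M x M symmetric matrix (Angstrom) with frame/reference ids as
#'   dimnames and attribute `frame_indices` (original frame index, NA for refs).
#' @export
dissimilarity_matrix <- function(ens, selection = NULL, stride = 1L, burn_in = 0,
                                 extra_refs = NULL, ref_selections = NULL) {
  frames <- strided_frames(ens, stride, burn_in)
  if (length(frames) < 2L && is.null(extra_refs)) stop("need at least 2 frames")
  D <- pair_dists(ens, selection, frames)
  ids <- paste0("frame", frames)
  orig <- frames
  if (!is.null(extra_refs)) {
    refs <- lapply(seq_along(extra_refs), function(i) {
      sel <- if (!is.null(ref_selections)) ref_selections[[i]] else selection
      v <- condensed_dists(extra_refs[[i]], sel)
      if (length(v) != ncol(D))
        stop("reference ", i, " does not map to the frame selection (",
             length(v), " vs ", ncol(D), " pairs)")
      v
    })
    D <- rbind(D, do.call(rbind, refs))
    rid <- names(extra_refs) %||% paste0("ref", seq_along(extra_refs))
    ids <- c(ids, rid)
    orig <- c(orig, rep(NA_integer_, length(extra_refs)))
  }
  m <- as.matrix(stats::dist(D)) / sqrt(ncol(D))
  dimnames(m) <- list(ids, ids)
  attr(m, "frame_indices") <- orig
  m
}

# WCSS (Angstrom^2): sum over frames of squared dRMSD to own cluster mean
# distance matrix, computed on a condensed pair matrix D.
wcss_of <- function(D, labels, k) {
  s <- 0
  for (c in seq_len(k)) {
    rows <- which(labels == c)
    if (length(rows) == 0L) next
    m <- colMeans(D[rows, , drop = FALSE])
    s <- s + sum(sweep(D[rows, , drop = FALSE], 2L, m)^2)
  }
  s / ncol(D)
}

# Squared dRMSD from every row of D to every centroid row of C.
d2_to_centroids <- function(D, C) {
  d2 <- outer(rowSums(D^2), rep(1, nrow(C))) - 2 * D %*% t(C) +
    outer(rep(1, nrow(D)), rowSums(C^2))
  pmax(d2, 0) / ncol(D)
}

# One Lloyd run from given initial centroid frames. Returns labels, centroids,
# wcss, the per-iteration wcss trace and iteration count.
lloyd_run <- function(D, k, init_rows, max_iter = 100L, tol = 1e-10) {
  C <- D[init_rows, , drop = FALSE]
  labels <- rep(0L, nrow(D))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- d2_to_centroids(D, C)
    new_labels <- max.col(-d2, ties.method = "first")
    empty <- which(tabulate(new_labels, k) == 0L)
    for (e in empty) {
      worst <- which.max(d2[cbind(seq_len(nrow(D)), new_labels)])
      new_labels[worst] <- e
      d2[worst, ] <- 0 # keep it from being re-picked for another empty cluster
    }
    C <- t(vapply(seq_len(k), function(c)
      colMeans(D[new_labels == c, , drop = FALSE]), numeric(ncol(D))))
    w <- wcss_of(D, new_labels, k)
    converged <- identical(new_labels, labels) ||
      (length(trace) > 0L && trace[length(trace)] - w < tol)
    labels <- new_labels
    trace <- c(trace, w)
    if (converged) break
  }
  list(labels = labels, centroids = C, wcss = trace[length(trace)],
       wcss_trace = trace, n_iter = length(trace))
}

# Greedy farthest-point seeding: random first frame, then repeatedly the frame
# farthest (in dRMSD) from its nearest chosen seed.
farthest_point_seeds <- function(D, k, first) {
  seeds <- first
  if (k > 1L) {
    d2 <- d2_to_centroids(D, D[first, , drop = FALSE])[, 1L]
    while (length(seeds) < k) {
      nxt <- which.max(d2)
      seeds <- c(seeds, nxt)
      d2 <- pmin(d2, d2_to_centroids(D, D[nxt, , drop = FALSE])[, 1L])
    }
  }
  seeds
}

#' k-means clustering of conformers in distance-matrix space
#'
#' Lloyd alternation where each frame is assigned to the cluster whose mean
#' distance matrix it is closest to in dRMSD, and cluster centroids are the
#' mean distance matrices of their members (which need not correspond to any
#' realisable 3D conformation). The objective is the within-cluster sum of
#' squared dRMSD (WCSS); it is non-increasing across iterations. The best of
#' `n_init` farthest-point-seeded restarts is returned; results are
#' deterministic given `seed`. Empty clusters are re-seeded with the frame
#' farthest from its own centroid.
#'
#' @param ens a `calpha_ensemble`.
#' @param selection optional `residue_selection`.
#' @param k number of clusters (1 allowed as a degenerate summary).
#' @param seed integer RNG seed.
#' @param n_init number of seeded restarts.
#' @param frames optional frame subset (default all; see [strided_frames()]).
#' @param max_iter Lloyd iteration cap.
#' @return object of class `cluster_result`: `k`, `labels` (per frame, 1..k),
#'   `cluster_means` (list of N x N matrices), `wcss` (A^2), `wcss_trace`,
#'   `silhouette`, `s_over`, `medoids` (frame index per cluster, in `frames`
#'   numbering), `sizes`, `n_iter`, `seed`, `frames`.
#' @export
kmeans_states <- function(ens, selection = NULL, k, seed = 1L, n_init = 10L,
                          frames = NULL, max_iter = 100L) {
  k <- as.integer(k)
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  K <- length(frames)
  if (k < 1L) stop("k must be >= 1")
  if (k > K) stop("k (", k, ") exceeds frame count (", K, ")")
  D <- pair_dists(ens, selection, frames)
  labels_res <- attr(D, "labels")

  best <- NULL
  with_seed(seed, {
    firsts <- sample.int(K, min(n_init, K), replace = n_init > K)
    for (f in firsts) {
      run <- lloyd_run(D, k, farthest_point_seeds(D, k, f), max_iter)
      if (is.null(best) || run$wcss < best$wcss) best <- run
    }
  })

  sil <- if (k >= 2L) silhouette_from_pairs(D, best$labels) else
    list(s = rep(NA_real_, K), s_over = NA_real_)
  dd <- as.matrix(stats::dist(D)) / sqrt(ncol(D))
  medoids <- vapply(seq_len(k), function(c) {
    members <- which(best$labels == c)
    members[medoid_index(dd[members, members, drop = FALSE])]
  }, integer(1))

  structure(list(k = k,
                 labels = best$labels,
                 cluster_means = lapply(seq_len(k), function(c)
                   unfold_condensed(best$centroids[c, ], labels_res)),
                 wcss = best$wcss,
                 wcss_trace = best$wcss_trace,
                 silhouette = sil$s,
                 s_over = sil$s_over,
                 medoids = frames[medoids],
                 sizes = tabulate(best$labels, k),
                 n_iter = best$n_iter,
                 seed = seed,
                 frames = frames),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("dRMSD k-means: k =", x$k, " sizes =", paste(x$sizes, collapse = "/"),
      sprintf(" WCSS = %.4g A^2", x$wcss))
  if (!is.na(x$s_over)) cat(sprintf("  S_OVER = %.3f", x$s_over))
  cat("\n")
  invisible(x)
}

medoid_index <- function(dd) {
  if (nrow(dd) == 1L) return(1L)
  which.min(rowSums(dd) / (nrow(dd) - 1L))
}

# Silhouette from a condensed pair matrix: a(i) mean dRMSD to own cluster's
# other members, b(i) smallest mean dRMSD to another cluster, S = (b-a)/max.
silhouette_from_pairs <- function(D, labels) {
  dd <- as.matrix(stats::dist(D)) / sqrt(ncol(D))
  silhouette_from_dissimilarity(dd, labels)
}

silhouette_from_dissimilarity <- function(dd, labels) {
  k <- max(labels)
  if (k < 2L) stop("silhouette needs at least 2 clusters")
  if (any(tabulate(labels, k) == 0L)) stop("empty cluster")
  M <- nrow(dd)
  s <- numeric(M)
  sums <- rowsum(t(dd), labels) # k x M: column j holds sums of d(j, members of c)
  sizes <- tabulate(labels, k)
  for (i in seq_len(M)) {
    c_own <- labels[i]
    if (sizes[c_own] == 1L) { s[i] <- 0; next }
    a <- sums[c_own, i] / (sizes[c_own] - 1L)
    b <- min(sums[-c_own, i] / sizes[-c_own])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(s = s, s_over = mean(s))
}

#' Silhouette validation of a clustering
#'
#' Per-frame silhouette S(i) = (b - a)/max(a, b), where a is the mean dRMSD of
#' frame i to the other members of its cluster and b the smallest mean dRMSD
#' to any other cluster; S_OVER is the mean over frames. Frames in singleton
#' clusters get S(i) = 0 (Rousseeuw convention).
#'
#' @inheritParams kmeans_states
#' @param labels per-frame cluster assignment in 1..k, every cluster nonempty.
#' @return list with `s` (per frame, in \[-1, 1\]) and `s_over`.
#' @export
silhouette_validate <- function(ens, selection = NULL, labels, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  if (length(labels) != length(frames)) stop("labels length must match frame count")
  silhouette_from_pairs(pair_dists(ens, selection, frames), as.integer(labels))
}

#' Choose k by maximal overall silhouette
#'
#' Runs [kmeans_states()] for each k in `k_range` and returns the k with the
#' highest S_OVER (ties broken toward smaller k), with all per-k results kept
#' for audit.
#'
#' @inheritParams kmeans_states
#' @param k_range integer vector of candidate k (all >= 2).
#' @return list with `best_k`, `s_over` (named vector) and `results` (named
#'   list of `cluster_result`).
#' @export
select_k <- function(ens, selection = NULL, k_range = 2:6, seed = 1L,
                     n_init = 10L, frames = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("empty k range")
  if (any(k_range < 2L)) stop("k range must be >= 2 for silhouette validation")
  results <- lapply(k_range, function(k)
    kmeans_states(ens, selection, k, seed = seed, n_init = n_init, frames = frames))
  names(results) <- paste0("k", k_range)
  s_over <- vapply(results, `[[`, numeric(1), "s_over")
  names(s_over) <- names(results)
  best_k <- k_range[which.max(s_over)] # which.max takes the first (smallest k) tie
  list(best_k = best_k, s_over = s_over, results = results)
}

#' Medoid of a set of frames
#'
#' The member minimising the mean dRMSD to all other members -- the most
#' representative conformation. Ties break toward the earliest frame.
#'
#' @inheritParams kmeans_states
#' @param member_frames frame indices of the set (>= 1 member).
#' @return a frame index (element of `member_frames`).
#' @export
medoid <- function(ens, selection = NULL, member_frames) {
  if (length(member_frames) == 0L) stop("empty member set")
  D <- pair_dists(ens, selection, member_frames)
  dd <- as.matrix(stats::dist(D)) / sqrt(ncol(D))
  member_frames[medoid_index(dd)]
}

#' Outlying frames relative to a medoid
#'
#' Frames whose dRMSD to the medoid conformer is greater than or equal to the
#' threshold ("equal or larger" is inclusive).
#'
#' @inheritParams kmeans_states
#' @param medoid_frame frame index of the medoid.
#' @param threshold dRMSD cutoff in Angstrom (> 0).
#' @param frames optional frame subset to scan (default all).
#' @return integer frame indices.
#' @export
find_outliers <- function(ens, selection = NULL, medoid_frame, threshold,
                          frames = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  D <- pair_dists(ens, selection, frames)
  ref <- condensed_dists(get_frame(ens, medoid_frame), selection)
  d <- sqrt(rowMeans(sweep(D, 2L, ref)^2))
  frames[d >= threshold]
}

#' Classical multidimensional scaling embedding
#'
#' Torgerson-Gower scaling of a dissimilarity matrix: double-center the
#' squared dissimilarities, eigendecompose, and take coordinates from the top
#' nonnegative eigenvalues, so that Euclidean distances between the embedded
#' points approximately reproduce the input. Axis signs are canonicalised
#' (the largest-magnitude loading on each axis is positive) so output is
#' reproducible across runs.
#'
#' @param d M x M symmetric dissimilarity matrix (e.g. from
#'   [dissimilarity_matrix()]).
#' @param dims embedding dimension (default 2).
#' @return object of class `cmds_embedding`: `coords` (M x dims),
#'   `eigenvalues` (all M, descending), `frame_ids`.
#' @export
cmds_embed <- function(d, dims = 2L) {
  dims <- as.integer(dims)
  if (dims < 1L) stop("dims must be >= 1")
  if (nrow(d) < dims + 1L) stop("need at least dims + 1 points")
  if (all(d == 0)) {
    warning("all dissimilarities are zero; returning coincident coordinates")
    coords <- matrix(0, nrow(d), dims)
    rownames(coords) <- rownames(d)
    return(structure(list(coords = coords, eigenvalues = rep(0, nrow(d)),
                          frame_ids = rownames(d)), class = "cmds_embedding"))
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < dims) # fewer positive eigenvalues than requested axes
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(d)
  structure(list(coords = coords,
                 eigenvalues = sort(fit$eig, decreasing = TRUE),
                 frame_ids = rownames(d)),
            class = "cmds_embedding")
}

#' @export
print.cmds_embedding <- function(x, ...) {
  cat("CMDS embedding:", nrow(x$coords), "points in", ncol(x$coords), "dims;",
      "top eigenvalues:", paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Assign conformers to the nearest cluster centroid
#'
#' Projects external conformers (e.g. ligand-bound references) onto an
#' existing clustering by dRMSD to the cluster mean distance matrices.
#'
#' @param result a `cluster_result`.
#' @param confs list of `calpha` conformers.
#' @param selections optional list of per-conformer selections.
#' @return integer cluster ids.
#' @export
assign_to_clusters <- function(result, confs, selections = NULL) {
  vapply(seq_along(confs), function(i) {
    sel <- if (!is.null(selections)) selections[[i]] else NULL
    dm <- distance_matrix(confs[[i]], sel)
    which.min(vapply(result$cluster_means, function(cm) drmsd(dm, cm), numeric(1)))
  }, integer(1))
}
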