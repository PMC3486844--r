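#' Calpha distance matrix of a conformer
#'
#' Euclidean Calpha-Calpha distances over the selected residues. Distance
#' matrices are the primitive every statistic in this package is built from:
#' they are invariant to rigid-body motion, so no structural superposition is
#' ever required.
#'
#' @param conf a `calpha` conformer.
#' @param selection optional `residue_selection` (default: all residues).
#' @return N x N symmetric numeric matrix (Angstrom) with residue-label dimnames.
#' @export
distance_matrix <- function(conf, selection = NULL) {
  idx <- selection_indices(selection, nrow(conf$xyz))
  if (length(idx) < 2L) stop("need at least 2 residues after selection")
  xyz <- conf$xyz[idx, , drop = FALSE]
  m <- as.matrix(stats::dist(xyz))
  dimnames(m) <- list(rownames(xyz), rownames(xyz))
  m
}

#' Difference distance matrix
#'
#' Entrywise difference `d^A - d^B` of two distance matrices. Positive entries
#' mark residue pairs further apart in A than in B; the matrix localises where
#' two conformations (or two aligned proteins) differ.
#'
#' @param a,b N x N distance matrices over the same residue set.
#' @return signed N x N matrix (Angstrom).
#' @export
difference_matrix <- function(a, b) {
  check_same_shape(a, b)
  a - b
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("matrix shape mismatch: ",
                                   paste(dim(a), collapse = "x"), " vs ",
                                   paste(dim(b), collapse = "x"))
  la <- rownames(a); lb <- rownames(b)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    warning("residue labels differ between operands")
  invisible(TRUE)
}

#' dRMSD dissimilarity between two structures
#'
#' The distance root-mean-square deviation: the root of the mean, over the
#' N(N-1)/2 unordered residue pairs, of the squared difference between the two
#' distance matrices. Unlike coordinate RMSD it needs no superposition, and it
#' is a pseudometric (a scaled Euclidean norm on pair-distance vectors).
#'
#' @param a,b N x N distance matrices (or `calpha` conformers, converted with
#'   `distance_matrix`).
#' @param selection optional selection applied when conformers are given.
#' @return dRMSD in Angstrom.
#' @export
drmsd <- function(a, b, selection = NULL) {
  if (inherits(a, "calpha")) a <- distance_matrix(a, selection)
  if (inherits(b, "calpha")) b <- distance_matrix(b, selection)
  check_same_shape(a, b)
  v <- a[upper.tri(a)] - b[upper.tri(b)]
  sqrt(mean(v^2))
}

# K x P matrix of condensed pairwise distances (stats::dist order, i.e. the
# lower triangle column-major), one row per frame. P = N(N-1)/2.
pair_dists <- function(ens, selection = NULL, frames = NULL) {
  n <- n_residues(ens)
  idx <- selection_indices(selection, n)
  if (length(idx) < 2L) stop("need at least 2 residues after selection")
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  cols <- as.vector(rbind(3L * (idx - 1L) + 1L, 3L * (idx - 1L) + 2L, 3L * idx))
  P <- length(idx) * (length(idx) - 1L) / 2L
  vals <- vapply(frames, function(f) {
    xyz <- matrix(ens$xyz[f, cols], ncol = 3L, byrow = TRUE)
    as.vector(stats::dist(xyz))
  }, numeric(P))
  # vapply drops to a plain vector when P == 1
  out <- if (P == 1L) matrix(vals, ncol = 1L) else t(vals)
  attr(out, "labels") <- residue_names(ens$labels)[idx]
  out
}

# Condensed vector (dist order) for one conformer over a selection.
condensed_dists <- function(conf, selection = NULL) {
  idx <- selection_indices(selection, nrow(conf$xyz))
  as.vector(stats::dist(conf$xyz[idx, , drop = FALSE]))
}

# Unfold a condensed vector (dist order) into a full symmetric matrix.
unfold_condensed <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}

pairstat <- function(m, kind) {
  attr(m, "kind") <- kind
  attr(m, "units") <- switch(kind, fluctuation = "A^2", "A")
  m
}

#' Fluctuation matrix F
#'
#' Per-pair population variance (divide by K) of the Calpha-Calpha distance
#' across the ensemble. The population form makes Theta's two definitions
#' (RMS dRMSD to the mean distance matrix, and root mean of F) agree exactly.
#'
#' @param ens a `calpha_ensemble` with K >= 2 frames.
#' @param selection optional `residue_selection`.
#' @return symmetric N x N matrix of variances (Angstrom^2), kind "fluctuation".
#' @export
fluctuation_matrix <- function(ens, selection = NULL) {
  if (n_frames(ens) < 2L) stop("fluctuation needs at least 2 frames")
  D <- pair_dists(ens, selection)
  v <- colMeans(sweep(D, 2L, colMeans(D))^2)
  pairstat(unfold_condensed(v, attr(D, "labels")), "fluctuation")
}

#' Flexibility matrix X
#'
#' Per-pair range (max minus min) of the Calpha-Calpha distance across the
#' ensemble. Variance can stay small while rare excursions are large; the
#' range captures those extreme movements.
#'
#' @inheritParams fluctuation_matrix
#' @return symmetric N x N matrix of ranges (Angstrom), kind "flexibility".
#' @export
flexibility_matrix <- function(ens, selection = NULL) {
  if (n_frames(ens) < 2L) stop("flexibility needs at least 2 frames")
  D <- pair_dists(ens, selection)
  v <- apply(D, 2L, max) - apply(D, 2L, min)
  pairstat(unfold_condensed(v, attr(D, "labels")), "flexibility")
}

#' Overall fluctuation Theta
#'
#' Theta is the root mean square of the dRMSD of each frame to the ensemble
#' mean distance matrix -- equivalently, the root of the mean off-diagonal
#' entry of the fluctuation matrix F. It summarises the size of conformational
#' space the (selected) residues explore.
#'
#' @inheritParams fluctuation_matrix
#' @param pair_scope `"all_pairs"` (every pair within the selection, default)
#'   or `"cross_block"` (only pairs spanning the first two blocks of the
#'   selection, e.g. strand x helix).
#' @return object of class `overall_fluctuation` with elements `theta`
#'   (Angstrom), `n_residues`, `n_frames`, `pair_scope`.
#' @export
overall_fluctuation <- function(ens, selection = NULL,
                                pair_scope = c("all_pairs", "cross_block")) {
  pair_scope <- match.arg(pair_scope)
  if (n_frames(ens) < 2L) stop("overall fluctuation needs at least 2 frames")
  D <- pair_dists(ens, selection)
  v <- colMeans(sweep(D, 2L, colMeans(D))^2)
  if (pair_scope == "cross_block") {
    keep <- cross_pair_mask(selection, length(attr(D, "labels")))
    if (!any(keep)) stop("empty pair scope")
    v <- v[keep]
  }
  structure(list(theta = sqrt(mean(v)),
                 n_residues = length(attr(D, "labels")),
                 n_frames = n_frames(ens),
                 pair_scope = pair_scope),
            class = "overall_fluctuation")
}

#' @export
print.overall_fluctuation <- function(x, ...) {
  cat(sprintf("Theta = %.4g A  (N = %d residues, K = %d frames, scope = %s)\n",
              x$theta, x$n_residues, x$n_frames, x$pair_scope))
  invisible(x)
}

# Logical mask over condensed (dist-order) pairs: TRUE for pairs spanning the
# first two blocks of the selection.
cross_pair_mask <- function(selection, n) {
  if (is.null(selection) || is.null(selection$blocks) || length(selection$blocks) < 2L)
    stop("cross_block scope needs a selection with two blocks")
  pos_a <- match(selection$blocks[[1L]], selection$indices)
  pos_b <- match(selection$blocks[[2L]], selection$indices)
  in_a <- seq_len(n) %in% pos_a
  in_b <- seq_len(n) %in% pos_b
  lt <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  (in_a[lt[, 1L]] & in_b[lt[, 2L]]) | (in_b[lt[, 1L]] & in_a[lt[, 2L]])
}

#' Mean absolute difference distance matrix (Delta)
#'
#' Per-pair mean over the given frames of the absolute deviation of the frame
#' distance matrix from a reference distance matrix. Applied to the neighbours
#' of a ligand-bound structure it localises which inter-residue distances
#' change most upon binding.
#'
#' @param ens a `calpha_ensemble` (typically a neighbour subset).
#' @param reference N x N reference distance matrix over the same selection.
#' @param selection optional `residue_selection` applied to the ensemble.
#' @param frames optional frame indices (default: all).
#' @return symmetric N x N matrix (Angstrom), kind "mean_abs_diff".
#' @export
mean_abs_difference_matrix <- function(ens, reference, selection = NULL, frames = NULL) {
  D <- pair_dists(ens, selection, frames)
  ref <- reference[lower.tri(reference)]
  if (length(ref) != ncol(D)) stop("reference shape does not match selection")
  v <- colMeans(abs(sweep(D, 2L, ref)))
  pairstat(unfold_condensed(v, attr(D, "labels")), "mean_abs_diff")
}

#' Cross-block submatrix
#'
#' Extract the rectangular block of a residue-pair matrix whose rows come from
#' one selection block and columns from another (e.g. the 5 x 10 strand x helix
#' submatrix characterising a binding pocket).
#'
#' @param m N x N matrix computed over `selection`.
#' @param selection `residue_selection` with named blocks.
#' @param block_a,block_b block names; must be disjoint.
#' @return |A| x |B| matrix with residue labels.
#' @export
cross_submatrix <- function(m, selection, block_a = "strand", block_b = "helix") {
  if (is.null(selection$blocks)) stop("selection has no blocks")
  if (!all(c(block_a, block_b) %in% names(selection$blocks)))
    stop("unknown block name")
  a <- selection$blocks[[block_a]]
  b <- selection$blocks[[block_b]]
  if (identical(block_a, block_b) || length(intersect(a, b)) > 0L)
    stop("overlapping blocks")
  pos_a <- match(a, selection$indices)
  pos_b <- match(b, selection$indices)
  if (any(is.na(pos_a)) || any(is.na(pos_b)) ||
      max(pos_a, pos_b) > nrow(m)) stop("block indices out of range")
  m[pos_a, pos_b, drop = FALSE]
}

#' Pearson correlation between two pair matrices
#'
#' For square symmetric matrices the correlation is taken over the
#' upper-triangle off-diagonal entries (each unordered pair counted once);
#' for rectangular cross-block submatrices over all entries.
#'
#' @param m1,m2 matrices of equal shape.
#' @return Pearson correlation in \[-1, 1\].
#' @export
matrix_correlation <- function(m1, m2) {
  check_same_shape(m1, m2)
  if (nrow(m1) == ncol(m1)) {
    x <- m1[upper.tri(m1)]; y <- m2[upper.tri(m2)]
  } else {
    x <- as.vector(m1); y <- as.vector(m2)
  }
  if (length(x) < 3L) stop("need at least 3 entries")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in operand")
  stats::cor(x, y)
}

# Kabsch least-squares superposition: rotation (no reflection) + translation
# taking X onto Y. Returns fitted X, rotation and rmsd.
kabsch_fit <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Xc %*% R
  list(xyz = sweep(fitted, 2L, cy, `+`),
       R = R,
       rmsd = sqrt(mean(rowSums((fitted - Yc)^2))))
}

#' Coordinate RMSD after optimal superposition
#'
#' Least-squares rigid-body superposition (rotation + translation, reflections
#' excluded) of paired Calpha sets, followed by coordinate RMSD. Used for
#' Table-style comparisons of aligned structures; all ensemble statistics in
#' this package instead use the superposition-free dRMSD.
#'
#' @param a,b `calpha` conformers.
#' @param pairs two-column matrix/data.frame of (index in a, index in b),
#'   1-based, e.g. from [map_equivalent_residues()]; default pairs all residues
#'   positionally when a and b have equal length.
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(a, b, pairs = NULL) {
  if (is.null(pairs)) {
    if (nrow(a$xyz) != nrow(b$xyz)) stop("pairs required for different-length conformers")
    pairs <- cbind(seq_len(nrow(a$xyz)), seq_len(nrow(a$xyz)))
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3L) stop("need at least 3 residue pairs")
  X <- a$xyz[pairs[, 1L], , drop = FALSE]
  Y <- b$xyz[pairs[, 2L], , drop = FALSE]
  for (Z in list(X, Y)) {
    sv <- svd(sweep(Z, 2L, colMeans(Z)))$d
    if (sv[2L] < 1e-8 * max(sv[1L], 1)) stop("degenerate (collinear) point set")
  }
  kabsch_fit(X, Y)$rmsd
}
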