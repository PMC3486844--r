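#' Construct a Calpha conformer
#'
#' A conformer is an ordered set of alpha-carbon positions together with the
#' residue labels (chain, author residue number, residue name) they belong to.
#' All analyses in this package operate on these reduced representations:
#' residues are represented by their Calpha atoms only.
#'
#' @param labels data.frame with columns `chain`, `resno`, `resid` (one row per
#'   residue, author PDB numbering, per chain).
#' @param xyz numeric N x 3 matrix of Calpha coordinates in Angstrom.
#' @param source_id free-text provenance (e.g. "2rey model 1", "frame 42").
#' @return object of class `calpha`.
#' @export
calpha_conformer <- function(labels, xyz, source_id = "") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (!is.data.frame(labels) || !all(c("chain", "resno", "resid") %in% names(labels)))
    stop("labels must be a data.frame with columns chain, resno, resid")
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  if (nrow(xyz) != nrow(labels))
    stop("coordinate rows (", nrow(xyz), ") do not match residue labels (", nrow(labels), ")")
  if (nrow(xyz) < 2L) stop("a conformer needs at least 2 residues")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  rownames(xyz) <- residue_names(labels)
  structure(list(labels = labels, xyz = xyz, source_id = as.character(source_id)),
            class = "calpha")
}

residue_names <- function(labels) paste0(labels$chain, labels$resno)

#' @export
print.calpha <- function(x, ...) {
  cat("Calpha conformer:", nrow(x$xyz), "residues",
      if (nzchar(x$source_id)) paste0("[", x$source_id, "]") else "", "\n")
  invisible(x)
}

#' Construct a conformational ensemble
#'
#' An ensemble S = \{S_1, ..., S_K\} of K conformers of the same N residues,
#' stored as a K x 3N coordinate matrix (bio3d xyz convention: x1,y1,z1,x2,...).
#' Frame times are in picoseconds; when only `dt` is given, frame k is placed
#' at time k*dt (first snapshot saved after one interval).
#'
#' @param frames list of `calpha` conformers sharing identical residue labels,
#'   or a K x 3N numeric matrix.
#' @param labels residue label data.frame (required when `frames` is a matrix).
#' @param frame_times optional numeric vector of times (ps), strictly increasing.
#' @param dt optional frame spacing (ps).
#' @return object of class `calpha_ensemble` with elements `xyz` (K x 3N),
#'   `labels`, `frame_times`, `dt`.
#' @export
calpha_ensemble <- function(frames, labels = NULL, frame_times = NULL, dt = NULL) {
  if (is.list(frames) && !is.matrix(frames)) {
    if (length(frames) < 1L) stop("ensemble needs at least one frame")
    labels <- frames[[1L]]$labels
    ok <- vapply(frames, function(f) identical(residue_key(f$labels), residue_key(labels)),
                 logical(1))
    if (!all(ok)) stop("all frames must share identical residue labels")
    xyz <- t(vapply(frames, function(f) as.vector(t(f$xyz)), numeric(3L * nrow(labels))))
  } else {
    xyz <- as.matrix(frames)
    if (is.null(labels)) stop("labels required when frames is a matrix")
    if (ncol(xyz) != 3L * nrow(labels)) stop("xyz columns must equal 3 * n residues")
  }
  storage.mode(xyz) <- "double"
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  if (!is.null(dt)) {
    stopifnot(dt > 0)
    if (is.null(frame_times)) frame_times <- dt * seq_len(nrow(xyz))
  }
  if (!is.null(frame_times)) {
    if (length(frame_times) != nrow(xyz)) stop("frame_times length must equal frame count")
    if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
    if (!is.null(dt) && length(frame_times) > 1L &&
        any(abs(diff(frame_times) - dt) > 1e-6))
      stop("frame_times are inconsistent with dt")
  }
  structure(list(xyz = xyz, labels = labels, frame_times = frame_times, dt = dt),
            class = "calpha_ensemble")
}

residue_key <- function(labels) paste(labels$chain, labels$resno, labels$resid)

#' Number of frames / residues in an ensemble
#' @param ens a `calpha_ensemble`.
#' @return integer count.
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' @rdname n_frames
#' @export
n_residues <- function(ens) nrow(ens$labels)

#' Extract one frame of an ensemble as a conformer
#' @param ens a `calpha_ensemble`.
#' @param i frame index (1-based).
#' @return a `calpha` conformer.
#' @export
get_frame <- function(ens, i) {
  i <- as.integer(i)
  if (i < 1L || i > n_frames(ens)) stop("frame index out of range")
  xyz <- matrix(ens$xyz[i, ], ncol = 3L, byrow = TRUE)
  calpha_conformer(ens$labels, xyz, source_id = paste("frame", i))
}

#' @export
print.calpha_ensemble <- function(x, ...) {
  cat("Calpha ensemble: K =", n_frames(x), "frames, N =", n_residues(x), "residues")
  if (!is.null(x$dt)) cat(", dt =", x$dt, "ps")
  cat("\n")
  invisible(x)
}

#' Residue selection
#'
#' An ordered selection of residues (1-based positions into a conformer's
#' residue list), optionally organised in named blocks such as the
#' binding-pocket "strand" and "helix" segments.
#'
#' @param indices integer vector of unique, in-range 1-based positions.
#' @param blocks optional named list of index vectors partitioning `indices`;
#'   indices must ascend within each block.
#' @param n_total optional residue count used for range validation.
#' @return object of class `residue_selection`.
#' @export
residue_selection <- function(indices, blocks = NULL, n_total = NULL) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  if (any(indices < 1L)) stop("selection indices must be positive")
  if (!is.null(n_total) && any(indices > n_total)) stop("selection index out of range")
  if (!is.null(blocks)) {
    blocks <- lapply(blocks, as.integer)
    if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) stop("blocks must be named")
    for (b in blocks) {
      if (any(diff(b) <= 0) && length(b) > 1L) stop("block indices must ascend")
      if (!all(b %in% indices)) stop("block indices must be part of the selection")
    }
  }
  structure(list(indices = indices, blocks = blocks), class = "residue_selection")
}

#' @export
print.residue_selection <- function(x, ...) {
  cat("Residue selection:", length(x$indices), "residues")
  if (!is.null(x$blocks))
    cat(" (", paste(names(x$blocks), vapply(x$blocks, length, 1L),
                    sep = ":", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

# Resolve a selection (or NULL = everything) to 1-based indices.
selection_indices <- function(selection, n) {
  if (is.null(selection)) return(seq_len(n))
  if (inherits(selection, "residue_selection")) idx <- selection$indices
  else idx <- as.integer(selection)
  if (any(idx < 1L | idx > n)) stop("selection index out of range")
  idx
}

# Run code with a temporary, seeded RNG state; the caller's state is restored.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
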