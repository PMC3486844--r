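# Random structures/ensembles and brute-force oracles used across the suite.
# Oracles deliberately use naive double loops, independent of the package's
# vectorised implementations.

rand_labels <- function(n) {
  data.frame(chain = "A", resno = seq_len(n), resid = "ALA", stringsAsFactors = FALSE)
}

rand_conformer <- function(n, seed = 1) {
  set.seed(seed)
  calpha_conformer(rand_labels(n), matrix(runif(3 * n, 0, 10), n, 3),
                   source_id = paste0("rand", seed))
}

rand_ensemble <- function(K, n, seed = 1, dt = 5) {
  set.seed(seed)
  xyz <- matrix(runif(K * 3 * n, 0, 10), K, 3 * n)
  calpha_ensemble(xyz, labels = rand_labels(n), dt = dt)
}

collinear_conformer <- function(xs) {
  n <- length(xs)
  calpha_conformer(rand_labels(n), cbind(xs, 0, 0))
}

full_dm <- function(conf) {
  xyz <- conf$xyz
  n <- nrow(xyz)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  m
}

oracle_drmsd <- function(a, b) {
  n <- nrow(a)
  s <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + (a[i, j] - b[i, j])^2
    np <- np + 1
  }
  sqrt(s / np)
}

# population variance of each pair distance, frame loop
oracle_fluctuation <- function(ens, sel = NULL) {
  frames <- lapply(seq_len(n_frames(ens)), function(f)
    distance_matrix(get_frame(ens, f), sel))
  n <- nrow(frames[[1]])
  K <- length(frames)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- vapply(frames, function(x) x[i, j], numeric(1))
    m[i, j] <- sum((d - mean(d))^2) / K
  }
  m
}

oracle_mad <- function(ens, ref, sel = NULL, frames = seq_len(n_frames(ens))) {
  dms <- lapply(frames, function(f) distance_matrix(get_frame(ens, f), sel))
  n <- nrow(ref)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- mean(vapply(dms, function(x) abs(x[i, j] - ref[i, j]), numeric(1)))
  m
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# per-frame pairwise dRMSD matrix, frame loop
oracle_pairwise_drmsd <- function(ens, sel = NULL, frames = seq_len(n_frames(ens))) {
  dms <- lapply(frames, function(f) distance_matrix(get_frame(ens, f), sel))
  M <- length(dms)
  dd <- matrix(0, M, M)
  for (i in seq_len(M)) for (j in seq_len(M)) dd[i, j] <- oracle_drmsd(dms[[i]], dms[[j]])
  dd
}

# silhouette straight from the per-frame definition
oracle_silhouette <- function(dd, labels) {
  M <- nrow(dd)
  k <- max(labels)
  s <- numeric(M)
  for (i in seq_len(M)) {
    own <- which(labels == labels[i] & seq_len(M) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(dd[i, own])
    b <- min(vapply(setdiff(seq_len(k), labels[i]), function(c)
      mean(dd[i, labels == c]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(s = s, s_over = mean(s))
}

oracle_medoid <- function(dd, members) {
  means <- vapply(seq_along(members), function(i)
    mean(dd[members[i], members[-i]]), numeric(1))
  members[which.min(means)]
}

oracle_q <- function(d_to_ref, ks) {
  sorted <- sort(d_to_ref)
  vapply(ks, function(k) mean(sorted[seq_len(k)]), numeric(1))
}

# minimal superposed RMSD by dense rotation search + Nelder-Mead refinement
oracle_superposed_rmsd <- function(X, Y, grid = 24) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, ca[3], -sa[3], 0, sa[3], ca[3]), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Xc %*% t(rot(ang)) - Yc)^2)))
  gs <- seq(0, 2 * pi, length.out = grid + 1)[-(grid + 1)]
  best <- c(0, 0, 0); best_v <- obj(best)
  for (a in gs) for (b in gs[gs <= pi]) for (c in gs) {
    v <- obj(c(a, b, c))
    if (v < best_v) { best <- c(a, b, c); best_v <- v }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# fixed-width PDB ATOM record (Calpha)
pdb_atom_line <- function(serial, resno, x, y, z, chain = "A", alt = " ",
                          icode = " ", occ = 1, resid = "ALA") {
  sprintf("ATOM  %5d  CA %1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, alt, resid, chain, resno, icode, x, y, z, occ, 0)
}

write_multimodel_pdb <- function(path, models) {
  # models: list of data.frames with resno, x, y, z (+ optional alt, icode, occ)
  lines <- character(0)
  for (m in seq_along(models)) {
    df <- models[[m]]
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (r in seq_len(nrow(df))) {
      lines <- c(lines, pdb_atom_line(r, df$resno[r], df$x[r], df$y[r], df$z[r],
                                      alt = df$alt[r] %||% " ",
                                      icode = df$icode[r] %||% " ",
                                      occ = df$occ[r] %||% 1))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_pockets <- function(sep = 9) {
  list(a = make_reference_pocket(cleft_base_distance = 6.3),
       b = make_reference_pocket(cleft_base_distance = sep))
}
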