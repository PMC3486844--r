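test_that("distance matrices are exact, symmetric and rigid-motion invariant", {
  conf <- collinear_conformer(c(0, 1, 2))
  expect_equal(unname(distance_matrix(conf)),
               matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3))

  r <- rand_conformer(10, seed = 3)
  dm <- distance_matrix(r)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 10))

  # rotated + translated copy
  ang <- 0.9
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  r2 <- r
  r2$xyz <- r$xyz %*% R + matrix(c(4, -2, 7), 10, 3, byrow = TRUE)
  expect_equal(distance_matrix(r2), dm, tolerance = 1e-12)
})

test_that("difference matrices are signed and antisymmetric under operand swap", {
  A <- distance_matrix(collinear_conformer(c(0, 1, 2)))
  B <- distance_matrix(collinear_conformer(c(0, 1, 3)))
  d <- difference_matrix(A, B)
  expect_equal(d[1, 3], -1)
  expect_equal(d[2, 3], -1)
  expect_equal(d[1, 2], 0)
  expect_equal(difference_matrix(A, A), A * 0, ignore_attr = TRUE)
  expect_equal(d + difference_matrix(B, A), A * 0, ignore_attr = TRUE)
  expect_error(difference_matrix(A, matrix(0, 2, 2)), "shape mismatch")
})

test_that("dRMSD follows the unordered-pair averaging convention", {
  A <- distance_matrix(collinear_conformer(c(0, 1, 2)))
  B <- distance_matrix(collinear_conformer(c(0, 1, 3)))
  expect_equal(drmsd(A, A), 0)
  expect_equal(drmsd(A, B), sqrt(2 / 3)) # squared diffs 0, 1, 1 over 3 pairs
  a <- rand_conformer(10, seed = 11); b <- rand_conformer(10, seed = 12)
  expect_lt(abs(drmsd(a, b) - oracle_drmsd(full_dm(a), full_dm(b))), 1e-12)
})

test_that("dRMSD is a pseudometric on random triples", {
  set.seed(42)
  for (i in 1:25) {
    dms <- lapply(1:3, function(j) full_dm(rand_conformer(8, seed = 100 * i + j)))
    ab <- drmsd(dms[[1]], dms[[2]]); bc <- drmsd(dms[[2]], dms[[3]])
    ac <- drmsd(dms[[1]], dms[[3]])
    expect_gte(ab, 0)
    expect_equal(ab, drmsd(dms[[2]], dms[[1]]))
    expect_lte(ac, ab + bc + 1e-12)
  }
})

test_that("fluctuation/flexibility match oracles and obey the range bound", {
  ens <- rand_ensemble(50, 8, seed = 5)
  Fm <- fluctuation_matrix(ens)
  expect_lt(max(abs(Fm - oracle_fluctuation(ens))), 1e-12)

  Xm <- flexibility_matrix(ens)
  expect_true(all(Fm <= Xm^2 / 4 + 1e-12))
  expect_equal(Fm, t(Fm)); expect_equal(Xm, t(Xm))
  expect_true(all(Fm >= 0) && all(Xm >= 0))

  same <- calpha_ensemble(matrix(rep(rand_ensemble(1, 6, seed = 2)$xyz, 5),
                                 5, 18, byrow = TRUE), labels = rand_labels(6))
  expect_equal(max(fluctuation_matrix(same)), 0)
  expect_equal(max(flexibility_matrix(same)), 0)
  expect_error(fluctuation_matrix(calpha_ensemble(matrix(runif(18), 1, 18),
                                                  labels = rand_labels(6))),
               "at least 2 frames")
})

test_that("two-frame example: pair range and variance behave as hand-computed", {
  f1 <- calpha_conformer(rand_labels(2), rbind(c(0, 0, 0), c(2, 0, 0)))
  f2 <- calpha_conformer(rand_labels(2), rbind(c(0, 0, 0), c(3, 0, 0)))
  ens <- calpha_ensemble(list(f1, f2))
  expect_equal(fluctuation_matrix(ens)[1, 2], 0.25)
  expect_equal(flexibility_matrix(ens)[1, 2], 1)
})

test_that("Theta squares to the mean off-diagonal fluctuation entry", {
  f1 <- collinear_conformer(c(0, 1, 2)); f2 <- collinear_conformer(c(0, 1, 3))
  ens <- calpha_ensemble(list(f1, f2))
  th <- overall_fluctuation(ens)
  expect_equal(th$theta, sqrt(1 / 6)) # off-diagonal F entries 0, 0.25, 0.25

  ens2 <- rand_ensemble(100, 10, seed = 8)
  th2 <- overall_fluctuation(ens2)
  Fm <- fluctuation_matrix(ens2)
  expect_lt(abs(th2$theta^2 - mean(Fm[upper.tri(Fm)])), 1e-12)
  # independent route: RMS of per-frame dRMSD to the mean distance matrix
  dms <- lapply(seq_len(100), function(f) full_dm(get_frame(ens2, f)))
  mean_dm <- Reduce(`+`, dms) / length(dms)
  rms <- sqrt(mean(vapply(dms, function(d) oracle_drmsd(d, mean_dm)^2, numeric(1))))
  expect_lt(abs(th2$theta - rms), 1e-12)
})

test_that("Theta supports a strand-x-helix cross-block pair scope", {
  p <- two_pockets()
  lab <- generate_two_state(p$a, p$b, 0.05, 0.05, K = 40, seed = 3)
  sel <- residue_selection(1:15, blocks = list(strand = 1:5, helix = 6:15))
  th_all <- overall_fluctuation(lab$ensemble, sel, "all_pairs")
  th_x <- overall_fluctuation(lab$ensemble, sel, "cross_block")
  # the two pockets differ only in the strand-helix placement, so cross pairs
  # fluctuate more than the within-block pairs
  expect_gt(th_x$theta, th_all$theta)
  # cross scope must equal the mean of the 5x10 submatrix of F
  Fm <- fluctuation_matrix(lab$ensemble, sel)
  sub <- cross_submatrix(Fm, sel)
  expect_lt(abs(th_x$theta^2 - mean(sub)), 1e-12)
  expect_error(overall_fluctuation(lab$ensemble, NULL, "cross_block"))
})

test_that("mean absolute difference matrix matches its brute-force oracle", {
  ens <- rand_ensemble(12, 7, seed = 21)
  ref <- distance_matrix(get_frame(ens, 1))
  expect_equal(max(mean_abs_difference_matrix(
    calpha_ensemble(ens$xyz[1, , drop = FALSE], labels = ens$labels), ref)), 0)

  d <- mean_abs_difference_matrix(ens, ref)
  expect_lt(max(abs(d - oracle_mad(ens, ref))), 1e-12)

  f1 <- calpha_conformer(rand_labels(2), rbind(c(0, 0, 0), c(2, 0, 0)))
  f2 <- calpha_conformer(rand_labels(2), rbind(c(0, 0, 0), c(4, 0, 0)))
  refm <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(mean_abs_difference_matrix(calpha_ensemble(list(f1, f2)), refm)[1, 2], 1)
})

test_that("cross submatrices pick exactly the strand-x-helix block", {
  sel <- residue_selection(1:15, blocks = list(strand = 1:5, helix = 6:15))
  m <- matrix(seq_len(225), 15, 15)
  sub <- cross_submatrix(m, sel)
  expect_equal(dim(sub), c(5L, 10L))
  expect_equal(sub[2, 3], m[2, 8])
  expect_equal(unname(sub), m[1:5, 6:15])
  expect_error(cross_submatrix(m, sel, "strand", "strand"), "overlapping")
})

test_that("matrix correlation follows the two-pass Pearson formula", {
  m <- matrix(runif(25), 5, 5); m <- m + t(m)
  expect_equal(matrix_correlation(m, m), 1)
  expect_equal(matrix_correlation(m, -2 * m + 3), -1)
  set.seed(6)
  a <- matrix(rnorm(50), 5, 10); b <- matrix(rnorm(50), 5, 10)
  expect_lt(abs(matrix_correlation(a, b) - oracle_pearson(as.vector(a), as.vector(b))),
            1e-12)
  expect_error(matrix_correlation(m, matrix(1, 5, 5)), "zero variance")
})

test_that("superposed RMSD is zero for rigid copies and matches the grid oracle", {
  a <- rand_conformer(6, seed = 31)
  expect_equal(superposed_rmsd(a, a), 0, tolerance = 1e-9)

  ang <- 1.2
  R <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0, -sin(ang), 0, cos(ang)), 3, 3)
  b <- a; b$xyz <- a$xyz %*% R + matrix(c(-3, 5, 1), 6, 3, byrow = TRUE)
  expect_lt(superposed_rmsd(a, b), 1e-9)

  # 4-point set with one perturbed coordinate: compare to dense rotation search
  X <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  Y <- X; Y[1, 1] <- Y[1, 1] + 0.2
  ca <- calpha_conformer(rand_labels(4), X)
  cb <- calpha_conformer(rand_labels(4), Y)
  ours <- superposed_rmsd(ca, cb)
  expect_lt(abs(ours - oracle_superposed_rmsd(X, Y)), 1e-3)
  # independent library cross-check (bio3d rounds its return to 3 decimals)
  expect_lt(abs(ours - bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE)),
            1e-3)

  expect_error(superposed_rmsd(ca, cb, pairs = cbind(1:2, 1:2)), "at least 3")
  lin <- calpha_conformer(rand_labels(4), cbind(1:4, 0, 0))
  expect_error(superposed_rmsd(lin, lin), "collinear")
})

test_that("ensemble statistics are invariant to rigid motion of input frames", {
  ens <- rand_ensemble(15, 6, seed = 44)
  rot <- function(v) {
    xyz <- matrix(v, ncol = 3, byrow = TRUE)
    ang <- 0.6
    R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
    as.vector(t(xyz %*% R + matrix(c(1, 2, 3), nrow(xyz), 3, byrow = TRUE)))
  }
  moved <- calpha_ensemble(t(apply(ens$xyz, 1, rot)), labels = ens$labels)
  expect_equal(fluctuation_matrix(moved), fluctuation_matrix(ens), tolerance = 1e-10)
  expect_equal(flexibility_matrix(moved), flexibility_matrix(ens), tolerance = 1e-10)
  expect_equal(overall_fluctuation(moved)$theta, overall_fluctuation(ens)$theta,
               tolerance = 1e-10)
})
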