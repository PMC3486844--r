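test_that("burn-in and striding select the documented frame subsets", {
  # 40000 snapshots at 5 ps (times 5..200000), 1 ns burn-in, 50 ps stride
  ens <- calpha_ensemble(matrix(0, 40000, 6) + runif(40000 * 6),
                         labels = rand_labels(2), dt = 5)
  idx <- strided_frames(ens, stride = 10L, burn_in = 1000)
  expect_length(idx, 3981L)
  expect_equal(ens$frame_times[idx[1]], 1000)
  expect_equal(diff(ens$frame_times[idx[1:3]]), c(50, 50))

  expect_equal(strided_frames(ens, 1L, 0), seq_len(40000L))
  expect_error(strided_frames(ens, 1L, 1e9), "no frames")
})

test_that("dissimilarity matrices are symmetric, zero-diagonal and accept references", {
  ens <- rand_ensemble(10, 6, seed = 13)
  d <- dissimilarity_matrix(ens)
  expect_equal(dim(d), c(10L, 10L))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 10))
  dd <- oracle_pairwise_drmsd(ens)
  expect_lt(max(abs(unname(d) - dd)), 1e-12)

  refs <- list(r1 = get_frame(ens, 1), r2 = rand_conformer(6, seed = 99),
               r3 = rand_conformer(6, seed = 98), r4 = rand_conformer(6, seed = 97))
  d14 <- dissimilarity_matrix(ens, extra_refs = refs)
  expect_equal(dim(d14), c(14L, 14L))
  expect_equal(d14["frame1", "r1"], 0)
  expect_error(dissimilarity_matrix(ens, extra_refs = list(rand_conformer(4, seed = 1))),
               "does not map")
})

test_that("k = 1 clustering reproduces the Theta identity for WCSS", {
  ens <- rand_ensemble(30, 8, seed = 17)
  cr <- kmeans_states(ens, k = 1, seed = 1, n_init = 2)
  th <- overall_fluctuation(ens)
  expect_lt(abs(cr$wcss - n_frames(ens) * th$theta^2), 1e-10)
  expect_equal(cr$sizes, 30L)
})

test_that("WCSS decreases monotonically and agrees with Euclidean k-means", {
  p <- two_pockets()
  lab <- generate_two_state(p$a, p$b, 0.03, 0.08, K = 200, seed = 5)
  cr <- kmeans_states(lab$ensemble, k = 2, seed = 2, n_init = 5)
  expect_true(all(diff(cr$wcss_trace) <= 1e-12))
  # the objective is Euclidean k-means on condensed pair-distance vectors
  D <- t(vapply(seq_len(200), function(f)
    as.vector(dist(get_frame(lab$ensemble, f)$xyz)), numeric(105)))
  km <- stats::kmeans(D, centers = 2, nstart = 10, iter.max = 50)
  expect_equal(cr$wcss, km$tot.withinss / 105, tolerance = 1e-8)
  # centroids are the mean distance matrices of the members
  m1 <- Reduce(`+`, lapply(which(cr$labels == 1), function(f)
    distance_matrix(get_frame(lab$ensemble, f)))) / sum(cr$labels == 1)
  expect_equal(cr$cluster_means[[1]], m1, tolerance = 1e-10)
})

test_that("clustering identical frames re-seeds empty clusters and terminates", {
  xyz <- matrix(rep(as.vector(t(rand_conformer(5, seed = 7)$xyz)), 12), 12, 15,
                byrow = TRUE)
  ens <- calpha_ensemble(xyz, labels = rand_labels(5))
  cr <- kmeans_states(ens, k = 2, seed = 1, n_init = 2)
  expect_equal(cr$k, 2L)
  expect_true(all(cr$sizes >= 1L))
  expect_equal(cr$wcss, 0)
})

test_that("clustering is deterministic given a seed", {
  ens <- rand_ensemble(40, 6, seed = 23)
  a <- kmeans_states(ens, k = 3, seed = 10, n_init = 5)
  b <- kmeans_states(ens, k = 3, seed = 10, n_init = 5)
  expect_identical(a$labels, b$labels)
  expect_identical(a$wcss, b$wcss)
})

test_that("silhouettes hit their closed-form values and the brute-force oracle", {
  # two internally-identical clusters 1 A apart in dRMSD -> all S(i) = 1
  f1 <- collinear_conformer(c(0, 1, 2))
  f2 <- collinear_conformer(c(0, 1, 2 + sqrt(3 / 2))) # drmsd = 1 to f1
  ens <- calpha_ensemble(list(f1, f1, f2, f2))
  sil <- silhouette_validate(ens, labels = c(1, 1, 2, 2))
  expect_equal(sil$s, rep(1, 4))
  expect_equal(sil$s_over, 1)

  # a frame equidistant between its own and the other cluster: a = b -> S = 0
  mid <- collinear_conformer(c(0, 1, 2 + sqrt(3 / 2) / 2))
  ens2 <- calpha_ensemble(list(f1, mid, f2, f2))
  sil2 <- silhouette_validate(ens2, labels = c(1, 1, 2, 2))
  expect_equal(sil2$s[2], 0)

  ens3 <- rand_ensemble(25, 6, seed = 31)
  set.seed(4)
  labs <- sample(1:3, 25, replace = TRUE)
  labs[1:3] <- 1:3 # every cluster nonempty
  sil3 <- silhouette_validate(ens3, labels = labs)
  o <- oracle_silhouette(oracle_pairwise_drmsd(ens3), labs)
  expect_lt(max(abs(sil3$s - o$s)), 1e-12)
  expect_lt(abs(sil3$s_over - o$s_over), 1e-12)
  expect_true(all(sil3$s >= -1 & sil3$s <= 1))

  # permutation invariance of cluster ids
  perm <- c(2L, 3L, 1L)[labs]
  sil4 <- silhouette_validate(ens3, labels = perm)
  expect_equal(sil4$s, sil3$s)

  # cross-check against the reference library implementation
  skip_if_not_installed("cluster")
  dd <- dissimilarity_matrix(ens3)
  cs <- cluster::silhouette(labs, dmatrix = unname(dd))
  expect_equal(sil3$s, unname(cs[, "sil_width"]), tolerance = 1e-12)
})

test_that("singleton clusters take silhouette zero by convention", {
  ens <- rand_ensemble(6, 5, seed = 41)
  sil <- silhouette_validate(ens, labels = c(1, 1, 1, 1, 1, 2))
  expect_equal(sil$s[6], 0)
  expect_error(silhouette_validate(ens, labels = rep(1, 6)), "at least 2")
})

test_that("select_k recovers the true state count on clean synthetic ensembles", {
  p <- two_pockets()
  lab2 <- generate_two_state(p$a, p$b, 0.03, 0.05, K = 150, seed = 8)
  sk2 <- select_k(lab2$ensemble, k_range = 2:4, seed = 1, n_init = 5)
  expect_equal(sk2$best_k, 2L)
  expect_named(sk2$results, c("k2", "k3", "k4"))

  pc <- make_reference_pocket(cleft_base_distance = 12)
  lab3 <- generate_markov_states(list(p$a, p$b, pc), 0.03, 0.05, K = 150, seed = 9)
  sk3 <- select_k(lab3$ensemble, k_range = 2:4, seed = 1, n_init = 5)
  expect_equal(sk3$best_k, 3L)
  expect_error(select_k(lab2$ensemble, k_range = integer(0)), "empty k range")
})

test_that("medoids minimise mean dissimilarity with earliest-frame tie-break", {
  base <- rand_conformer(5, seed = 51)
  far <- rand_conformer(5, seed = 52)
  xyz <- rbind(matrix(rep(as.vector(t(base$xyz)), 9), 9, 15, byrow = TRUE),
               as.vector(t(far$xyz)))
  ens <- calpha_ensemble(xyz, labels = rand_labels(5))
  expect_equal(medoid(ens, member_frames = 1:10), 1L) # duplicated frame, earliest tie
  expect_equal(medoid(ens, member_frames = 10L), 10L) # single member
  expect_error(medoid(ens, member_frames = integer(0)), "empty")

  ens2 <- rand_ensemble(20, 6, seed = 53)
  dd <- oracle_pairwise_drmsd(ens2)
  expect_equal(medoid(ens2, member_frames = 1:20), oracle_medoid(dd, 1:20))
})

test_that("outlier detection is inclusive at the threshold", {
  # single-pair conformers keep the arithmetic exact: drmsd = |d - d_ref|
  f0 <- collinear_conformer(c(0, 1))
  exact <- collinear_conformer(c(0, 1.75)) # drmsd to f0 exactly 0.75
  ens <- calpha_ensemble(list(f0, f0, exact, f0))
  out <- find_outliers(ens, medoid_frame = 1L, threshold = 0.75)
  expect_equal(out, 3L)
  same <- calpha_ensemble(list(f0, f0, f0))
  expect_length(find_outliers(same, medoid_frame = 1L, threshold = 0.8), 0L)
  expect_error(find_outliers(ens, medoid_frame = 1L, threshold = 0), "positive")
})

test_that("classical MDS reproduces plane- and space-embeddable distances", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  d <- as.matrix(dist(sq))
  emb <- cmds_embed(d, dims = 2)
  expect_lt(max(abs(as.matrix(dist(emb$coords)) - d)), 1e-9)
  expect_lt(max(abs(emb$eigenvalues[3:4])), 1e-9)

  set.seed(77)
  pts <- matrix(rnorm(30), 10, 3)
  d3 <- as.matrix(dist(pts))
  emb3 <- cmds_embed(d3, dims = 3)
  expect_lt(max(abs(as.matrix(dist(emb3$coords)) - d3)), 1e-8)

  # identical points coincide; all-zero input warns and returns zeros
  d0 <- matrix(0, 3, 3)
  expect_warning(e0 <- cmds_embed(d0, dims = 2), "zero")
  expect_equal(unname(e0$coords), matrix(0, 3, 2))

  dup <- rbind(pts, pts[1, ])
  embd <- cmds_embed(as.matrix(dist(dup)), dims = 3)
  expect_lt(max(abs(embd$coords[11, ] - embd$coords[1, ])), 1e-8)

  # sign canonicalisation makes repeated embeddings identical
  expect_identical(cmds_embed(d3, 2)$coords, cmds_embed(d3, 2)$coords)
})

test_that("external conformers project onto the nearest cluster centroid", {
  p <- two_pockets()
  lab <- generate_two_state(p$a, p$b, 0.05, 0.05, K = 100, seed = 12)
  cr <- kmeans_states(lab$ensemble, k = 2, seed = 1, n_init = 5)
  got <- assign_to_clusters(cr, list(p$a, p$b))
  # the two references must land in different clusters
  expect_length(unique(got), 2L)
  # and each on the side its generator state dominates
  state_of_cluster <- vapply(1:2, function(c)
    as.integer(round(mean(lab$true_labels[cr$labels == c]))), integer(1))
  expect_equal(state_of_cluster[got], 1:2)
})
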