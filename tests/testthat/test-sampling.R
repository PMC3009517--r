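# Quaternion (Horn) superposition oracle, independent of the Kabsch/SVD
# route used by the package.
quaternion_superpose_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  S <- t(P0) %*% Q0
  key <- function(i, j) S[i, j]
  N <- matrix(c(
    key(1,1)+key(2,2)+key(3,3), key(2,3)-key(3,2), key(3,1)-key(1,3), key(1,2)-key(2,1),
    key(2,3)-key(3,2), key(1,1)-key(2,2)-key(3,3), key(1,2)+key(2,1), key(3,1)+key(1,3),
    key(3,1)-key(1,3), key(1,2)+key(2,1), -key(1,1)+key(2,2)-key(3,3), key(2,3)+key(3,2),
    key(1,2)-key(2,1), key(3,1)+key(1,3), key(2,3)+key(3,2), -key(1,1)-key(2,2)+key(3,3)),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
}

small_bundle_pool <- function(seed = 3, samples = 4, workers = 1) {
  b <- make_bundle(bundle_spec(n_helices = 2, helix_lengths = c(10, 14),
                               seed = seed))
  list(bundle = b,
       pool = predict_structures(b$skeletons, b$sequence, b$segments,
                                 samples = samples, seed = 7,
                                 workers = workers))
}

test_that("rank percentiles match the reporting convention", {
  expect_equal(percentile_of_rank(759, 219000), 0.35)
  expect_equal(percentile_of_rank(10, 3000), 0.33)
  expect_equal(percentile_of_rank(500, 500), 100)
})

test_that("pool ranking is a stable ascending sort with documented ties", {
  ent <- data.frame(topo_index = c(1L, 2L, 3L, 2L), sample = c(1L, 1L, 1L, 2L),
                    energy = c(-5, -7, -5, -5))
  p <- rank_pool(ent)
  expect_equal(p$entries$energy, c(-7, -5, -5, -5))
  # equal energies: topology order, then sample index
  expect_equal(p$entries$topo_index[2:4], c(1L, 2L, 3L))
  rev_in <- ent[order(-ent$energy), ]
  expect_equal(rank_pool(rev_in)$entries$energy, c(-7, -5, -5, -5))
})

test_that("annealing is deterministic and samples_per_topology scales pools", {
  b <- make_bundle(bundle_spec(n_helices = 2, helix_lengths = c(10, 14),
                               seed = 3))
  tp <- b$truth$topology
  r1 <- sample_topology(tp, b$skeletons, b$segments, b$sequence,
                        n_samples = 6, seed = 11, topo_index = 2)
  r2 <- sample_topology(tp, b$skeletons, b$segments, b$sequence,
                        n_samples = 6, seed = 11, topo_index = 2)
  expect_identical(r1, r2)
  r3 <- sample_topology(tp, b$skeletons, b$segments, b$sequence,
                        n_samples = 6, seed = 12, topo_index = 2)
  expect_false(identical(r1$energy, r3$energy))

  sp <- small_bundle_pool(samples = 3)
  expect_equal(length(sp$pool), 3 * sp$pool$meta$n_valid)
  expect_equal(sp$pool$meta$n_generated, length(sp$pool))
})

test_that("zero-temperature annealing is pure greedy descent", {
  b <- make_bundle(bundle_spec(n_helices = 2, helix_lengths = c(10, 14),
                               seed = 3))
  sched <- anneal_schedule(T0 = 1e-9, T_min = 1e-10, alpha = 0.5,
                           steps_per_T = 100)
  r <- sample_topology(b$truth$topology, b$skeletons, b$segments,
                       b$sequence, n_samples = 20, schedule = sched,
                       seed = 5)
  expect_true(all(r$energy <= r$energy0))
})

test_that("annealing improves on the initial state for almost all runs", {
  sp <- small_bundle_pool(samples = 10)
  e <- sp$pool$entries
  expect_gte(mean(e$energy <= e$energy0), 0.95)
})

test_that("C++ annealing energies agree with the R contact energy", {
  sp <- small_bundle_pool(samples = 3)
  pool <- sp$pool
  for (r in c(1L, length(pool))) {
    m <- pool_model(pool, r, select = "first")
    expect_equal(contact_energy(m, pool$meta$config$energy),
                 pool$entries$energy[pool$entries$rank == r],
                 tolerance = 1e-9)
  }
})

test_that("prediction is byte-identical across worker counts", {
  csvs <- lapply(c(1, 2, 4), function(w) {
    sp <- small_bundle_pool(samples = 3, workers = w)
    f <- tempfile(fileext = ".csv")
    write_ranked_csv(sp$pool, f)
    readBin(f, "raw", file.info(f)$size)
  })
  expect_identical(csvs[[1]], csvs[[2]])
  expect_identical(csvs[[1]], csvs[[3]])
})

test_that("backbone RMSD matches definitions and the quaternion oracle", {
  b <- make_bundle(bundle_spec(n_helices = 3, seed = 2))
  native <- b$truth$native
  expect_equal(backbone_rmsd(native, native), 0)

  shifted <- native
  for (k in seq_along(shifted$helices))
    for (i in seq_along(shifted$helices[[k]]$resno))
      shifted$helices[[k]]$bb[i, , ] <- shifted$helices[[k]]$bb[i, , ] +
        rep(c(3/sqrt(3), 3/sqrt(3), 3/sqrt(3)), each = 4)
  expect_equal(backbone_rmsd(shifted, native), 3, tolerance = 1e-9)
  expect_equal(backbone_rmsd(shifted, native, superpose = TRUE), 0,
               tolerance = 1e-7)

  # randomly deformed toy coordinates: Kabsch result equals the quaternion
  # brute-force oracle
  set.seed(9)
  for (rep in 1:5) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- P + matrix(rnorm(30, 0, 0.5), 10, 3)
    got <- sqrt(mean(rowSums((hxskel:::kabsch_transform(P, Q) - Q)^2)))
    expect_equal(got, quaternion_superpose_rmsd(P, Q), tolerance = 1e-9)
  }

  other <- native
  for (k in seq_along(other$helices))
    other$helices[[k]]$resno <- other$helices[[k]]$resno + 1000L
  expect_error(backbone_rmsd(other, native), "share no residue")
})

test_that("combining regions ranks pair sums lazily and screens conflicts", {
  # hand-built pools over one shared sequence: K = 1 skeleton per region
  cfg <- read_config()
  meta_a <- list(K = 1L, skeleton_ids = "S1",
                 segments = list(segment_rec("H1", 5, 12),
                                 segment_rec("H2", 20, 27)),
                 sequence = strrep("A", 40), config = cfg,
                 skeleton_residues = 8L)
  meta_b <- meta_a
  meta_b$skeleton_ids <- "S2"
  mk <- function(meta, segs, energies) {
    ent <- data.frame(topo_index = seq_along(segs), sample = 1L,
                      topology = paste0("H", segs), energy = energies,
                      seg_1 = segs, dir_1 = 1L, s_1 = 0L, theta_1 = 0,
                      t_1 = 0)
    rank_pool(ent, meta)
  }
  pa <- mk(meta_a, c(1L, 2L), c(-10, -8))
  pb <- mk(meta_b, c(2L, 1L), c(-9, -7))
  cp <- combine_regions(pa, pb, top_pairs = 10)
  expect_equal(cp$prescreen_pairs, 4)
  # conflict-free pairs: (H1,H2)=-19, (H1,H1) conflict, (H2,H2) conflict,
  # (H2,H1)=-15
  expect_equal(nrow(cp$pairs), 2)
  expect_equal(cp$pairs$energy, c(-19, -15))
  expect_equal(cp$n_conflict, 2L)
  # shared skeleton ids refuse to combine
  expect_error(combine_regions(pa, pa), "share skeleton")
  # Cartesian product size at two-region scale stays exact in doubles
  expect_equal(combined_pool_size(6973800, 8473300), 5909109954e4)
  expect_equal(signif(combined_pool_size(6973800, 8473300), 2), 5.9e13)
})
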