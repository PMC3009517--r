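# Brute-force oracle: all ordered K-subsets x direction sign vectors,
# built with plain nested loops via recursion.
brute_force_topologies <- function(N, K) {
  out <- list()
  recurse <- function(prefix) {
    if (length(prefix) == K) {
      dirs <- expand.grid(rep(list(c(-1L, 1L)), K))
      for (r in seq_len(nrow(dirs)))
        out[[length(out) + 1L]] <<- list(segments = prefix,
                                         directions = as.integer(dirs[r, ]))
      return()
    }
    for (j in setdiff(seq_len(N), prefix)) recurse(c(prefix, j))
  }
  recurse(integer(0))
  out
}

topo_key <- function(tp) paste(c(tp$segments, tp$directions), collapse = ",")

test_that("topology count formula matches brute-force enumeration size", {
  for (N in 1:6) for (K in 1:N) {
    expect_equal(count_topologies(N, K),
                 factorial(N) / factorial(N - K) * 2^K)
    expect_equal(length(enumerate_topologies(N, K)), count_topologies(N, K))
  }
  expect_equal(count_topologies(1, 1), 2)
  expect_error(count_topologies(3, 4), "K <= N")
  expect_error(count_topologies(3, 0), "K <= N")
})

test_that("enumeration is exhaustive, distinct, and deterministically ordered", {
  # exhaustive set equality against the nested-loop oracle
  for (N in 2:5) for (K in 1:N) {
    got <- enumerate_topologies(N, K)
    keys <- vapply(seq_len(length(got)),
                   function(i) topo_key(hxskel:::topology_at(got, i)),
                   character(1))
    oracle <- vapply(brute_force_topologies(N, K), topo_key, character(1))
    expect_setequal(keys, oracle)
    expect_false(anyDuplicated(keys) > 0)
  }
  # documented order for (2,1): (1,-),(1,+),(2,-),(2,+)
  e <- enumerate_topologies(2, 1)
  expect_equal(e$segments[, 1], c(1L, 1L, 2L, 2L))
  expect_equal(e$directions[, 1], c(-1L, 1L, -1L, 1L))
})

test_that("skeleton residue estimate follows the 1.3 A rise rule", {
  p <- screening_params()
  expect_equal(estimate_skeleton_residues(straight_skeleton("s", L = 13), p),
               11L)
  expect_equal(estimate_skeleton_residues(straight_skeleton("s", L = 26), p),
               21L)
  expect_equal(estimate_skeleton_residues(straight_skeleton("s", L = 1.3), p),
               2L)
  p2 <- screening_params(endpoint_convention = FALSE)
  expect_equal(estimate_skeleton_residues(straight_skeleton("s", L = 13), p2),
               10L)
})

test_that("length screen compares residue counts with inclusive boundary", {
  # skeleton of 10 estimated residues: axis length 9 * 1.3 = 11.7
  sk10 <- straight_skeleton("s", L = 11.7)
  expect_equal(estimate_skeleton_residues(sk10), 10L)
  expect_true(length_screen(sk10, segment_rec("h", 1, 15)))   # |10-15| = 5
  expect_false(length_screen(sk10, segment_rec("h", 1, 16)))  # |10-16| = 6
  expect_true(length_screen(sk10, segment_rec("h", 1, 10)))
})

test_that("distance screen eliminates by strict loop-reachability inequality", {
  # two parallel skeletons; C-end of first to N-start of second = 26.6 A
  skA <- straight_skeleton("A", from = c(0, 0, 0), L = 10)
  skB <- straight_skeleton("B", from = c(0, 0, 10 + 26.6), L = 10)
  segs <- list(segment_rec("H1", 1, 9), segment_rec("H2", 15, 23))
  tp <- list(segments = c(1L, 2L), directions = c(1L, 1L))
  p <- screening_params(s_max = 2)
  # n_loop = 5: threshold 3.8 * 9 = 34.2 > 26.6 -> retained
  expect_true(distance_screen(tp, list(skA, skB), segs, p))
  # n_loop = 0: threshold 15.2 < 26.6 -> eliminated
  segs0 <- list(segment_rec("H1", 1, 9), segment_rec("H2", 10, 18))
  expect_false(distance_screen(tp, list(skA, skB), segs0, p))
  # boundary: d exactly equal to threshold is retained (rule is strict >)
  skB2 <- straight_skeleton("B", from = c(0, 0, 10 + 3.8 * 9), L = 10)
  expect_true(distance_screen(tp, list(skA, skB2), segs, p))
  skB3 <- straight_skeleton("B", from = c(0, 0, 10 + 3.8 * 9 + 0.001), L = 10)
  expect_false(distance_screen(tp, list(skA, skB3), segs, p))
})

test_that("screening respects directions when picking axis endpoints", {
  skA <- straight_skeleton("A", from = c(0, 0, 0), L = 10)
  skB <- straight_skeleton("B", from = c(0, 0, 18), L = 10)
  segs0 <- list(segment_rec("H1", 1, 9), segment_rec("H2", 10, 18))
  p <- screening_params(s_max = 2)
  # antiparallel second helix: its N-start is the far end (z = 28), d = 18
  tp_anti <- list(segments = c(1L, 2L), directions = c(1L, -1L))
  expect_false(distance_screen(tp_anti, list(skA, skB), segs0, p))
  # parallel: N-start at z = 18, d = 8 < 15.2 -> retained
  tp_par <- list(segments = c(1L, 2L), directions = c(1L, 1L))
  expect_true(distance_screen(tp_par, list(skA, skB), segs0, p))
})

test_that("valid_topologies keeps the truth, prunes the impossible", {
  b <- make_bundle(bundle_spec(n_helices = 3, seed = 11))
  vt <- valid_topologies(b$skeletons, b$segments)
  keys <- vapply(seq_len(length(vt)),
                 function(i) topo_key(hxskel:::topology_at(vt, i)),
                 character(1))
  expect_true(topo_key(b$truth$topology) %in% keys)
  expect_equal(attr(vt, "n_possible"), 48)
  expect_lte(length(vt), 48)

  # skeletons moved 500 A apart with short loops: nothing survives
  far <- b$skeletons
  for (k in seq_along(far)) far[[k]]$points <-
    far[[k]]$points + (k - 1) * 500
  expect_equal(length(valid_topologies(far, b$segments)), 0L)

  # screens relaxed to no-op: full topology space returned
  segsame <- list(segment_rec("H1", 4, 13), segment_rec("H2", 17, 26))
  sk2 <- list(straight_skeleton("A", L = 1.3 * 9),
              straight_skeleton("B", from = c(8, 0, 0), L = 1.3 * 9))
  p_off <- screening_params(loop_rate = 1e9, length_tol = 1)
  expect_equal(length(valid_topologies(sk2, segsame, p_off)),
               count_topologies(2, 2))
})

test_that("screening is monotone in s_max and length_tol", {
  b <- make_bundle(bundle_spec(n_helices = 3, seed = 5))
  base <- length(valid_topologies(b$skeletons, b$segments,
                                  screening_params(s_max = 1,
                                                   length_tol = 0.3)))
  bigger_s <- length(valid_topologies(b$skeletons, b$segments,
                                      screening_params(s_max = 3,
                                                       length_tol = 0.3)))
  bigger_tol <- length(valid_topologies(b$skeletons, b$segments,
                                        screening_params(s_max = 1,
                                                         length_tol = 0.8)))
  expect_gte(bigger_s, base)
  expect_gte(bigger_tol, base)
})
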