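bb_at <- function(ih, i, a) ih$xyz[(i - 1) * 4 + match(a, c("N", "CA", "C", "O")), ]

recompute_phi_psi <- function(xyz, n) {
  idx <- function(i, a) (i - 1) * 4 + match(a, c("N", "CA", "C", "O"))
  phi <- vapply(2:n, function(i)
    dihedral(xyz[idx(i - 1, "C"), ], xyz[idx(i, "N"), ],
             xyz[idx(i, "CA"), ], xyz[idx(i, "C"), ]), numeric(1))
  psi <- vapply(1:(n - 1), function(i)
    dihedral(xyz[idx(i, "N"), ], xyz[idx(i, "CA"), ],
             xyz[idx(i, "C"), ], xyz[idx(i + 1, "N"), ]), numeric(1))
  list(phi = phi, psi = psi)
}

test_that("ideal helix reproduces its construction torsions and geometry", {
  ih <- build_ideal_helix(10)
  tors <- recompute_phi_psi(ih$xyz, 10)
  expect_lt(max(abs(tors$phi - (-60))), 1e-6)
  expect_lt(max(abs(tors$psi - (-50))), 1e-6)
  ca <- ih$xyz[ih$atom == "CA", ]
  dd <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(dd - 3.8) < 0.1))
  expect_error(build_ideal_helix(1), "at least 2")
})

test_that("the geometric rise is ~1.5 A/residue and constant along the axis", {
  ih <- build_ideal_helix(12)
  ca <- ih$xyz[ih$atom == "CA", ]
  # brute-force projection of each CA onto the fitted helix axis
  ax <- helix_axis(ca)
  proj <- as.vector(sweep(ca, 2, ax$point) %*% ax$dir)
  rises <- diff(sort(proj))
  expect_lt(stats::sd(rises), 0.01)
  expect_gt(mean(rises), 1.4)
  expect_lt(mean(rises), 1.6)
  # canonical frame: axis is +z through the origin, first CA azimuth 0
  expect_lt(abs(abs(ax$dir[3]) - 1), 1e-9)
  expect_lt(sqrt(sum(ax$point[1:2]^2)), 1e-9)
  expect_lt(abs(ca[1, 2]), 1e-9)
  expect_gt(ca[1, 1], 0)
  # all CAs sit on one cylinder around the axis
  expect_lt(ax$residual, 1e-9)
})

test_that("axis fit matches an SVD oracle and handles degenerate input", {
  pts <- cbind(0, 0, c(0, 4, 9, 13))
  ax <- fit_axis_line(pts)
  expect_equal(ax$residual, 0)
  expect_equal(ax$length, 13)
  expect_equal(abs(ax$dir), c(0, 0, 1))
  # noisy cloud: residual equals the direct SVD tail
  set.seed(4)
  noisy <- cbind(rnorm(20, 0, 0.3), rnorm(20, 0, 0.3), seq(0, 19))
  ax2 <- fit_axis_line(noisy)
  sv <- svd(sweep(noisy, 2, colMeans(noisy)))
  expect_equal(ax2$residual, sqrt(sum(sv$d[2:3]^2)), tolerance = 1e-9)
  # two points: the segment itself
  ax3 <- fit_axis_line(rbind(c(1, 1, 1), c(1, 1, 6)))
  expect_equal(ax3$length, 5)
  expect_equal(ax3$p0, c(1, 1, 1))
})

test_that("placement puts the helix on the axis and composes rotations", {
  ih <- build_ideal_helix(9)
  sk <- straight_skeleton("s", from = c(2, -1, 0), dir = c(1, 2, 2), L = 12)
  ax <- fit_axis_line(sk)
  w <- place_helix(ih, ax, 1L, theta = 30, t = 0)
  ca <- w[ih$atom == "CA", ]
  fitted <- helix_axis(ca)
  expect_lt(abs(abs(sum(fitted$dir * ax$dir)) - 1), 1e-9)
  # helix axis mid-span lands on the skeleton axis midpoint
  expect_lt(sqrt(sum(((fitted$p0 + fitted$p1) / 2 -
                        (ax$p0 + ax$p1) / 2)^2)), 1e-9)

  # theta-composition: rotating theta by delta rotates atoms about the axis
  w2 <- place_helix(ih, ax, 1L, theta = 30 + 360, t = 0)
  expect_lt(max(abs(w - w2)), 1e-9)
  # direction flip reverses CA order along the axis
  wr <- place_helix(ih, ax, -1L, theta = 0, t = 0)
  pr <- as.vector(sweep(wr[ih$atom == "CA", ], 2, ax$point) %*% ax$dir)
  pf <- as.vector(sweep(place_helix(ih, ax, 1L, 0, 0)[ih$atom == "CA", ],
                        2, ax$point) %*% ax$dir)
  expect_lt(max(abs(pr - rev(pf))), 1e-9)
  # t translates along the axis
  wt <- place_helix(ih, ax, 1L, theta = 30, t = 2.5)
  expect_lt(max(abs(wt - (w + rep(2.5 * ax$dir, each = nrow(w))))), 1e-9)
  # 180-degree spin leaves axis projections of CAs unchanged
  w180 <- place_helix(ih, ax, 1L, theta = 30 + 180, t = 0)
  p1 <- as.vector(sweep(w[ih$atom == "CA", ], 2, ax$point) %*% ax$dir)
  p2 <- as.vector(sweep(w180[ih$atom == "CA", ], 2, ax$point) %*% ax$dir)
  expect_lt(max(abs(p1 - p2)), 1e-9)
})

test_that("internal geometry is preserved under any rigid placement", {
  ih <- build_ideal_helix(8)
  sk <- straight_skeleton("s", from = c(5, 5, 5), dir = c(-1, 1, 3), L = 11)
  w <- place_helix(ih, fit_axis_line(sk), -1L, theta = 123.4, t = -1.1)
  tors0 <- recompute_phi_psi(ih$xyz, 8)
  tors1 <- recompute_phi_psi(w, 8)
  expect_lt(max(abs(tors0$phi - tors1$phi)), 1e-9)
  expect_lt(max(abs(tors0$psi - tors1$psi)), 1e-9)
  d0 <- dist(ih$xyz)
  d1 <- dist(w)
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("window assignment centers, shifts, clamps and rejects", {
  seg <- segment_rec("h", 10, 19)   # centre 14 (left-of-centre)
  expect_equal(assign_window(seg, 8, 0, 40), c(11L, 18L))
  expect_equal(assign_window(seg, 8, 2, 40), c(13L, 20L))
  expect_equal(assign_window(seg, 10, 0, 40), c(10L, 19L))
  # clamped back inside by <= s_max: slides, still valid
  expect_equal(assign_window(segment_rec("h", 1, 8), 10, 0, 40, s_max = 2),
               c(1L, 10L))
  # would need a slide beyond s_max: invalid
  expect_null(assign_window(segment_rec("h", 1, 4), 12, -2, 40, s_max = 2))
  # window longer than the sequence: invalid
  expect_null(assign_window(seg, 50, 0, 40))
})
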