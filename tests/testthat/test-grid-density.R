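test_that("2D lattice spans the range with ceiling(sqrt(n)) levels per axis", {
  coords <- matrix(runif(400), 200, 2)
  g <- select_grid_2d(coords, 100)
  expect_identical(nrow(g$points), 100L)          # 10 x 10
  expect_equal(range(g$points[, 1]), range(coords[, 1]))

  corners <- select_grid_2d(rbind(c(0, 0), c(1, 1), c(0.3, 0.8)), 4)
  expect_equal(sort(apply(corners$points, 1, paste, collapse = ",")),
               c("0,0", "0,1", "1,0", "1,1"))

  flat <- cbind(runif(10), rep(2, 10))
  expect_error(select_grid_2d(flat, 4), "axis 2")
})

test_that("high-dimensional grids are deterministic and cover the blobs", {
  centers <- rbind(c(0, 0, 0), c(10, 10, 10))
  coords <- make_blobs(50, centers, sd = 0.5, seed = 5)
  g1 <- select_grid_highd(coords, 2, seed = 9)
  g2 <- select_grid_highd(coords, 2, seed = 9)
  expect_identical(g1$points, g2$points)          # bit-reproducible
  # one grid point per blob
  d <- sqrt(outer(rowSums(g1$points^2), rowSums(centers^2), "+") -
              2 * tcrossprod(g1$points, centers))
  expect_equal(sort(apply(d, 2, which.min)), 1:2)
  expect_true(all(apply(d, 1, min) < sqrt(sum((centers[1,] - centers[2,])^2)) / 2))

  g_all <- select_grid_highd(coords, nrow(coords), seed = 1)
  expect_equal(g_all$points, coords, ignore_attr = TRUE)
  expect_error(select_grid_highd(coords, nrow(coords) + 1), "exceeds")
})

test_that("default bandwidth is scale-equivariant with a grid fallback", {
  coords <- make_blobs(40, rbind(c(0, 0), c(4, 4)), seed = 6)
  g <- select_grid_highd(coords, 5, seed = 2)
  h <- default_bandwidth(coords, g)
  expect_gt(h, 0)
  g2 <- g; g2$points <- 2 * g$points
  expect_equal(default_bandwidth(2 * coords, g2), 2 * h)
  # permutation invariance
  perm <- sample(nrow(coords))
  expect_equal(default_bandwidth(coords[perm, ], g), h)
  # unit-spaced grid pair -> h equals the grid spacing
  pts <- rbind(c(0, 0), c(1, 0))
  gg <- structure(list(points = pts, bandwidth = NULL, space_label = "x"),
                  class = "divergescan_grid")
  expect_equal(default_bandwidth(pts[c(1, 2, 1, 2), ], gg), 1)
  # degenerate single-point grid falls back to cell distances
  g1 <- structure(list(points = pts[1, , drop = FALSE], bandwidth = NULL,
                       space_label = "x"), class = "divergescan_grid")
  expect_equal(default_bandwidth(rbind(c(3, 0), c(5, 0)), g1), 4)
  expect_error(default_bandwidth(pts[c(1, 1), ], g1), "coincident")
})

test_that("Gaussian kernel weights match the closed form", {
  g <- structure(list(points = matrix(c(0, 0), 1), bandwidth = 2),
                 class = "divergescan_grid")
  cells <- rbind(c(0, 0), c(2, 0), c(4, 0))   # d = 0, h, 2h
  w <- kernel_weights(cells, g)
  expect_equal(as.vector(w), c(1, exp(-0.5), exp(-2)), tolerance = 1e-12)
})

test_that("density profiles are normalized and obey the mixture identity", {
  coords <- make_blobs(30, rbind(c(0, 0), c(5, 5)), seed = 7)
  g <- select_grid_highd(coords, 8, seed = 3)
  g$bandwidth <- default_bandwidth(coords, g)
  dm <- kernel_weights(coords, g)
  q <- reference_distribution(dm)
  expect_equal(sum(q), 1, tolerance = 1e-12)

  detected <- rep(c(TRUE, FALSE), each = 30)
  cd <- class_distributions(dm, detected)
  expect_equal(sum(cd$p_t), 1, tolerance = 1e-12)
  expect_equal(sum(cd$p_f), 1, tolerance = 1e-12)
  # complement swaps the classes exactly
  cd2 <- class_distributions(dm, !detected)
  expect_identical(cd2$p_t, cd$p_f)
  # mass-weighted mixture of the class profiles reconstitutes Q
  s_t <- sum(dm[detected, ])
  s_f <- sum(dm[!detected, ])
  mix <- s_t * cd$p_t + s_f * cd$p_f
  expect_equal(mix / sum(mix), q, tolerance = 1e-6)
  expect_error(class_distributions(dm, rep(TRUE, 60)), "all or in no cells")
})

test_that("profiles are invariant to rigid motions of the space", {
  coords <- make_blobs(25, rbind(c(0, 0), c(3, 1)), seed = 8)
  g <- select_grid_highd(coords, 6, seed = 4)
  g$bandwidth <- 0.8
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  g2 <- g; g2$points <- sweep(g$points %*% rot, 2L, c(5, -2), "+")
  coords2 <- sweep(coords %*% rot, 2L, c(5, -2), "+")
  q1 <- reference_distribution(kernel_weights(coords, g))
  q2 <- reference_distribution(kernel_weights(coords2, g2))
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("weighted reference reflects the cell weights", {
  pts <- rbind(c(0, 0), c(100, 0))
  g <- structure(list(points = pts, bandwidth = 1), class = "divergescan_grid")
  dm <- kernel_weights(pts, g)   # two cells atop the two grid points
  q <- reference_distribution(dm, weights = c(2 / 3, 1 / 3))
  expect_equal(q, c(2 / 3, 1 / 3), tolerance = 1e-6)
  # uniform explicit weights equal the default
  expect_equal(reference_distribution(dm, weights = c(0.5, 0.5)),
               reference_distribution(dm), tolerance = 1e-12)
})
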