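test_that("switching function: limits, removable singularity, monotonicity", {
  expect_equal(switching(0, 1.34), 1)
  expect_equal(switching(1.34, 1.34), 0.5)      # nn/mm at r = r0
  expect_equal(switching(1.0, 1.0, nn = 4, mm = 10), 0.4)
  # independent arithmetic at r = 2 r0
  r0 <- 1.34; r <- 2 * r0
  expect_equal(switching(r, r0), (1 - 2^6) / (1 - 2^12))
  # continuity at r0 from both sides
  eps <- 1e-7
  expect_equal(switching(r0 - eps, r0), 0.5, tolerance = 1e-5)
  expect_equal(switching(r0 + eps, r0), 0.5, tolerance = 1e-5)
  # strictly decreasing
  rr <- seq(0, 4, by = 0.01)
  expect_true(all(diff(switching(rr, 1.34)) < 0))
  expect_true(all(switching(rr, 1.34) >= 0 & switching(rr, 1.34) <= 1))
})

test_that("collective variables map reactant and product to -0.5 / +0.5", {
  cvdef <- cv_definition(pair_formed = c(1, 2), pair_broken = c(3, 4),
                         r0_formed = 1.34, r0_broken = 1.0)
  # formed contact absent (far), broken present (short) -> approx -0.5
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 5, 0), c(0.05, 5, 0))
  expect_equal(evaluate_cv(coords, cvdef), -0.5, tolerance = 1e-3)
  # formed present, broken absent -> approx +0.5
  coords2 <- rbind(c(0, 0, 0), c(0.05, 0, 0), c(0, 5, 0), c(9, 5, 0))
  expect_equal(evaluate_cv(coords2, cvdef), 0.5, tolerance = 1e-3)
  # both distances at their r0 -> exactly 0 by symmetry
  coords3 <- rbind(c(0, 0, 0), c(1.34, 0, 0), c(0, 5, 0), c(1.0, 5, 0))
  expect_equal(evaluate_cv(coords3, cvdef), 0, tolerance = 1e-12)
  # bounded by the coefficients
  set.seed(12)
  for (k in 1:20) {
    coords4 <- matrix(stats::runif(12, 0, 6), 4, 3)
    v <- evaluate_cv(coords4, cvdef)
    expect_true(v >= -0.5 - 1e-12 && v <= 0.5 + 1e-12)
  }
  expect_error(evaluate_cv(coords[1:2, ], cvdef), "index")
})

test_that("upper-wall bias: zero inside, polynomial beyond", {
  expect_equal(wall_energy(5.5), 0)
  expect_equal(wall_energy(5.0), 0)
  expect_equal(wall_energy(6.5), 200)            # 200 * 1^2
  expect_equal(wall_energy(6.0, location = 5.5, force_constant = 200,
                           exponent = 2), 200 * 0.25)
})

test_that("bias potential equals brute-force summation and is linear in hills", {
  set.seed(13)
  centers <- matrix(stats::runif(200, -0.5, 0.5), 100, 2)
  h <- hills_table(seq_len(100) * 0.1, centers,
                   sigma = c(0.05, 0.06), height = 0.59)
  pt <- c(0.1, -0.2)
  brute <- sum(0.59 * exp(-((pt[1] - centers[, 1])^2 / (2 * 0.05^2) +
                              (pt[2] - centers[, 2])^2 / (2 * 0.06^2))))
  expect_equal(bias_potential(pt, h), brute, tolerance = 1e-12)
  # single hill at its center -> its height
  h1 <- hills_table(0.1, matrix(c(0.2, 0.3), 1), sigma = c(0.005, 0.006),
                    height = 0.59)
  expect_equal(bias_potential(c(0.2, 0.3), h1), 0.59)
  # far from every center -> essentially zero
  expect_lt(bias_potential(c(0.2 + 8 * 0.005 * 3, 0.3), h1), 1e-10)
  # additivity over hill subsets
  hA <- h[1:40, ]; hB <- h[41:100, ]
  class(hA) <- class(hB) <- class(h)
  expect_equal(bias_potential(pt, hA) + bias_potential(pt, hB),
               bias_potential(pt, h), tolerance = 1e-12)
})

test_that("hills files round-trip losslessly including the bias function", {
  set.seed(14)
  centers <- matrix(stats::runif(2000, -0.6, 0.6), 1000, 2)
  h <- hills_table(seq_len(1000) * 0.1, centers, sigma = c(0.005, 0.006),
                   height = 0.59)
  f <- tempfile()
  write_hills(h, f)
  h2 <- read_hills(f)
  expect_equal(nrow(h2), 1000L)
  pts <- matrix(stats::runif(20, -0.5, 0.5), 10, 2)
  expect_equal(bias_potential(pts, h2), bias_potential(pts, h),
               tolerance = 1e-9)
  # comment preservation on write
  expect_true(any(grepl("^#! FIELDS", readLines(f))))
  # header + rows parse; biasf column tolerated
  lines <- readLines(f)
  lines[1] <- paste(lines[1], "biasf")
  body <- lines[-1]
  lines <- c(lines[1], paste(body, "10"))
  f2 <- tempfile()
  writeLines(lines, f2)
  h3 <- read_hills(f2)
  expect_equal(bias_potential(pts, h3), bias_potential(pts, h),
               tolerance = 1e-9)
  # malformed row reported with its line
  writeLines(c("1 0.1 0.2 0.005 0.006 0.59", "2 bad 0.2 0.005 0.006 0.59"),
             f2)
  expect_error(read_hills(f2, ncv = 2), "line 2")
})

test_that("FES reconstruction: empty hills give a flat zero surface", {
  h <- hills_table(numeric(0), matrix(numeric(0), 0, 2))
  fes <- reconstruct_fes(h, min = -0.5, max = 0.5, spacing = 0.1)
  expect_true(all(fes$values == 0))
  expect_equal(min(fes$values), 0)
})

test_that("depositing hills lowers -F pointwise before re-shifting", {
  set.seed(15)
  c1 <- matrix(stats::runif(40, -0.3, 0.3), 20, 2)
  h1 <- hills_table(seq_len(20), c1, sigma = c(0.05, 0.05), height = 0.5)
  h2 <- hills_table(21, matrix(c(0, 0), 1), sigma = c(0.05, 0.05),
                    height = 0.5)
  grid_pts <- as.matrix(expand.grid(seq(-0.4, 0.4, 0.1),
                                    seq(-0.4, 0.4, 0.1)))
  v1 <- bias_potential(grid_pts, h1)
  both <- rbind(h1, h2)
  class(both) <- class(h1)
  v2 <- bias_potential(grid_pts, both)
  expect_true(all(v2 >= v1))   # -F = V is pointwise non-decreasing
})

test_that("minimax path: flat surface gives barrier 0 on an adjacent-node chain", {
  fes <- structure(list(axes = list(seq(-0.5, 0.5, 0.1),
                                    seq(-0.5, 0.5, 0.1)),
                        values = matrix(0, 11, 11),
                        spacing = c(0.1, 0.1)), class = "fes_grid")
  p <- min_free_energy_path(fes, c(-0.4, -0.4), c(0.4, 0.4))
  expect_equal(p$barrier, 0)
  steps <- abs(diff(p$indices[, 1])) <= 1 & abs(diff(p$indices[, 2])) <= 1
  expect_true(all(steps))
  expect_error(min_free_energy_path(fes, c(-2, 0), c(0.4, 0.4)), "outside")
})

test_that("minimax barrier equals exhaustive threshold enumeration on random grids", {
  set.seed(16)
  for (k in 1:6) {
    n <- sample(6:12, 1)
    vals <- matrix(stats::runif(n * n, 0, 10), n, n)
    ax <- seq(0, 1, length.out = n)
    vals <- vals - min(vals)
    fes <- structure(list(axes = list(ax, ax), values = vals,
                          spacing = rep(ax[2] - ax[1], 2)),
                     class = "fes_grid")
    s <- c(ax[1], ax[1]); e <- c(ax[n], ax[n])
    p <- min_free_energy_path(fes, s, e)
    oracle_level <- oracle_minimax(vals, c(1, 1), c(n, n))
    expect_equal(max(p$profile), oracle_level, tolerance = 1e-12)
  }
})

test_that("constructed saddle: path barrier matches the analytic construction", {
  # two Gaussian wells; saddle height known from dense-grid search
  spec <- double_well_surface(barrier = 5, width = 0.12)
  true_b <- surface_saddle(spec)
  ax <- seq(-0.8, 0.8, by = 0.01)
  u <- outer(ax, ax, function(x, y) surface_energy(spec, x, y))
  fes <- structure(list(axes = list(ax, ax), values = u - min(u),
                        spacing = c(0.01, 0.01)), class = "fes_grid")
  p <- min_free_energy_path(fes, c(-0.4, -0.4), c(0.4, 0.4))
  expect_equal(p$barrier, true_b, tolerance = 0.02)
  # integrated mode exists and returns a connected path
  p2 <- min_free_energy_path(fes, c(-0.4, -0.4), c(0.4, 0.4),
                             mode = "integrated")
  expect_true(p2$barrier >= 0)
})

test_that("transition detection: step, no-crossing, and dwell filtering", {
  t <- seq(0, 80, by = 0.05)
  cv1 <- ifelse(t < 40.9, -0.5, 0.5)
  cv2 <- ifelse(t < 40.9, -0.5, 0.5)
  expect_equal(detect_transition(t, cbind(cv1, cv2)), 40.9)
  # monotone series that never crosses
  expect_true(is.na(detect_transition(t, cbind(-1 + t / 200, -0.5 + 0 * t))))
  # a joint spike shorter than the dwell window is skipped
  cv3 <- cv1; cv4 <- cv2
  spike <- t >= 20 & t < 20.1
  cv3[spike] <- 0.4; cv4[spike] <- 0.4
  expect_equal(detect_transition(t, cbind(cv3, cv4), dwell = 0.2), 40.9)
})
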