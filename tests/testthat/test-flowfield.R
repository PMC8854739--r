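test_that("frame velocities are finite differences that respect boundaries", {
  rt <- reduced_trajectory("t1", rbind(c(0, 0), c(1, 0), c(2, 0)))
  fv <- frame_velocities(rt)
  expect_equal(unname(fv$positions), rbind(c(0, 0), c(1, 0)))
  expect_equal(unname(fv$velocities), rbind(c(1, 0), c(1, 0)))

  rt_const <- reduced_trajectory("t2", matrix(1, 5, 2))
  expect_true(all(frame_velocities(rt_const)$velocities == 0))

  # two trajectories: no velocity spans the boundary
  rts <- list(reduced_trajectory("a", matrix(runif(8), 4, 2)),
              reduced_trajectory("b", matrix(runif(6), 3, 2)))
  fv2 <- frame_velocities(rts)
  expect_equal(nrow(fv2$positions), (4 - 1) + (3 - 1))
  expect_equal(fv2$trajectory_id, c("a", "a", "a", "b", "b"))

  expect_warning(frame_velocities(reduced_trajectory("s", matrix(1, 1, 2))),
                 "single frame")
})

test_that("bin_flow reports exact means and honours the strict count threshold", {
  # constant drift: every reported cell's mean equals the drift exactly
  set.seed(21)
  n <- 3000
  pos <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  drift <- cbind(rep(0.5, n), rep(0, n))
  pts <- list(positions = pos, velocities = drift,
              trajectory_id = rep("t", n))
  ff <- bin_flow(pts, axes = c(1, 2), bins_per_axis = 3, min_count = 100)
  est <- ff$cells[!is.na(ff$cells$v1), ]
  expect_gt(nrow(est), 0)
  expect_true(all(abs(est$v1 - 0.5) < 1e-9))
  expect_true(all(abs(est$v2) < 1e-9))

  # strict threshold: exactly 100 samples suppressed, 101 reported
  mk <- function(k) list(positions = matrix(0.5, k, 2),
                         velocities = matrix(1, k, 2),
                         trajectory_id = rep("t", k))
  f100 <- bin_flow(mk(100), c(1, 2), bins_per_axis = 2, min_count = 100)
  expect_true(all(is.na(f100$cells$v1[f100$cells$count == 100])))
  f101 <- bin_flow(mk(101), c(1, 2), bins_per_axis = 2, min_count = 100)
  expect_true(any(!is.na(f101$cells$v1[f101$cells$count == 101])))

  # equal counts of opposite velocities average to zero
  p2 <- list(positions = matrix(0.5, 300, 2),
             velocities = rbind(matrix(c(1, 0), 150, 2, byrow = TRUE),
                                matrix(c(-1, 0), 150, 2, byrow = TRUE)),
             trajectory_id = rep("t", 300))
  f2 <- bin_flow(p2, c(1, 2), bins_per_axis = 2, min_count = 100)
  cell <- f2$cells[f2$cells$count == 300, ]
  expect_equal(cell$v1, 0)
})

test_that("bin_flow cell means equal a brute-force groupby oracle", {
  set.seed(22)
  n <- 2000
  pts <- list(positions = matrix(runif(3 * n, 0, 5), n, 3),
              velocities = matrix(rnorm(3 * n), n, 3),
              trajectory_id = rep("t", n))
  ff <- bin_flow(pts, axes = c(1, 3), bins_per_axis = 4, min_count = 10)
  oracle <- groupby_flow_oracle(pts, c(1, 3), ff$edges)
  expect_equal(sum(ff$cells$count), n)
  for (r in seq_len(nrow(ff$cells))) {
    key <- paste(ff$cells$i1[r], ff$cells$i2[r], sep = ",")
    expect_equal(ff$cells$count[r], oracle[[key]]$count)
    if (!is.na(ff$cells$v1[r])) {
      expect_equal(c(ff$cells$v1[r], ff$cells$v2[r]),
                   unname(oracle[[key]]$mean), tolerance = 1e-12)
    }
  }
})

test_that("velocity histograms select the open region and find planted modes", {
  set.seed(23)
  n <- 4000
  pos <- cbind(runif(n, 0, 5), runif(n, 0, 5))
  vel <- rbind(cbind(rnorm(n / 2, -2, 0.2), rnorm(n / 2, 1, 0.2)),
               cbind(rnorm(n / 2, 2, 0.2), rnorm(n / 2, -1, 0.2)))
  pts <- list(positions = pos, velocities = vel, trajectory_id = rep("t", n))
  h <- velocity_histogram(pts, c(1, 2), list(c(0, 5), c(0, 5)), bins = 15)
  expect_equal(h$n, sum(h$counts))
  # two local maxima near the planted modes, within one bin
  top2 <- order(h$counts, decreasing = TRUE)[1:2]
  cx <- (h$vx_edges[-1] + h$vx_edges[-length(h$vx_edges)]) / 2
  modes_x <- sort(cx[(top2 - 1) %% 15 + 1])
  binw <- diff(h$vx_edges)[1]
  expect_lt(abs(modes_x[1] - (-2)), binw)
  expect_lt(abs(modes_x[2] - 2), binw)

  expect_warning(
    h0 <- velocity_histogram(pts, c(1, 2), list(c(90, 91), c(0, 5))),
    "no samples")
  expect_equal(h0$n, 0)
})

test_that("density histogram conserves counts", {
  set.seed(24)
  pos <- matrix(runif(600, 0, 3), 200, 3)
  dh <- density_histogram(pos, axes = c(1, 2), bins = 5)
  expect_equal(sum(dh$counts), 200)
  # point mass occupies a single cell
  dh1 <- density_histogram(matrix(1, 50, 3), axes = c(1, 2), bins = 4)
  expect_equal(sum(dh1$counts > 0), 1)
})

test_that("score smoothing suppresses single-frame blips but keeps plateaus", {
  x <- c(0, 0, 2.1, 0, 0, 1.5, 1.5, 1.5, 1.5)
  rt <- reduced_trajectory("t", cbind(x, x))
  sm <- smooth_scores(rt, k = 3)
  expect_lt(max(sm$scores[1:5, 1]), 1)          # blip averaged away
  expect_equal(sm$scores[9, 1], 1.5)            # plateau preserved
  expect_equal(sm$scores[1, 1], 0)              # partial window at start
  expect_equal(nrow(sm$scores), 9)
})

test_that("classify_paths orders threshold crossings and swaps with components", {
  sA <- cbind(c(0, 0.2, 1.5, 2, 2), c(0, 0, 0, 1.4, 2))   # comp1 first
  sB <- cbind(c(0, 0, 0, 1.4, 2), c(0, 0.2, 1.5, 2, 2))   # comp2 first
  sN <- matrix(0.01, 5, 2)
  rts <- list(reduced_trajectory("a", sA), reduced_trajectory("b", sB),
              reduced_trajectory("n", sN))
  lab <- classify_paths(rts, components = c(1, 2), threshold = 1)
  expect_equal(lab$label, c("A", "B", "unresolved"))
  # swapping the component order swaps A and B
  lab2 <- classify_paths(rts, components = c(2, 1), threshold = 1)
  expect_equal(lab2$label, c("B", "A", "unresolved"))
})
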