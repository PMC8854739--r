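test_that("nmf_fit reconstructs exactly factorizable matrices", {
  pl <- simulate_planted_factors(40, 60, 3, noise = 0, seed = 1)
  fit <- nmf_fit(pl$V, 3, seed = 2, max_iter = 3000, tol = 1e-10)
  expect_lt(fit$objective / sqrt(sum(pl$V^2)), 1e-3)
})

test_that("rank-1 factorization recovers the planted direction", {
  set.seed(3)
  w <- rexp(30); h <- rexp(50)
  V <- outer(w, h)
  fit <- nmf_fit(V, 1, seed = 4)
  cosine <- sum(fit$W[, 1] * w) / sqrt(sum(fit$W^2) * sum(w^2))
  expect_gt(cosine, 0.999)
})

test_that("objective is non-increasing and factors deterministic in the seed", {
  pl <- simulate_planted_factors(30, 40, 3, noise = 0.05, seed = 5)
  fit <- nmf_fit(pl$V, 3, seed = 6)
  expect_true(all(diff(fit$objective_trace) <= 1e-9 * fit$objective_trace[1]))
  fit2 <- nmf_fit(pl$V, 3, seed = 6)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$H, fit2$H)
  # normalization invariant
  expect_lt(max(abs(sqrt(colSums(fit$W^2)) - 1)), 1e-9)
  expect_error(nmf_fit(-pl$V, 2), "non-negative")
  expect_error(nmf_fit(pl$V, 100), "rank")
})

test_that("normalize_factors rescales without changing the product", {
  set.seed(7)
  W <- matrix(rexp(20), 10, 2); H <- matrix(rexp(8), 2, 4)
  W[, 1] <- W[, 1] / sqrt(sum(W[, 1]^2)) * 2       # norm exactly 2
  nf <- normalize_factors(W, H)
  expect_equal(sqrt(colSums(nf$W^2)), c(1, 1), tolerance = 1e-12)
  expect_equal(nf$W[, 1], W[, 1] / 2, tolerance = 1e-12)
  expect_equal(nf$H[1, ], H[1, ] * 2, tolerance = 1e-12)
  expect_equal(nf$W %*% nf$H, W %*% H, tolerance = 1e-12)
  # already normalized input is unchanged
  nf2 <- normalize_factors(nf$W, nf$H)
  expect_equal(nf2$W, nf$W, tolerance = 1e-12)
  W0 <- W; W0[, 2] <- 0
  expect_error(normalize_factors(W0, H), "all-zero")
})

test_that("projection onto a fixed basis is consistent and non-negative", {
  pl <- simulate_planted_factors(40, 80, 4, noise = 0.02, seed = 8)
  fit <- nmf_fit(pl$V, 4, seed = 9, max_iter = 3000, tol = 1e-9)
  proj <- nmf_project(fit, pl$V, max_iter = 2000, tol = 1e-12)
  expect_true(all(proj$H >= 0))
  # refit consistency: projecting the training columns reproduces H closely
  rel <- sqrt(sum((proj$H - fit$H)^2)) / sqrt(sum(fit$H^2))
  expect_lt(rel, 0.05)
  # zero column -> zero scores
  proj0 <- nmf_project(fit, matrix(0, 40, 1))
  expect_equal(unname(proj0$H[, 1]), rep(0, 4))
  expect_error(nmf_project(fit, matrix(1, 5, 2)), "mismatch")
})

test_that("planted factors are recovered across seeds", {
  cosines <- vapply(1:3, function(s) {
    pl <- simulate_planted_factors(60, 150, 4, noise = 0.05, seed = s)
    fit <- nmf_fit(pl$V, 4, seed = s + 100, max_iter = 1500, tol = 1e-8)
    factor_cosine(fit$W, pl$W)$mean
  }, numeric(1))
  expect_gt(mean(cosines), 0.95)
})

test_that("RSS rank selection flags the planted rank and degrades gracefully", {
  pl <- simulate_planted_factors(50, 120, 4, noise = 0.03, seed = 11)
  rs <- rank_selection_rss(pl$V, ranks = 2:7, n_subsample = 120, seed = 12)
  expect_false(is.unsorted(-rs$table$rss))   # RSS non-increasing in rank
  expect_false(rs$no_inflection)
  expect_equal(rs$selected, 4)

  # pure-noise matrix: "no inflection" is a reported outcome, not an error
  set.seed(13)
  noise <- matrix(rexp(50 * 60), 50, 60)
  rs2 <- rank_selection_rss(noise, ranks = 2:7, n_subsample = 60, seed = 14)
  expect_type(rs2$no_inflection, "logical")
  expect_true(rs2$no_inflection || !is.na(rs2$selected))

  expect_warning(rank_selection_rss(pl$V, ranks = 2:4, n_subsample = 1e5,
                                    seed = 1, max_iter = 50), "exceeds")
})

test_that("cophenetic coefficient is 1 for perfectly consistent consensus", {
  lab <- rep(1:3, each = 6)
  consensus <- outer(lab, lab, "==") * 1
  expect_equal(phfold:::cophenetic_coefficient(consensus), 1)
  # all-in-one-block consensus is also perfectly stable
  expect_equal(phfold:::cophenetic_coefficient(matrix(1, 10, 10)), 1)
})

test_that("cophenetic rank selection peaks at the planted block rank", {
  pl <- simulate_block_factors(60, 150, 5, noise = 0.1, seed = 1)
  cs <- suppressWarnings(
    cophenetic_rank_selection(pl$V, ranks = 3:8, n_runs = 15,
                              n_subsample = 150, seed = 101, max_iter = 300))
  expect_true(all(cs$table$cophenetic >= 0 & cs$table$cophenetic <= 1))
  expect_equal(cs$selected, 5)
})
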