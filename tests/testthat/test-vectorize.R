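test_that("feature dimension and pair indexing are consistent", {
  expect_identical(feature_dimension(35), 595L)
  expect_identical(feature_dimension(2), 1L)
  expect_identical(feature_dimension(10), 45L)
  expect_error(feature_dimension(1), "integer")

  # pair_index is a bijection onto 1..R(R-1)/2
  for (R in c(4, 10, 35)) {
    pr <- t(combn(R, 2))
    idx <- pair_index(pr[, 1], pr[, 2], R)
    expect_identical(sort(idx), seq_len(feature_dimension(R)))
    back <- index_pair(idx, R)
    expect_equal(unname(back), unname(pr))
  }
  # order-insensitive
  expect_identical(pair_index(5, 2, 10), pair_index(2, 5, 10))
})

fake_cycle <- function(edges, b, d) {
  structure(list(birth = b, death = d,
                 cycle = matrix(edges, ncol = 2, byrow = TRUE),
                 volume_size = 1L), class = "ph_cycle")
}

test_that("bag_of_simplices sums lifetimes over cycles containing each edge", {
  # no cycles -> zero vector
  v0 <- bag_of_simplices(list(), 10)
  expect_length(v0, 45)
  expect_true(all(v0 == 0))

  # single triangle cycle (1-based residues 1,2,3), lifetime 0.5
  cy <- fake_cycle(c(1, 2, 2, 3, 1, 3), b = 1.0, d = 1.5)
  v <- bag_of_simplices(list(cy), 5)
  expect_equal(unname(v[pair_index(c(1, 2, 1), c(2, 3, 3), 5)]),
               c(0.5, 0.5, 0.5))
  expect_equal(sum(v), 1.5)

  # shared edge accumulates both lifetimes
  cy2 <- fake_cycle(c(1, 2, 2, 4, 1, 4), b = 1.0, d = 1.2)
  v2 <- bag_of_simplices(list(cy, cy2), 5)
  expect_equal(unname(v2[pair_index(1, 2, 5)]), 0.5 + 0.2, tolerance = 1e-12)

  # duplicated edge in a pathological cycle counts once
  cy3 <- fake_cycle(c(1, 2, 1, 2, 2, 3, 1, 3), b = 0, d = 1)
  v3 <- bag_of_simplices(list(cy3), 5)
  expect_equal(unname(v3[pair_index(1, 2, 5)]), 1)

  expect_error(bag_of_simplices(list(fake_cycle(c(1, 6), 0, 1)), 5), "range")
})

test_that("vectorization conserves total lifetime-weighted edge count", {
  spec <- chain_spec()
  nat <- make_native(spec, seed = 1)
  tr <- simulate_folding_trajectory(nat, path_plan("A"), n_frames = 6, seed = 8)
  for (f in tr$frames[c(1, 3, 6)]) {
    d <- diagram_for_snapshot(f)
    v <- bag_of_simplices(d, spec$n_residues)
    expected <- sum(vapply(d$cycles, function(cy) {
      nrow(unique(cy$cycle)) * (cy$death - cy$birth)
    }, numeric(1)))
    expect_equal(sum(v), expected, tolerance = 1e-12)
  }
})

test_that("relabelling residues permutes feature entries consistently", {
  cloud <- random_cloud(9, seed = 3)
  v1 <- bag_of_simplices(diagram_for_snapshot(cloud), 9)
  set.seed(6)
  perm <- sample.int(9)
  v2 <- bag_of_simplices(diagram_for_snapshot(cloud[perm, ]), 9)
  # entry for pair (i,j) of the permuted cloud equals entry for the
  # original labels (perm[i], perm[j])
  pr <- t(combn(9, 2))
  orig_idx <- pair_index(perm[pr[, 1]], perm[pr[, 2]], 9)
  expect_equal(unname(v2[pair_index(pr[, 1], pr[, 2], 9)]),
               unname(v1[orig_idx]), tolerance = 1e-6)
})

test_that("stack_features builds a non-negative matrix with metadata", {
  vs <- list(c(a = 1, b = 0), c(a = 2, b = 3), c(a = 0, b = 0))
  meta <- data.frame(snapshot_id = c("s1", "s2", "s3"),
                     trajectory_id = "t", frame = 1:3)
  V <- stack_features(vs, meta)
  expect_equal(dim(V), c(2, 3))
  expect_equal(unname(V[, 2]), c(2, 3))
  expect_identical(attr(V, "meta")$snapshot_id, meta$snapshot_id)

  V1 <- stack_features(vs[1])
  expect_equal(dim(V1), c(2, 1))

  expect_error(stack_features(list(1:2, 1:3)), "dimension")
  expect_error(stack_features(list()), "at least one")
})
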