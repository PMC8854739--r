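test_that("make_helix produces equidistant points with the right chord", {
  spec <- chain_spec()
  h2 <- make_helix(2, spec)
  chord <- sqrt(spec$helix_rise^2 +
                  (2 * spec$helix_radius * sin(spec$helix_twist / 2 * pi / 180))^2)
  expect_equal(sqrt(sum((h2[2, ] - h2[1, ])^2)), chord, tolerance = 1e-12)

  h10 <- make_helix(10, spec)
  d <- sqrt(rowSums((h10[-1, ] - h10[-10, ])^2))
  expect_lt(max(d) - min(d), 1e-9)

  line <- make_helix(5, chain_spec(helix_radius = 0, helix_twist = 1e-9))
  expect_equal(unname(line[, 1]), rep(0, 5))
  expect_equal(unname(diff(line[, 3])), rep(1.5, 4))

  expect_error(make_helix(1, spec), "n")
})

test_that("chain_spec validates segments and geometry", {
  expect_error(chain_spec(helix_segments = list(c(3, 10), c(8, 15))),
               "disjoint")
  expect_error(chain_spec(helix_segments = list(c(0, 5))), "inside")
  expect_error(chain_spec(helix_rise = -1), "positive")
})

test_that("make_native is compact, deterministic, with contacts in place", {
  spec <- chain_spec()
  nat <- make_native(spec, seed = 7)
  nat2 <- make_native(spec, seed = 7)
  expect_identical(nat, nat2)
  for (m in spec$contact_sets) {
    d <- sqrt(rowSums((nat[m[, 1], , drop = FALSE] -
                         nat[m[, 2], , drop = FALSE])^2))
    expect_true(all(d < spec$contact_distance))
  }
  ext <- phfold:::extended_coil(spec$n_residues, seed = 1, jitter = 0)
  expect_lt(phfold:::radius_of_gyration(nat),
            phfold:::radius_of_gyration(ext))
})

test_that("folding trajectories interpolate to native and order contacts by plan", {
  spec <- chain_spec()
  nat <- make_native(spec, seed = 1)

  tr0 <- simulate_folding_trajectory(nat, path_plan("A"), n_frames = 30,
                                     noise_sigma = 0, seed = 5)
  expect_lt(kabsch_rmsd(tr0$frames[[30]], nat), 1e-9)

  first_contact <- function(tr, set) {
    d <- apply(contact_distance_series(tr, spec$contact_sets[[set]]), 1, max)
    which(d < spec$contact_distance)[1]
  }
  trA <- simulate_folding_trajectory(nat, path_plan("A"), n_frames = 40,
                                     seed = 11)
  trB <- simulate_folding_trajectory(nat, path_plan("B"), n_frames = 40,
                                     seed = 11)
  expect_lt(first_contact(trA, 1), first_contact(trA, 2))
  expect_gt(first_contact(trB, 1), first_contact(trB, 2))

  # noiseless plans have strictly opposite formation order
  trA0 <- simulate_folding_trajectory(nat, path_plan("A"), n_frames = 40,
                                      noise_sigma = 0, seed = 11)
  trB0 <- simulate_folding_trajectory(nat, path_plan("B"), n_frames = 40,
                                      noise_sigma = 0, seed = 11)
  expect_lt(first_contact(trA0, 1), first_contact(trA0, 2))
  expect_gt(first_contact(trB0, 1), first_contact(trB0, 2))

  # folded criterion at default noise
  rmsds <- vapply(trA$frames, kabsch_rmsd, numeric(1), Q = nat)
  expect_lt(min(rmsds), 1.0)

  # determinism
  trA2 <- simulate_folding_trajectory(nat, path_plan("A"), n_frames = 40,
                                      seed = 11)
  expect_identical(trA$frames, trA2$frames)
})

test_that("non-folding trajectories stay away from native and are reproducible", {
  spec <- chain_spec()
  nat <- make_native(spec, seed = 1)
  tr <- simulate_nonfolding_trajectory(35, 15, seed = 3, native = nat)
  rmsds <- vapply(tr$frames, kabsch_rmsd, numeric(1), Q = nat)
  expect_gte(min(rmsds), 3)
  tr2 <- simulate_nonfolding_trajectory(35, 15, seed = 3, native = nat)
  expect_identical(tr$frames, tr2$frames)
  # excluded by the folded filter
  res <- filter_trajectories(list(tr), nat, cutoff = 1.0)
  expect_length(res$kept, 0)
})

test_that("append_frozen_tail adds degenerate frames that strip back off", {
  spec <- chain_spec()
  nat <- make_native(spec, seed = 1)
  tr <- simulate_folding_trajectory(nat, path_plan("A"), n_frames = 10, seed = 2)
  tl <- append_frozen_tail(tr, 5)
  expect_length(tl$frames, 15)
  for (f in tail(tl$frames, 5)) {
    expect_equal(max(apply(f, 2, var)), 0)
    expect_equal(unname(f[1, ]), c(22.5, 22.5, 22.5))
  }
  back <- strip_degenerate_frames(tl)
  expect_equal(back$removed, 5)
  expect_identical(back$trajectory$frames, tr$frames)
})
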