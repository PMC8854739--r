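test_that("alpha filtration values match closed-form circumradii", {
  # regular tetrahedron: every edge is Gabriel and enters at half its length
  f <- build_alpha_filtration(regular_tetrahedron(edge = 2))
  expect_equal(f$edge_val, rep(1, 6), tolerance = 1e-6)

  # equilateral triangle: edges at half side, triangle at circumradius
  f3 <- build_alpha_filtration(equilateral_triangle(2))
  expect_equal(f3$edge_val, rep(1, 3), tolerance = 1e-6)
  expect_equal(f3$tri_val, 2 / sqrt(3), tolerance = 1e-6)

  expect_error(build_alpha_filtration(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear")
  expect_error(build_alpha_filtration(random_cloud(2, 1)), "3 points")
})

test_that("face filtration values never exceed coface values", {
  for (s in 1:5) {
    f <- build_alpha_filtration(random_cloud(12, seed = s))
    for (t in seq_len(nrow(f$tri))) {
      expect_true(all(f$edge_val[f$tri_edges[t, ]] <= f$tri_val[t] + 1e-12))
    }
    # triangle values vs tetra cofaces
    n <- f$n
    tri_key <- (f$tri[, 1] * (n + 1) + f$tri[, 2]) * (n + 1) + f$tri[, 3]
    for (k in seq_len(nrow(f$tet))) {
      v <- f$tet[k, ]
      for (face in list(v[1:3], v[c(1, 2, 4)], v[c(1, 3, 4)], v[2:4])) {
        i <- match((face[1] * (n + 1) + face[2]) * (n + 1) + face[3], tri_key)
        expect_true(f$tri_val[i] <= f$tet_val[k] + 1e-12)
      }
    }
  }
})

test_that("degree-1 pairs match hand-derived fixture values", {
  d <- compute_ph1(build_alpha_filtration(equilateral_triangle(2)))
  expect_equal(nrow(d), 1)
  expect_equal(d$birth, 1, tolerance = 1e-6)
  expect_equal(d$death, 2 / sqrt(3), tolerance = 1e-6)

  d2 <- compute_ph1(build_alpha_filtration(two_triangles(2, gap = 100)))
  expect_equal(nrow(d2), 2)
  expect_equal(d2$birth, c(1, 1), tolerance = 1e-6)
  expect_equal(d2$death, rep(2 / sqrt(3), 2), tolerance = 1e-6)
})

test_that("production reduction equals naive full-matrix reduction", {
  for (s in 1:10) {
    f <- build_alpha_filtration(random_cloud(8, seed = 100 + s))
    mine <- compute_ph1(f)
    ref <- naive_ph1_pairs(f)
    expect_equal(nrow(mine), nrow(ref))
    expect_equal(mine$birth, ref$birth, tolerance = 1e-12)
    expect_equal(mine$death, ref$death, tolerance = 1e-12)
  }
})

test_that("persistence is invariant under residue reordering", {
  cloud <- random_cloud(10, seed = 9)
  d1 <- compute_ph1(build_alpha_filtration(cloud))
  set.seed(42)
  perm <- sample.int(10)
  d2 <- compute_ph1(build_alpha_filtration(cloud[perm, ]))
  expect_equal(sort(d1$birth), sort(d2$birth), tolerance = 1e-6)
  expect_equal(sort(d1$death), sort(d2$death), tolerance = 1e-6)
})

test_that("pairs are stable under small perturbations", {
  cloud <- random_cloud(10, seed = 5)
  d1 <- compute_ph1(build_alpha_filtration(cloud))
  set.seed(77)
  d2 <- compute_ph1(build_alpha_filtration(
    cloud + matrix(runif(30, -1e-4, 1e-4), 10, 3)))
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(sort(d1$birth), sort(d2$birth), tolerance = 1e-2)
  expect_equal(sort(d1$death), sort(d2$death), tolerance = 1e-2)
})

test_that("volume-optimal cycles satisfy their defining constraints", {
  spec <- chain_spec()
  nat <- make_native(spec, seed = 1)
  f <- build_alpha_filtration(nat)
  pairs <- compute_ph1(f)
  vols <- attr(pairs, "volumes")
  for (i in seq_len(min(nrow(pairs), 25))) {
    cy <- volume_optimal_cycle(f, pairs[i, ], warm_start = vols[[i]])
    # Z2 cycle: every vertex has even degree
    deg <- table(as.vector(cy$cycle))
    expect_true(all(deg %% 2 == 0))
    # all cycle edges exist at the birth radius
    for (r in seq_len(nrow(cy$cycle))) {
      len2 <- sum((f$points[cy$cycle[r, 1], ] - f$points[cy$cycle[r, 2], ])^2)
      eid <- which(f$edges[, 1] == cy$cycle[r, 1] &
                     f$edges[, 2] == cy$cycle[r, 2])
      expect_true(f$edge_val[eid] <= cy$birth + 1e-9 * max(1, cy$birth))
    }
    # the optimal volume is no larger than the reduction's feasible one
    expect_lte(cy$volume_size, length(vols[[i]]))
  }
})

test_that("volume-optimal solver agrees with exhaustive subset search", {
  # pentagon: single pair, cycle = the 5 boundary edges, volume = all 3
  # Delaunay triangles
  f <- build_alpha_filtration(pentagon_points())
  p <- compute_ph1(f)
  expect_equal(nrow(p), 1)
  cy <- volume_optimal_cycle(f, p[1, ], warm_start = attr(p, "volumes")[[1]])
  expect_equal(nrow(cy$cycle), 5)
  ex <- exhaustive_voc(f, p[1, ])
  expect_equal(cy$volume_size, ex$size)
  expect_true(any(vapply(ex$solutions, identical, logical(1),
                         y = cy$triangles)))

  # random small planar clouds: solver optimum equals exhaustive optimum
  for (s in 1:5) {
    set.seed(200 + s)
    pts <- cbind(matrix(runif(14, 0, 4), 7, 2), 0)
    ft <- try(build_alpha_filtration(pts), silent = TRUE)
    if (inherits(ft, "try-error") || nrow(ft$tri) > 20) next
    pp <- compute_ph1(ft)
    vv <- attr(pp, "volumes")
    for (i in seq_len(nrow(pp))) {
      cyc <- volume_optimal_cycle(ft, pp[i, ], warm_start = vv[[i]])
      exo <- exhaustive_voc(ft, pp[i, ])
      expect_equal(cyc$volume_size, exo$size)
    }
  }
})

test_that("six-point configuration has a two-triangle optimal volume", {
  f <- build_alpha_filtration(six_point_volume_fixture())
  p <- compute_ph1(f)
  # the quadrilateral hole is the longest-lived class
  i <- which.max(p$death - p$birth)
  cy <- volume_optimal_cycle(f, p[i, ], warm_start = attr(p, "volumes")[[i]])
  expect_equal(cy$volume_size, 2)
  expect_equal(nrow(cy$cycle), 4)
  ex <- exhaustive_voc(f, p[i, ])
  expect_equal(ex$size, 2)
  # a three-triangle filling exists but is not optimal
  expect_gt(length(attr(p, "volumes")[[i]]), 0)
})

test_that("coil snapshots carry little or no loop signal", {
  coil <- phfold:::extended_coil(35, seed = 4)
  d <- diagram_for_snapshot(coil)
  if (nrow(d$pairs)) {
    expect_lt(max(d$pairs$death - d$pairs$birth), 0.5)
  }
  nat <- make_native(chain_spec(), seed = 1)
  dn <- diagram_for_snapshot(nat)
  expect_gt(max(dn$pairs$death - dn$pairs$birth), 0.2)
})
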