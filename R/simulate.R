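#' Simulate a folding trajectory
#'
#' Generates a synthetic folding trajectory: frame 1 is an extended coil
#' (straight chain, 3.8 Angstrom per residue, seeded jitter), and the chain
#' interpolates toward the native bundle along a monotone progress
#' coordinate. The planted contact sets activate in the order given by the
#' path plan: the trajectory first reaches an intermediate in which only the
#' plan's first contact set is docked (the remaining helix is swung away on a
#' hinge), then the full native state, then stays at the native state for the
#' remaining frames. I.i.d. Gaussian displacement noise of scale
#' `noise_sigma` is added to every frame. There is no force field and no
#' excluded volume: the downstream analysis needs geometry, not physics.
#'
#' @param native native point cloud from [make_native()] (the chain spec is
#'   read from its attribute unless `spec` is given).
#' @param plan a [path_plan()].
#' @param n_frames number of frames (>= 2).
#' @param noise_sigma per-coordinate Gaussian noise, Angstrom. At the default
#'   the trajectory's minimum RMSD to native stays well below the 1.0
#'   Angstrom folded criterion.
#' @param seed integer seed; the trajectory is a pure function of its inputs.
#' @param spec optional [chain_spec()] override.
#' @param frame_interval snapshot spacing, ps.
#' @return A `fold_trajectory`.
#' @export
simulate_folding_trajectory <- function(native, plan = path_plan("A"),
                                        n_frames = 40L, noise_sigma = 0.25,
                                        seed = 1L, spec = NULL,
                                        frame_interval = 250) {
  stopifnot_scalar_count(n_frames, "n_frames", min = 2L)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  spec <- spec %||% attr(native, "chain_spec")
  if (is.null(spec)) stop("no chain_spec available; pass `spec`")
  n <- spec$n_residues
  if (nrow(native) != n) stop("native residue count does not match spec")

  first_set <- plan$contact_schedule$contact_set[1]
  f1 <- plan$contact_schedule$activation[1]
  f2 <- plan$contact_schedule$activation[2]

  native <- unclass(native)
  attr(native, "chain_spec") <- NULL
  coil <- extended_coil(n, seed = derive_seed(seed, 11L))
  inter <- folding_intermediate(native, spec, first_set)

  lambda <- seq(0, 1, length.out = n_frames)
  noise <- if (noise_sigma > 0) {
    with_seed(derive_seed(seed, 13L),
              array(rnorm(n_frames * n * 3, sd = noise_sigma),
                    dim = c(n, 3, n_frames)))
  } else NULL

  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    lam <- lambda[t]
    base <- if (lam <= f1) {
      coil + (lam / f1) * (inter - coil)
    } else if (lam <= f2) {
      inter + ((lam - f1) / (f2 - f1)) * (native - inter)
    } else {
      native
    }
    if (!is.null(noise)) base <- base + noise[, , t]
    dimnames(base) <- list(NULL, c("x", "y", "z"))
    frames[[t]] <- unclass(base)
  }
  new_trajectory(id = sprintf("fold_%s_%d", plan$label, seed), frames,
                 frame_interval = frame_interval, seed = seed,
                 meta = list(plan_label = plan$label, noise_sigma = noise_sigma,
                             activation = c(f1, f2), first_set = first_set))
}

# Straight extended chain with seeded jitter (coil initial state).
extended_coil <- function(n, seed, spacing = 3.8, jitter = 0.3) {
  base <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  base + with_seed(seed, matrix(rnorm(3 * n, sd = jitter), n, 3))
}

# Intermediate with only `first_set` docked, the docked part keeping its
# native geometry while the remaining helix's contacts are broken:
#  - first_set = 1 (helices 1 & 3 docked): the middle block (helix 2 plus
#    linkers) is rebuilt as an outward Bezier detour between its two anchor
#    residues, preserving chain continuity at both ends;
#  - first_set = 2 (helices 1 & 2 docked): the C-terminal block (helix 3
#    onward) is rebuilt as an extended arm pointing away from the docked
#    bundle, an unfolded C-terminus.
folding_intermediate <- function(native, spec, first_set, min_break = 12) {
  seg <- spec$helix_segments
  pts <- unclass(native)
  attr(pts, "chain_spec") <- NULL
  n <- nrow(pts)
  other_set <- spec$contact_sets[[if (first_set == 1L) 2L else 1L]]
  for (amp in c(12, 16, 20, 26)) {
    cand <- pts
    if (first_set == 1L) {
      i0 <- seg[[1]][2]; i1 <- seg[[3]][1]
      block <- (i0 + 1L):(i1 - 1L)
      docked <- colMeans(pts[-block, , drop = FALSE])
      mid <- (pts[i0, ] + pts[i1, ]) / 2
      u <- mid - docked
      u <- u / max(sqrt(sum(u^2)), 1e-8)
      ctrl <- mid + 2 * amp * u
      tt <- seq_along(block) / (length(block) + 1L)
      cand[block, ] <- outer((1 - tt)^2, pts[i0, ]) +
        outer(2 * tt * (1 - tt), ctrl) + outer(tt^2, pts[i1, ])
    } else {
      i0 <- seg[[2]][2]
      block <- (i0 + 1L):n
      docked <- colMeans(pts[seq_len(i0), , drop = FALSE])
      u <- pts[i0, ] - docked
      u <- u / max(sqrt(sum(u^2)), 1e-8)
      cand[block, ] <- pts[rep(i0, length(block)), , drop = FALSE] +
        outer(seq_along(block) * 3.4 * (amp / 12), u)
    }
    d <- sqrt(rowSums((cand[other_set[, 1], , drop = FALSE] -
                         cand[other_set[, 2], , drop = FALSE])^2))
    if (all(d > min_break)) return(cand)
  }
  stop("could not construct an intermediate that breaks contact set ",
       if (first_set == 1L) 2L else 1L)
}

#' Simulate a non-folding trajectory
#'
#' Generates a random-coil trajectory (persistent random walk evolving by
#' small per-frame displacements) whose every frame stays at least
#' `min_rmsd` Angstrom away from the native state, enforced by rejection.
#'
#' @param n_residues residue count.
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @param native native reference; defaults to the default chain's native
#'   state (only valid when `n_residues` matches it).
#' @param min_rmsd required minimum Kabsch RMSD to native, Angstrom.
#' @param max_tries rejection budget per frame.
#' @param frame_interval snapshot spacing, ps.
#' @return A `fold_trajectory`.
#' @export
simulate_nonfolding_trajectory <- function(n_residues = 35L, n_frames = 40L,
                                           seed = 1L, native = NULL,
                                           min_rmsd = 3, max_tries = 20L,
                                           frame_interval = 250) {
  stopifnot_scalar_count(n_frames, "n_frames", min = 2L)
  if (is.null(native)) {
    spec <- chain_spec(n_residues = n_residues)
    native <- make_native(spec, seed = 1L)
  }
  if (nrow(native) != n_residues) {
    stop("`native` residue count does not match n_residues")
  }
  frames <- vector("list", n_frames)
  cur <- random_coil_walk(n_residues, seed = derive_seed(seed, 17L))
  if (kabsch_rmsd(cur, native) < min_rmsd) {
    stop("initial random coil unexpectedly close to native")
  }
  frames[[1]] <- cur
  for (t in 2:n_frames) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      step <- with_seed(derive_seed(seed, 19L, t, k),
                        matrix(rnorm(3 * n_residues, sd = 0.4),
                               n_residues, 3))
      cand <- cur + step
      if (kabsch_rmsd(cand, native) >= min_rmsd) {
        cur <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("rejection budget exhausted at frame ", t)
    frames[[t]] <- cur
  }
  new_trajectory(id = sprintf("coil_%d", seed), frames,
                 frame_interval = frame_interval, seed = seed,
                 meta = list(plan_label = "none"))
}

# Persistent random walk with fixed 3.8 A bond length; direction decorrelates
# slowly so the coil is expanded rather than collapsed.
random_coil_walk <- function(n, seed, spacing = 3.8, stiffness = 0.75) {
  with_seed(seed, {
    pts <- matrix(0, n, 3)
    dir <- c(1, 0, 0)
    for (i in 2:n) {
      dir <- stiffness * dir + (1 - stiffness) * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pts[i, ] <- pts[i - 1L, ] + spacing * dir
    }
    colnames(pts) <- c("x", "y", "z")
    pts
  })
}

#' Append frozen-coordinate frames to a trajectory
#'
#' Emulates the data artifact in which all atoms of trailing snapshots sit at
#' one identical coordinate triple (as produced by errors when merging
#' distributed-computing results).
#'
#' @param traj a `fold_trajectory`.
#' @param n_tail number of frozen frames to append (>= 1).
#' @param frozen_point coordinate triple, Angstrom.
#' @return The trajectory with `n_tail` degenerate frames appended.
#' @export
append_frozen_tail <- function(traj, n_tail, frozen_point = c(22.5, 22.5, 22.5)) {
  stopifnot_scalar_count(n_tail, "n_tail", min = 1L)
  r <- traj_residues(traj)
  frozen <- matrix(rep(as.numeric(frozen_point), each = r), r, 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  traj$frames <- c(traj$frames, rep(list(frozen), n_tail))
  traj$meta$frozen_tail <- (traj$meta$frozen_tail %||% 0L) + as.integer(n_tail)
  traj
}

#' Simulate a trajectory ensemble
#'
#' Convenience wrapper building the study-style ensemble: folding
#' trajectories split between the two planted paths, non-folding coil
#' trajectories, and optionally extra non-folding trajectories carrying
#' frozen-coordinate tails.
#'
#' @param n_folding,n_nonfolding,n_frozen trajectory counts per class.
#' @param native native state (built from `spec` if `NULL`).
#' @param spec a [chain_spec()].
#' @param n_frames frames per trajectory.
#' @param noise_sigma folding-trajectory noise, Angstrom.
#' @param tail_length frozen frames appended to each frozen-tail trajectory.
#' @param seed integer seed.
#' @return list with elements `trajectories` (list of `fold_trajectory`),
#'   `native`, `spec`, and `labels` (planted path label per trajectory).
#' @export
simulate_ensemble <- function(n_folding = 20L, n_nonfolding = 10L,
                              n_frozen = 0L, native = NULL,
                              spec = chain_spec(), n_frames = 40L,
                              noise_sigma = 0.25, tail_length = 5L,
                              seed = 1L) {
  if (is.null(native)) native <- make_native(spec, seed = derive_seed(seed, 1L))
  trajs <- list()
  labels <- character(0)
  for (i in seq_len(n_folding)) {
    lab <- if (i %% 2L == 1L) "A" else "B"
    tr <- simulate_folding_trajectory(native, path_plan(lab),
                                      n_frames = n_frames,
                                      noise_sigma = noise_sigma,
                                      seed = derive_seed(seed, 100L, i),
                                      spec = spec)
    tr$id <- sprintf("fold_%03d_%s", i, lab)
    trajs <- c(trajs, list(tr))
    labels <- c(labels, lab)
  }
  for (i in seq_len(n_nonfolding)) {
    tr <- simulate_nonfolding_trajectory(spec$n_residues, n_frames,
                                         seed = derive_seed(seed, 200L, i),
                                         native = native)
    tr$id <- sprintf("coil_%03d", i)
    trajs <- c(trajs, list(tr))
    labels <- c(labels, "none")
  }
  for (i in seq_len(n_frozen)) {
    tr <- simulate_nonfolding_trajectory(spec$n_residues, n_frames,
                                         seed = derive_seed(seed, 300L, i),
                                         native = native)
    tr <- append_frozen_tail(tr, tail_length)
    tr$id <- sprintf("frozen_%03d", i)
    trajs <- c(trajs, list(tr))
    labels <- c(labels, "none")
  }
  list(trajectories = trajs, native = native, spec = spec, labels = labels)
}
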