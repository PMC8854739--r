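#' Specification of a synthetic three-helix bead chain
#'
#' Describes the coarse-grained chain used by the synthetic trajectory
#' generator: one bead per residue, with three helical segments mimicking the
#' three alpha-helices of a villin-headpiece-like 35-residue subdomain, and
#' two planted inter-helix contact sets whose formation order distinguishes
#' folding paths.
#'
#' @param n_residues number of residues (beads) in the chain.
#' @param helix_segments list of length-2 integer vectors `c(first, last)`
#'   (1-based, inclusive) marking the helical segments. Segments must be
#'   disjoint, ordered and inside `[1, n_residues]`.
#' @param helix_rise rise per residue along the helix axis, in Angstrom.
#' @param helix_radius helix radius, in Angstrom.
#' @param helix_twist twist per residue, in degrees.
#' @param contact_sets list of two integer matrices (one row per residue
#'   pair) giving the planted inter-helix contacts. Set 1 bridges helices
#'   1 and 3, set 2 bridges helices 1 and 2. Defaults mimic the roles of
#'   terminal-subdomain helix pairings in the native bundle.
#' @param contact_distance distance (Angstrom) below which a planted pair
#'   counts as formed.
#'
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(n_residues = 35L,
                       helix_segments = list(c(3L, 10L), c(14L, 19L), c(22L, 32L)),
                       helix_rise = 1.5,
                       helix_radius = 2.3,
                       helix_twist = 100,
                       contact_sets = NULL,
                       contact_distance = 8) {
  stopifnot_scalar_count(n_residues, "n_residues", min = 2L)
  if (!is.list(helix_segments) || length(helix_segments) < 1L) {
    stop("`helix_segments` must be a non-empty list of c(first, last) ranges")
  }
  seg <- lapply(helix_segments, function(s) as.integer(s))
  for (s in seg) {
    if (length(s) != 2L || s[1] > s[2] || s[1] < 1L || s[2] > n_residues) {
      stop("helix segments must be ordered ranges inside [1, n_residues]")
    }
  }
  if (length(seg) > 1L) {
    for (k in seq_len(length(seg) - 1L)) {
      if (seg[[k]][2] >= seg[[k + 1L]][1]) {
        stop("helix segments must be disjoint and in increasing order")
      }
    }
  }
  if (helix_rise <= 0 || helix_radius < 0 || helix_twist <= 0) {
    stop("helix geometry parameters must be positive")
  }
  if (is.null(contact_sets)) {
    contact_sets <- default_contact_sets(seg, n_residues)
  }
  contact_sets <- lapply(contact_sets, function(m) {
    m <- matrix(as.integer(m), ncol = 2L)
    if (any(m < 1L) || any(m > n_residues)) {
      stop("contact pairs out of residue range")
    }
    m
  })
  structure(list(
    n_residues = as.integer(n_residues),
    helix_segments = seg,
    helix_rise = helix_rise,
    helix_radius = helix_radius,
    helix_twist = helix_twist,
    contact_sets = contact_sets,
    contact_distance = contact_distance
  ), class = "chain_spec")
}

# Planted contacts: pairs sitting mid-helix so that docking the helix pair
# brings them within contact range. Chosen relative to the default segments;
# scaled positions are used for non-default segment lists.
default_contact_sets <- function(seg, n_residues) {
  if (length(seg) < 3L) {
    stop("default contact sets need three helix segments")
  }
  pick <- function(range, frac) {
    as.integer(round(range[1] + frac * (range[2] - range[1])))
  }
  h1 <- seg[[1]]; h2 <- seg[[2]]; h3 <- seg[[3]]
  # pairs sit strictly inside the helices, away from the hinge anchor
  # residues used when constructing partially folded intermediates
  set1 <- rbind(c(pick(h1, 0.85), pick(h3, 1.0)),
                c(pick(h1, 0.45), pick(h3, 0.7)))
  set2 <- rbind(c(pick(h1, 0.7), pick(h2, 0.2)),
                c(pick(h1, 0.3), pick(h2, 0.7)))
  list(set1, set2)
}

#' @export
print.chain_spec <- function(x, ...) {
  cat("<chain_spec>", x$n_residues, "residues;",
      length(x$helix_segments), "helix segments:",
      paste(vapply(x$helix_segments, function(s) paste(s, collapse = "-"),
                   character(1)), collapse = ", "), "\n")
  cat("  rise", x$helix_rise, "A, radius", x$helix_radius, "A, twist",
      x$helix_twist, "deg/residue\n")
  for (k in seq_along(x$contact_sets)) {
    m <- x$contact_sets[[k]]
    cat("  contact set", k, ":",
        paste(apply(m, 1, paste, collapse = "-"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Folding-path plan
#'
#' Orders the planted contact sets along the folding progress coordinate.
#' The two labels differ only in the order in which the two contact sets
#' form: plan A docks helix 1 onto helix 3 (contact set 1) first, plan B
#' docks helix 1 onto helix 2 (contact set 2) first.
#'
#' @param label `"A"` or `"B"`.
#' @param contact_schedule data frame with columns `contact_set` (1 or 2)
#'   and `activation` (fraction of folding progress, non-decreasing).
#'   Defaults: first set at 0.45, second at 0.8.
#' @return An object of class `path_plan`.
#' @export
path_plan <- function(label = c("A", "B"), contact_schedule = NULL) {
  label <- match.arg(label)
  if (is.null(contact_schedule)) {
    sets <- if (label == "A") c(1L, 2L) else c(2L, 1L)
    contact_schedule <- data.frame(contact_set = sets,
                                   activation = c(0.45, 0.8))
  }
  cs <- contact_schedule
  if (!all(c("contact_set", "activation") %in% names(cs))) {
    stop("`contact_schedule` needs columns contact_set and activation")
  }
  if (is.unsorted(cs$activation)) {
    stop("activation fractions must be non-decreasing")
  }
  if (any(cs$activation < 0 | cs$activation > 1)) {
    stop("activation fractions must lie in [0, 1]")
  }
  structure(list(label = label, contact_schedule = cs), class = "path_plan")
}

#' @export
print.path_plan <- function(x, ...) {
  cat("<path_plan", x$label, "> contact order:",
      paste(sprintf("set %d @ %.2f", x$contact_schedule$contact_set,
                    x$contact_schedule$activation), collapse = ", "), "\n")
  invisible(x)
}

#' Ideal alpha-helix point cloud
#'
#' Places `n` points on an ideal helix with the rise, radius and twist of a
#' chain specification. Consecutive points are equidistant, with chord length
#' `sqrt(rise^2 + (2 r sin(twist/2))^2)`.
#'
#' @param n number of points (>= 2).
#' @param spec a [chain_spec()] supplying the helix geometry.
#' @return An `n` x 3 coordinate matrix (Angstrom).
#' @export
make_helix <- function(n, spec = chain_spec()) {
  stopifnot_scalar_count(n, "n", min = 2L)
  i <- seq_len(n) - 1
  theta <- i * spec$helix_twist * pi / 180
  cbind(x = spec$helix_radius * cos(theta),
        y = spec$helix_radius * sin(theta),
        z = i * spec$helix_rise)
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c0 + s0 * K + (1 - c0) * tcrossprod(u)
}

# Rotate rows of `pts` about the line through `origin` with direction `axis`.
rotate_points <- function(pts, origin, axis, angle) {
  Rm <- rotation_about_axis(axis, angle)
  sweep(sweep(pts, 2, origin) %*% t(Rm), 2, origin, "+")
}

radius_of_gyration <- function(pts) {
  ctr <- colMeans(pts)
  sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
}

#' Synthetic native three-helix bundle
#'
#' Builds a compact native-state point cloud: each helix segment is an ideal
#' helix, the three helices are packed as an antiparallel bundle, linker and
#' terminal residues are placed by interpolation/extension, and a small
#' seeded jitter is added. Placement is retried with tighter packing until
#' both planted contact sets are within the contact distance.
#'
#' @param spec a [chain_spec()].
#' @param seed integer seed; the construction is deterministic given it.
#' @param max_tries retry budget for the packing.
#' @return An `n_residues` x 3 coordinate matrix with the chain spec attached
#'   as attribute `"chain_spec"`.
#' @export
make_native <- function(spec = chain_spec(), seed = 1L, max_tries = 20L) {
  seg <- spec$helix_segments
  if (length(seg) != 3L) stop("make_native needs exactly three helix segments")
  n <- spec$n_residues
  rise <- spec$helix_rise

  # transverse helix-axis offsets (x, y) and base z for each helix;
  # helix 2 runs antiparallel. z offsets centre the planted contacts.
  base_offsets <- list(c(0, 0), c(3.6, -6.4), c(6.8, 0.6))
  len2 <- (seg[[2]][2] - seg[[2]][1]) * rise
  z0 <- c(0,
          (seg[[1]][2] - seg[[1]][1]) * rise * 0.5 + len2 * 0.5,
          -0.5 * rise * (seg[[3]][2] - seg[[3]][1] -
                           (seg[[1]][2] - seg[[1]][1])))
  phases <- c(0, 40, 200) * pi / 180

  for (try in seq_len(max_tries)) {
    shrink <- 0.94^(try - 1)
    pts <- matrix(NA_real_, n, 3)
    for (k in 1:3) {
      rng <- seg[[k]]
      m <- rng[2] - rng[1] + 1L
      h <- make_helix(m, spec)
      # per-helix phase about its own axis
      h <- h %*% t(rotation_about_axis(c(0, 0, 1), phases[k]))
      if (k == 2L) h[, 3] <- -h[, 3]           # antiparallel
      h[, 1] <- h[, 1] + base_offsets[[k]][1] * shrink
      h[, 2] <- h[, 2] + base_offsets[[k]][2] * shrink
      h[, 3] <- h[, 3] + z0[k]
      pts[rng[1]:rng[2], ] <- h
    }
    # linkers: equally spaced interpolation between flanking helix ends
    for (k in 1:2) {
      a <- seg[[k]][2]; b <- seg[[k + 1L]][1]
      gap <- b - a
      if (gap > 1L) {
        for (j in seq_len(gap - 1L)) {
          pts[a + j, ] <- pts[a, ] + (j / gap) * (pts[b, ] - pts[a, ])
        }
      }
    }
    # termini: extend outward from the first/last helix
    first <- seg[[1]][1]; last <- seg[[3]][2]
    if (first > 1L) {
      d <- pts[first, ] - pts[first + 1L, ]
      d <- d / sqrt(sum(d^2))
      for (j in seq_len(first - 1L)) {
        pts[first - j, ] <- pts[first, ] + j * 3.8 * d
      }
    }
    if (last < n) {
      d <- pts[last, ] - pts[last - 1L, ]
      d <- d / sqrt(sum(d^2))
      for (j in seq_len(n - last)) {
        pts[last + j, ] <- pts[last, ] + j * 3.8 * d
      }
    }
    pts <- pts + with_seed(derive_seed(seed, 7L, try),
                           matrix(rnorm(3 * n, sd = 0.05), n, 3))
    ok <- all(vapply(spec$contact_sets, function(m) {
      all(sqrt(rowSums((pts[m[, 1], , drop = FALSE] -
                          pts[m[, 2], , drop = FALSE])^2)) <
            spec$contact_distance)
    }, logical(1)))
    if (ok) {
      dimnames(pts) <- list(NULL, c("x", "y", "z"))
      attr(pts, "chain_spec") <- spec
      return(pts)
    }
  }
  stop("could not place helices with all planted contacts within ",
       spec$contact_distance, " A after ", max_tries, " tries")
}

#' Distances of planted contact pairs along a trajectory
#'
#' @param traj a `fold_trajectory`.
#' @param pairs integer matrix of residue pairs (one per row, 1-based).
#' @return numeric matrix, frames x pairs, of Euclidean distances (Angstrom).
#' @export
contact_distance_series <- function(traj, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  t(vapply(traj$frames, function(f) {
    sqrt(rowSums((f[pairs[, 1], , drop = FALSE] -
                    f[pairs[, 2], , drop = FALSE])^2))
  }, numeric(nrow(pairs))))
}

#' Construct a trajectory object
#'
#' @param id trajectory identifier.
#' @param frames list of R x 3 coordinate matrices with a common residue
#'   count (>= 1 frame).
#' @param frame_interval snapshot spacing, ps (> 0).
#' @param seed generating seed, if any (metadata only).
#' @param meta free-form metadata list.
#' @return An object of class `fold_trajectory`.
#' @export
new_trajectory <- function(id, frames, frame_interval = 250, seed = NA_integer_,
                           meta = list()) {
  if (length(frames) < 1L) stop("a trajectory needs at least one frame")
  nr <- nrow(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || ncol(f) != 3L || nrow(f) != nr) {
      stop("all frames must be R x 3 matrices with a common residue count")
    }
  }
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(list(id = id, frames = frames, frame_interval = frame_interval,
                 seed = seed, meta = meta),
            class = "fold_trajectory")
}

#' @export
print.fold_trajectory <- function(x, ...) {
  cat("<fold_trajectory", x$id, ">", length(x$frames), "frames,",
      nrow(x$frames[[1]]), "residues, dt =", x$frame_interval, "ps\n")
  if (!is.null(x$meta$plan_label)) cat("  planted path:", x$meta$plan_label, "\n")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)
traj_residues <- function(traj) nrow(traj$frames[[1]])
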