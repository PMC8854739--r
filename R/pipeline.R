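#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with its default. All
#' randomness derives from `seed`; every stage logs the parameters it
#' actually used.
#'
#' @param n_folding,n_nonfolding,n_frozen ensemble composition.
#' @param n_frames frames per simulated trajectory.
#' @param noise_sigma folding-trajectory noise, Angstrom.
#' @param tail_length frozen frames per frozen-tail trajectory.
#' @param cutoff preprocessing RMSD cutoff, Angstrom.
#' @param jitter_seed homology jitter seed.
#' @param rank NMF rank for the final fit.
#' @param ranks optional candidate ranks; when given, rank selection is run
#'   and its cophenetic choice overrides `rank`.
#' @param n_runs NMF restarts per rank during rank selection.
#' @param n_subsample columns subsampled for rank selection.
#' @param bins_per_axis,min_count flow-field grid settings.
#' @param flow_components score components for the 2D flow field and the
#'   path classification (chosen automatically from the planted contact
#'   sets when `NULL`).
#' @param seed global seed.
#' @param out_dir optional directory; when set, every stage writes its
#'   artifact there (PDB/XYZ trajectories, filter report CSV, diagram CSV,
#'   cycle JSON, feature matrix CSV, factor CSVs, flow CSV, manifest YAML).
#' @return A `run_config` list.
#' @export
run_config <- function(n_folding = 20L, n_nonfolding = 10L, n_frozen = 0L,
                       n_frames = 40L, noise_sigma = 0.25, tail_length = 5L,
                       cutoff = 1.0, jitter_seed = 1L,
                       rank = 5L, ranks = NULL, n_runs = 10L,
                       n_subsample = 500L, bins_per_axis = 20L,
                       min_count = 100L, flow_components = NULL,
                       seed = 1L, out_dir = NULL) {
  cfg <- list(n_folding = as.integer(n_folding),
              n_nonfolding = as.integer(n_nonfolding),
              n_frozen = as.integer(n_frozen),
              n_frames = as.integer(n_frames),
              noise_sigma = noise_sigma,
              tail_length = as.integer(tail_length),
              cutoff = cutoff,
              jitter_seed = as.integer(jitter_seed),
              rank = as.integer(rank),
              ranks = if (!is.null(ranks)) as.integer(ranks),
              n_runs = as.integer(n_runs),
              n_subsample = as.integer(n_subsample),
              bins_per_axis = as.integer(bins_per_axis),
              min_count = as.integer(min_count),
              flow_components = if (!is.null(flow_components)) as.integer(flow_components),
              seed = as.integer(seed),
              out_dir = out_dir)
  if (cfg$cutoff < 0) stop("cutoff must be >= 0")
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> persistent homology -> vectorize ->
#' NMF -> flow field in order, asserting count consistency across stage
#' boundaries (snapshots entering homology equal feature-matrix columns),
#' and returns a manifest of what was run. With a cutoff that keeps no
#' trajectory the pipeline stops gracefully after preprocessing.
#'
#' @param config a [run_config()].
#' @return Object of class `run_manifest`: config snapshot, per-stage counts
#'   and wall-clock seconds, the filter report, rank report (when rank
#'   selection ran), the fitted `nmf_fit`, reduced trajectories, flow field
#'   and path labels.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  # -- simulate ---------------------------------------------------------
  ens <- tick("simulate", simulate_ensemble(
    n_folding = config$n_folding, n_nonfolding = config$n_nonfolding,
    n_frozen = config$n_frozen, n_frames = config$n_frames,
    noise_sigma = config$noise_sigma, tail_length = config$tail_length,
    seed = config$seed))
  if (!is.null(out)) {
    write_trajectory(ens$trajectories[[1]],
                     file.path(out, paste0(ens$trajectories[[1]]$id, ".pdb")),
                     "pdb_multimodel")
  }
  spec <- ens$spec
  message("simulate: ", length(ens$trajectories), " trajectories, ",
          config$n_frames, " frames each (seed ", config$seed, ")")

  # -- preprocess -------------------------------------------------------
  filt <- tick("preprocess", filter_trajectories(
    ens$trajectories, ens$native, cutoff = config$cutoff))
  report <- filt$report
  if (!is.null(out)) write_filter_report(report, file.path(out, "filter_report.csv"))
  message("preprocess: kept ", length(filt$kept), "/", nrow(report),
          " trajectories (cutoff ", config$cutoff, " A, strict); removed ",
          sum(report$frames_removed), " degenerate frames")
  kept_labels <- ens$labels[report$kept]
  if (length(filt$kept) == 0L) {
    return(structure(list(config = config, counts = list(
      simulated = length(ens$trajectories), kept = 0L,
      frames_removed = sum(report$frames_removed)),
      filter_report = report, timings = timings, completed = "preprocess"),
      class = "run_manifest"))
  }

  # -- persistent homology + vectorize ---------------------------------
  meta <- do.call(rbind, lapply(filt$kept, function(tr) {
    data.frame(trajectory_id = tr$id, frame = seq_along(tr$frames),
               snapshot_id = sprintf("%s:%03d", tr$id, seq_along(tr$frames)),
               stringsAsFactors = FALSE)
  }))
  diagrams <- tick("homology", {
    res <- vector("list", nrow(meta))
    i <- 0L
    for (tr in filt$kept) {
      for (t in seq_along(tr$frames)) {
        i <- i + 1L
        res[[i]] <- diagram_for_snapshot(tr$frames[[t]],
                                         jitter_seed = config$jitter_seed,
                                         snapshot_id = meta$snapshot_id[i])
      }
    }
    res
  })
  vectors <- lapply(diagrams, bag_of_simplices, n_residues = spec$n_residues)
  V <- tick("vectorize", stack_features(vectors, meta))
  stopifnot(ncol(V) == nrow(meta), ncol(V) == length(diagrams))
  if (!is.null(out)) {
    write_diagrams(diagrams, file.path(out, "diagrams.csv"))
    write_cycles_json(diagrams, file.path(out, "cycles.json"))
    write_feature_matrix(V, file.path(out, "feature_matrix.csv"))
  }
  message("homology/vectorize: ", ncol(V), " snapshots -> ", nrow(V),
          "-dimensional bag-of-simplices matrix")

  # -- NMF --------------------------------------------------------------
  rank_report <- NULL
  rank <- config$rank
  if (!is.null(config$ranks)) {
    rank_report <- tick("rank_selection", select_rank(
      V, ranks = config$ranks, n_runs = config$n_runs,
      n_subsample = min(config$n_subsample, ncol(V)),
      seed = derive_seed(config$seed, 51L)))
    rank <- rank_report$selected_cophenetic
    message("rank selection: cophenetic argmax ", rank,
            if (rank_report$no_inflection) "; RSS curve has no inflection" else "")
  }
  fit <- tick("nmf", nmf_fit(V, rank, seed = derive_seed(config$seed, 53L)))
  message("nmf: rank ", rank, ", ||V-WH||_F = ", signif(fit$objective, 5),
          " after ", fit$iterations, " iterations")
  if (!is.null(out)) {
    write.csv(data.frame(feature = rownames(V), fit$W), file.path(out, "W.csv"),
              row.names = FALSE)
    write.csv(fit$H, file.path(out, "H.csv"), row.names = FALSE)
  }

  # -- flow field -------------------------------------------------------
  rts <- split_scores(fit$H, meta)
  pts <- frame_velocities(rts)
  stopifnot(nrow(pts$positions) ==
              sum(vapply(rts, function(r) nrow(r$scores) - 1L, integer(1))))
  comps <- config$flow_components %||% contact_components(fit, spec, V = V)
  # classification runs on lightly smoothed scores so single-frame score
  # blips cannot register as threshold crossings; the flow field itself
  # uses the raw finite-difference velocities
  rts_s <- lapply(rts, smooth_scores)
  thr <- component_thresholds(rts_s, comps)
  flow <- tick("flow", bin_flow(pts, axes = comps,
                                bins_per_axis = config$bins_per_axis,
                                min_count = config$min_count))
  labels <- classify_paths(rts_s, comps, thr)
  if (!is.null(out)) {
    write_flow_field(flow, file.path(out, "flow_field.csv"))
    write.csv(labels, file.path(out, "path_labels.csv"), row.names = FALSE)
  }
  message("flow: components ", paste(comps, collapse = ","),
          "; thresholds ", paste(signif(thr, 3), collapse = ","), " A")

  manifest <- structure(list(
    config = config,
    counts = list(simulated = length(ens$trajectories),
                  kept = length(filt$kept),
                  frames_removed = sum(report$frames_removed),
                  snapshots = ncol(V),
                  matrix_shape = dim(V),
                  cycles = sum(vapply(diagrams, function(d) length(d$cycles),
                                      integer(1))),
                  rank = rank),
    filter_report = report, rank_report = rank_report, fit = fit,
    meta = meta, reduced = rts, flow = flow, path_labels = labels,
    planted_labels = kept_labels, flow_components = comps,
    thresholds = thr, timings = timings,
    version = as.character(utils::packageVersion("phfold")),
    completed = "flow"), class = "run_manifest")
  if (!is.null(out)) {
    yaml::write_yaml(list(counts = manifest$counts, timings = as.list(timings),
                          version = manifest$version),
                     file.path(out, "manifest.yaml"))
  }
  manifest
}

#' Identify the score components tracking the planted contact sets
#'
#' Each planted contact set bridges a specific helix pair (1-3 for set 1,
#' 1-2 for set 2). For each set, this sums the feature weights on all edges
#' bridging that helix pair (helices extended by `flank` flanking residues;
#' edges shared between the two bridge regions are dropped so the series
#' stay distinct) and picks the component whose coefficient row correlates
#' best with that series, without reusing a component. Summing over the
#' whole inter-helix bridge, rather than only the planted pairs themselves,
#' makes the series robust to which exact residue pairs the volume-optimal
#' cycles of partially docked conformations run through.
#'
#' @param fit an `nmf_fit`.
#' @param spec the [chain_spec()] with the planted contact sets.
#' @param V optional feature matrix used for the bridge-weight series
#'   (defaults to the reconstruction `WH`).
#' @param flank residues appended to each helix end when defining bridges.
#' @return integer vector, one component per contact set.
#' @export
contact_components <- function(fit, spec, V = NULL, flank = 2L) {
  n <- spec$n_residues
  seg <- spec$helix_segments
  W <- fit$W; H <- fit$H
  res_helix <- function(r) {
    for (h in seq_along(seg)) {
      if (r >= seg[[h]][1] && r <= seg[[h]][2]) return(h)
    }
    # off-helix residues attach to the nearest segment
    which.min(vapply(seg, function(s) min(abs(r - s)), numeric(1)))
  }
  bridge_idx <- function(a, b) {
    ia <- max(1, seg[[a]][1] - flank):min(n, seg[[a]][2] + flank)
    ib <- max(1, seg[[b]][1] - flank):min(n, seg[[b]][2] + flank)
    idx <- integer(0)
    for (i in ia) for (j in ib) if (i < j) idx <- c(idx, pair_index(i, j, n))
    unique(idx)
  }
  regions <- lapply(spec$contact_sets, function(pairs) {
    hp <- sort(unique(c(res_helix(pairs[1, 1]), res_helix(pairs[1, 2]))))
    bridge_idx(hp[1], hp[2])
  })
  shared <- Reduce(intersect, regions)
  regions <- lapply(regions, setdiff, y = shared)
  comps <- integer(length(regions))
  taken <- integer(0)
  for (k in seq_along(regions)) {
    idx <- regions[[k]]
    series <- if (!is.null(V)) colSums(V[idx, , drop = FALSE])
    else colSums(W[idx, , drop = FALSE] %*% H)
    cors <- vapply(seq_len(nrow(H)), function(l) {
      if (sd(H[l, ]) == 0) return(-Inf)
      cor(H[l, ], series)
    }, numeric(1))
    cors[taken] <- -Inf
    comps[k] <- which.max(cors)
    taken <- c(taken, comps[k])
  }
  comps
}

#' Data-driven crossing thresholds for path classification
#'
#' For each selected component: half the median late-stage (final quarter)
#' score over the trajectories that express the component (late-stage mean
#' above 5 percent of the largest).
#'
#' @param rts list of `reduced_trajectory`.
#' @param comps component indices.
#' @return numeric thresholds, Angstrom.
#' @export
component_thresholds <- function(rts, comps) {
  vapply(comps, function(cp) {
    finals <- vapply(rts, function(rt) {
      s <- rt$scores[, cp]
      n <- length(s)
      mean(s[max(1, n - floor(n / 4)):n])
    }, numeric(1))
    expressed <- finals[finals > 0.05 * max(finals)]
    max(0.5 * stats::median(expressed), 1e-6)
  }, numeric(1))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> completed through:", x$completed, "\n")
  cnt <- x$counts
  cat("  trajectories:", cnt$simulated, "simulated,", cnt$kept, "kept;",
      cnt$frames_removed, "degenerate frames removed\n")
  if (!is.null(cnt$snapshots)) {
    cat("  snapshots:", cnt$snapshots, "; feature matrix",
        paste(cnt$matrix_shape, collapse = " x "), ";", cnt$cycles,
        "cycles; NMF rank", cnt$rank, "\n")
  }
  cat("  timings (s):", paste(names(x$timings), unlist(x$timings),
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}
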