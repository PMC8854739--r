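# Trajectory readers/writers. On-disk formats use 1-based residue numbering
# (the structural-biology convention); multi-model PDB carries one MODEL per
# frame with C-alpha-only ATOM records, and the XYZ table is a whitespace-
# separated (frame, residue, x, y, z) listing written at full precision so
# it round-trips exactly.

#' Write a trajectory to disk
#'
#' @param traj a `fold_trajectory`.
#' @param path output file path.
#' @param format `"pdb_multimodel"` (one MODEL per frame, C-alpha-only ATOM
#'   records, fixed-width coordinates) or `"xyz_table"` (whitespace-separated
#'   `frame residue x y z`, full precision).
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("pdb_multimodel", "xyz_table")) {
  format <- match.arg(format)
  if (format == "pdb_multimodel") {
    con <- file(path, "w")
    on.exit(close(con))
    for (t in seq_along(traj$frames)) {
      writeLines(sprintf("MODEL %8d", t), con)
      f <- traj$frames[[t]]
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        seq_len(nrow(f)), seq_len(nrow(f)), f[, 1], f[, 2], f[, 3]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    rows <- do.call(rbind, lapply(seq_along(traj$frames), function(t) {
      f <- traj$frames[[t]]
      cbind(t, seq_len(nrow(f)), f)
    }))
    lines <- sprintf("%d %d %.17g %.17g %.17g",
                     rows[, 1], rows[, 2], rows[, 3], rows[, 4], rows[, 5])
    writeLines(c("# frame residue x y z", lines), path)
  }
  invisible(path)
}

#' Read a trajectory from disk
#'
#' Counterpart of [write_trajectory()]; parses C-alpha coordinates and maps
#' the on-disk 1-based residue numbering to row order.
#'
#' @param path input file path.
#' @param format `"pdb_multimodel"` or `"xyz_table"`.
#' @param id trajectory identifier for the result.
#' @param frame_interval snapshot spacing, ps.
#' @return A `fold_trajectory`.
#' @export
read_trajectory <- function(path, format = c("pdb_multimodel", "xyz_table"),
                            id = sub("\\.(pdb|xyz|txt)$", "", basename(path)),
                            frame_interval = 250) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "pdb_multimodel") {
    frames <- list()
    cur <- NULL
    in_model <- FALSE
    for (ln in seq_along(lines)) {
      line <- lines[ln]
      tag <- substr(line, 1, 6)
      if (startsWith(line, "MODEL")) {
        if (in_model) stop("parse error at line ", ln, ": nested MODEL")
        in_model <- TRUE
        cur <- list()
      } else if (startsWith(line, "ENDMDL")) {
        if (!in_model) stop("parse error at line ", ln, ": ENDMDL without MODEL")
        in_model <- FALSE
        frames <- c(frames, list(do.call(rbind, cur)))
        cur <- NULL
      } else if (tag == "ATOM  ") {
        if (!in_model) stop("parse error at line ", ln, ": ATOM outside MODEL")
        if (trimws(substr(line, 13, 16)) != "CA") next
        xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                             substr(line, 39, 46),
                                             substr(line, 47, 54))))
        if (any(is.na(xyz))) stop("parse error at line ", ln,
                                  ": malformed coordinates")
        cur <- c(cur, list(xyz))
      }
    }
    if (in_model) stop("parse error: file ends inside a MODEL (truncated?)")
    if (length(frames) == 0L) stop("no MODEL records found in ", path)
    frames <- lapply(frames, function(f) {
      colnames(f) <- c("x", "y", "z")
      f
    })
  } else {
    body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) != 5L)
    if (length(bad)) stop("parse error at line ", bad[1], ": expected 5 fields")
    m <- matrix(as.numeric(unlist(parts)), ncol = 5, byrow = TRUE)
    if (any(is.na(m))) stop("parse error: non-numeric field")
    frames <- lapply(split.data.frame(m, m[, 1]), function(fm) {
      fm <- fm[order(fm[, 2]), , drop = FALSE]
      out <- fm[, 3:5, drop = FALSE]
      colnames(out) <- c("x", "y", "z")
      out
    })
    frames <- frames[order(as.numeric(names(frames)))]
    names(frames) <- NULL
  }
  new_trajectory(id = id, frames = frames, frame_interval = frame_interval)
}

#' Write persistence diagrams to CSV
#'
#' One row per cycle: snapshot id, birth, death, optimal volume size.
#'
#' @param diagrams list of `ph_diagram`.
#' @param path output CSV path.
#' @export
write_diagrams <- function(diagrams, path) {
  rows <- lapply(diagrams, function(d) {
    if (nrow(d$pairs) == 0L) return(NULL)
    cbind(data.frame(snapshot_id = d$snapshot_id), d$pairs)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(snapshot_id = character(0), birth = numeric(0),
                      death = numeric(0), n_edges = integer(0),
                      volume_size = integer(0))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write volume-optimal cycles to JSON
#'
#' Maps snapshot id to its list of cycles `{birth, death, edges}`. Residue
#' indices are written 0-based with an explicit `"indexing"` field, for
#' interoperability with array-indexed tooling.
#'
#' @param diagrams list of `ph_diagram`.
#' @param path output JSON path.
#' @export
write_cycles_json <- function(diagrams, path) {
  payload <- list(indexing = "0-based", snapshots = list())
  for (d in diagrams) {
    cyc <- lapply(d$cycles, function(cy) {
      list(birth = cy$birth, death = cy$death,
           edges = unname(cy$cycle) - 1L)
    })
    payload$snapshots[[as.character(d$snapshot_id)]] <- cyc
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Flat key-value configuration covering chain/plan parameters, the
#' preprocessing cutoff, homology jitter seed, NMF settings, flow grid and
#' the global seed; unknown keys are rejected. See [run_config()] for the
#' defaults.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
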