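#' Rank selection by the residual-sum-of-squares curve
#'
#' Fits NMF at each candidate rank on a seeded random column subsample and
#' records the residual sum of squares `||V - WH||_F^2`. A rank is selected
#' at the inflection of the RSS curve: the interior rank with the dominant
#' discrete second difference `RSS(L-1) - 2 RSS(L) + RSS(L+1)`. When no rank
#' concentrates the curvature — the RSS decreases essentially linearly, as
#' happens for heterogeneous real ensembles — the report states that no
#' inflection exists rather than forcing a choice (see the methods vignette
#' for this operationalization).
#'
#' @param V non-negative feature matrix.
#' @param ranks ascending integer ranks to evaluate.
#' @param n_subsample number of columns to subsample (clamped with a warning
#'   when it exceeds `ncol(V)`).
#' @param seed integer seed (controls the subsample and the per-rank fits).
#' @param max_iter,tol passed to [nmf_fit()].
#' @return list with `table` (data frame: rank, rss), `selected` (integer or
#'   `NA`), `no_inflection` flag, `n_subsample`, `seed`.
#' @export
rank_selection_rss <- function(V, ranks = 3:10, n_subsample = 10000L,
                               seed = 1L, max_iter = 500L, tol = 1e-6) {
  V <- as.matrix(V)
  ranks <- as.integer(ranks)
  if (is.unsorted(ranks, strictly = TRUE)) stop("`ranks` must be strictly ascending")
  if (n_subsample > ncol(V)) {
    warning("n_subsample exceeds the number of samples; using all ", ncol(V))
    n_subsample <- ncol(V)
  }
  cols <- with_seed(derive_seed(seed, 31L), sample.int(ncol(V), n_subsample))
  sub <- V[, cols, drop = FALSE]
  if (max(ranks) > min(dim(sub))) stop("largest rank exceeds min(dim) of the subsample")
  rss <- vapply(ranks, function(L) {
    fit <- nmf_fit(sub, L, seed = derive_seed(seed, 37L, L),
                   max_iter = max_iter, tol = tol)
    fit$objective^2
  }, numeric(1))
  sel <- NA_integer_
  no_inflection <- TRUE
  if (length(ranks) >= 3L) {
    d2 <- rss[seq_len(length(rss) - 2L)] - 2 * rss[seq(2L, length(rss) - 1L)] +
      rss[seq(3L, length(rss))]
    pos <- pmax(d2, 0)
    if (sum(pos) > 0 && max(pos) / sum(pos) > 0.5) {
      sel <- ranks[which.max(pos) + 1L]
      no_inflection <- FALSE
    }
  }
  list(table = data.frame(rank = ranks, rss = rss), selected = sel,
       no_inflection = no_inflection, n_subsample = n_subsample,
       seed = as.integer(seed))
}

#' Rank selection by cophenetic correlation of consensus clustering
#'
#' For every candidate rank, NMF is run `n_runs` times from different seeded
#' initializations on a column subsample; each sample is assigned to the
#' basis with the largest coefficient in its column (ties to the lowest
#' index), and the M x M consensus matrix records the fraction of runs in
#' which two samples co-cluster. The cophenetic correlation between the
#' consensus dissimilarity `1 - consensus` and the cophenetic distances of
#' its average-linkage dendrogram measures clustering stability; the
#' selected rank maximizes it (smallest rank on ties). A perfectly stable
#' clustering (binary consensus) yields coefficient 1.
#'
#' @param V non-negative feature matrix.
#' @param ranks integer ranks to evaluate.
#' @param n_runs NMF restarts per rank (>= 2).
#' @param n_subsample columns to subsample (clamped with a warning).
#' @param seed integer seed.
#' @param max_iter,tol passed to [nmf_fit()].
#' @return list with `table` (data frame: rank, cophenetic), `selected`,
#'   `n_runs`, `n_subsample`, `seed`, and `consensus` (per-rank consensus
#'   matrices).
#' @export
cophenetic_rank_selection <- function(V, ranks = 3:10, n_runs = 30L,
                                      n_subsample = 10000L, seed = 1L,
                                      max_iter = 500L, tol = 1e-6) {
  V <- as.matrix(V)
  ranks <- as.integer(ranks)
  stopifnot_scalar_count(n_runs, "n_runs", min = 2L)
  if (n_subsample > ncol(V)) {
    warning("n_subsample exceeds the number of samples; using all ", ncol(V))
    n_subsample <- ncol(V)
  }
  cols <- with_seed(derive_seed(seed, 41L), sample.int(ncol(V), n_subsample))
  sub <- V[, cols, drop = FALSE]
  M <- ncol(sub)
  coph <- numeric(length(ranks))
  consensus_list <- vector("list", length(ranks))
  for (r in seq_along(ranks)) {
    L <- ranks[r]
    consensus <- matrix(0, M, M)
    for (run in seq_len(n_runs)) {
      fit <- nmf_fit(sub, L, seed = derive_seed(seed, 43L, L, run),
                     max_iter = max_iter, tol = tol)
      lab <- apply(fit$H, 2, which.max)
      if (length(unique(lab)) < L) {
        warning("rank ", L, " run ", run, ": ", L - length(unique(lab)),
                " basis column(s) attracted no samples")
      }
      consensus <- consensus + outer(lab, lab, "==")
    }
    consensus <- consensus / n_runs
    coph[r] <- cophenetic_coefficient(consensus)
    consensus_list[[r]] <- consensus
  }
  list(table = data.frame(rank = ranks, cophenetic = coph),
       selected = ranks[which.max(coph)], n_runs = as.integer(n_runs),
       n_subsample = n_subsample, seed = as.integer(seed),
       consensus = consensus_list)
}

# Cophenetic correlation between a consensus matrix's dissimilarities and
# the cophenetic distances of their average-linkage dendrogram. A constant
# dissimilarity structure (perfectly stable clustering collapsing to one
# block) is maximally consistent: coefficient 1.
cophenetic_coefficient <- function(consensus) {
  d <- as.dist(1 - consensus)
  if (sd(d) == 0) return(1)
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (sd(cd) == 0) return(1)
  cor(d, cd)
}

#' Run both rank-selection criteria
#'
#' Convenience wrapper combining [rank_selection_rss()] and
#' [cophenetic_rank_selection()] into one report.
#'
#' @inheritParams cophenetic_rank_selection
#' @return Object of class `rank_report`: merged per-rank table and both
#'   selections.
#' @export
select_rank <- function(V, ranks = 3:10, n_runs = 30L, n_subsample = 10000L,
                        seed = 1L, max_iter = 500L, tol = 1e-6) {
  rss <- rank_selection_rss(V, ranks, n_subsample = n_subsample, seed = seed,
                            max_iter = max_iter, tol = tol)
  cop <- cophenetic_rank_selection(V, ranks, n_runs = n_runs,
                                   n_subsample = n_subsample, seed = seed,
                                   max_iter = max_iter, tol = tol)
  tab <- merge(rss$table, cop$table, by = "rank")
  tab$selected_rss <- tab$rank %in% rss$selected
  tab$selected_cophenetic <- tab$rank %in% cop$selected
  structure(list(table = tab, selected_rss = rss$selected,
                 no_inflection = rss$no_inflection,
                 selected_cophenetic = cop$selected,
                 n_runs = cop$n_runs, n_subsample = cop$n_subsample,
                 seed = as.integer(seed)),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat("<rank_report> over ranks", paste(range(x$table$rank), collapse = "-"), "\n")
  print(x$table, row.names = FALSE)
  cat("RSS inflection:",
      if (x$no_inflection) "none (RSS decreases ~linearly)" else x$selected_rss,
      "\n")
  cat("Cophenetic argmax:", x$selected_cophenetic, "\n")
  invisible(x)
}
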