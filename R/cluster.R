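# Correlation-metric K-means with leave-one-out centroids.
#
# Profiles are randomly split into k sets; each sweep compares every cell
# k to the per-gene sums of each set computed *without* cell k's own
# transcripts (leave-one-out, so a cell is not attracted to itself) and
# reassigns it to the set with the highest Pearson correlation.  Sweeps
# repeat until no more than 1% of cells switch in each of the last 4
# iterations.  Pearson correlation is scale-invariant, so using the sum
# rather than the mean of member profiles changes nothing.

#' Pearson correlation with explicit degenerate handling
#'
#' Standard Pearson correlation on raw count vectors.  If either vector
#' has zero variance the correlation is undefined: `NA` is returned with
#' a warning rather than an arbitrary value.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: zero variance")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# Correlations of every row of X with each cluster's leave-one-out
# centroid sum, via sufficient statistics (one matrix product per
# cluster).  Undefined correlations map to -Inf so such a centroid never
# attracts a cell.
.loo_correlations <- function(X, assign, k) {
  n <- nrow(X); G <- ncol(X)
  rs <- rowSums(X)
  rq <- rowSums(X^2)
  C <- matrix(-Inf, n, k)
  for (c in seq_len(k)) {
    members <- assign == c
    A <- colSums(X[members, , drop = FALSE])
    sA <- sum(A); sA2 <- sum(A^2)
    cross <- as.numeric(X %*% A)
    own <- as.numeric(members)
    sxA <- cross - own * rq          # sum x * (A - own x)
    sAp <- sA - own * rs             # sum (A - own x)
    sA2p <- sA2 - own * (2 * cross - rq)
    num <- sxA - rs * sAp / G
    den2 <- (rq - rs^2 / G) * (sA2p - sAp^2 / G)
    ok <- den2 > 0
    C[ok, c] <- num[ok] / sqrt(den2[ok])
  }
  C
}

#' Cluster single-cell profiles by leave-one-out correlation K-means
#'
#' Starts from a seeded balanced random split and iterates batch sweeps:
#' every cell is compared with each cluster's leave-one-out centroid
#' (per-gene sum of members excluding the cell itself, frozen at sweep
#' start) and moves to the highest-correlation cluster; exact ties are
#' broken toward the cell's current cluster.  The run converges when the
#' fraction of cells switching is at most `switch_tolerance` in each of
#' the last `stability_window` iterations (a zero-switch sweep is a fixed
#' point and stops immediately).  A cluster emptied mid-run is re-seeded
#' with the cell least correlated to the remaining centroids, and logged.
#'
#' @param x Counts matrix (cells x genes), or a `counts_matrix`.
#' @param k Number of clusters (the validated surface is k = 2).
#' @param seed Seed for the initial split.
#' @param max_iterations Sweep cap; exceeding it flags non-convergence.
#' @param switch_tolerance Maximum switching fraction for a "stable"
#'   iteration.
#' @param stability_window Number of consecutive stable iterations
#'   required.
#' @param transform `"none"` (raw counts, the default) or `"log1p"`.
#' @return An object of class `cluster_result`: list with `assignments`
#'   (named integer vector in `1..k`), `switch_history`, `iterations`,
#'   `converged`, `reseeded` (count), `seed`, `k`.
#' @export
correlation_kmeans <- function(x, k = 2L, seed = 1L, max_iterations = 100L,
                               switch_tolerance = 0.01,
                               stability_window = 4L,
                               transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  X <- if (inherits(x, "counts_matrix")) x$counts else as.matrix(x)
  if (transform == "log1p") X <- log1p(X)
  n <- nrow(X)
  if (n < 2L * k) stop("need at least 2k cells", call. = FALSE)
  if (ncol(X) < 2L) stop("need at least 2 genes", call. = FALSE)

  assign <- .with_seed(seed, sample(rep_len(seq_len(k), n)))
  history <- numeric(0)
  converged <- FALSE
  reseeded <- 0L

  for (it in seq_len(max_iterations)) {
    C <- .loo_correlations(X, assign, k)
    cur <- C[cbind(seq_len(n), assign)]
    best <- max.col(C, ties.method = "first")
    move <- C[cbind(seq_len(n), best)] > cur   # strict: ties stay put
    new_assign <- ifelse(move, best, assign)

    # re-seed any emptied cluster with the least-attracted cell
    for (c in seq_len(k)) {
      if (!any(new_assign == c)) {
        pool_best <- apply(C, 1L, max)
        victim <- which.min(pool_best)
        new_assign[victim] <- c
        reseeded <- reseeded + 1L
      }
    }
    switched <- mean(new_assign != assign)
    history <- c(history, switched)
    assign <- new_assign
    if (switched == 0) { converged <- TRUE; break }
    if (length(history) >= stability_window &&
        all(utils::tail(history, stability_window) <= switch_tolerance)) {
      converged <- TRUE
      break
    }
  }
  names(assign) <- rownames(X)
  structure(list(assignments = assign,
                 switch_history = history,
                 iterations = length(history),
                 converged = converged,
                 reseeded = reseeded,
                 seed = as.integer(seed),
                 k = as.integer(k)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k=%d, sizes %s, %d iterations (%s)\n",
              x$k, paste(tabulate(x$assignments, x$k), collapse = "/"),
              x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Best-permutation clustering accuracy
#'
#' Fraction of cells whose cluster matches their true label under the
#' best mapping of cluster ids to labels (cluster labels are arbitrary).
#'
#' @param assignments Cluster ids (vector or `cluster_result`).
#' @param truth True labels (any type; same length).
#' @return Accuracy in `[0, 1]`.
#' @export
clustering_accuracy <- function(assignments, truth) {
  if (inherits(assignments, "cluster_result")) {
    assignments <- assignments$assignments
  }
  stopifnot(length(assignments) == length(truth))
  a <- as.integer(factor(assignments))
  b <- as.integer(factor(truth))
  k <- max(a, b)
  if (k > 6L) stop("accuracy by permutation only supported for k <= 6",
                   call. = FALSE)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, mean(p[a] == b))
  }
  best
}

#' Replace transcripts with draws from the aggregate transcriptome
#'
#' For every cell, removes `m` transcripts uniformly without replacement
#' from its own profile and adds `m` transcripts drawn from the aggregate
#' profile of all cells (column sums of the input matrix), preserving
#' per-cell totals.  This is the in-silico crosstalk injection used to
#' probe clustering robustness.
#'
#' @param x Counts matrix (cells x genes) or `counts_matrix`.
#' @param m Transcripts to replace per cell (scalar or per-cell vector).
#' @param seed RNG seed.
#' @return Perturbed integer matrix of the same shape.
#' @export
inject_foreign <- function(x, m, seed = 1L) {
  X <- if (inherits(x, "counts_matrix")) x$counts else as.matrix(x)
  n <- nrow(X); G <- ncol(X)
  m <- rep_len(as.integer(m), n)
  totals <- rowSums(X)
  if (any(m > totals)) {
    bad <- which(m > totals)[1L]
    stop(sprintf("cell '%s' has %d transcripts, cannot replace %d",
                 rownames(X)[bad] %||% bad, totals[bad], m[bad]), call. = FALSE)
  }
  agg <- colSums(X)
  .with_seed(seed, {
    for (i in seq_len(n)) {
      if (m[i] == 0L) next
      pool <- rep.int(seq_len(G), X[i, ])
      removed <- tabulate(pool[sample.int(length(pool), m[i])], nbins = G)
      added <- tabulate(sample.int(G, m[i], replace = TRUE, prob = agg),
                        nbins = G)
      X[i, ] <- X[i, ] - removed + added
    }
    X
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clustering robustness to injected crosstalk
#'
#' For each value of `m` in the grid and each of `n_trials` trials,
#' replaces `m` transcripts per cell with aggregate draws
#' ([inject_foreign()]), reclusters ([correlation_kmeans()]) and scores
#' the best-permutation accuracy against the true labels; the per-`m`
#' mean over trials is reported.
#'
#' @param x Counts matrix (cells x genes).
#' @param true_labels True population per cell.
#' @param m_grid Integer vector of foreign-transcript counts.
#' @param n_trials Clustering trials per grid point.
#' @param seed Master seed (each trial gets a derived sub-seed).
#' @param ... Passed to [correlation_kmeans()].
#' @return An object of class `robustness_curve`: data.frame with `m`,
#'   `mean_accuracy`, `sd_accuracy`, `n_trials`, and the per-trial
#'   accuracy matrix as attribute `"trials"`.
#' @export
robustness_curve <- function(x, true_labels, m_grid, n_trials = 20L,
                             seed = 1L, ...) {
  X <- if (inherits(x, "counts_matrix")) x$counts else as.matrix(x)
  stopifnot(length(true_labels) == nrow(X))
  seeds <- matrix(.subseeds(seed, 2L * length(m_grid) * n_trials),
                  nrow = 2L)
  acc <- matrix(NA_real_, length(m_grid), n_trials)
  col <- 0L
  for (mi in seq_along(m_grid)) {
    for (t in seq_len(n_trials)) {
      col <- col + 1L
      Xp <- inject_foreign(X, m_grid[mi], seed = seeds[1L, col])
      cl <- correlation_kmeans(Xp, seed = seeds[2L, col], ...)
      acc[mi, t] <- clustering_accuracy(cl, true_labels)
    }
  }
  out <- data.frame(m = m_grid,
                    mean_accuracy = rowMeans(acc),
                    sd_accuracy = apply(acc, 1L, stats::sd),
                    n_trials = n_trials)
  attr(out, "trials") <- acc
  class(out) <- c("robustness_curve", "data.frame")
  out
}
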