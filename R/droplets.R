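# Droplet-loading statistics.
#
# Cells are encapsulated at a Poisson "filling number" lambda (mean cells
# per drop); cell-bearing drops are then fused with barcode drops at
# frequency f.  Closed forms below are each paired with a Monte-Carlo
# sampler so the two routes can be cross-checked.

#' Conditional doublet probability under Poisson loading
#'
#' Probability that an occupied droplet contains two or more cells,
#' \eqn{P(K \ge 2 \mid K \ge 1)} for \eqn{K \sim Poisson(\lambda)}:
#' \deqn{(1 - e^{-\lambda} - \lambda e^{-\lambda}) / (1 - e^{-\lambda}).}
#' At the working filling number \eqn{\lambda = 0.1} this is about 4.9%,
#' under the 5% operating bound.
#'
#' @param lambda Filling number (mean cells per drop), > 0.
#' @return Probability in `[0, 1]`.
#' @seealso [cell_multiplet_fraction()] for the related (larger) fraction
#'   of *cells* that share a drop with another cell.
#' @examples
#' doublet_fraction(0.1)
#' @export
doublet_fraction <- function(lambda) {
  .assert_scalar_number(lambda, "lambda", lower = 0, strict = TRUE)
  (1 - exp(-lambda) - lambda * exp(-lambda)) / (1 - exp(-lambda))
}

#' Fraction of cells residing in multi-cell drops
#'
#' For a randomly chosen *cell* (size-biased occupancy), the probability
#' that its drop holds at least one other cell: \eqn{1 - e^{-\lambda}}.
#' This is the larger of the two common "doublet rate" readings (about
#' 9.5% at \eqn{\lambda = 0.1}); the per-occupied-drop reading is
#' [doublet_fraction()].
#'
#' @param lambda Filling number, > 0.
#' @return Probability in `[0, 1]`.
#' @export
cell_multiplet_fraction <- function(lambda) {
  .assert_scalar_number(lambda, "lambda", lower = 0, strict = TRUE)
  1 - exp(-lambda)
}

#' Monte-Carlo doublet fraction
#'
#' Simulates droplet occupancies and returns the observed fraction of
#' occupied drops holding two or more cells, with a binomial standard
#' error for comparison against [doublet_fraction()].
#'
#' @param lambda Filling number.
#' @param n_drops Number of simulated drops.
#' @param seed RNG seed.
#' @return List with `estimate`, `se`, `n_occupied`.
#' @export
simulate_doublet_fraction <- function(lambda, n_drops = 1e6, seed = 1L) {
  .assert_scalar_number(lambda, "lambda", lower = 0, strict = TRUE)
  k <- .with_seed(seed, stats::rpois(n_drops, lambda))
  occ <- k[k >= 1L]
  p <- mean(occ >= 2L)
  list(estimate = p,
       se = sqrt(p * (1 - p) / length(occ)),
       n_occupied = length(occ))
}

#' Expected number of cells without a unique barcode
#'
#' When `n_cells` cells each draw a barcode independently from a library
#' of `n_barcodes` (uniformly, or with probabilities `weights`), the
#' expected number of cells that share their barcode with at least one
#' other cell is
#' \deqn{n \sum_b w_b \left(1 - (1 - w_b)^{n-1}\right),}
#' which reduces to \eqn{n (1 - (1 - 1/B)^{n-1})} in the uniform case.
#' For 100 cells and 1152 barcodes this is about 8.2 cells, under the
#' operating bound of 10 per sample.
#'
#' @param n_cells Number of cells.
#' @param n_barcodes Library size.
#' @param weights Optional barcode draw probabilities (length
#'   `n_barcodes`, normalized internally); NULL = uniform.
#' @return Expected number of colliding cells.
#' @examples
#' expected_collisions(100, 1152)
#' @export
expected_collisions <- function(n_cells, n_barcodes, weights = NULL) {
  .assert_scalar_number(n_cells, "n_cells", lower = 1)
  .assert_scalar_number(n_barcodes, "n_barcodes", lower = 1)
  n <- n_cells
  if (is.null(weights)) {
    return(n * (1 - (1 - 1 / n_barcodes)^(n - 1)))
  }
  stopifnot(length(weights) == n_barcodes, all(weights >= 0))
  w <- weights / sum(weights)
  n * sum(w * (1 - (1 - w)^(n - 1)))
}

#' Monte-Carlo barcode collisions
#'
#' Repeatedly assigns barcodes to cells and counts cells whose barcode was
#' drawn by at least one other cell.
#'
#' @param n_cells Number of cells per trial.
#' @param n_barcodes Library size.
#' @param n_trials Number of trials.
#' @param seed RNG seed.
#' @param weights Optional draw probabilities.
#' @return List with `estimate` (mean colliding cells per trial), `se`.
#' @export
simulate_collisions <- function(n_cells, n_barcodes, n_trials = 1e5,
                                seed = 1L, weights = NULL) {
  counts <- .with_seed(seed, {
    vapply(seq_len(n_trials), function(i) {
      draw <- sample.int(n_barcodes, n_cells, replace = TRUE, prob = weights)
      tab <- tabulate(draw, nbins = n_barcodes)
      as.integer(n_cells) - sum(tab == 1L)
    }, integer(1))
  })
  list(estimate = mean(counts),
       se = stats::sd(counts) / sqrt(n_trials))
}

#' Collection throughput plan
#'
#' Time to collect `n_cells` labeled cells when fused drop pairs form at
#' frequency `fusion_rate` (Hz) and a fraction \eqn{\lambda} of cell-side
#' drops carry a cell: \eqn{T = n / (\lambda f)}, generalizing the
#' 100-cell collection time \eqn{T_{100} = 100/\lambda f} (10 s at
#' \eqn{\lambda = 0.1}, f = 100 Hz).
#'
#' @param n_cells Target number of cells.
#' @param lambda Filling number.
#' @param fusion_rate Fused-pair frequency f in Hz.
#' @return An object of class `collection_plan`: list with
#'   `n_cells_target`, `pairs_needed` (`ceiling(n / lambda)`) and
#'   `collection_time_s`.
#' @examples
#' collection_time(100, lambda = 0.1, fusion_rate = 100)  # 10 s, 1000 pairs
#' @export
collection_time <- function(n_cells, lambda, fusion_rate) {
  .assert_scalar_number(n_cells, "n_cells", lower = 1)
  .assert_scalar_number(lambda, "lambda", lower = 0, strict = TRUE)
  .assert_scalar_number(fusion_rate, "fusion_rate", lower = 0, strict = TRUE)
  structure(list(n_cells_target = as.integer(n_cells),
                 pairs_needed = as.integer(ceiling(n_cells / lambda)),
                 collection_time_s = n_cells / (lambda * fusion_rate)),
            class = "collection_plan")
}

#' @export
print.collection_plan <- function(x, ...) {
  cat(sprintf("collection_plan: %d cells, %d fused pairs, %.3g s\n",
              x$n_cells_target, x$pairs_needed, x$collection_time_s))
  invisible(x)
}
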