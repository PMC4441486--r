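# Cell calling: separate cell-bearing barcodes from empty-drop background.
#
# Empty fused drops still pick up a few ambient transcripts; their
# per-barcode totals are modeled as a low-mean Poisson component.  A
# two-component mixture (Poisson background + heavy cell component) is fit
# by EM and barcodes above the background's upper-tail confidence
# threshold are called cells.

#' Fit the empty-drop background rate
#'
#' Fits a two-component Poisson mixture to per-barcode unique-transcript
#' totals by expectation-maximization and returns the component with the
#' smaller mean as the background.  If EM does not converge within
#' `max_em_iterations`, falls back to the trimmed-moment estimator (mean
#' of counts at or below the 75th percentile) with a warning flag.
#'
#' @param counts Per-barcode totals (vector, matrix or `counts_matrix`;
#'   at least 10 barcodes).
#' @param fit_method `"two_component_em"` or `"trimmed_moment"`.
#' @param max_em_iterations Maximum EM iterations.
#' @param tolerance Convergence tolerance on the background mean.
#' @return List with `background_mean`, `components` (means `mu`, mixing
#'   weight `pi_background`), `converged`, `method_used`.
#' @examples
#' x <- c(rpois(900, 39), rpois(100, 340))
#' fit_background(x)$background_mean
#' @export
fit_background <- function(counts,
                           fit_method = c("two_component_em", "trimmed_moment"),
                           max_em_iterations = 500L, tolerance = 1e-8) {
  fit_method <- match.arg(fit_method)
  x <- .barcode_totals(counts)
  if (length(x) < 10L) stop("need at least 10 barcodes", call. = FALSE)
  if (stats::var(x) == 0) {
    # degenerate: all totals identical
    return(list(background_mean = x[1L],
                components = list(mu = c(x[1L], x[1L]), pi_background = 1),
                converged = TRUE, method_used = "degenerate"))
  }
  trimmed <- mean(x[x <= stats::quantile(x, 0.75)])
  if (fit_method == "trimmed_moment") {
    return(list(background_mean = trimmed,
                components = NULL, converged = TRUE,
                method_used = "trimmed_moment"))
  }

  # EM init: split at the overall median
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(hi) == 0L) hi <- max(x)
  mu <- c(mean(lo), mean(hi))
  if (mu[2] <= mu[1]) mu[2] <- mu[1] + 1
  pi1 <- length(lo) / length(x)
  converged <- FALSE
  collapsed <- FALSE
  ll_old <- -Inf
  for (it in seq_len(max_em_iterations)) {
    l1 <- log(pi1) + stats::dpois(x, mu[1], log = TRUE)
    l2 <- log1p(-pi1) + stats::dpois(x, mu[2], log = TRUE)
    m <- pmax(l1, l2)
    g1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
    mu_new <- c(sum(g1 * x) / sum(g1),
                sum((1 - g1) * x) / sum(1 - g1))
    pi_new <- mean(g1)
    if (!all(is.finite(mu_new)) || any(is.nan(mu_new)) ||
        pi_new < 1e-6 || pi_new > 1 - 1e-6) {
      # one component vanished: the data is effectively single-component
      collapsed <- TRUE
      break
    }
    mu <- mu_new; pi1 <- pi_new
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    if (is.finite(ll) && abs(ll - ll_old) < tolerance * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (collapsed) {
    return(list(background_mean = mean(x),
                components = list(mu = c(mean(x), mean(x)), pi_background = 1),
                converged = TRUE, method_used = "single_component"))
  }
  if (!converged) {
    warning("EM did not converge; falling back to trimmed-moment estimate")
    return(list(background_mean = trimmed, components = NULL,
                converged = FALSE, method_used = "trimmed_moment_fallback"))
  }
  # model selection: on data that is actually single-component, a forced
  # two-component fit biases the smaller mean downward -- keep the
  # mixture only if BIC prefers it over one Poisson
  ll2 <- sum(log(pi1 * stats::dpois(x, mu[1]) +
                   (1 - pi1) * stats::dpois(x, mu[2])))
  ll1 <- sum(stats::dpois(x, mean(x), log = TRUE))
  n <- length(x)
  bic2 <- -2 * ll2 + 3 * log(n)
  bic1 <- -2 * ll1 + 1 * log(n)
  if (bic1 <= bic2) {
    return(list(background_mean = mean(x),
                components = list(mu = c(mean(x), mean(x)), pi_background = 1),
                converged = TRUE, method_used = "single_component"))
  }
  bg <- which.min(mu)
  list(background_mean = mu[bg],
       components = list(mu = mu,
                         pi_background = if (bg == 1L) pi1 else 1 - pi1),
       converged = TRUE, method_used = "two_component_em")
}

#' Call cell-bearing barcodes
#'
#' Fits the background rate (see [fit_background()]) and calls as cells
#' all barcodes whose total is at least the smallest integer `t` with
#' \eqn{F_{Poisson}(t - 1; \mu_{bg}) \ge P}, i.e. totals that a pure
#' background barcode would exceed with probability below `1 - P`.
#'
#' @param counts Per-barcode totals (named vector, matrix or
#'   `counts_matrix`).
#' @param confidence Confidence level P (default 0.99).
#' @param background Optional known background mean; skips fitting.
#' @param ... Passed to [fit_background()].
#' @return An object of class `cell_call_result`: list with
#'   `background_mean`, `threshold`, `called` (barcode names or indices),
#'   `is_cell` (per-barcode logical), `confidence`, `fit`.
#' @export
call_cells <- function(counts, confidence = 0.99, background = NULL, ...) {
  .assert_scalar_number(confidence, "confidence", lower = 0, strict = TRUE)
  if (confidence >= 1) stop("'confidence' must be in (0, 1)", call. = FALSE)
  x <- .barcode_totals(counts)
  fit <- if (is.null(background)) fit_background(x, ...) else
    list(background_mean = background, method_used = "supplied")
  thr <- max(1L, stats::qpois(confidence, fit$background_mean) + 1L)
  is_cell <- x >= thr
  called <- if (!is.null(names(x))) names(x)[is_cell] else which(is_cell)
  structure(list(background_mean = fit$background_mean,
                 threshold = as.integer(thr),
                 called = called,
                 is_cell = is_cell,
                 confidence = confidence,
                 fit = fit),
            class = "cell_call_result")
}

#' @export
print.cell_call_result <- function(x, ...) {
  cat(sprintf("cell_call_result: background mean %.2f, threshold %d, %d cells called\n",
              x$background_mean, x$threshold, sum(x$is_cell)))
  invisible(x)
}

#' Naive top-k cell selection
#'
#' The naive alternative to model-based calling: take the `k` barcodes
#' with the largest totals.
#'
#' @param counts Per-barcode totals (any form accepted by
#'   [call_cells()]).
#' @param k Number of barcodes to select.
#' @return Logical vector (same order as the totals), TRUE for selected.
#' @export
naive_top_k <- function(counts, k) {
  x <- .barcode_totals(counts)
  stopifnot(k >= 1L, k <= length(x))
  sel <- rep(FALSE, length(x))
  sel[order(x, decreasing = TRUE)[seq_len(k)]] <- TRUE
  names(sel) <- names(x)
  sel
}
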