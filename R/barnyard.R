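# Barnyard crosstalk estimation.
#
# In a deliberate mixed-organism (mouse/human) run, transcripts of the
# "wrong" organism under a barcode must come from cell-to-cell crosstalk.
# Each organism's cells only make the other organism's contamination
# visible, so the total foreign load per barcode is estimated by summing
# independent draws from the two visible-foreign distributions.

#' Assign a barcode to an organism
#'
#' Majority vote over organism-exclusive transcript counts; exact ties
#' (or two zeros) are flagged ambiguous.
#'
#' @param mouse_count,human_count Exclusive transcript counts.
#' @return `"mouse"`, `"human"` or `NA` (ambiguous / empty); vectorized.
#' @export
assign_organism <- function(mouse_count, human_count) {
  stopifnot(all(mouse_count >= 0), all(human_count >= 0))
  out <- ifelse(mouse_count > human_count, "mouse",
                ifelse(human_count > mouse_count, "human", NA_character_))
  out
}

#' Per-barcode barnyard profiles
#'
#' For each barcode above the inclusion threshold, counts transcripts of
#' genes exclusive to each organism, assigns the barcode to the
#' majority organism and flags ties/empties as excluded.
#'
#' @param counts A `counts_matrix` or barcodes x genes matrix.
#' @param gene_organisms Organism per gene: named character vector, or a
#'   data.frame with columns `gene_id` and `organism`.  Genes labeled
#'   anything other than `"mouse"`/`"human"` (e.g. `"shared"`) are
#'   excluded from the exclusive counts.
#' @param min_total Inclusion threshold: only barcodes with *more than*
#'   this many total transcripts enter the profiles (default 200).
#' @return An object of class `barnyard_profile`: data.frame with
#'   `barcode`, `total`, `mouse_count`, `human_count`, `organism`,
#'   `included`, `reason`.
#' @export
barnyard_profile <- function(counts, gene_organisms, min_total = 200L) {
  m <- if (inherits(counts, "counts_matrix")) counts$counts else counts
  if (is.data.frame(gene_organisms)) {
    gene_organisms <- stats::setNames(gene_organisms$organism,
                                      gene_organisms$gene_id)
  }
  org <- gene_organisms[colnames(m)]
  if (anyNA(org)) stop("every gene needs an organism label", call. = FALSE)
  total <- rowSums(m)
  mouse <- rowSums(m[, org == "mouse", drop = FALSE])
  human <- rowSums(m[, org == "human", drop = FALSE])
  assigned <- assign_organism(mouse, human)
  included <- total > min_total & !is.na(assigned)
  reason <- rep("", nrow(m))
  reason[total <= min_total] <- "below_threshold"
  reason[total > min_total & is.na(assigned)] <-
    ifelse(mouse[total > min_total & is.na(assigned)] +
             human[total > min_total & is.na(assigned)] == 0,
           "no_exclusive_transcripts", "tie")
  out <- data.frame(barcode = rownames(m), total = total,
                    mouse_count = mouse, human_count = human,
                    organism = assigned, included = included,
                    reason = reason, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("barnyard_profile", "data.frame")
  out
}

#' Visible-foreign transcript distributions
#'
#' The foreign count of a mouse-assigned barcode is its human-exclusive
#' count, and vice versa.  Returns both empirical distributions; when one
#' organism is absent the result is flagged partial.
#'
#' @param profiles A [barnyard_profile()].
#' @return An object of class `foreign_distributions`: list with
#'   `human_in_mouse`, `mouse_in_human` (integer vectors), `partial`.
#' @export
foreign_distributions <- function(profiles) {
  stopifnot(inherits(profiles, "barnyard_profile"))
  p <- profiles[profiles$included, , drop = FALSE]
  him <- p$human_count[p$organism == "mouse"]
  mih <- p$mouse_count[p$organism == "human"]
  structure(list(human_in_mouse = him,
                 mouse_in_human = mih,
                 partial = length(him) == 0L || length(mih) == 0L),
            class = "foreign_distributions")
}

#' @export
print.foreign_distributions <- function(x, ...) {
  cat(sprintf(paste0("foreign_distributions: human-in-mouse n=%d (mean %.1f), ",
                     "mouse-in-human n=%d (mean %.1f)%s\n"),
              length(x$human_in_mouse), mean(x$human_in_mouse),
              length(x$mouse_in_human), mean(x$mouse_in_human),
              if (x$partial) " [PARTIAL]" else ""))
  invisible(x)
}

#' Total foreign-transcript distribution
#'
#' Distribution of the total foreign load per barcode, estimated as sums
#' of independent pairs sampled (with replacement) from the two
#' visible-foreign distributions.
#'
#' @param d_visible_in_mouse,d_visible_in_human Nonempty numeric vectors
#'   (or a single [foreign_distributions()] object passed as the first
#'   argument).
#' @param n_samples Number of sampled pairs.
#' @param seed RNG seed.
#' @return Numeric vector of `n_samples` total-foreign draws.
#' @export
total_foreign_distribution <- function(d_visible_in_mouse,
                                       d_visible_in_human = NULL,
                                       n_samples = 1e5, seed = 1L) {
  if (inherits(d_visible_in_mouse, "foreign_distributions")) {
    fd <- d_visible_in_mouse
    d_visible_in_mouse <- fd$human_in_mouse
    d_visible_in_human <- fd$mouse_in_human
  }
  stopifnot(length(d_visible_in_mouse) >= 1L,
            length(d_visible_in_human) >= 1L, n_samples >= 1L)
  # index-based draws: sample(x, ...) on a length-1 numeric would
  # misinterpret x as 1:x
  .with_seed(seed, {
    a <- d_visible_in_mouse[sample.int(length(d_visible_in_mouse),
                                       n_samples, replace = TRUE)]
    b <- d_visible_in_human[sample.int(length(d_visible_in_human),
                                       n_samples, replace = TRUE)]
    a + b
  })
}

#' Summarize a barnyard analysis
#'
#' Convenience wrapper: profiles, visible distributions and quantiles of
#' the total-foreign distribution.
#'
#' @param counts Counts matrix.
#' @param gene_organisms See [barnyard_profile()].
#' @param min_total Inclusion threshold.
#' @param n_samples Draws for the total distribution.
#' @param seed RNG seed.
#' @return List with `profiles`, `visible`, `total` (draws) and
#'   `summary` (means and quantiles).
#' @export
barnyard_summary <- function(counts, gene_organisms, min_total = 200L,
                             n_samples = 1e5, seed = 1L) {
  prof <- barnyard_profile(counts, gene_organisms, min_total = min_total)
  vis <- foreign_distributions(prof)
  tot <- total_foreign_distribution(vis, n_samples = n_samples, seed = seed)
  list(profiles = prof, visible = vis, total = tot,
       summary = list(mean_human_in_mouse = mean(vis$human_in_mouse),
                      mean_mouse_in_human = mean(vis$mouse_in_human),
                      mean_total_foreign = mean(tot),
                      total_quantiles = stats::quantile(tot,
                        c(0.05, 0.25, 0.5, 0.75, 0.95))))
}
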