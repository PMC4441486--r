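# Synthetic transcriptome.
#
# Genome alignment is out of scope for the simulator: each gene instead
# carries a unique 25-nt tag (minimum pairwise Hamming distance 2, built by
# the same greedy packer as the barcode library) so that read-2 assignment
# is an exact lookup and the downstream computations are isolated from
# aligner behavior.

#' Generate a synthetic transcriptome
#'
#' Genes get an organism label, a unique 25-nt tag and per-population
#' expression weights.  Base weights are log-normal per organism; a
#' `marker_fraction` of each organism's genes are population markers with
#' heterogeneous effect sizes: marker `g` draws a log-fold-change
#' `e_g = divergence * Exp(1)` and its weight is multiplied by
#' `exp(e_g / 2)` in its favored population and `exp(-e_g / 2)` in the
#' other populations of the same organism (differential expression in
#' real data spans a spectrum of effect sizes, not one fixed fold).
#' Thus `divergence = 0` makes same-organism profiles identical and the
#' mean absolute marker log-fold-change equals `divergence` in
#' expectation.  Populations of different organisms (barnyard designs)
#' express disjoint gene sets.
#'
#' @param n_genes Number of genes (>= 2), split evenly across organisms.
#' @param n_populations Number of cell populations.
#' @param divergence Marker log-fold-change scale between populations that
#'   share an organism (dimensionless, >= 0).
#' @param marker_fraction Fraction of each organism's genes made markers.
#' @param population_organisms Character vector (length `n_populations`)
#'   assigning each population to an organism, e.g. `c("mouse", "mouse")`
#'   for two murine populations or `c("mouse", "human")` for a barnyard
#'   mix.
#' @param tag_length Gene tag length in nucleotides.
#' @param seed RNG seed; the result is a pure function of the arguments.
#' @return An object of class `transcriptome`: list with `genes`
#'   (data.frame: gene_id, organism, tag), `profiles` (genes x populations
#'   weight matrix, columns normalized to sum 1), `markers` (data.frame:
#'   gene_id, favored population), and the generating parameters.
#' @examples
#' tx <- make_transcriptome(60, divergence = 1, seed = 1)
#' colSums(tx$profiles)
#' @export
make_transcriptome <- function(n_genes, n_populations = 2L, divergence = 1,
                               marker_fraction = 0.2,
                               population_organisms = rep("mouse", n_populations),
                               tag_length = 25L, seed = 1L) {
  .assert_scalar_number(n_genes, "n_genes", lower = 2)
  .assert_scalar_number(divergence, "divergence", lower = 0)
  stopifnot(length(population_organisms) == n_populations)
  n_genes <- as.integer(n_genes)
  organisms <- unique(population_organisms)
  seeds <- .subseeds(seed, 3L)

  gene_org <- rep(organisms, each = ceiling(n_genes / length(organisms)),
                  length.out = n_genes)
  gene_id <- sprintf("g%05d", seq_len(n_genes))

  tag_rules <- barcode_rules(length = tag_length, min_pairwise_distance = 2L,
                             forbid_terminal = character(0),
                             min_distinct_nucleotides = 1L,
                             max_homopolymer_run = tag_length,
                             at_count_range = c(0L, tag_length))
  tags <- build_library(tag_rules, target_size = n_genes, seed = seeds[1L],
                        order = "seeded_shuffle")
  if (!tags$complete) stop("gene tag generation exhausted", call. = FALSE)

  pop_names <- sprintf("pop%d", seq_len(n_populations))
  profiles <- matrix(0, n_genes, n_populations,
                     dimnames = list(gene_id, pop_names))

  base_w <- .with_seed(seeds[2L], stats::rlnorm(n_genes, meanlog = 0, sdlog = 1))
  marker_draw <- .with_seed(seeds[3L], stats::runif(n_genes))
  # unit-mean effect sizes, scaled by `divergence`; drawn for all genes so
  # the marker set and effects are stable across divergence values
  effect_draw <- .with_seed(seeds[3L] + 1L, stats::rexp(n_genes))
  markers <- data.frame(gene_id = character(0), favored = character(0),
                        lfc = numeric(0))

  for (org in organisms) {
    idx <- which(gene_org == org)
    pops <- which(population_organisms == org)
    for (p in pops) profiles[idx, p] <- base_w[idx]
    if (length(pops) >= 2L && divergence > 0 && marker_fraction > 0) {
      n_mark <- floor(marker_fraction * length(idx))
      if (n_mark > 0L) {
        mark <- idx[order(marker_draw[idx])[seq_len(n_mark)]]
        favored <- rep(pops, length.out = n_mark)  # cycle markers over pops
        lfc <- divergence * effect_draw[mark]
        for (i in seq_len(n_mark)) {
          g <- mark[i]
          for (p in pops) {
            profiles[g, p] <- profiles[g, p] *
              exp(if (p == favored[i]) lfc[i] / 2 else -lfc[i] / 2)
          }
        }
        markers <- rbind(markers,
                         data.frame(gene_id = gene_id[mark],
                                    favored = pop_names[favored],
                                    lfc = lfc))
      }
    }
  }
  profiles <- sweep(profiles, 2L, colSums(profiles), "/")

  structure(list(genes = data.frame(gene_id = gene_id, organism = gene_org,
                                    tag = tags$sequences,
                                    stringsAsFactors = FALSE),
                 profiles = profiles,
                 markers = markers,
                 population_organisms = stats::setNames(population_organisms,
                                                        pop_names),
                 divergence = divergence,
                 marker_fraction = marker_fraction,
                 seed = as.integer(seed)),
            class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d genes (%s), %d populations, divergence %.3g\n",
              nrow(x$genes), paste(unique(x$genes$organism), collapse = "/"),
              ncol(x$profiles), x$divergence))
  invisible(x)
}

# Mix-weighted aggregate expression profile over populations.
.aggregate_profile <- function(tx, mix = NULL) {
  if (is.null(mix)) mix <- rep(1 / ncol(tx$profiles), ncol(tx$profiles))
  as.numeric(tx$profiles %*% (mix / sum(mix)))
}

#' Write a transcriptome to disk
#'
#' Emits `tags.fasta` (gene tags, ids = gene ids) and `genes.tsv`
#' (gene_id, organism, tag, one weight column per population).
#'
#' @param tx A `transcriptome`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_transcriptome <- function(tx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_fasta(tx$genes$tag, file.path(dir, "tags.fasta"), ids = tx$genes$gene_id)
  tab <- cbind(tx$genes, as.data.frame(tx$profiles))
  utils::write.table(tab, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a transcriptome written by [write_transcriptome()]
#'
#' @param dir Directory containing `genes.tsv`.
#' @return A `transcriptome` (markers and generating parameters are not
#'   recoverable from disk and are left empty).
#' @export
read_transcriptome <- function(dir) {
  tab <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  pop_cols <- setdiff(names(tab), c("gene_id", "organism", "tag"))
  profiles <- as.matrix(tab[, pop_cols, drop = FALSE])
  rownames(profiles) <- tab$gene_id
  structure(list(genes = tab[, c("gene_id", "organism", "tag")],
                 profiles = profiles,
                 markers = data.frame(gene_id = character(0),
                                      favored = character(0)),
                 population_organisms = NULL,
                 divergence = NA_real_, marker_fraction = NA_real_,
                 seed = NA_integer_),
            class = "transcriptome")
}
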