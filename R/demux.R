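# Demultiplexing: paired reads -> unique-transcript counts matrix R_ij
# (rows i = cell barcodes, columns j = genes).

# Map from every 1-mismatch neighbor of `seqs` to the index of its source
# sequence.  Neighbors reachable from two different sequences (possible
# when the library's pairwise distance is exactly 2) map to -1 =
# "ambiguous"; neighbors identical to a library member are dropped (exact
# match takes priority).
.mismatch1_map <- function(seqs) {
  L <- nchar(seqs[1L])
  n <- length(seqs)
  variants <- character(n * L * 3L)
  source <- integer(n * L * 3L)
  k <- 0L
  for (p in seq_len(L)) {
    orig <- substr(seqs, p, p)
    for (nt in .NUCS) {
      keep <- which(orig != nt)
      v <- seqs[keep]
      substr(v, p, p) <- nt
      variants[k + seq_along(keep)] <- v
      source[k + seq_along(keep)] <- keep
      k <- k + length(keep)
    }
  }
  variants <- variants[seq_len(k)]
  source <- source[seq_len(k)]
  drop <- variants %in% seqs
  variants <- variants[!drop]; source <- source[!drop]
  dup <- variants[duplicated(variants)]
  if (length(dup) > 0L) {
    source[variants %in% dup] <- -1L
  }
  first <- !duplicated(variants)
  stats::setNames(source[first], variants[first])
}

#' Match reads to library barcodes
#'
#' Exact matches win; with `max_mismatch = 1` a read matching exactly one
#' barcode at Hamming distance 1 is rescued, while reads at distance 1
#' from two or more barcodes (possible since the library only guarantees
#' pairwise distance >= 2) are left unassigned.  Reads shorter than the
#' barcode length are unassigned with their own reason.
#'
#' @param reads Character vector of read-1 sequences (their first
#'   `rules$length` bases are used).
#' @param library A `barcode_library`.
#' @param max_mismatch 0 or 1.
#' @return Integer vector of library indices (NA = unassigned) with an
#'   attribute `"reason"`: factor with levels `exact`, `corrected`,
#'   `ambiguous`, `no_match`, `too_short`.
#' @export
match_barcode <- function(reads, library, max_mismatch = 1L) {
  stopifnot(inherits(library, "barcode_library"), max_mismatch %in% c(0L, 1L))
  L <- library$rules$length
  reason <- factor(rep("no_match", length(reads)),
                   levels = c("exact", "corrected", "ambiguous",
                              "no_match", "too_short"))
  idx <- rep(NA_integer_, length(reads))
  short <- nchar(reads) < L
  reason[short] <- "too_short"
  q <- substr(reads[!short], 1L, L)
  hit <- match(q, library$sequences)
  sub_idx <- hit
  sub_reason <- ifelse(is.na(hit), "no_match", "exact")
  if (max_mismatch >= 1L && anyNA(hit)) {
    map <- .mismatch1_map(library$sequences)
    miss <- which(is.na(hit))
    m <- map[q[miss]]
    found <- !is.na(m) & m > 0L
    ambig <- !is.na(m) & m == -1L
    sub_idx[miss[found]] <- m[found]
    sub_reason[miss[found]] <- "corrected"
    sub_reason[miss[ambig]] <- "ambiguous"
  }
  idx[!short] <- sub_idx
  reason[!short] <- sub_reason
  attr(idx, "reason") <- reason
  idx
}

#' Assign reads to genes by tag lookup
#'
#' Exact 25-mer (tag-length) lookup against the synthetic transcriptome's
#' gene tags, with optional 1-mismatch rescue (ambiguous rescues are left
#' unassigned).
#'
#' @param reads Character vector of read-2 sequences (their first
#'   tag-length bases are used).
#' @param transcriptome A `transcriptome`.
#' @param max_mismatch 0 or 1.
#' @return Integer vector of gene indices (NA = unassigned) with a
#'   `"reason"` attribute as in [match_barcode()].
#' @export
assign_gene <- function(reads, transcriptome, max_mismatch = 0L) {
  stopifnot(inherits(transcriptome, "transcriptome"), max_mismatch %in% c(0L, 1L))
  lib <- structure(list(sequences = transcriptome$genes$tag,
                        rules = list(length = nchar(transcriptome$genes$tag[1L]))),
                   class = "barcode_library")
  match_barcode(reads, lib, max_mismatch = max_mismatch)
}

#' Build the counts matrix from paired reads
#'
#' Identifies the cell barcode on read 1 and the gene tag on read 2,
#' collapses duplicate reads (identical barcode/gene/read-2 sequence
#' triples -- read 2 carries the molecule-distinguishing suffix when the
#' simulator wrote one) and tabulates unique transcripts per (barcode,
#' gene).  Unassigned reads are counted by reason, never silently
#' dropped.  Rows are all observed barcodes; cell calling happens
#' downstream.
#'
#' @param r1,r2 Character vectors of paired read sequences (equal length),
#'   or paths to FASTQ files.
#' @param library A `barcode_library`.
#' @param transcriptome A `transcriptome`.
#' @param max_mismatch Barcode mismatch tolerance (0 or 1).
#' @param gene_max_mismatch Gene-tag mismatch tolerance (0 or 1).
#' @return An object of class `counts_matrix`: list with `counts`
#'   (integer matrix, barcodes x genes) and `meta` (totals of reads seen /
#'   barcode-assigned / gene-assigned / post-dedup and per-reason
#'   unassigned counts).
#' @export
build_matrix <- function(r1, r2, library, transcriptome,
                         max_mismatch = 1L, gene_max_mismatch = 0L) {
  if (length(r1) == 1L && file.exists(r1)) r1 <- read_fastq(r1)
  if (length(r2) == 1L && file.exists(r2)) r2 <- read_fastq(r2)
  if (length(r1) != length(r2)) {
    stop("read-1 and read-2 streams have different lengths", call. = FALSE)
  }
  r1 <- unname(as.character(r1)); r2 <- unname(as.character(r2))
  bc <- match_barcode(r1, library, max_mismatch = max_mismatch)
  gn <- assign_gene(r2, transcriptome, max_mismatch = gene_max_mismatch)
  bc_reason <- attr(bc, "reason")
  gn_reason <- attr(gn, "reason")

  assigned <- !is.na(bc) & !is.na(gn)
  key <- paste(bc[assigned], gn[assigned], r2[assigned], sep = "\r")
  uniq <- !duplicated(key)
  ub <- bc[assigned][uniq]
  ug <- gn[assigned][uniq]

  obs_bc <- sort(unique(ub))
  gene_ids <- transcriptome$genes$gene_id
  counts <- as.matrix(Matrix::sparseMatrix(i = match(ub, obs_bc), j = ug,
                                           x = 1L,
                                           dims = c(length(obs_bc),
                                                    length(gene_ids))))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(library$sequences[obs_bc], gene_ids)

  meta <- list(reads_total = length(r1),
               barcode_assigned = sum(!is.na(bc)),
               gene_assigned = sum(assigned),
               post_dedup = sum(uniq),
               barcode_unassigned_by_reason =
                 c(table(bc_reason[is.na(bc)])),
               gene_unassigned_by_reason =
                 c(table(gn_reason[is.na(gn)])))
  structure(list(counts = counts, meta = meta), class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf(paste0("counts_matrix: %d barcodes x %d genes; reads %d -> ",
                     "barcode-assigned %d -> gene-assigned %d -> unique %d\n"),
              nrow(x$counts), ncol(x$counts), x$meta$reads_total,
              x$meta$barcode_assigned, x$meta$gene_assigned,
              x$meta$post_dedup))
  invisible(x)
}

#' @export
as.matrix.counts_matrix <- function(x, ...) x$counts

# Accept a counts_matrix, matrix, or per-barcode vector and return the
# per-barcode total unique-transcript counts.
.barcode_totals <- function(x) {
  if (inherits(x, "counts_matrix")) x <- x$counts
  if (is.matrix(x)) rowSums(x) else x
}

#' Chi-square test of equal barcode representation
#'
#' Pearson goodness-of-fit of per-barcode totals against the uniform
#' expectation over observed barcodes, quantifying whether barcodes are
#' equally represented in the sample (a mixing-quality check).
#'
#' @param x A `counts_matrix`, a barcodes x genes matrix, or a vector of
#'   per-barcode totals.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
barcode_uniformity <- function(x) {
  totals <- .barcode_totals(x)
  if (length(totals) < 2L) {
    stop("need at least 2 barcodes for a uniformity test", call. = FALSE)
  }
  ht <- stats::chisq.test(totals)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Write a counts matrix as TSV
#'
#' Barcodes x genes table with barcode sequences in the first column.
#'
#' @param x A `counts_matrix` or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  m <- if (inherits(x, "counts_matrix")) x$counts else x
  tab <- data.frame(barcode = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts matrix written by [write_counts_tsv()]
#'
#' @param path Input path.
#' @return Integer matrix (barcodes x genes).
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1L]]
  m
}

#' Write a counts matrix as MatrixMarket triplets
#'
#' Emits `matrix.mtx` plus `barcodes.txt` and `genes.txt` name sidecars
#' in `dir`.
#'
#' @param x A `counts_matrix` or matrix.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  m <- if (inherits(x, "counts_matrix")) x$counts else x
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "barcodes.txt"))
  writeLines(colnames(m), file.path(dir, "genes.txt"))
  invisible(dir)
}

#' Read a counts matrix written by [write_counts_mtx()]
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.txt`,
#'   `genes.txt`.
#' @return Integer matrix (barcodes x genes).
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  rownames(m) <- readLines(file.path(dir, "barcodes.txt"))
  colnames(m) <- readLines(file.path(dir, "genes.txt"))
  m
}
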