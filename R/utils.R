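# Internal helpers shared across modules: nucleotide encoding, seeded
# evaluation, derived sub-seeds and FASTQ/FASTA round-trips.

.NUCS <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL means "use the current stream".
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# k reproducible 31-bit sub-seeds derived from one master seed.  Every
# stochastic stage of a pipeline gets its own stream so that adding a stage
# does not shift the draws of the others.
.subseeds <- function(seed, k) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

.assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf("'%s' must be %s %s", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  }
  invisible(x)
}

# Character sequences -> integer matrix (rows = sequences, values 1..4 for
# A,C,G,T).  Errors name the first offending position, as rule validation
# reports positions to the user.
.seq_to_int <- function(x, width = NULL) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)
  n <- lengths(chars)
  if (!is.null(width) && any(n != width)) {
    bad <- which(n != width)[1L]
    stop(sprintf("sequence %d has length %d, expected %d", bad, n[bad], width),
         call. = FALSE)
  }
  if (length(unique(n)) > 1L) {
    stop("sequences must all have the same length", call. = FALSE)
  }
  m <- matrix(match(unlist(chars), .NUCS), nrow = length(x), byrow = TRUE)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-ACGT character at position %d of sequence %d",
                 idx[["col"]], idx[["row"]]), call. = FALSE)
  }
  m
}

.int_to_seq <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  apply(m, 1L, function(r) paste(.NUCS[r], collapse = ""))
}

.random_dna <- function(n, width) {
  m <- matrix(sample.int(4L, n * width, replace = TRUE), nrow = n)
  .int_to_seq(m)
}

# Apply substitution errors at per-base rate `rate` to a character vector of
# equal-length sequences; each error replaces the base with one of the three
# other nucleotides.
.mutate_seqs <- function(seqs, rate, width) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  total <- length(seqs) * width
  n_mut <- stats::rbinom(1L, total, rate)
  if (n_mut == 0L) return(seqs)
  slots <- sample.int(total, n_mut)
  read_idx <- ((slots - 1L) %/% width) + 1L
  pos_idx <- ((slots - 1L) %% width) + 1L
  for (i in seq_len(n_mut)) {
    r <- read_idx[i]; p <- pos_idx[i]
    old <- substr(seqs[r], p, p)
    substr(seqs[r], p, p) <- sample(setdiff(.NUCS, old), 1L)
  }
  seqs
}

#' Read sequences from a FASTQ file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' character sequences named by read id.
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

# Write sequences as FASTQ with a constant quality string.
.write_fastq <- function(seqs, path, ids = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(seqs))
  names(x) <- ids
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read a FASTA file as a character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

.write_fasta <- function(seqs, path, ids = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(ids)) ids <- sprintf("seq%05d", seq_along(seqs))
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}
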