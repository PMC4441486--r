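# Barcode library design.
#
# Each cell label is a short DNA barcode embedded in a 48-nt single-stranded
# oligo: a priming region, the barcode proper (the N positions), a poly-T
# stretch that hybridizes to mRNA poly-A tails, and one anchor nucleotide
# (V, never T).  Libraries are built greedily under five composition rules
# plus a minimum pairwise Hamming distance, so that sequencing errors rarely
# convert one barcode into another.

# The priming region as printed in the oligo layout.  Note the printed
# string is 21 nt even though the layout describes a 19-bp priming region;
# the default template uses its first 19 nt so the assembled oligo is the
# documented 48 nt, and keeps the full string for reference.
.PRINTED_PRIMING_REGION <- "AGACGTGTGCTCTTCCGATCT"

#' Barcode composition rules
#'
#' Bundles the five single-sequence / library-level design rules for cell
#' barcodes: a fixed length, a minimum pairwise Hamming distance across the
#' library, a forbidden terminal nucleotide set, a minimum number of
#' distinct nucleotides, a maximum homopolymer run, and an allowed range for
#' the A+T count.
#'
#' @param length Barcode length in nucleotides.
#' @param min_pairwise_distance Minimum Hamming distance between any two
#'   library members.
#' @param forbid_terminal Nucleotides the barcode must not end with
#'   (character vector; may be empty).
#' @param min_distinct_nucleotides Minimum number of distinct nucleotides
#'   each barcode must contain.
#' @param max_homopolymer_run Longest allowed run of identical consecutive
#'   nucleotides.
#' @param at_count_range Inclusive `[lo, hi]` bounds on the total number of
#'   A and T nucleotides per barcode.
#' @return An object of class `barcode_rules`.
#' @examples
#' barcode_rules()            # the 10-mer defaults
#' barcode_rules(length = 6)  # reduced length for exhaustive checks
#' @export
barcode_rules <- function(length = 10L,
                          min_pairwise_distance = 2L,
                          forbid_terminal = "T",
                          min_distinct_nucleotides = 3L,
                          max_homopolymer_run = 3L,
                          at_count_range = c(2L, 6L)) {
  length <- as.integer(length)
  .assert_scalar_number(length, "length", lower = 1)
  .assert_scalar_number(min_pairwise_distance, "min_pairwise_distance", lower = 1)
  stopifnot(all(forbid_terminal %in% .NUCS))
  if (length(at_count_range) != 2L || at_count_range[1] > at_count_range[2] ||
      at_count_range[1] < 0 || at_count_range[2] > length) {
    stop("'at_count_range' must be an interval within [0, length]", call. = FALSE)
  }
  structure(list(length = length,
                 min_pairwise_distance = as.integer(min_pairwise_distance),
                 forbid_terminal = as.character(forbid_terminal),
                 min_distinct_nucleotides = as.integer(min_distinct_nucleotides),
                 max_homopolymer_run = as.integer(max_homopolymer_run),
                 at_count_range = as.integer(at_count_range)),
            class = "barcode_rules")
}

# Vectorized single-sequence rule checks on an integer-encoded matrix
# (rows = candidate barcodes).  Returns a logical matrix, TRUE = violated.
.rule_violations <- function(m, rules) {
  L <- ncol(m)
  n <- nrow(m)
  viol <- matrix(FALSE, n, 4L,
                 dimnames = list(NULL, c("terminal_nucleotide",
                                         "distinct_nucleotides",
                                         "homopolymer_run",
                                         "at_count")))
  if (length(rules$forbid_terminal) > 0L) {
    forb <- match(rules$forbid_terminal, .NUCS)
    viol[, "terminal_nucleotide"] <- m[, L] %in% forb
  }
  distinct <- Reduce(`+`, lapply(1:4, function(v) as.integer(rowSums(m == v) > 0L)))
  viol[, "distinct_nucleotides"] <- distinct < rules$min_distinct_nucleotides
  run <- rules$max_homopolymer_run
  if (run < L) {
    same <- m[, -1L, drop = FALSE] == m[, -L, drop = FALSE]
    # a run of (run + 1) identical bases = `run` consecutive TRUEs in `same`
    w <- ncol(same) - run + 1L
    hit <- rep(FALSE, n)
    for (s in seq_len(w)) {
      window <- same[, s:(s + run - 1L), drop = FALSE]
      hit <- hit | (rowSums(window) == run)
    }
    viol[, "homopolymer_run"] <- hit
  }
  at <- rowSums(m == 1L) + rowSums(m == 4L)
  viol[, "at_count"] <- at < rules$at_count_range[1] | at > rules$at_count_range[2]
  viol
}

#' Validate a single barcode against the composition rules
#'
#' Checks the four single-sequence rules (terminal nucleotide, distinct
#' nucleotide count, homopolymer run, A+T count).  The pairwise-distance
#' rule is a library-level property and is checked by
#' [validate_library()] instead.
#'
#' @param seq A single barcode sequence (A/C/G/T).
#' @param rules A [barcode_rules()] object.
#' @return A list with elements `pass` (logical) and `violations`
#'   (character vector of violated rule names, empty when `pass`).
#' @examples
#' validate_barcode("AGGCTAGCAC")            # passes all rules
#' validate_barcode("ACGCACGCGT")$violations # ends with T
#' @export
validate_barcode <- function(seq, rules = barcode_rules()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  m <- .seq_to_int(seq, width = rules$length)
  v <- .rule_violations(m, rules)[1L, ]
  list(pass = !any(v), violations = names(v)[v])
}

#' Hamming distance between equal-length sequences
#'
#' Number of positions at which two aligned sequences differ.  Vectorized
#' over pairs with the usual recycling of a length-1 argument.
#'
#' @param a,b Character vectors of sequences.
#' @return Integer vector of distances.
#' @examples
#' hamming_distance("ACGT", "ACGA")  # 1
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (any(nchar(a) != nchar(b))) {
    stop("sequences must have equal lengths", call. = FALSE)
  }
  ca <- strsplit(a, "", fixed = TRUE)
  cb <- strsplit(b, "", fixed = TRUE)
  as.integer(mapply(function(x, y) sum(x != y), ca, cb))
}

#' Build a barcode library by greedy first-fit packing
#'
#' Scans candidate sequences of the configured length in the requested
#' order and accepts a candidate iff it passes all single-sequence rules
#' and lies at Hamming distance at least `rules$min_pairwise_distance`
#' from every barcode accepted so far.  `order = "lexicographic"` scans
#' A...A to T...T deterministically; `order = "seeded_shuffle"` scans a
#' seeded random permutation of the candidate space (or, when the space is
#' too large to enumerate, a seeded stream of random candidates).
#'
#' @param rules A [barcode_rules()] object.
#' @param target_size Number of barcodes requested.
#' @param seed Integer seed (used by `"seeded_shuffle"`).
#' @param order Candidate scan order.
#' @param max_candidates Cap on the number of candidates scanned in the
#'   random-stream regime (ignored when the space is enumerable).
#' @return An object of class `barcode_library`: list with `sequences`,
#'   `rules`, `seed`, `order`, `complete` (FALSE when the candidate space
#'   was exhausted before `target_size` acceptances) and `n_scanned`.
#' @examples
#' lib <- build_library(target_size = 24, seed = 7, order = "seeded_shuffle")
#' length(lib$sequences)
#' @export
build_library <- function(rules = barcode_rules(), target_size, seed = 1L,
                          order = c("lexicographic", "seeded_shuffle"),
                          max_candidates = NULL) {
  order <- match.arg(order)
  target_size <- as.integer(target_size)
  .assert_scalar_number(target_size, "target_size", lower = 1)
  L <- rules$length
  total <- 4^L
  enumerable <- total <= 2^24
  if (is.null(max_candidates)) {
    max_candidates <- 10000 + 2000 * target_size
  }

  acc <- matrix(0L, nrow = target_size, ncol = L)
  k <- 0L
  scanned <- 0L
  chunk <- 8192L
  d_min <- rules$min_pairwise_distance

  take_chunk <- if (enumerable) {
    idx_order <- if (order == "lexicographic") NULL else
      .with_seed(seed, sample.int(total))
    pos <- 0L
    function() {
      if (pos >= total) return(NULL)
      hi <- min(pos + chunk, total)
      ii <- if (is.null(idx_order)) (pos + 1):hi else idx_order[(pos + 1):hi]
      pos <<- hi
      # index -> base-4 digits, big-endian so order 1.. maps to lexicographic
      ii <- ii - 1
      m <- matrix(0L, length(ii), L)
      for (p in seq_len(L)) {
        m[, p] <- as.integer((ii %/% 4^(L - p)) %% 4) + 1L
      }
      m
    }
  } else {
    if (order == "lexicographic") {
      stop("candidate space too large to enumerate; use order = 'seeded_shuffle'",
           call. = FALSE)
    }
    stream_i <- 0L
    function() {
      if (scanned >= max_candidates) return(NULL)
      stream_i <<- stream_i + 1L
      # deterministic per-chunk sub-seed, kept inside 31 bits
      chunk_seed <- (as.numeric(seed) * 48271 + stream_i) %% 2147483647
      .with_seed(as.integer(chunk_seed),
                 matrix(sample.int(4L, chunk * L, replace = TRUE), chunk, L))
    }
  }

  while (k < target_size) {
    m <- take_chunk()
    if (is.null(m)) break
    scanned <- scanned + nrow(m)
    ok <- !apply(.rule_violations(m, rules), 1L, any)
    m <- m[ok, , drop = FALSE]
    for (i in seq_len(nrow(m))) {
      cand <- m[i, ]
      if (k > 0L) {
        d <- rowSums(acc[seq_len(k), , drop = FALSE] !=
                       matrix(cand, k, L, byrow = TRUE))
        if (min(d) < d_min) next
      }
      k <- k + 1L
      acc[k, ] <- cand
      if (k == target_size) break
    }
  }

  structure(list(sequences = .int_to_seq(acc[seq_len(k), , drop = FALSE]),
                 rules = rules,
                 seed = as.integer(seed),
                 order = order,
                 complete = k == target_size,
                 n_scanned = scanned),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("barcode_library: %d x %d-mers (order %s, seed %d, %s)\n",
              length(x$sequences), x$rules$length, x$order, x$seed,
              if (x$complete) "complete" else "INCOMPLETE"))
  invisible(x)
}

#' Validate a whole library
#'
#' Re-checks every member against the single-sequence rules and scans all
#' pairs for the minimum Hamming distance.
#'
#' @param library A `barcode_library` (or character vector of sequences,
#'   validated against `rules`).
#' @param rules Rules to use when `library` is a bare character vector.
#' @return List with `n_rule_violations`, `violating_sequences`,
#'   `min_pairwise_distance` (NA for libraries of size < 2) and `pass`.
#' @export
validate_library <- function(library, rules = barcode_rules()) {
  if (inherits(library, "barcode_library")) {
    seqs <- library$sequences
    rules <- library$rules
  } else {
    seqs <- as.character(library)
  }
  if (anyDuplicated(seqs)) {
    stop("library contains duplicated sequences", call. = FALSE)
  }
  m <- .seq_to_int(seqs, width = rules$length)
  viol <- .rule_violations(m, rules)
  bad <- rowSums(viol) > 0L
  dmin <- NA_integer_
  n <- nrow(m)
  if (n >= 2L) {
    dmin <- ncol(m)
    for (i in seq_len(n - 1L)) {
      d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                     matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
      dmin <- min(dmin, d)
      if (dmin < rules$min_pairwise_distance) break
    }
  }
  list(n_rule_violations = sum(bad),
       violating_sequences = seqs[bad],
       min_pairwise_distance = dmin,
       pass = !any(bad) &&
         (is.na(dmin) || dmin >= rules$min_pairwise_distance))
}

#' Oligo layout template
#'
#' Describes the 48-nt labeling oligo: priming region + barcode slot +
#' poly-T stretch + one anchor nucleotide V drawn from \{A, C, G\} (never T,
#' so the anchor sits on the last templated base of the poly-A tail).
#'
#' The priming region as printed in the layout is 21 nt although it is
#' described as 19 bp; the default stores the first 19 nt (so the
#' assembled oligo is the documented 48 nt) and keeps the printed 21-mer
#' in `priming_region_printed`.
#'
#' @param priming_region Priming-region sequence.
#' @param barcode_slot_length Length of the barcode (N) slot.
#' @param polyT_length Number of T's following the barcode.
#' @param anchor_alphabet Allowed anchor (V) nucleotides; must exclude T.
#' @return An object of class `oligo_template`.
#' @export
oligo_template <- function(priming_region = substr(.PRINTED_PRIMING_REGION, 1L, 19L),
                           barcode_slot_length = 10L,
                           polyT_length = 18L,
                           anchor_alphabet = c("A", "C", "G")) {
  stopifnot(!"T" %in% anchor_alphabet, all(anchor_alphabet %in% .NUCS))
  structure(list(priming_region = priming_region,
                 priming_region_printed = .PRINTED_PRIMING_REGION,
                 barcode_slot_length = as.integer(barcode_slot_length),
                 polyT_length = as.integer(polyT_length),
                 anchor_alphabet = as.character(anchor_alphabet),
                 assembled_length = nchar(priming_region) +
                   as.integer(barcode_slot_length) + as.integer(polyT_length) + 1L),
            class = "oligo_template")
}

#' Assemble full labeling oligos from barcodes
#'
#' Concatenates priming region, barcode, poly-T stretch and one anchor
#' nucleotide sampled per oligo from the template's anchor alphabet.
#'
#' @param barcode Character vector of barcode sequences.
#' @param template An [oligo_template()].
#' @param seed Seed for the anchor draws (NULL = current RNG stream).
#' @return Character vector of assembled oligos (48 nt with defaults).
#' @examples
#' nchar(assemble_oligo("ACGCATGCAG", seed = 1))  # 48
#' @export
assemble_oligo <- function(barcode, template = oligo_template(), seed = NULL) {
  m <- .seq_to_int(barcode, width = template$barcode_slot_length)  # validates
  anchors <- .with_seed(seed,
    sample(template$anchor_alphabet, length(barcode), replace = TRUE))
  paste0(template$priming_region, barcode,
         strrep("T", template$polyT_length), anchors)
}

#' Write a barcode library to FASTA or plain text
#'
#' FASTA records are named `BC0001`, `BC0002`, ...; plain text is one
#' barcode per line (the dialect of published barcode lists).
#'
#' @param library A `barcode_library` or character vector.
#' @param path Output path.
#' @param format `"fasta"` or `"txt"`.
#' @return `path`, invisibly.
#' @export
write_barcode_library <- function(library, path, format = c("fasta", "txt")) {
  format <- match.arg(format)
  seqs <- if (inherits(library, "barcode_library")) library$sequences else
    as.character(library)
  ids <- sprintf("BC%04d", seq_along(seqs))
  if (format == "fasta") {
    .write_fasta(seqs, path, ids = ids)
  } else {
    writeLines(seqs, path)
  }
  invisible(path)
}

#' Read a barcode library from FASTA or plain text
#'
#' @param path Input path.
#' @param rules Rules recorded on (and optionally enforced for) the
#'   returned library.
#' @param validate Stop if any sequence violates the single-sequence rules
#'   or the pairwise-distance floor.
#' @return A `barcode_library`.
#' @export
read_barcode_library <- function(path, rules = barcode_rules(), validate = TRUE) {
  first <- readLines(path, n = 1L)
  seqs <- if (startsWith(first, ">")) unname(read_fasta(path)) else {
    x <- trimws(readLines(path))
    x[nzchar(x)]
  }
  lib <- structure(list(sequences = toupper(seqs), rules = rules,
                        seed = NA_integer_, order = "file",
                        complete = TRUE, n_scanned = NA_integer_),
                   class = "barcode_library")
  if (validate) {
    rep <- validate_library(lib)
    if (!rep$pass) {
      stop(sprintf("library fails validation: %d rule violations, min distance %s",
                   rep$n_rule_violations, rep$min_pairwise_distance), call. = FALSE)
    }
  }
  lib
}
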