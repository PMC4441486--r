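# Shared fixtures and independent reference implementations ("oracles").
# The oracles deliberately use a different style (regex / plain loops /
# stats::cor) than the package internals they check.

# --- independent single-sequence rule checker (regex/strsplit based) -----
oracle_rule_check <- function(seq, rules) {
  ch <- strsplit(seq, "")[[1]]
  ok_terminal <- !(ch[length(ch)] %in% rules$forbid_terminal)
  ok_distinct <- length(unique(ch)) >= rules$min_distinct_nucleotides
  runs <- rle(ch)$lengths
  ok_run <- max(runs) <= rules$max_homopolymer_run
  at <- sum(ch %in% c("A", "T"))
  ok_at <- at >= rules$at_count_range[1] && at <= rules$at_count_range[2]
  ok_terminal && ok_distinct && ok_run && ok_at
}

# all 4^L sequences of length L, lexicographic
all_kmers <- function(L) {
  nt <- c("A", "C", "G", "T")
  do.call(paste0, rev(expand.grid(rep(list(nt), L), stringsAsFactors = FALSE)))
}

oracle_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# independent greedy packer over an explicit candidate vector
oracle_greedy_pack <- function(candidates, rules) {
  acc <- character(0)
  for (s in candidates) {
    if (!oracle_rule_check(s, rules)) next
    if (length(acc) > 0 &&
        any(vapply(acc, function(a) oracle_hamming(a, s), 0) <
            rules$min_pairwise_distance)) next
    acc <- c(acc, s)
  }
  acc
}

# --- reference leave-one-out correlation sweep (plain loops + cor) -------
oracle_loo_sweep <- function(X, assign) {
  n <- nrow(X)
  new_assign <- assign
  S <- list(colSums(X[assign == 1, , drop = FALSE]),
            colSums(X[assign == 2, , drop = FALSE]))
  for (i in seq_len(n)) {
    cors <- vapply(1:2, function(c) {
      M <- S[[c]]
      if (assign[i] == c) M <- M - X[i, ]
      if (stats::sd(M) == 0 || stats::sd(X[i, ]) == 0) return(-Inf)
      stats::cor(X[i, ], M)
    }, 0)
    other <- 3L - assign[i]
    if (cors[other] > cors[assign[i]]) new_assign[i] <- other
  }
  new_assign
}

# reference run of the full clustering loop (batch sweeps, ties stay,
# 4-iteration 1%-switch window, zero-switch fixed point)
oracle_corr_kmeans <- function(X, seed, max_iterations = 100,
                               tol = 0.01, window = 4) {
  n <- nrow(X)
  assign <- withr::with_seed(seed, sample(rep_len(1:2, n)))
  hist <- numeric(0)
  for (it in seq_len(max_iterations)) {
    new_assign <- oracle_loo_sweep(X, assign)
    hist <- c(hist, mean(new_assign != assign))
    assign <- new_assign
    if (hist[length(hist)] == 0) break
    if (length(hist) >= window && all(tail(hist, window) <= tol)) break
  }
  list(assignments = assign, history = hist)
}

# --- small shared fixtures (memoized per test run) ----------------------
.fixture_env <- new.env()

fixture_library <- function(n = 200, seed = 11) {
  key <- paste0("lib", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_library(target_size = n, seed = seed,
                                         order = "seeded_shuffle")
  }
  .fixture_env[[key]]
}

fixture_tx <- function(n_genes = 300, divergence = 0.5, seed = 12,
                       organisms = c("mouse", "mouse")) {
  key <- paste0("tx", n_genes, "_", divergence, "_", seed,
                paste(organisms, collapse = ""))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_transcriptome(
      n_genes, divergence = divergence,
      population_organisms = organisms, seed = seed)
  }
  .fixture_env[[key]]
}

# hand-built library object for constructed demux fixtures
manual_library <- function(seqs) {
  structure(list(sequences = seqs,
                 rules = barcode_rules(length = nchar(seqs[1])),
                 seed = NA_integer_, order = "manual", complete = TRUE,
                 n_scanned = NA_integer_),
            class = "barcode_library")
}
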