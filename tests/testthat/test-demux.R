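test_that("match_barcode: exact, 1-mismatch rescue, ambiguity, short reads", {
  # hand-built library: b1 and b2 at distance 2, so their midpoint read is
  # ambiguous at max_mismatch = 1
  lib <- manual_library(c("AAAACCCCGG",   # b1
                          "AAAACCCCTT",   # b2 (distance 2 from b1)
                          "GGGGTTTTAA"))  # b3 (far from both)
  expect_identical(unname(match_barcode("AAAACCCCGG", lib)[1]), 1L)

  # distance 1 from exactly b3
  hit <- match_barcode("GGGGTTTTAC", lib, max_mismatch = 1)
  expect_identical(unname(hit[1]), 3L)
  expect_identical(as.character(attr(hit, "reason")), "corrected")

  # midpoint between b1 and b2: distance 1 from both -> unassigned
  amb <- match_barcode("AAAACCCCGT", lib, max_mismatch = 1)
  expect_true(is.na(amb[1]))
  expect_identical(as.character(attr(amb, "reason")), "ambiguous")

  # with max_mismatch = 0 the correctable read is a plain miss
  m0 <- match_barcode("GGGGTTTTAC", lib, max_mismatch = 0)
  expect_true(is.na(m0[1]))
  expect_identical(as.character(attr(m0, "reason")), "no_match")

  # short read
  sh <- match_barcode("AAAA", lib)
  expect_true(is.na(sh[1]))
  expect_identical(as.character(attr(sh, "reason")), "too_short")
})

test_that("match_barcode corrected fraction tracks the binomial error model", {
  lib <- fixture_library(n = 150, seed = 11)
  set.seed(99)
  n_reads <- 20000
  truth <- sample.int(150, n_reads, replace = TRUE)
  reads <- lib$sequences[truth]
  # mutate each base independently with p = 0.1 (test-side implementation)
  mat <- do.call(rbind, strsplit(reads, ""))
  mut <- matrix(runif(length(mat)) < 0.1, nrow(mat))
  mat[mut] <- sapply(sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE),
                     identity)
  reads <- apply(mat, 1, paste, collapse = "")

  hit <- match_barcode(reads, lib, max_mismatch = 1)
  assigned <- mean(!is.na(hit))
  # random replacement keeps the original base 1/4 of the time: the
  # effective substitution rate is 0.075
  p <- 0.075
  expected <- (1 - p)^10 + 10 * p * (1 - p)^9
  expect_lt(abs(assigned - expected), 0.03)
  # assigned reads are overwhelmingly correct
  ok <- hit[!is.na(hit)] == truth[!is.na(hit)]
  expect_gt(mean(ok), 0.99)
})

test_that("assign_gene looks up tags exactly with optional rescue", {
  tx <- fixture_tx()
  tags <- tx$genes$tag
  expect_identical(unname(assign_gene(tags[5], tx)[1]), 5L)
  # random non-tag 25-mers are unassigned
  set.seed(7)
  rnd <- replicate(50, paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                             collapse = ""))
  rnd <- setdiff(rnd, tags)
  expect_true(all(is.na(assign_gene(rnd, tx))))
  # 1-mismatch rescue
  v <- tags[7]; substr(v, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                           substr(v, 3, 3))[1]
  expect_true(is.na(assign_gene(v, tx, max_mismatch = 0)[1]))
  expect_identical(unname(assign_gene(v, tx, max_mismatch = 1)[1]), 7L)
})

test_that("clean simulated run demultiplexes to the exact ground truth", {
  lib <- fixture_library()
  tx <- fixture_tx()
  cfg <- sim_config(n_cells = 30, seed = 9,
                    foreign_transcript_range = c(0, 0),
                    fusion_error_rates = c(two_cells_one_barcode = 0,
                                           two_barcodes_one_cell = 0),
                    duplicate_read_fraction = 0,
                    sequencing_error_rate = 0)
  run <- simulate_run(cfg, tx, lib)
  d <- withr::local_tempdir()
  rd <- write_reads(run, d)
  cm <- build_matrix(rd$r1, rd$r2, lib, tx)
  gt <- ground_truth_matrix(run)
  expect_identical(cm$counts[rownames(gt), colnames(gt)], gt)
  expect_identical(cm$meta$gene_assigned, cm$meta$reads_total)  # 100% assigned
})

test_that("duplicates collapse and never change the matrix", {
  lib <- fixture_library()
  tx <- fixture_tx()
  r1 <- rep(lib$sequences[3], 10)
  r2 <- rep(paste0(tx$genes$tag[8], "AAAAAAAAAAAA"), 10)
  cm <- build_matrix(r1, r2, lib, tx)
  expect_identical(unname(cm$counts[1, 8]), 1L)
  expect_identical(cm$meta$post_dedup, 1L)

  # appending more duplicates of existing reads leaves counts unchanged
  cm2 <- build_matrix(c(r1, r1), c(r2, r2), lib, tx)
  expect_identical(cm2$counts, cm$counts)
})

test_that("assignment counters satisfy the conservation chain", {
  lib <- fixture_library()
  tx <- fixture_tx()
  run <- simulate_run(sim_config(n_cells = 20, seed = 14), tx, lib)
  d <- withr::local_tempdir()
  rd <- write_reads(run, d)
  cm <- build_matrix(rd$r1, rd$r2, lib, tx)
  m <- cm$meta
  expect_lte(m$post_dedup, m$gene_assigned)
  expect_lte(m$gene_assigned, m$barcode_assigned)
  expect_lte(m$barcode_assigned, m$reads_total)
  expect_identical(sum(cm$counts), m$post_dedup)

  expect_error(build_matrix(c("A", "B"), "C", lib, tx), "different lengths")
})

test_that("barcode_uniformity behaves at the extremes and under the null", {
  expect_identical(barcode_uniformity(rep(50, 20))$statistic, 0)
  expect_lt(barcode_uniformity(c(1000, rep(0, 19)))$p_value, 1e-10)
  expect_error(barcode_uniformity(5), "at least 2")

  # p-values approximately uniform under a uniform simulation
  set.seed(123)
  pv <- replicate(500, {
    counts <- c(rmultinom(1, 2500, rep(1 / 40, 40)))
    barcode_uniformity(counts)$p_value
  })
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("counts matrices round-trip through TSV and MTX", {
  lib <- fixture_library()
  tx <- fixture_tx()
  run <- simulate_run(sim_config(n_cells = 10, seed = 2), tx, lib)
  gt <- ground_truth_matrix(run)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(gt, f)
  expect_identical(read_counts_tsv(f), gt)
  d <- withr::local_tempdir()
  write_counts_mtx(gt, d)
  expect_identical(read_counts_mtx(d), gt)
})
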