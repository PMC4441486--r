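no_error_cfg <- function(n_cells, seed, ...) {
  sim_config(n_cells = n_cells, seed = seed,
             fusion_error_rates = c(two_cells_one_barcode = 0,
                                    two_barcodes_one_cell = 0), ...)
}

test_that("number of fused events is ~ n_cells / lambda", {
  lib <- fixture_library()
  tx <- fixture_tx()
  for (s in c(1, 2, 3)) {
    run <- simulate_run(sim_config(n_cells = 100, seed = s,
                                   foreign_transcript_range = c(0, 0)),
                        tx, lib)
    # waiting-count sd for 100 Poisson(0.1) arrivals ~ sqrt(100)/0.1 = 100
    expect_lt(abs(nrow(run$events) - 1000), 300)
  }
})

test_that("per-unit transcript means recover the 340 / 39 parameters", {
  lib <- fixture_library()
  tx <- fixture_tx()
  run <- simulate_run(no_error_cfg(500, seed = 8), tx, lib)
  u <- drop_unit_counts(run)
  # single-cell units (exclude doublets, which are higher by construction)
  cells_per_unit <- table(paste(run$cells$event, run$cells$barcode))
  single <- names(cells_per_unit)[cells_per_unit == 1]
  x <- u$n_transcripts[u$cell_bearing &
                         paste(u$event, u$barcode) %in% single]
  expect_lt(abs(mean(x) - 340), 3 * sd(x) / sqrt(length(x)))
  y <- u$n_transcripts[!u$cell_bearing]
  expect_lt(abs(mean(y) - 39), 3 * sd(y) / sqrt(length(y)))
})

test_that("ground truth conservation: transcript records match matrix totals", {
  lib <- fixture_library()
  tx <- fixture_tx()
  run <- simulate_run(sim_config(n_cells = 50, seed = 13), tx, lib)
  gt <- ground_truth_matrix(run)
  per_bc <- table(run$library$sequences[run$transcripts$barcode])
  expect_equal(rowSums(gt)[names(per_bc)], c(per_bc)[names(per_bc)],
               ignore_attr = TRUE)
  expect_identical(sum(gt), nrow(run$transcripts))
})

test_that("the run is a pure function of the config seed", {
  lib <- fixture_library()
  tx <- fixture_tx()
  r1 <- simulate_run(sim_config(n_cells = 30, seed = 77), tx, lib)
  r2 <- simulate_run(sim_config(n_cells = 30, seed = 77), tx, lib)
  expect_identical(r1$transcripts, r2$transcripts)
  expect_identical(r1$events, r2$events)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_reads(r1, d1); f2 <- write_reads(r2, d2)
  expect_identical(readLines(f1$r1), readLines(f2$r1))
  expect_identical(readLines(f1$r2), readLines(f2$r2))
})

test_that("fusion-error events stay within the configured rates", {
  lib <- fixture_library()
  tx <- fixture_tx()
  run <- simulate_run(sim_config(n_cells = 200, seed = 30), tx, lib)
  frac_err <- mean(run$events$type != "normal")
  expect_lte(frac_err, 0.10)
})

test_that("write_reads controls the duplicate fraction", {
  lib <- fixture_library()
  tx <- fixture_tx()

  # duplicate fraction 0: exactly one read per molecule, and with zero
  # error rate every read 1 is a library barcode
  run0 <- simulate_run(no_error_cfg(20, seed = 41,
                                    duplicate_read_fraction = 0,
                                    sequencing_error_rate = 0,
                                    foreign_transcript_range = c(0, 0)),
                       tx, lib)
  d <- withr::local_tempdir()
  out0 <- write_reads(run0, d, basename = "dup0")
  expect_identical(out0$n_reads, nrow(run0$transcripts))
  r1 <- read_fastq(out0$r1)
  expect_true(all(r1 %in% lib$sequences))

  # duplicate fraction 0.9: ~10x reads per molecule
  run9 <- simulate_run(no_error_cfg(20, seed = 42), tx, lib)
  out9 <- write_reads(run9, d, basename = "dup9")
  n_mol <- nrow(run9$transcripts)
  # total reads = sum over molecules of 1 + Poisson(9): sd = sqrt(9 n)
  expect_lt(abs(out9$n_reads - 10 * n_mol), 3 * sqrt(9 * n_mol))
})

test_that("intermediate cells are generated and labeled", {
  tx <- fixture_tx(divergence = 1)
  cnt <- simulate_population_counts(c(40, 20), tx,
                                    intermediate_fraction = 0.5, seed = 3)
  expect_identical(dim(cnt), c(60L, 300L))
  expect_identical(table(attr(cnt, "population")),
                   table(rep(c("pop1", "pop2"), c(40, 20))))
  inter <- attr(cnt, "intermediate")
  expect_gt(sum(inter), 10)  # ~30 expected at fraction 0.5
  # intermediates correlate better with the opposite profile than pure
  # cells of their population do, on average
  p2 <- tx$profiles[, 2]
  pop1 <- attr(cnt, "population") == "pop1"
  c_pure <- mean(apply(cnt[pop1 & !inter, ], 1, cor, y = p2))
  c_int <- mean(apply(cnt[pop1 & inter, ], 1, cor, y = p2))
  expect_gt(c_int, c_pure)
})

test_that("write_run emits a complete text bundle", {
  lib <- fixture_library()
  tx <- fixture_tx()
  run <- simulate_run(sim_config(n_cells = 10, seed = 55), tx, lib)
  d <- withr::local_tempdir()
  write_run(run, d)
  expect_true(all(file.exists(file.path(d,
    c("run_R1.fastq", "run_R2.fastq", "ground_truth.tsv",
      "barcodes.txt", "config.json", "transcriptome/genes.tsv")))))
  gt <- read.table(file.path(d, "ground_truth.tsv"), header = TRUE, sep = "\t")
  expect_identical(nrow(gt), nrow(run$cells))
})
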