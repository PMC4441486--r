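barnyard_fixture <- function(seed, n_cells = 100) {
  # large library keeps barcode reuse across fused drops (which mixes
  # background and doublet signal into cell barcodes) modest
  lib <- fixture_library(n = 5000, seed = 17)
  tx <- fixture_tx(n_genes = 300, divergence = 0, seed = 18,
                   organisms = c("mouse", "human"))
  cfg <- sim_config(n_cells = n_cells, seed = seed,
                    population_mix = c(0.75, 0.25),
                    fusion_error_rates = c(two_cells_one_barcode = 0,
                                           two_barcodes_one_cell = 0))
  run <- simulate_run(cfg, tx, lib)
  list(run = run, tx = tx,
       counts = ground_truth_matrix(run),
       orgs = setNames(tx$genes$organism, tx$genes$gene_id))
}

test_that("assign_organism majority vote with tie exclusion", {
  expect_identical(assign_organism(300, 5), "mouse")
  expect_identical(assign_organism(5, 300), "human")
  expect_true(is.na(assign_organism(10, 10)))
  expect_true(is.na(assign_organism(0, 0)))
})

test_that("inclusion threshold and exclusion reasons are respected", {
  fx <- barnyard_fixture(seed = 51)
  prof <- barnyard_profile(fx$counts, fx$orgs, min_total = 200)
  expect_true(all(prof$total[prof$included] > 200))
  expect_true(all(prof$reason[prof$total <= 200] == "below_threshold"))
  # all organisms assigned among included barcodes
  expect_false(anyNA(prof$organism[prof$included]))
})

test_that("pure profiles give point-mass-zero foreign distributions", {
  m <- rbind(a = c(300, 0), b = c(0, 280), c = c(250, 0))
  colnames(m) <- c("gm", "gh")
  orgs <- c(gm = "mouse", gh = "human")
  fd <- foreign_distributions(barnyard_profile(m, orgs, min_total = 100))
  expect_true(all(fd$human_in_mouse == 0))
  expect_true(all(fd$mouse_in_human == 0))
  expect_false(fd$partial)

  # single organism present -> partial flag
  m2 <- m[c("a", "c"), ]
  fd2 <- foreign_distributions(barnyard_profile(m2, orgs, min_total = 100))
  expect_true(fd2$partial)
  expect_length(fd2$mouse_in_human, 0)
})

test_that("total_foreign_distribution convolves by sampling pairs", {
  # degenerate: point masses add exactly
  tot <- total_foreign_distribution(5, 11, n_samples = 100, seed = 1)
  expect_true(all(tot == 16))

  # means add within Monte-Carlo error
  set.seed(9)
  d1 <- rpois(400, 30); d2 <- rpois(400, 100)
  tot <- total_foreign_distribution(d1, d2, n_samples = 1e5, seed = 2)
  se <- sqrt((var(d1) + var(d2)) / 1e5)
  expect_lt(abs(mean(tot) - (mean(d1) + mean(d2))), 4 * se + 0.5)

  # deterministic under seed
  expect_identical(total_foreign_distribution(d1, d2, 1000, seed = 3),
                   total_foreign_distribution(d1, d2, 1000, seed = 3))
})

test_that("visible-foreign asymmetry tracks the 75/25 mix", {
  fx <- barnyard_fixture(seed = 52)
  fd <- foreign_distributions(barnyard_profile(fx$counts, fx$orgs))
  # human cells see mostly-mouse contamination (75% of the aggregate),
  # mouse cells see mostly-human-free contamination: strong asymmetry
  expect_gt(mean(fd$mouse_in_human), mean(fd$human_in_mouse))
})

test_that("estimated total foreign load recovers the injected truth", {
  est <- truth <- numeric(10)
  for (i in 1:10) {
    fx <- barnyard_fixture(seed = 300 + i)
    sm <- barnyard_summary(fx$counts, fx$orgs, seed = i)
    est[i] <- sm$summary$mean_total_foreign
    # true injected foreign transcripts per cell-bearing unit
    tx_tab <- fx$run$transcripts
    key <- paste(tx_tab$event, tx_tab$barcode)
    foreign_per_unit <- tapply(tx_tab$type == "foreign", key, sum)
    bearing <- tapply(tx_tab$type != "background", key, any)
    truth[i] <- mean(foreign_per_unit[bearing])
  }
  expect_lt(abs(mean(est) - mean(truth)) / mean(truth), 0.15)
})

test_that("zero injected crosstalk concentrates the estimate at zero", {
  lib <- fixture_library(n = 5000, seed = 17)
  tx <- fixture_tx(n_genes = 300, divergence = 0, seed = 18,
                   organisms = c("mouse", "human"))
  # ambient background off as well: any residual foreign signal can then
  # only come from rare mixed-organism barcode collisions
  cfg <- sim_config(n_cells = 40, seed = 71,
                    population_mix = c(0.75, 0.25),
                    foreign_transcript_range = c(0, 0),
                    mean_background_transcripts = 0,
                    fusion_error_rates = c(two_cells_one_barcode = 0,
                                           two_barcodes_one_cell = 0))
  run <- simulate_run(cfg, tx, lib)
  counts <- ground_truth_matrix(run)
  orgs <- setNames(tx$genes$organism, tx$genes$gene_id)
  sm <- barnyard_summary(counts, orgs, seed = 4)
  # the distribution concentrates at zero; residual mass can only come
  # from genuine mixed-organism doublets under one barcode (which the
  # barnyard estimator is designed to expose)
  expect_identical(median(sm$total), 0)
  expect_lt(mean(sm$total > 0), 0.05)
})
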