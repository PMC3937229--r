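test_that("simulation is deterministic for a fixed seed", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e7), n_genes = 200,
                    n_samples = 4, background_per_sample = 50,
                    drivers = cisSelect:::default_driver_table(c(chr1 = 5e7),
                                                               n_drivers = 3),
                    seed = 33)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$truth[, c("role", "driver_id", "clone_id")],
                   b$truth[, c("role", "driver_id", "clone_id")])
  c <- simulate_cohort(cfg, seed = 34)
  expect_false(identical(a$sites, c$sites))
})

test_that("degenerate driver parameters give fully penetrant forward insertions", {
  drv <- data.frame(driver_id = "d1", chrom = "chr1", locus = 2e7,
                    window = 5000, orientation_prob = 1, selection_prob = 1,
                    genotype = NA_character_)
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e7), n_genes = 100,
                    n_samples = 28, background_per_sample = 10,
                    drivers = drv, passenger_rate = 0, seed = 8)
  sim <- simulate_cohort(cfg)
  planted <- sim$sites[sim$truth$role == "driver", ]
  expect_equal(nrow(planted), 28)
  expect_true(all(planted$strand == "+"))
  expect_true(all(abs(planted$pos - 2e7) <= 5000))
  expect_equal(length(unique(planted$sample_id)), 28)
})

test_that("read supports separate expanded clones from background exactly", {
  sim <- simulate_cohort(default_screen_config(seed = 12))
  bg <- sim$truth$role == "background"
  expect_true(all(sim$sites$reads[bg] < 100))
  expect_true(all(sim$sites$reads[!bg] >= 100))
  fl <- flag_expanded(sim$sites, 100)
  keyed <- function(s) paste(s$chrom, s$pos, s$sample_id, s$reads)
  expect_setequal(keyed(fl$expanded), keyed(sim$sites[!bg, ]))
})

test_that("passengers share their clone's sample and read count", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e8), n_genes = 100,
                    n_samples = 10, background_per_sample = 20,
                    drivers = cisSelect:::default_driver_table(c(chr1 = 1e8),
                                                               n_drivers = 5),
                    passenger_rate = 2, seed = 5)
  sim <- simulate_cohort(cfg)
  pass <- which(sim$truth$role == "passenger")
  expect_gt(length(pass), 0)
  drv_rows <- which(sim$truth$role == "driver")
  clone_of <- setNames(drv_rows, sim$truth$clone_id[drv_rows])
  for (i in pass) {
    j <- clone_of[[sim$truth$clone_id[i]]]
    expect_equal(sim$sites$reads[i], sim$sites$reads[j])
    expect_equal(sim$sites$sample_id[i], sim$sites$sample_id[j])
  }
})

test_that("genotype-restricted drivers only appear in matching samples", {
  drv <- data.frame(driver_id = c("d1", "d2"), chrom = "chr1",
                    locus = c(2e7, 6e7), window = 5000,
                    orientation_prob = 0.5, selection_prob = 1,
                    genotype = c("MYC", NA))
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e8), n_genes = 100,
                    n_samples = 12, genotypes = rep(c("MYC", "WT"), each = 6),
                    background_per_sample = 10, drivers = drv, seed = 19)
  sim <- simulate_cohort(cfg)
  d1 <- sim$sites$genotype[sim$truth$driver_id %in% "d1"]
  expect_true(all(d1 == "MYC"))
  expect_equal(length(d1), 6)
  d2 <- sim$sites[sim$truth$driver_id %in% "d2", ]
  expect_equal(nrow(d2), 12)
  # and the planted restriction is detectable by the presence test
  res <- genotype_presence_test(sim$sites, list(chrom = "chr1", start = 2e7 - 5000,
                                                end = 2e7 + 5000), focal = "MYC")
  expect_lt(res$p, 0.01)
})

test_that("background positions are uniform when the TSS weight is zero", {
  ks_ps <- vapply(1:20, function(s) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 1e8), n_genes = 50,
                      n_samples = 4, background_per_sample = 250,
                      tss_weight = 0,
                      drivers = cisSelect:::default_driver_table(c(chr1 = 1e8),
                                                                 n_drivers = 1,
                                                                 selection_prob = 0),
                      seed = 1000 + s)
    sim <- simulate_cohort(cfg)
    stats::ks.test(sim$sites$pos / 1e8, "punif")$p.value
  }, 0)
  expect_gte(mean(ks_ps > 0.01), 0.95)
})

test_that("orientation fractions at drivers converge to the configured bias", {
  drv <- data.frame(driver_id = "d1", chrom = "chr1", locus = 5e7,
                    window = 5000, orientation_prob = 0.9,
                    selection_prob = 1, genotype = NA_character_)
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e8), n_genes = 50,
                    n_samples = 200, background_per_sample = 1,
                    drivers = drv, seed = 77)
  sim <- simulate_cohort(cfg)
  fwd <- mean(sim$sites$strand[sim$truth$role == "driver"] == "+")
  expect_lt(abs(fwd - 0.9), 3 * sqrt(0.9 * 0.1 / 200))
})

test_that("the default screen configuration matches the study conditions", {
  cfg <- default_screen_config(seed = 1)
  expect_equal(cfg$n_samples, 28)
  expect_equal(nrow(cfg$drivers), 50)
  expect_equal(mean(cfg$drivers$orientation_prob == 0.9), 0.6)
  expect_equal(mean(cfg$drivers$orientation_prob == 0.5), 0.4)
  # expected cohort size ~ 12,485 unique insertion sites
  n <- vapply(1:3, function(s) {
    nrow(simulate_cohort(default_screen_config(seed = s))$sites)
  }, 0)
  expect_lt(abs(mean(n) - 12485), 250)
})

test_that("recovery scoring is exact on perfect and empty call sets", {
  sim <- simulate_cohort(sim_config(
    chrom_lengths = c(chr1 = 1e8), n_genes = 100, n_samples = 8,
    background_per_sample = 20,
    drivers = cisSelect:::default_driver_table(c(chr1 = 1e8), n_drivers = 4,
                                               selection_prob = 1),
    seed = 3
  ))
  drv <- attr(sim$truth, "drivers")
  perfect <- data.frame(cis_id = sprintf("CIS%d", seq_len(nrow(drv))),
                        chrom = drv$chrom, start = drv$locus - drv$window,
                        end = drv$locus + drv$window)
  sc <- score_recovery(perfect, sim)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$false_cis_rate, 0)
  empty <- data.frame(cis_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0))
  expect_equal(score_recovery(empty, sim)$sensitivity, 0)
})
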