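test_that("orientation test uses the majority tail with ties at p = 1", {
  # tie between forward and reverse members
  s <- make_sites(1:20, strand = rep(c("+", "-"), 10))
  cis <- data.frame(cis_id = "c1")
  cis$members <- list(1:10)  # 5 forward, 5 reverse
  res <- orientation_test(cis, s)
  expect_equal(res$p, 1)
  expect_equal(res$bias, 0.5)
  expect_equal(res$fwd_in + res$rev_in, res$n_insertions)

  # 10 forward members against a balanced 5000/5000 background
  big <- rbind(make_sites(1:10, strand = "+"),
               make_sites(11:5010, strand = "+"),
               make_sites(6000 + 1:5000, strand = "-"))
  cis2 <- data.frame(cis_id = "c2")
  cis2$members <- list(1:10)
  res2 <- orientation_test(cis2, big)
  want <- oracle_fisher_one_tail(10, 0, 5000, 5000)
  expect_equal(res2$p, want, tolerance = 1e-9)
  expect_lt(abs(res2$p - 9.7e-4), 1e-4)
  expect_equal(res2$bias, 1)
})

test_that("one-tailed Fisher agrees with hypergeometric enumeration on random tables", {
  set.seed(123)
  for (rep in 1:400) {
    n_in <- sample(2:30, 1)
    fwd_in <- sample(0:n_in, 1)
    fwd_out <- sample(0:50, 1)
    rev_out <- sample(0:50, 1)
    strands <- c(rep("+", fwd_in), rep("-", n_in - fwd_in),
                 rep("+", fwd_out), rep("-", rev_out))
    s <- make_sites(seq_along(strands), strand = strands)
    cis <- data.frame(cis_id = "c")
    cis$members <- list(seq_len(n_in))
    got <- orientation_test(cis, s)$p
    maj_in <- max(fwd_in, n_in - fwd_in)
    min_in <- n_in - maj_in
    if (fwd_in >= n_in - fwd_in) {
      want <- oracle_fisher_one_tail(fwd_in, n_in - fwd_in, fwd_out, rev_out)
    } else {
      want <- oracle_fisher_one_tail(n_in - fwd_in, fwd_in, rev_out, fwd_out)
    }
    if (maj_in == min_in) want <- 1
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up formula and is order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(99)
  for (rep in 1:300) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
  }
})

test_that("biased CIS filter is strictly below the cutoff", {
  res <- data.frame(cis_id = c("a", "b", "c"), q = c(0.049999, 0.05, 0.2))
  expect_equal(biased_cis_set(res)$cis_id, "a")
  expect_equal(nrow(biased_cis_set(res[0, ])), 0)
})

test_that("TSS distances are signed in gene orientation with deterministic ties", {
  tss <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    tss_pos = c(10000, 50000), gene_strand = c("+", "-"))
  gm <- genome_model(c(chr1 = 1e6, chr2 = 1e6), tss = tss)
  s <- make_sites(c(10000, 49500, 10600, 30000, 500), chrom = c(rep("chr1", 4), "chr2"))
  prof <- tss_distance_profile(s, gm)
  d <- prof$distances
  expect_equal(d$distance[1], 0)              # exactly at a TSS
  expect_equal(d$distance[2], 500)            # 500 bp left of minus-strand TSS -> downstream
  expect_equal(d$distance[3], 600)            # plus strand, downstream
  expect_equal(d$gene_id[4], "gA")            # equidistant tie -> smaller gene id
  expect_false(d$defined[5])                  # no TSS on chr2
  expect_equal(sum(prof$hist$count), 4)
})

test_that("TSS-preference weight is recovered from simulated cohorts", {
  cfg <- sim_config(
    chrom_lengths = c(chr1 = 6e7, chr2 = 6e7, chr3 = 6e7),
    n_genes = 600, n_samples = 10, background_per_sample = 1000,
    tss_weight = 0.7, tss_decay = 3000,
    drivers = cisSelect:::default_driver_table(c(chr1 = 6e7), n_drivers = 1,
                                               selection_prob = 0),
    seed = 2024
  )
  sim <- simulate_cohort(cfg)
  est <- estimate_tss_weight(sim$sites, sim$genome, decay = 3000)
  expect_lt(abs(est$w_hat - 0.7), 0.05)
  # and a uniform cohort estimates ~0
  cfg0 <- sim_config(chrom_lengths = cfg$chrom_lengths, n_genes = 600,
                     n_samples = 10, background_per_sample = 1000,
                     tss_weight = 0, tss_decay = 3000,
                     drivers = cfg$drivers, seed = 2025)
  sim0 <- simulate_cohort(cfg0)
  est0 <- estimate_tss_weight(sim0$sites, sim0$genome, decay = 3000)
  expect_lt(est0$w_hat, 0.05)
})

test_that("CIS overlap uses >= 1 shared nucleotide and matches the all-pairs oracle", {
  a <- data.frame(cis_id = c("a1", "a2"), chrom = "chr1",
                  start = c(1, 100), end = c(10, 200))
  b <- data.frame(cis_id = c("b1", "b2"), chrom = "chr1",
                  start = c(11, 100), end = c(20, 200))
  ov <- cis_overlap(a, b)
  expect_equal(ov$pairs$b_id, "b2")  # abutting [1,10]/[11,20] share nothing
  expect_equal(ov$n_a_with_partner, 1)
  set.seed(55)
  for (rep in 1:120) {
    na <- sample(1:15, 1); nb <- sample(1:15, 1)
    mk <- function(n, pre) {
      st <- sample.int(5000, n)
      data.frame(cis_id = sprintf("%s%02d", pre, 1:n),
                 chrom = sample(c("c1", "c2"), n, TRUE),
                 start = st, end = st + sample(0:800, n, TRUE))
    }
    a <- mk(na, "a"); b <- mk(nb, "b")
    got <- cis_overlap(a, b)$pairs
    want <- oracle_overlap_pairs(a, b)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("bin enrichment reproduces the printed syntenic-region contingency", {
  res <- bin_enrichment(counts = list(cis_in_region = 43, cis_total = 771,
                                      region_bins = 2613, total_bins = 89796))
  expect_lt(res$p, 0.0001)
  # regions covering every bin give p = 1
  res1 <- bin_enrichment(counts = list(cis_in_region = 10, cis_total = 10,
                                       region_bins = 100, total_bins = 100))
  expect_equal(res1$p, 1)
})

test_that("bin enrichment from intervals equals hypergeometric enumeration on a toy genome", {
  gm <- toy_genome(c(chr1 = 300))
  regions <- data.frame(chrom = "chr1", start = c(1, 105), end = c(30, 130))
  cis <- data.frame(cis_id = c("c1", "c2", "c3"), chrom = "chr1",
                    start = c(5, 100, 250), end = c(20, 120, 260),
                    peak_pos = c(10, 110, 255))
  res <- bin_enrichment(cis, regions, gm, bin_size = 30)
  expect_equal(res$total_bins, 10)
  expect_equal(res$region_bins, 3)  # bins 1, 4, 5 intersect the regions
  expect_equal(res$cis_in_region, 2)
  want <- oracle_fisher_one_tail(2, 1, 1, 6)
  expect_equal(res$p, want, tolerance = 1e-9)
  expect_error(bin_enrichment(cis, data.frame(chrom = "chr1", start = 1, end = 400),
                              gm, 30), "outside genome")
})

test_that("genotype presence test builds the right contingency table", {
  samples <- data.frame(sample_id = sprintf("S%02d", 1:24),
                        genotype = rep(c("MYC", "WT"), each = 12))
  s <- make_sites(rep(1000, 10), sample_id = sprintf("S%02d", 1:10),
                  reads = 500, genotype = "MYC")
  s <- rbind(s, make_sites(2000, sample_id = "S13", reads = 500, genotype = "WT"))
  locus <- list(chrom = "chr1", start = 500, end = 1500)
  res <- genotype_presence_test(s, locus, focal = "MYC", samples = samples)
  want <- oracle_fisher_two_tail(10, 2, 0, 12)
  expect_equal(res$p, want, tolerance = 1e-9)
  # identical presence in both groups gives p = 1
  s2 <- make_sites(rep(1000, 4), sample_id = c("S01", "S02", "S13", "S14"),
                   reads = 500)
  res2 <- genotype_presence_test(s2, locus, focal = "MYC", samples = samples)
  expect_equal(res2$p, 1)
  expect_error(genotype_presence_test(s2, locus, focal = "nope",
                                      samples = samples), "genotype")
})

test_that("Mann-Whitney: exact enumeration for small n, approximation beyond", {
  expect_equal(mann_whitney_test(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(mann_whitney_test(c(2, 2, 2), c(2, 2, 2))$p, 1)
  set.seed(31)
  for (rep in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:10, n1, TRUE); y <- sample(1:10, n2, TRUE)
    expect_equal(mann_whitney_test(x, y)$p, oracle_mw_two_sided(x, y),
                 tolerance = 1e-12)
  }
  # tie-free exact path agrees with the reference implementation
  for (rep in 1:40) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- sample(seq(0.1, 99, by = 0.7), n1)
    y <- sample(seq(0.15, 99, by = 0.7), n2)
    expect_equal(mann_whitney_test(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  # large samples: normal approximation close to the reference
  set.seed(7)
  x <- rnorm(30); y <- rnorm(35, 0.4)
  got <- mann_whitney_test(x, y)
  expect_equal(got$method, "normal_tie_corrected")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(got$p - ref), 0.005)
})

test_that("genotype reads comparison uses per-tumour mean reads with zeros", {
  samples <- data.frame(sample_id = c("A", "B", "C", "D", "E", "F"),
                        genotype = rep(c("g1", "g2"), each = 3))
  s <- rbind(
    make_sites(c(100, 110), sample_id = "A", reads = c(200, 400), genotype = "g1"),
    make_sites(100, sample_id = "B", reads = 150, genotype = "g1"),
    make_sites(100, sample_id = "D", reads = 10, genotype = "g2")
  )
  locus <- list(chrom = "chr1", start = 1, end = 1000)
  res <- genotype_reads_test(s, locus, "g1", "g2", samples = samples)
  expect_equal(sort(res$values$g1), c(0, 150, 300))
  expect_equal(sort(res$values$g2), c(0, 0, 10))
  expect_equal(res$p, oracle_mw_two_sided(c(300, 150, 0), c(10, 0, 0)),
               tolerance = 1e-12)
})

test_that("gene-set enrichment: closed form, saturation and top-k removal", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(hit = sprintf("g%02d", 1:5), other = sprintf("g%02d", 16:20))
  targets <- data.frame(gene_id = c("g01", "g02", "g03", "g10"),
                        n_ris = c(9, 5, 3, 2))
  res <- geneset_enrichment(targets, sets, universe)
  expect_equal(res$p[res$set == "hit"],
               sum(stats::dhyper(3:4, 5, 15, 4)), tolerance = 1e-12)
  expect_lt(res$p[res$set == "hit"], res$p[res$set == "other"])
  # dropping every target forces p = 1
  res_all <- geneset_enrichment(targets, sets, universe, drop_top_k = 4)
  expect_true(all(res_all$p == 1))
  # robustness grid: p for "hit" rises as its top genes are removed
  grid <- geneset_enrichment(targets, sets, universe, drop_top_k = c(0, 2, 4))
  p_hit <- grid$p[grid$set == "hit"]
  expect_true(all(diff(p_hit) >= 0))
  expect_warning(geneset_enrichment(targets, list(bad = "zz"), universe),
                 "skipped")
})

test_that("global-null orientation calls stay below the nominal FDR level", {
  # randomized strands in window clusters: the q < 0.05 discovery
  # fraction over repeated cohorts stays at or below 0.05 on average
  set.seed(61)
  n_disc <- 0
  n_tests <- 0
  for (rep in 1:60) {
    n <- 400
    pos <- sort(sample.int(4e6, n))
    s <- make_sites(pos, strand = sample(c("+", "-"), n, TRUE),
                    sample_id = sample(c("A", "B", "C"), n, TRUE))
    cl <- cluster_window(s, window = 12587, min_sites = 3)
    if (nrow(cl) == 0) next
    res <- orientation_test(cl, s)
    n_disc <- n_disc + sum(res$q < 0.05)
    n_tests <- n_tests + nrow(res)
  }
  expect_gt(n_tests, 200)
  expect_lte(n_disc / n_tests, 0.05)
})
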