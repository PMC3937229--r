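# Shared fixtures. Everything is generated in code; the expensive null
# thresholds for the screen-sized genome are computed once per test run
# and shared across test files.

toy_genome <- function(lengths = c(chr1 = 1e8)) genome_model(lengths)

make_sites <- function(pos, chrom = "chr1", strand = "+", sample_id = "S1",
                       reads = 1, genotype = NA_character_) {
  data.frame(chrom = chrom, pos = pos, strand = strand,
             sample_id = sample_id, genotype = genotype, reads = reads,
             stringsAsFactors = FALSE)
}

# a uniform random cohort of the screen's size, split over pseudo-samples
uniform_cohort <- function(n, genome, n_samples = 28, seed = 1) {
  set.seed(seed)
  u <- cisSelect:::uniform_positions(n, genome)
  make_sites(u$pos, chrom = u$chrom,
             strand = sample(c("+", "-"), n, replace = TRUE),
             sample_id = sample(sprintf("T%02d", seq_len(n_samples)), n,
                                replace = TRUE),
             reads = 1 + stats::rgeom(n, 0.25))
}

.fixture_cache <- new.env(parent = emptyenv())

# GKC null thresholds for a 12,485-site cohort on the mm9-sized genome
# at the default scale ladder; thresholds depend only on (n, genome,
# scale, alpha), so one computation serves every same-size cohort
screen_thresholds <- function() {
  if (is.null(.fixture_cache$thr)) {
    .fixture_cache$thr <- null_thresholds(
      12485, mm9_genome(), gkc_config()$scales,
      alpha = 0.05, n_null = 300, seed = 424242
    )
  }
  .fixture_cache$thr
}
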