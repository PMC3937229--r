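# Statistical evidence of post-integration selection: orientation bias,
# TSS-distance profiles, CIS-set overlap, genotype comparisons, region
# and gene-set enrichment.

#' Orientation-bias test for each CIS
#'
#' For every CIS the member insertions are split by orientation and
#' compared, by a one-tailed Fisher's exact test, against the strand
#' frequencies of all remaining insertions not in that CIS. The tested
#' tail is enrichment of the CIS's majority orientation; an exact tie
#' between forward and reverse members gives p = 1 by definition.
#' P-values are Benjamini-Hochberg adjusted across CISs.
#'
#' @param cis a `cis_set` with a `members` list-column.
#' @param sites the full cohort the CIS members index into.
#' @return data.frame of class `orientation_result`: `cis_id,
#'   n_insertions, fwd_in, rev_in, fwd_out, rev_out, bias, p, q`. `bias`
#'   is the majority fraction among members (in `[0.5, 1]`).
#' @export
orientation_test <- function(cis, sites) {
  sites <- validate_sites(sites)
  if (nrow(cis) == 0) {
    return(structure(data.frame(
      cis_id = character(0), n_insertions = integer(0), fwd_in = integer(0),
      rev_in = integer(0), fwd_out = integer(0), rev_out = integer(0),
      bias = numeric(0), p = numeric(0), q = numeric(0)
    ), class = c("orientation_result", "data.frame")))
  }
  if (any(lengths(cis$members) == 0)) stop_field("CIS with no members")
  fwd_all <- sum(sites$strand == "+")
  rev_all <- sum(sites$strand == "-")
  fwd_in <- vapply(cis$members, function(i) sum(sites$strand[i] == "+"), 0L)
  n_in <- lengths(cis$members)
  rev_in <- n_in - fwd_in
  fwd_out <- fwd_all - fwd_in
  rev_out <- rev_all - rev_in
  maj_in <- pmax(fwd_in, rev_in)
  min_in <- pmin(fwd_in, rev_in)
  maj_out <- ifelse(fwd_in >= rev_in, fwd_out, rev_out)
  min_out <- ifelse(fwd_in >= rev_in, rev_out, fwd_out)
  # P(X >= maj_in), X ~ Hypergeom(majority pool, minority pool, draws)
  p <- phyper(maj_in - 1L, maj_in + maj_out, min_in + min_out, n_in,
              lower.tail = FALSE)
  p[fwd_in == rev_in] <- 1
  p <- pmin(p, 1)
  structure(data.frame(
    cis_id = cis$cis_id, n_insertions = n_in, fwd_in = fwd_in,
    rev_in = rev_in, fwd_out = fwd_out, rev_out = rev_out,
    bias = maj_in / n_in, p = p, q = bh_adjust(p),
    row.names = NULL
  ), class = c("orientation_result", "data.frame"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_(j >= i) p_(j) m / j`, capped at 1; the result is
#' invariant to the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_field("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Filter orientation results to the biased CIS set
#'
#' Keeps CISs whose BH-adjusted p-value is strictly below `q_cut`.
#'
#' @param results an `orientation_result` data.frame.
#' @param q_cut strict upper bound on q (default 0.05).
#' @return the biased subset, same columns.
#' @export
biased_cis_set <- function(results, q_cut = 0.05) {
  results[results$q < q_cut, , drop = FALSE]
}

#' Signed distances from insertions to the nearest TSS
#'
#' Each insertion is mapped to the transcription start site of its
#' nearest annotated gene (nearest by absolute distance; ties broken by
#' lexicographically smaller gene id). Distances are signed in gene
#' orientation: positive downstream of the TSS (into the gene), negative
#' upstream, so the sign is flipped for minus-strand genes.
#'
#' @param sites insertion-site data.frame.
#' @param genome [genome_model()] with a `tss` table.
#' @param breaks histogram breakpoints (bp, in signed gene-oriented
#'   distance) or a single bin width.
#' @return list with `distances` (per-insertion data.frame: `chrom, pos,
#'   gene_id, distance, defined`) and `hist` (data.frame `lo, hi, count`
#'   over defined distances). Insertions on chromosomes without any TSS
#'   have `defined = FALSE` and NA distance.
#' @export
tss_distance_profile <- function(sites, genome, breaks = 5000) {
  sites <- validate_sites(sites, genome)
  if (is.null(genome$tss)) stop_field("genome has no TSS table")
  n <- nrow(sites)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (chr in unique(sites$chrom)) {
    t <- genome$tss[genome$tss$chrom == chr, , drop = FALSE]
    rows <- which(sites$chrom == chr)
    if (nrow(t) == 0) next
    o <- order(t$tss_pos, t$gene_id)
    tp <- t$tss_pos[o]
    tg <- t$gene_id[o]
    ts <- t$gene_strand[o]
    pos <- sites$pos[rows]
    idx <- findInterval(pos, tp)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(tp))
    d_left <- abs(pos - tp[left])
    d_right <- abs(pos - tp[right])
    d_left[idx < 1L] <- Inf
    d_right[idx >= length(tp)] <- Inf
    # ties by absolute distance -> smaller gene_id
    use_left <- d_left < d_right |
      (d_left == d_right & tg[left] <= tg[right])
    pick <- ifelse(use_left, left, right)
    raw <- pos - tp[pick]
    signed <- ifelse(ts[pick] == "-", -raw, raw)
    gene_id[rows] <- tg[pick]
    dist[rows] <- signed
  }
  defined <- !is.na(dist)
  d <- dist[defined]
  if (length(breaks) == 1L) {
    if (length(d)) {
      lim <- max(abs(d), breaks)
      breaks <- seq(-ceiling(lim / breaks) * breaks,
                    ceiling(lim / breaks) * breaks, by = breaks)
    } else {
      breaks <- c(-breaks, 0, breaks)
    }
  }
  counts <- if (length(d)) {
    as.integer(table(cut(d, breaks, include.lowest = TRUE, right = FALSE)))
  } else {
    integer(length(breaks) - 1L)
  }
  list(
    distances = data.frame(chrom = sites$chrom, pos = sites$pos,
                           gene_id = gene_id, distance = dist,
                           defined = defined, row.names = NULL),
    hist = data.frame(lo = breaks[-length(breaks)], hi = breaks[-1L],
                      count = counts)
  )
}

#' Estimate the TSS-preference weight of a cohort
#'
#' Method-of-moments estimate of the fraction `w` of insertions drawn
#' from a TSS-centred component rather than the uniform background:
#' compares the observed fraction of insertions within `window` bp of a
#' TSS to its expectation under the uniform model (fraction of the
#' genome within `window` of a TSS) and under a double-exponential
#' offset of scale `decay`.
#'
#' @param sites insertion-site data.frame.
#' @param genome [genome_model()] with a `tss` table.
#' @param decay assumed double-exponential offset scale (bp).
#' @param window absolute-distance window (bp), default `4 * decay`.
#' @return list `w_hat, p_obs, p_uniform, p_tss`.
#' @export
estimate_tss_weight <- function(sites, genome, decay, window = 4 * decay) {
  prof <- tss_distance_profile(sites, genome)
  d <- prof$distances$distance[prof$distances$defined]
  p_obs <- mean(abs(d) <= window)
  covered <- 0
  for (chr in unique(genome$tss$chrom)) {
    tp <- genome$tss$tss_pos[genome$tss$chrom == chr]
    m <- merge_closed(pmax(1, tp - window), pmin(genome$chrom_lengths[[chr]], tp + window))
    covered <- covered + sum(m$end - m$start + 1)
  }
  p_uniform <- covered / genome_size(genome)
  p_tss <- 1 - exp(-window / decay)
  w <- (p_obs - p_uniform) / (p_tss - p_uniform)
  list(w_hat = min(max(w, 0), 1), p_obs = p_obs,
       p_uniform = p_uniform, p_tss = p_tss)
}

#' Overlap between two CIS sets
#'
#' Two CISs overlap when their extents share at least one nucleotide
#' (closed-interval intersection).
#'
#' @param a,b CIS data.frames with `cis_id, chrom, start, end`.
#' @return list with `pairs` (data.frame `a_id, b_id`),
#'   `n_a_with_partner` and `n_b_with_partner`.
#' @export
cis_overlap <- function(a, b) {
  pairs <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == chr)
    bi <- which(b$chrom == chr)
    ra <- IRanges::IRanges(start = a$start[ai], end = a$end[ai])
    rb <- IRanges::IRanges(start = b$start[bi], end = b$end[bi])
    hits <- IRanges::findOverlaps(ra, rb, minoverlap = 1L)
    if (length(hits)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        a_id = a$cis_id[ai[S4Vectors::queryHits(hits)]],
        b_id = b$cis_id[bi[S4Vectors::subjectHits(hits)]]
      )
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(a_id = character(0), b_id = character(0))
  }
  pairs <- pairs[order(pairs$a_id, pairs$b_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       n_a_with_partner = length(unique(pairs$a_id)),
       n_b_with_partner = length(unique(pairs$b_id)))
}

#' Genomic-bin enrichment of CISs in a region set
#'
#' The genome is tiled into fixed-size bins per chromosome; a bin is a
#' region-bin when it intersects any region. Each CIS occupies the bin
#' containing its peak (or any bin its extent overlaps with
#' `assign = "extent"`), and a one-sided Fisher's exact test asks
#' whether CIS bins fall in region-bins more often than chance. The
#' test can also be run directly from printed counts via `counts`.
#'
#' @param cis a `cis_set` (ignored when `counts` given).
#' @param regions region data.frame `chrom, start, end` (1-based closed).
#' @param genome [genome_model()].
#' @param bin_size bin width in bp (default 30 kb, the average CIS size
#'   the comparison was built on).
#' @param assign `"peak"` (default) or `"extent"`.
#' @param counts optional list `cis_in_region, cis_total, region_bins,
#'   total_bins` bypassing the tiling.
#' @return list of class `bin_enrichment`: bin/CIS counts and the
#'   one-sided p-value.
#' @export
bin_enrichment <- function(cis = NULL, regions = NULL, genome = NULL,
                           bin_size = 30000, assign = c("peak", "extent"),
                           counts = NULL) {
  assign <- match.arg(assign)
  if (is.null(counts)) {
    if (is.null(cis) || is.null(regions) || is.null(genome)) {
      stop_field("either counts or (cis, regions, genome) must be given")
    }
    if (bin_size <= 0) stop_field("bin_size must be > 0")
    lens <- genome$chrom_lengths
    nbins <- ceiling(lens / bin_size)
    offsets <- setNames(c(0, cumsum(nbins))[seq_along(nbins)], names(nbins))
    total_bins <- sum(nbins)
    if (any(!regions$chrom %in% names(lens)) ||
        any(regions$end > lens[regions$chrom]) || any(regions$start < 1)) {
      stop_field("region outside genome")
    }
    region_bin_ids <- unlist(lapply(seq_len(nrow(regions)), function(i) {
      chr <- regions$chrom[i]
      b0 <- floor((regions$start[i] - 1) / bin_size)
      b1 <- floor((regions$end[i] - 1) / bin_size)
      offsets[[chr]] + seq.int(b0, b1) + 1
    }))
    region_bin_ids <- unique(region_bin_ids)
    if (assign == "peak") {
      cis_bins <- offsets[cis$chrom] + floor((cis$peak_pos - 1) / bin_size) + 1
      in_region <- cis_bins %in% region_bin_ids
    } else {
      in_region <- vapply(seq_len(nrow(cis)), function(i) {
        b0 <- floor((cis$start[i] - 1) / bin_size)
        b1 <- floor((cis$end[i] - 1) / bin_size)
        any((offsets[[cis$chrom[i]]] + seq.int(b0, b1) + 1) %in% region_bin_ids)
      }, TRUE)
    }
    counts <- list(cis_in_region = sum(in_region), cis_total = nrow(cis),
                   region_bins = length(region_bin_ids),
                   total_bins = total_bins)
  }
  with(counts, {
    if (cis_in_region > cis_total) stop_field("cis_in_region > cis_total")
    if (region_bins > total_bins) stop_field("region_bins > total_bins")
    if (cis_total - cis_in_region > total_bins - region_bins) {
      stop_field("more CIS bins outside regions than available bins")
    }
    tab <- matrix(c(cis_in_region, cis_total - cis_in_region,
                    region_bins - cis_in_region,
                    (total_bins - region_bins) - (cis_total - cis_in_region)),
                  nrow = 2, byrow = TRUE)
    p <- fisher.test(tab, alternative = "greater")$p.value
    structure(list(bin_size = bin_size, total_bins = total_bins,
                   region_bins = region_bins, cis_total = cis_total,
                   cis_in_region = cis_in_region, table = tab, p = p),
              class = "bin_enrichment")
  })
}

#' @export
print.bin_enrichment <- function(x, ...) {
  cat(sprintf("bin enrichment: %d/%d CISs in %d/%d region-bins, one-sided p = %.3g\n",
              x$cis_in_region, x$cis_total, x$region_bins, x$total_bins, x$p))
  invisible(x)
}

locus_presence <- function(sites, locus, threshold) {
  hit <- sites$chrom == locus$chrom & sites$pos >= locus$start &
    sites$pos <= locus$end & sites$reads >= threshold
  tapply(hit, sites$sample_id, any)
}

#' Fisher test of genotype-restricted presence of an expanded locus
#'
#' Per tumour, presence is defined as carrying at least one expanded RIS
#' (reads >= `threshold`) within the locus extent; presence counts are
#' compared between the focal genotype and the others (or between two
#' named genotypes) by a two-sided Fisher's exact test.
#'
#' @param sites insertion-site data.frame with a `genotype` column.
#' @param locus list or one-row data.frame with `chrom, start, end`.
#' @param focal focal genotype label.
#' @param other optional second genotype; default: all other genotypes
#'   pooled.
#' @param threshold expansion read threshold (default 100).
#' @param samples optional data.frame `sample_id, genotype` enumerating
#'   tumours (defaults to the samples present in `sites`; tumours with
#'   no insertions at all must be supplied here to be counted).
#' @return list `p, table, presence` (per-tumour logical).
#' @export
genotype_presence_test <- function(sites, locus, focal, other = NULL,
                                   threshold = 100, samples = NULL) {
  sites <- validate_sites(sites)
  if (is.null(samples)) {
    samples <- unique(sites[, c("sample_id", "genotype")])
  }
  if (anyNA(samples$genotype)) stop_field("genotype missing for some samples")
  pres <- locus_presence(sites, locus, threshold)
  present <- samples$sample_id %in% names(pres)[!is.na(pres) & pres]
  grp <- if (is.null(other)) {
    ifelse(samples$genotype == focal, focal, "rest")
  } else {
    ifelse(samples$genotype == focal, focal,
           ifelse(samples$genotype == other, other, NA))
  }
  keep <- !is.na(grp)
  if (!any(keep)) stop_field("no tumours in the requested genotypes")
  grp <- factor(grp[keep], levels = unique(c(focal, setdiff(unique(grp[keep]), focal))))
  if (nlevels(grp) < 2 || any(table(grp) == 0)) {
    stop_field("both genotype groups must contain tumours")
  }
  tab <- table(grp, factor(present[keep], levels = c(TRUE, FALSE)))
  list(p = fisher.test(tab)$p.value, table = tab,
       presence = setNames(present, samples$sample_id))
}

# exact two-sided Mann-Whitney by enumeration (handles ties);
# U counts pairs (x > y) + 0.5 * (x == y)
mw_exact_p <- function(x, y) {
  u_stat <- function(xv, yv) {
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  mid <- n1 * length(y) / 2
  obs <- abs(u_stat(x, y) - mid)
  combos <- combn(length(pooled), n1)
  stats <- apply(combos, 2L, function(i) {
    abs(u_stat(pooled[i], pooled[-i]) - mid)
  })
  mean(stats >= obs - 1e-9)
}

mw_approx_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  n <- n1 + n2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact by full enumeration of group assignments for small samples
#' (combined n <= `exact_max`, correct under ties), normal approximation
#' with tie correction and continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_max combined sample size up to which the exact
#'   enumeration is used.
#' @return list `p, U, method`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 16) {
  if (length(x) == 0 || length(y) == 0) stop_field("both groups must be non-empty")
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  if (length(x) + length(y) <= exact_max) {
    list(p = mw_exact_p(x, y), U = u, method = "exact")
  } else {
    list(p = mw_approx_p(x, y), U = u, method = "normal_tie_corrected")
  }
}

#' Mann-Whitney comparison of per-tumour clonality at a locus
#'
#' The per-tumour statistic is the mean read count per RIS within the
#' locus extent (0 when the tumour carries no insertion there, unless
#' `include_zeros = FALSE`). Two genotype groups are compared two-sided.
#'
#' @param sites insertion-site data.frame with genotypes.
#' @param locus list with `chrom, start, end`.
#' @param group1,group2 genotype labels to compare.
#' @param include_zeros count absent tumours as 0 (default TRUE).
#' @param samples optional `sample_id, genotype` table (see
#'   [genotype_presence_test()]).
#' @return list `p, U, method, values` (named per-group value lists).
#' @export
genotype_reads_test <- function(sites, locus, group1, group2,
                                include_zeros = TRUE, samples = NULL) {
  sites <- validate_sites(sites)
  if (is.null(samples)) samples <- unique(sites[, c("sample_id", "genotype")])
  at_locus <- sites$chrom == locus$chrom & sites$pos >= locus$start &
    sites$pos <= locus$end
  per_sample <- tapply(sites$reads[at_locus], sites$sample_id[at_locus], mean)
  value_of <- function(ids) {
    v <- per_sample[ids]
    v[is.na(v)] <- 0
    if (!include_zeros) v <- v[v > 0]
    as.numeric(v)
  }
  x <- value_of(samples$sample_id[samples$genotype == group1])
  y <- value_of(samples$sample_id[samples$genotype == group2])
  if (length(x) == 0 || length(y) == 0) stop_field("both groups must be non-empty")
  res <- mann_whitney_test(x, y)
  res$values <- setNames(list(x, y), c(group1, group2))
  res
}

#' Gene-set enrichment of insertion target genes
#'
#' One-sided hypergeometric enrichment of each gene set among the target
#' genes, after removing the `drop_top_k` most frequently hit genes - a
#' robustness analysis probing whether enrichment is carried only by the
#' top targets. A vector of `drop_top_k` values produces the full
#' robustness profile.
#'
#' @param targets data.frame `gene_id, n_ris` (insertion counts), or a
#'   named numeric vector.
#' @param genesets named list of character vectors.
#' @param universe character vector of all assayable genes.
#' @param drop_top_k scalar or vector of top-target removals.
#' @return data.frame `drop_top_k, set, n_set, n_targets, overlap, p`.
#' @export
geneset_enrichment <- function(targets, genesets, universe, drop_top_k = 0) {
  if (!is.data.frame(targets)) {
    targets <- data.frame(gene_id = names(targets), n_ris = as.numeric(targets))
  }
  targets <- targets[targets$gene_id %in% universe, , drop = FALSE]
  targets <- targets[order(-targets$n_ris, targets$gene_id), , drop = FALSE]
  out <- list()
  for (k in drop_top_k) {
    kept <- if (k >= nrow(targets)) character(0) else targets$gene_id[-seq_len(k)]
    if (k == 0) kept <- targets$gene_id
    for (nm in names(genesets)) {
      set <- intersect(genesets[[nm]], universe)
      if (length(set) == 0) {
        warning(sprintf("gene set '%s' has no universe members; skipped", nm))
        next
      }
      ov <- length(intersect(kept, set))
      p <- phyper(ov - 1, length(set), length(universe) - length(set),
                  length(kept), lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        drop_top_k = k, set = nm, n_set = length(set),
        n_targets = length(kept), overlap = ov, p = p
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
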