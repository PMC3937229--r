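# Multi-scale Gaussian kernel convolution CIS calling with a
# Monte-Carlo random-integration null, plus the fixed-window cluster
# rule used for vector integration sets.

#' Configuration for the multi-scale GKC caller
#'
#' @param scales kernel widths sigma (bp), ascending. The default ladder
#'   2, 5, 10, 15, 30, 60, 120, 250, 500 kb brackets tight intragenic
#'   clusters up to long-range enhancer-mode targets and includes the
#'   15 kb and 30 kb anchor scales of the screen's analyses.
#' @param alpha genome-wide significance level per scale (max-statistic
#'   calibration).
#' @param n_null Monte-Carlo draws for the null threshold (>= 100).
#' @param grid_step density evaluation step as a fraction of sigma.
#' @param trunc kernel truncation radius in units of sigma; contributions
#'   beyond it are dropped (6 sigma keeps the error below 2e-8 per site).
#' @param seed seed for the null draws (NULL = use current RNG state).
#' @return list of class `gkc_config`.
#' @export
gkc_config <- function(scales = c(2, 5, 10, 15, 30, 60, 120, 250, 500) * 1000,
                       alpha = 0.05, n_null = 300, grid_step = 0.25,
                       trunc = 6, seed = NULL) {
  scales <- as.numeric(scales)
  if (is.unsorted(scales, strictly = TRUE) || any(scales <= 0)) {
    stop_field("scales must be strictly ascending and positive")
  }
  if (alpha <= 0 || alpha > 1) stop_field("alpha must be in (0, 1]")
  if (n_null < 100) stop_field("n_null must be >= 100")
  if (grid_step <= 0 || trunc <= 0) stop_field("grid_step and trunc must be > 0")
  structure(list(scales = scales, alpha = alpha, n_null = as.integer(n_null),
                 grid_step = grid_step, trunc = trunc, seed = seed),
            class = "gkc_config")
}

#' Gaussian kernel density profile of insertion positions
#'
#' Evaluates `f(x) = sum_i exp(-(x - x_i)^2 / (2 sigma^2))` (each unique
#' RIS weighted 1) on a grid of step `grid_step * sigma` anchored at
#' multiples of the step, restricted to within `trunc * sigma` of any
#' site, plus exactly at every site position.
#'
#' @param positions numeric positions on one chromosome.
#' @param scale kernel width sigma (bp).
#' @param grid_step grid step as a fraction of sigma.
#' @param xlim evaluation range (defaults to the span padded by the
#'   truncation radius).
#' @param trunc truncation radius in units of sigma.
#' @return data.frame `x, density` (zero rows for empty input).
#' @export
kde_profile <- function(positions, scale, grid_step = 0.25, xlim = NULL,
                        trunc = 6) {
  if (scale <= 0) stop_field("scale must be > 0")
  positions <- sort(as.numeric(positions))
  if (length(positions) == 0) {
    return(data.frame(x = numeric(0), density = numeric(0)))
  }
  r <- trunc * scale
  if (is.null(xlim)) xlim <- c(positions[1] - r, positions[length(positions)] + r)
  xs <- cpp_kde_grid(positions, grid_step * scale, r, xlim[1], xlim[2])
  data.frame(x = xs, density = cpp_kde_eval(xs, positions, scale, r))
}

# shared machinery: genome-wide max of the kernel profile for a cohort
# split per chromosome (list of sorted numeric vectors)
kde_genome_max <- function(by_chrom, lengths, scale, grid_step, trunc) {
  best <- 0
  for (chr in names(by_chrom)) {
    p <- by_chrom[[chr]]
    if (length(p) == 0) next
    m <- cpp_kde_max(p, scale, grid_step * scale, trunc * scale, 1, lengths[[chr]])
    if (m > best) best <- m
  }
  best
}

split_positions <- function(sites, genome) {
  out <- split(sites$pos, factor(sites$chrom, levels = names(genome$chrom_lengths)))
  lapply(out, sort)
}

#' Null peak-height thresholds from simulated random integration
#'
#' For each Monte-Carlo draw, `n_sites` positions are placed uniformly
#' over the genome (per-chromosome probability proportional to length)
#' and the genome-wide maximum kernel height is recorded per scale. The
#' threshold at a scale is the empirical `(1 - alpha)` quantile (upper
#' order statistic) of those maxima, so calling any CIS on a random
#' cohort is a genome-wide level-`alpha` event per scale.
#'
#' @param n_sites cohort size being calibrated for (>= 2).
#' @param genome [genome_model()].
#' @param scales kernel widths (bp).
#' @param alpha significance level; `alpha = 1` degenerates to the
#'   minimum of the null maxima (useful for testing).
#' @param n_null number of draws.
#' @param seed RNG seed (NULL = current RNG state).
#' @param grid_step,trunc see [gkc_config()].
#' @return named numeric vector of thresholds, one per scale.
#' @export
null_thresholds <- function(n_sites, genome, scales, alpha = 0.05,
                            n_null = 300, seed = NULL, grid_step = 0.25,
                            trunc = 6) {
  if (n_sites < 2) stop_field("n_sites must be >= 2")
  scales <- as.numeric(scales)
  lengths <- genome$chrom_lengths
  maxima <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      draw <- uniform_positions(n_sites, genome)
      by_chrom <- split(draw$pos, factor(draw$chrom, levels = names(lengths)))
      by_chrom <- lapply(by_chrom, sort)
      vapply(scales, function(sc) {
        kde_genome_max(by_chrom, lengths, sc, grid_step, trunc)
      }, 0)
    }, numeric(length(scales)))
  })
  maxima <- matrix(maxima, nrow = length(scales))
  k <- min(max(1L, as.integer(ceiling((1 - alpha) * n_null))), n_null)
  thr <- apply(maxima, 1L, function(v) sort(v)[k])
  setNames(thr, as.character(scales))
}

#' Null threshold at a single scale
#'
#' Convenience wrapper around [null_thresholds()] for one kernel width.
#'
#' @inheritParams null_thresholds
#' @param scale kernel width sigma (bp).
#' @return numeric threshold.
#' @export
null_threshold <- function(n_sites, genome, scale, alpha = 0.05,
                           n_null = 300, seed = NULL, grid_step = 0.25,
                           trunc = 6) {
  unname(null_thresholds(n_sites, genome, scale, alpha, n_null, seed,
                         grid_step, trunc))
}

new_cis_set <- function(df) {
  structure(df, class = c("cis_set", "data.frame"))
}

#' Call common insertion sites by multi-scale kernel convolution
#'
#' At each scale, contiguous runs of the density profile above that
#' scale's null threshold become candidate CISs; their members are the
#' insertions inside the above-threshold run, the peak is the density
#' argmax within the member span (ties towards the smaller coordinate),
#' and candidates with fewer than `min_insertions` members are dropped.
#' Candidates overlapping by >= 1 nt across scales are consolidated into
#' one CIS reported at the smallest scale at which significance holds
#' for the cluster as a whole: with the default
#' `consolidate = "smallest_scale"` the reported extent, peak, height
#' and members are those of the candidate at the finest scale where a
#' single candidate spans every smaller-scale candidate of the
#' component (the scale-space point where the cluster is one blob;
#' candidates at very large scales therefore do not inflate the
#' reported extent), while the union of members over all overlapping
#' candidates is recorded in the `members_union` column. With
#' `consolidate = "union"` the member union itself defines the CIS. In
#' both modes the CIS extent spans the minimum and maximum member
#' positions.
#'
#' @param sites merged insertion-site data.frame (all samples pooled;
#'   each unique RIS has weight 1 regardless of reads).
#' @param genome [genome_model()].
#' @param config a [gkc_config()].
#' @param thresholds optional precomputed named vector from
#'   [null_thresholds()] (names = scales); computed when `NULL`.
#' @param min_insertions minimum members per CIS (>= 2).
#' @param min_samples optional minimum number of distinct samples per
#'   CIS (default 1: within-tumour recurrence counts).
#' @param consolidate cross-scale consolidation mode, see Details.
#' @return a `cis_set` data.frame: `cis_id, chrom, start, end, peak_pos,
#'   peak_height, scale, n_insertions, n_samples` plus a `members`
#'   list-column of row indices into `sites`.
#' @export
call_cis <- function(sites, genome, config = gkc_config(), thresholds = NULL,
                     min_insertions = 2, min_samples = 1,
                     consolidate = c("smallest_scale", "union")) {
  consolidate <- match.arg(consolidate)
  sites <- validate_sites(sites, genome)
  empty <- new_cis_set(data.frame(
    cis_id = character(0), chrom = character(0), start = numeric(0),
    end = numeric(0), peak_pos = numeric(0), peak_height = numeric(0),
    scale = numeric(0), n_insertions = integer(0), n_samples = integer(0)
  ))
  empty$members <- list()
  empty$members_union <- list()
  if (nrow(sites) < min_insertions) return(empty)
  if (is.null(thresholds)) {
    thresholds <- null_thresholds(nrow(sites), genome, config$scales,
                                  config$alpha, config$n_null, config$seed,
                                  config$grid_step, config$trunc)
  }
  if (!all(as.character(config$scales) %in% names(thresholds))) {
    stop_field("thresholds must be named by scale")
  }
  lengths <- genome$chrom_lengths
  cand <- list()
  for (chr in unique(sites$chrom)) {
    rows <- which(sites$chrom == chr)
    o <- rows[order(sites$pos[rows])]
    p <- sites$pos[o]
    for (sc in config$scales) {
      thr <- thresholds[[as.character(sc)]]
      r <- config$trunc * sc
      xs <- cpp_kde_grid(p, config$grid_step * sc, r, 1, lengths[[chr]])
      dens <- cpp_kde_eval(xs, p, sc, r)
      above <- dens > thr
      if (!any(above)) next
      runs <- rle(above)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (ri in which(runs$values)) {
        lo <- xs[starts[ri]]
        hi <- xs[ends[ri]]
        mem <- o[p >= lo & p <= hi]
        if (length(mem) < min_insertions) next
        span <- range(sites$pos[mem])
        in_span <- which(xs >= span[1] & xs <= span[2])
        pk <- in_span[which.max(dens[in_span])]
        cand[[length(cand) + 1L]] <- list(
          chrom = chr, start = span[1], end = span[2],
          peak_pos = xs[pk], peak_height = dens[pk], scale = sc,
          members = mem
        )
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cd <- data.frame(
    chrom = vapply(cand, `[[`, "", "chrom"),
    start = vapply(cand, `[[`, 0, "start"),
    end = vapply(cand, `[[`, 0, "end"),
    peak_pos = vapply(cand, `[[`, 0, "peak_pos"),
    peak_height = vapply(cand, `[[`, 0, "peak_height"),
    scale = vapply(cand, `[[`, 0, "scale"),
    stringsAsFactors = FALSE
  )
  cd$members <- lapply(cand, `[[`, "members")
  # connected components of the >=1-nt overlap graph on extents
  o <- order(cd$chrom, cd$start, cd$end)
  cd <- cd[o, , drop = FALSE]
  same <- c(FALSE, cd$chrom[-1L] == cd$chrom[-nrow(cd)])
  chrom_block <- cumsum(!same)
  runmax <- stats::ave(cd$end, chrom_block, FUN = cummax)
  prev_max <- c(-Inf, runmax[-nrow(cd)])
  new_comp <- !same | cd$start > prev_max
  comp <- cumsum(new_comp)
  out <- lapply(split(seq_len(nrow(cd)), comp), function(idx) {
    sub <- cd[idx, , drop = FALSE]
    union_mem <- sort(unique(unlist(cd$members[idx])))
    if (consolidate == "union") {
      rep_i <- idx[order(sub$scale, sub$start)][1L]
      mem <- union_mem
    } else {
      # representative: the candidate at the smallest scale at which a
      # single candidate spans every candidate of the component at that
      # scale or below - the finest scale where the cluster is one blob
      rep_local <- NA_integer_
      for (s in sort(unique(sub$scale))) {
        le <- which(sub$scale <= s)
        span_lo <- min(sub$start[le])
        span_hi <- max(sub$end[le])
        at_s <- which(sub$scale == s & sub$start <= span_lo &
                        sub$end >= span_hi)
        if (length(at_s)) {
          rep_local <- at_s[order(-sub$peak_height[at_s], sub$start[at_s])][1L]
          break
        }
      }
      if (is.na(rep_local)) {
        # no single covering candidate at any scale (rare): fall back to
        # the dominant candidate at the smallest scale
        at_min <- which(sub$scale == min(sub$scale))
        rep_local <- at_min[order(-sub$peak_height[at_min],
                                  sub$start[at_min])][1L]
      }
      rep_i <- idx[rep_local]
      mem <- cd$members[[rep_i]]
    }
    span <- range(sites$pos[mem])
    list(chrom = cd$chrom[rep_i], start = span[1], end = span[2],
         peak_pos = cd$peak_pos[rep_i], peak_height = cd$peak_height[rep_i],
         scale = cd$scale[rep_i], members = mem, members_union = union_mem)
  })
  res <- data.frame(
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, `[[`, 0, "start"),
    end = vapply(out, `[[`, 0, "end"),
    peak_pos = vapply(out, `[[`, 0, "peak_pos"),
    peak_height = vapply(out, `[[`, 0, "peak_height"),
    scale = vapply(out, `[[`, 0, "scale"),
    stringsAsFactors = FALSE
  )
  res$members <- lapply(out, `[[`, "members")
  res$members_union <- lapply(out, `[[`, "members_union")
  res$n_insertions <- lengths(res$members)
  res$n_samples <- vapply(res$members, function(i) {
    length(unique(sites$sample_id[i]))
  }, 0L)
  if (min_samples > 1) {
    res <- res[res$n_samples >= min_samples, , drop = FALSE]
  }
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  if (nrow(res)) res$cis_id <- sprintf("CIS%04d", seq_len(nrow(res))) else res$cis_id <- character(0)
  rownames(res) <- NULL
  new_cis_set(res[, c("cis_id", "chrom", "start", "end", "peak_pos",
                      "peak_height", "scale", "n_insertions", "n_samples",
                      "members", "members_union")])
}

#' Fixed-window clustering of integration sites
#'
#' The cluster rule used for the near-baseline vector integration set:
#' scanning left to right per chromosome, a region is grown from the
#' leftmost unassigned site while its span (max - min + 1) stays within
#' `window` nucleotides, and emitted as a cluster when it holds at least
#' `min_sites` sites. Sites of a failed (too small) window can seed or
#' join later windows; emitted clusters are disjoint.
#'
#' @param sites insertion-site data.frame (all samples pooled).
#' @param window maximum cluster span in nucleotides, inclusive.
#' @param min_sites minimum number of sites per cluster.
#' @return a `cis_set`-like data.frame (`cis_id, chrom, start, end,
#'   n_insertions, n_samples, members`).
#' @export
cluster_window <- function(sites, window = 12587, min_sites = 3) {
  sites <- validate_sites(sites)
  clusters <- list()
  for (chr in unique(sites$chrom)) {
    rows <- which(sites$chrom == chr)
    o <- rows[order(sites$pos[rows])]
    p <- sites$pos[o]
    i <- 1L
    while (i <= length(p)) {
      j <- i
      while (j < length(p) && p[j + 1L] - p[i] + 1 <= window) j <- j + 1L
      if (j - i + 1L >= min_sites) {
        clusters[[length(clusters) + 1L]] <- list(
          chrom = chr, start = p[i], end = p[j], members = o[i:j]
        )
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(clusters) == 0) {
    out <- data.frame(cis_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_insertions = integer(0), n_samples = integer(0))
    out$members <- list()
    return(new_cis_set(out))
  }
  out <- data.frame(
    chrom = vapply(clusters, `[[`, "", "chrom"),
    start = vapply(clusters, `[[`, 0, "start"),
    end = vapply(clusters, `[[`, 0, "end"),
    stringsAsFactors = FALSE
  )
  out$members <- lapply(clusters, `[[`, "members")
  out$n_insertions <- lengths(out$members)
  out$n_samples <- vapply(out$members, function(i) {
    length(unique(sites$sample_id[i]))
  }, 0L)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$cis_id <- sprintf("W%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  new_cis_set(out[, c("cis_id", "chrom", "start", "end", "n_insertions",
                      "n_samples", "members")])
}
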