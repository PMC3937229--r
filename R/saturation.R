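# Saturation analysis: pseudo-kernel coverage as a function of cohort
# size, against a random-placement control.

#' Pseudo-kernel regions for one sample
#'
#' Each insertion contributes a fixed interval of `half_width` bp either
#' side of the site - a pseudo-kernel approximating a Gaussian kernel of
#' width `2 * half_width` - and overlapping or adjacent kernels within
#' the sample are merged into continuous regions. Intervals are clipped
#' at chromosome ends, so an interior site yields exactly
#' `2 * half_width` bp of coverage.
#'
#' @param sites insertion sites of one sample.
#' @param genome [genome_model()].
#' @param half_width half kernel width in bp (default 7,500, mimicking
#'   15 kb Gaussian kernels).
#' @return data.frame `chrom, start, end` (1-based closed, merged).
#' @export
pseudo_kernel_regions <- function(sites, genome, half_width = 7500) {
  sites <- validate_sites(sites, genome)
  if (half_width <= 0) stop_field("half_width must be > 0")
  out <- lapply(unique(sites$chrom), function(chr) {
    pos <- sites$pos[sites$chrom == chr]
    len <- genome$chrom_lengths[[chr]]
    # half-open [pos - hw, pos + hw) clipped to [0, len), stored closed
    s0 <- pmax(0, pos - half_width)
    e0 <- pmin(len, pos + half_width)
    m <- merge_closed(s0 + 1, e0)
    data.frame(chrom = chr, start = m$start, end = m$end)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-sample pseudo-kernel intervals projected onto one offset
# coordinate line so subset unions need no per-chromosome handling
sample_interval_line <- function(sites, genome, half_width) {
  lens <- genome$chrom_lengths
  offsets <- setNames(c(0, cumsum(lens + 1))[seq_along(lens)], names(lens))
  lapply(split(sites, sites$sample_id), function(s) {
    reg <- pseudo_kernel_regions(s, genome, half_width)
    off <- offsets[reg$chrom]
    list(start = reg$start + off, end = reg$end + off)
  })
}

subset_pool <- function(n_samples, n, max_combos) {
  if (choose(n_samples, n) <= max_combos) {
    m <- combn(n_samples, n)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  } else {
    seen <- new.env(hash = TRUE)
    out <- vector("list", max_combos)
    got <- 0L
    while (got < max_combos) {
      cand <- sort(sample.int(n_samples, n))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[[got]] <- cand
      }
    }
    out
  }
}

#' Coverage saturation curve over sample subsets
#'
#' For every subset size n, evaluates the base-pair coverage of the
#' union of per-sample pseudo-kernel regions over all n-subsets of
#' samples (exhaustively when there are at most `max_combos` of them,
#' otherwise over `max_combos` distinct subsets sampled uniformly), and
#' reports the 25th/50th/75th coverage percentiles. A flattening curve
#' indicates the screen is approaching saturation; random placement
#' grows linearly.
#'
#' @param sites insertion-site data.frame (>= 2 samples).
#' @param genome [genome_model()].
#' @param half_width pseudo-kernel half width (bp).
#' @param max_combos maximum subsets evaluated per size.
#' @param seed RNG seed for subset sampling.
#' @param label curve label (`"real"` or `"random_control"`).
#' @return data.frame of class `saturation_curve`: `n, q25, median, q75,
#'   n_combinations, label`.
#' @export
coverage_curve <- function(sites, genome, half_width = 7500,
                           max_combos = 1000, seed = NULL, label = "real") {
  sites <- validate_sites(sites, genome)
  ivs <- sample_interval_line(sites, genome, half_width)
  n_samples <- length(ivs)
  if (n_samples < 2) stop_field("need >= 2 samples")
  rows <- with_seed(seed, {
    lapply(seq_len(n_samples), function(n) {
      subsets <- subset_pool(n_samples, n, max_combos)
      cov <- vapply(subsets, function(idx) {
        s <- unlist(lapply(ivs[idx], `[[`, "start"), use.names = FALSE)
        e <- unlist(lapply(ivs[idx], `[[`, "end"), use.names = FALSE)
        union_width(s, e)
      }, 0)
      q <- unname(quantile(cov, c(0.25, 0.5, 0.75)))
      data.frame(n = n, q25 = q[1], median = q[2], q75 = q[3],
                 n_combinations = length(subsets), label = label)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, seed = seed, class = c("saturation_curve", "data.frame"))
}

#' Random-placement control for the saturation curve
#'
#' Replaces each sample's sites with the same number of positions drawn
#' uniformly over the genome, then computes the coverage curve with the
#' same settings. The same `seed` gives the same subset choices as the
#' matching [coverage_curve()] call.
#'
#' @inheritParams coverage_curve
#' @return a `saturation_curve` labelled `"random_control"`.
#' @export
random_control <- function(sites, genome, half_width = 7500,
                           max_combos = 1000, seed = NULL) {
  sites <- validate_sites(sites, genome)
  placed <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 77L), {
    parts <- lapply(split(sites, sites$sample_id), function(s) {
      u <- uniform_positions(nrow(s), genome)
      s$chrom <- u$chrom
      s$pos <- u$pos
      s
    })
    do.call(rbind, parts)
  })
  coverage_curve(placed, genome, half_width = half_width,
                 max_combos = max_combos, seed = seed,
                 label = "random_control")
}
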