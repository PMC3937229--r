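# Independent brute-force oracles used to check the package's
# statistical operations. These deliberately avoid the code paths (and
# where possible the base functions) used by the implementation.

# one-tailed Fisher p for the 2x2 table [[a, b], [c, d]]: probability of
# tables with first cell >= a at fixed margins, probabilities from
# factorials directly
oracle_fisher_one_tail <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  }
  sum(exp(vapply(a:hi, logp, 0)))
}

# two-sided Fisher p: sum of probabilities of tables no more likely
# than the observed one (R's convention)
oracle_fisher_two_tail <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- exp(vapply(lo:hi, function(x) {
    lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  }, 0))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up from the defining formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# exact two-sided Mann-Whitney by enumerating all group assignments of
# the pooled values (rank-free: uses the U statistic directly)
oracle_mw_two_sided <- function(x, y) {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  mid <- n1 * length(y) / 2
  obs <- abs(u_of(x, y) - mid)
  sel <- utils::combn(length(pooled), n1)
  devs <- apply(sel, 2, function(i) abs(u_of(pooled[i], pooled[-i]) - mid))
  mean(devs >= obs - 1e-9)
}

# direct Gaussian kernel sum
oracle_kde <- function(x, positions, sigma) {
  vapply(x, function(xx) sum(exp(-(xx - positions)^2 / (2 * sigma^2))), 0)
}

# union width of closed intervals by integer enumeration (small ranges)
oracle_union_width <- function(start, end) {
  length(unique(unlist(mapply(seq, start, end, SIMPLIFY = FALSE))))
}

# fixed-window greedy clustering re-derived from the rule statement
oracle_window_clusters <- function(pos, window, min_sites) {
  pos <- sort(pos)
  out <- list()
  assigned <- rep(FALSE, length(pos))
  repeat {
    left <- which(!assigned)
    if (length(left) == 0) break
    i <- left[1]
    inside <- which(!assigned & pos >= pos[i] & pos - pos[i] + 1 <= window)
    if (length(inside) >= min_sites) {
      out[[length(out) + 1]] <- pos[inside]
      assigned[inside] <- TRUE
    } else {
      assigned[i] <- TRUE
    }
  }
  out
}

# all-pairs closed-interval overlap
oracle_overlap_pairs <- function(a, b) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] <= b$end[j] && b$start[j] <= a$end[i]) {
        pairs[[length(pairs) + 1]] <- c(a$cis_id[i], b$cis_id[j])
      }
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(a_id = character(0), b_id = character(0)))
  }
  out <- data.frame(a_id = vapply(pairs, `[`, "", 1),
                    b_id = vapply(pairs, `[`, "", 2))
  out[order(out$a_id, out$b_id), , drop = FALSE]
}
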