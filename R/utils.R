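# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a temporary RNG state; NULL seed leaves the RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# deterministic sub-seed derivation; keeps results < 2^31 - 1
derive_seed <- function(seed, k) {
  v <- (as.numeric(seed) %% 2147483399) * 48271 + as.numeric(k)
  as.integer(v %% 2147483647)
}

# total width of the union of closed integer intervals
union_width <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start)
  s <- start[o]
  e <- cummax(end[o])
  brk <- which(s[-1L] > e[-length(e)] + 1)
  firsts <- c(1L, brk + 1L)
  lasts <- c(brk, length(s))
  sum(e[lasts] - s[firsts] + 1)
}

# merge closed integer intervals (adjacent intervals coalesce)
merge_closed <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start)
  s <- start[o]
  e <- cummax(end[o])
  brk <- which(s[-1L] > e[-length(e)] + 1)
  firsts <- c(1L, brk + 1L)
  lasts <- c(brk, length(s))
  data.frame(start = s[firsts], end = e[lasts])
}

# distance from points to nearest interval in a merged, sorted set
# (0 when the point lies inside an interval)
point_interval_distance <- function(pos, start, end) {
  if (length(start) == 0L) return(rep(Inf, length(pos)))
  idx <- findInterval(pos, start)
  d_left <- ifelse(idx >= 1L, pos - end[pmax(idx, 1L)], Inf)
  d_left <- pmax(d_left, 0)
  inside <- idx >= 1L & pos <= end[pmax(idx, 1L)]
  d_right <- ifelse(idx < length(start), start[pmin(idx + 1L, length(start))] - pos, Inf)
  out <- pmin(d_left, d_right)
  out[inside] <- 0
  out
}

stop_field <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
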