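# Collapsing raw mapped read starts into unique RISs and clonality
# summaries.

#' Merge nearby read alignments into unique insertion sites
#'
#' Within each (sample, chromosome, strand) group, positions forming
#' single-linkage chains with consecutive gaps `<= max_gap` are collapsed
#' into one RIS. The merged read count is the sum over members and the
#' representative position is that of the member with the most reads
#' (ties broken towards the smallest position). Merging is idempotent and
#' conserves total reads.
#'
#' @param sites insertion-site data.frame.
#' @param max_gap maximum distance (bp) between consecutive positions
#'   that still merges them; the screen's read-collapsing rule uses 3.
#' @param ignore_strand merge across strands as well (the laxer reading
#'   of the merging rule; off by default because opposite-strand junction
#'   reads indicate distinct provirus ends).
#' @return insertion-site data.frame of unique RISs.
#' @export
merge_sites <- function(sites, max_gap = 3, ignore_strand = FALSE) {
  sites <- validate_sites(sites)
  if (max_gap < 0) stop_field("max_gap must be >= 0")
  if (nrow(sites) == 0) return(sites)
  key <- if (ignore_strand) {
    paste(sites$sample_id, sites$chrom, sep = "\r")
  } else {
    paste(sites$sample_id, sites$chrom, sites$strand, sep = "\r")
  }
  o <- order(key, sites$pos)
  s <- sites[o, , drop = FALSE]
  k <- key[o]
  new_chain <- c(TRUE, k[-1L] != k[-length(k)] | diff(s$pos) > max_gap)
  chain <- cumsum(new_chain)
  reads <- as.vector(rowsum(s$reads, chain, reorder = FALSE))
  # representative: highest reads, ties -> smallest position
  po <- order(chain, -s$reads, s$pos)
  rep_rows <- po[!duplicated(chain[po])]
  out <- s[rep_rows, , drop = FALSE]
  out$reads <- reads
  out <- out[order(out$chrom, out$pos, out$sample_id, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag clonally expanded insertions
#'
#' Returns the RISs whose read count reaches the clonal-expansion
#' threshold (100 reads in the screen's analysis), together with
#' per-sample counts of expanded RISs.
#'
#' @param sites insertion-site data.frame.
#' @param threshold minimum read count, inclusive; must be >= 1.
#' @return list with `expanded` (subset of `sites`) and `per_sample`
#'   (data.frame `sample_id, n_expanded`, covering all samples present).
#' @export
flag_expanded <- function(sites, threshold = 100) {
  sites <- validate_sites(sites)
  if (threshold < 1) stop_field("threshold must be >= 1")
  keep <- sites$reads >= threshold
  expanded <- sites[keep, , drop = FALSE]
  rownames(expanded) <- NULL
  samples <- sort(unique(sites$sample_id))
  counts <- table(factor(expanded$sample_id, levels = samples))
  list(
    expanded = expanded,
    per_sample = data.frame(sample_id = samples,
                            n_expanded = as.integer(counts),
                            row.names = NULL)
  )
}

#' Per-CIS member summaries (insertions, samples, mean reads per RIS)
#'
#' Recomputes, for every CIS, the number of member insertions, the number
#' of distinct tumours contributing, and the arithmetic mean read count
#' per member RIS.
#'
#' @param cis a `cis_set` (or any data.frame with a `members` list-column
#'   of row indices into `sites`).
#' @param sites the cohort the CIS members index into.
#' @return data.frame `cis_id, n_insertions, n_samples, mean_reads`.
#' @export
cis_member_stats <- function(cis, sites) {
  if (nrow(cis) == 0) {
    return(data.frame(cis_id = character(0), n_insertions = integer(0),
                      n_samples = integer(0), mean_reads = numeric(0)))
  }
  if (any(lengths(cis$members) == 0)) stop_field("CIS with no members")
  data.frame(
    cis_id = cis$cis_id,
    n_insertions = lengths(cis$members),
    n_samples = vapply(cis$members, function(i) length(unique(sites$sample_id[i])), 0L),
    mean_reads = vapply(cis$members, function(i) mean(sites$reads[i]), 0),
    row.names = NULL
  )
}

#' Classify insertions as CIS members, gene-proximal, or passengers
#'
#' A passenger is operationally an isolated RIS far from any annotated
#' gene: not a member of any called CIS and more than `max_gene_distance`
#' bp from every gene interval.
#'
#' @param sites insertion-site data.frame.
#' @param cis a `cis_set` called on `sites` (member indices refer to rows
#'   of `sites`).
#' @param genome [genome_model()] with `genes` annotation.
#' @param max_gene_distance distance (bp) to a gene interval, inclusive,
#'   within which a non-CIS insertion is labelled `near_gene`.
#' @return character vector of labels (`cis_member`, `near_gene`,
#'   `passenger`), one per row of `sites`.
#' @export
classify_passengers <- function(sites, cis, genome, max_gene_distance = 100000) {
  sites <- validate_sites(sites, genome)
  if (is.null(genome$genes)) stop_field("genome has no gene annotation")
  labels <- rep("passenger", nrow(sites))
  in_cis <- unique(unlist(cis$members))
  labels[in_cis] <- "cis_member"
  rest <- which(labels == "passenger")
  for (chr in unique(sites$chrom[rest])) {
    g <- genome$genes[genome$genes$chrom == chr, , drop = FALSE]
    rows <- rest[sites$chrom[rest] == chr]
    if (nrow(g) == 0) next
    m <- merge_closed(g$start, g$end)
    d <- point_interval_distance(sites$pos[rows], m$start, m$end)
    labels[rows[d <= max_gene_distance]] <- "near_gene"
  }
  labels
}
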