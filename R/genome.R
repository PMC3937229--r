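#' Genome model: chromosome lengths plus optional gene annotation
#'
#' A light container describing the reference genome an insertion cohort
#' was mapped to: named chromosome lengths, and optionally a table of
#' transcription start sites (TSS) and gene intervals used by the
#' TSS-distance and passenger-classification operations.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp),
#'   all positive.
#' @param tss optional data.frame with columns `gene_id`, `chrom`,
#'   `tss_pos` (1-based) and `gene_strand` (`"+"`/`"-"`).
#' @param genes optional data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (1-based, closed).
#' @return an object of class `genome_model`.
#' @examples
#' gm <- genome_model(c(chr1 = 1e6, chr2 = 5e5))
#' gm
#' @export
genome_model <- function(chrom_lengths, tss = NULL, genes = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop_field("chrom_lengths must be a named vector")
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop_field("duplicated chromosome names in chrom_lengths")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop_field("all chromosome lengths must be positive and finite")
  }
  if (!is.null(tss)) {
    need <- c("gene_id", "chrom", "tss_pos", "gene_strand")
    if (!all(need %in% names(tss))) {
      stop_field("tss table must have columns %s", paste(need, collapse = ", "))
    }
    bad <- !tss$chrom %in% names(chrom_lengths)
    if (any(bad)) stop_field("TSS on unknown chromosome: %s", tss$chrom[which(bad)[1]])
    if (any(tss$tss_pos < 1 | tss$tss_pos > chrom_lengths[tss$chrom])) {
      stop_field("TSS position outside its chromosome")
    }
    if (!all(tss$gene_strand %in% c("+", "-"))) {
      stop_field("gene_strand must be '+' or '-'")
    }
    tss <- tss[order(tss$chrom, tss$tss_pos, tss$gene_id), , drop = FALSE]
    rownames(tss) <- NULL
  }
  if (!is.null(genes)) {
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(genes))) {
      stop_field("genes table must have columns %s", paste(need, collapse = ", "))
    }
    if (any(genes$start > genes$end)) stop_field("gene start > end")
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(
    list(chrom_lengths = chrom_lengths, tss = tss, genes = genes),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "genome_model: %d chromosomes, %.1f Mb total%s%s\n",
    length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
    if (!is.null(x$tss)) sprintf(", %d TSS", nrow(x$tss)) else "",
    if (!is.null(x$genes)) sprintf(", %d gene intervals", nrow(x$genes)) else ""
  ))
  invisible(x)
}

#' mm9-sized mouse genome model
#'
#' Chromosome lengths of the mouse mm9 assembly (chr1-chr19, chrX), the
#' reference the MoMLV screen data were mapped to. No annotation is
#' attached; supply a TSS table with [read_tss_table()] when needed.
#'
#' @return a [genome_model()].
#' @export
mm9_genome <- function() {
  genome_model(c(
    chr1 = 197195432, chr2 = 181748087, chr3 = 159599783, chr4 = 155630120,
    chr5 = 152537259, chr6 = 149517037, chr7 = 152524553, chr8 = 131738871,
    chr9 = 124076172, chr10 = 129993255, chr11 = 121843856, chr12 = 121257530,
    chr13 = 120284312, chr14 = 125194864, chr15 = 103494974, chr16 = 98319150,
    chr17 = 95272651, chr18 = 90772031, chr19 = 61342430, chrX = 166650296
  ))
}

genome_size <- function(genome) sum(genome$chrom_lengths)

# draw n positions uniformly over the genome (chromosome prob ~ length);
# returns a data.frame(chrom, pos) in draw order
uniform_positions <- function(n, genome) {
  len <- genome$chrom_lengths
  cum <- cumsum(len)
  u <- runif(n) * cum[length(cum)]
  ci <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
  ci <- pmin(pmax(ci, 1L), length(len))
  off <- c(0, cum[-length(cum)])
  pos <- floor(u - off[ci]) + 1
  pos <- pmin(pos, len[ci])
  data.frame(chrom = names(len)[ci], pos = as.numeric(pos))
}
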