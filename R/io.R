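# BED and table I/O. Point insertion sites are 1-based internally;
# intervals are 1-based closed (the IRanges convention); BED files are
# 0-based half-open and conversion happens only at this boundary.

SITE_COLS <- c("chrom", "pos", "strand", "sample_id", "genotype", "reads")

validate_sites <- function(sites, genome = NULL) {
  miss <- setdiff(setdiff(SITE_COLS, "genotype"), names(sites))
  if (length(miss)) stop_field("missing site columns: %s", paste(miss, collapse = ", "))
  if (!"genotype" %in% names(sites)) sites$genotype <- NA_character_
  if (any(sites$pos < 1)) stop_field("insertion position < 1")
  if (any(sites$reads < 1)) stop_field("read counts must be >= 1")
  if (any(sites$reads != round(sites$reads))) stop_field("read counts must be integer")
  if (!all(sites$strand %in% c("+", "-"))) stop_field("strand must be '+' or '-'")
  if (!is.null(genome)) {
    unknown <- !sites$chrom %in% names(genome$chrom_lengths)
    if (any(unknown)) {
      stop_field("site on unknown chromosome '%s'", sites$chrom[which(unknown)[1]])
    }
    over <- sites$pos > genome$chrom_lengths[sites$chrom]
    if (any(over)) {
      stop_field("site position beyond chromosome end (row %d)", which(over)[1])
    }
  }
  sites[, SITE_COLS]
}

#' Read mapped retroviral insertion sites from a BED6 file
#'
#' Each row is one unique insertion site: `chrom, start, end, name,
#' score, strand` where `name` carries the tumour/sample identity,
#' `score` the read count and `strand` the provirus orientation relative
#' to the reference + strand. BED starts are 0-based and are converted to
#' 1-based positions.
#'
#' @param path file path.
#' @param genome a [genome_model()]; rows on chromosomes absent from it
#'   are an error unless `ignore_unplaced = TRUE`, in which case they are
#'   dropped with a warning.
#' @param name_dialect `"sample"` for plain sample names, or
#'   `"sample_extra"` when names are `sample|genotype` (the extra field is
#'   stored in the `genotype` column).
#' @param ignore_unplaced drop rows on unknown chromosomes instead of
#'   erroring.
#' @return data.frame with columns `chrom, pos, strand, sample_id,
#'   genotype, reads`.
#' @export
read_ris_bed <- function(path, genome,
                         name_dialect = c("sample", "sample_extra"),
                         ignore_unplaced = FALSE) {
  name_dialect <- match.arg(name_dialect)
  raw <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    return(validate_sites(data.frame(
      chrom = character(0), pos = numeric(0), strand = character(0),
      sample_id = character(0), genotype = NA_character_[0], reads = numeric(0)
    )))
  }
  if (ncol(raw) < 6) stop_field("BED file must have >= 6 columns: %s", path)
  names(raw)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  for (col in c("start", "end", "score")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      stop_field("malformed BED row at line %d of %s (non-numeric %s)",
                 which(is.na(v))[1], path, col)
    }
    raw[[col]] <- v
  }
  if (any(raw$start < 0)) {
    stop_field("negative BED start at line %d of %s", which(raw$start < 0)[1], path)
  }
  if (any(raw$end <= raw$start)) {
    stop_field("BED end <= start at line %d of %s",
               which(raw$end <= raw$start)[1], path)
  }
  if (ignore_unplaced) {
    unk <- !raw$chrom %in% names(genome$chrom_lengths)
    if (any(unk)) {
      warning(sprintf("dropping %d rows on unplaced chromosomes", sum(unk)))
      raw <- raw[!unk, , drop = FALSE]
    }
  }
  name <- as.character(raw$name)
  if (name_dialect == "sample_extra") {
    parts <- strsplit(name, "|", fixed = TRUE)
    sample_id <- vapply(parts, `[[`, "", 1L)
    genotype <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_, "")
  } else {
    sample_id <- name
    genotype <- rep(NA_character_, nrow(raw))
  }
  sites <- data.frame(
    chrom = as.character(raw$chrom), pos = raw$start + 1,
    strand = as.character(raw$strand), sample_id = sample_id,
    genotype = genotype, reads = raw$score,
    stringsAsFactors = FALSE
  )
  validate_sites(sites, genome)
}

#' Write insertion sites as BED6
#'
#' Inverse of [read_ris_bed()]: positions become 0-based single-base
#' intervals, the name field is `sample_id` (or `sample_id|genotype` when
#' any genotype is recorded) and the score field is the read count.
#' Output is sorted by (chrom, start) for reproducibility.
#'
#' @param sites insertion-site data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ris_bed <- function(sites, path) {
  sites <- validate_sites(sites)
  sites <- sites[order(sites$chrom, sites$pos, sites$sample_id, sites$strand), ]
  name <- if (any(!is.na(sites$genotype))) {
    paste(sites$sample_id, ifelse(is.na(sites$genotype), "", sites$genotype), sep = "|")
  } else {
    sites$sample_id
  }
  bed <- data.frame(
    chrom = sites$chrom, start = format(sites$pos - 1, scientific = FALSE, trim = TRUE),
    end = format(sites$pos, scientific = FALSE, trim = TRUE),
    name = name, score = sites$reads, strand = sites$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write called CISs as BED + TSV
#'
#' Writes `<prefix>.bed` with the CIS extents (0-based half-open) and
#' `<prefix>.tsv` with peak position, peak height, kernel scale and
#' member counts. An empty CIS set yields a header-only TSV and an empty
#' BED.
#'
#' @param cis a `cis_set` as returned by [call_cis()].
#' @param path_prefix output path prefix.
#' @return named character vector of the two paths, invisibly.
#' @export
write_cis_outputs <- function(cis, path_prefix) {
  tsv_cols <- c("cis_id", "chrom", "start", "end", "peak_pos", "peak_height",
                "scale", "n_insertions", "n_samples")
  bed_path <- paste0(path_prefix, ".bed")
  tsv_path <- paste0(path_prefix, ".tsv")
  if (is.null(cis) || nrow(cis) == 0) {
    file.create(bed_path)
    write.table(as.data.frame(setNames(rep(list(character(0)), length(tsv_cols)), tsv_cols)),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(c(bed = bed_path, tsv = tsv_path)))
  }
  cis <- cis[order(cis$chrom, cis$start), , drop = FALSE]
  bed <- data.frame(
    chrom = cis$chrom,
    start = format(cis$start - 1, scientific = FALSE, trim = TRUE),
    end = format(cis$end, scientific = FALSE, trim = TRUE),
    name = cis$cis_id, score = cis$n_insertions, strand = "."
  )
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tsv <- as.data.frame(cis)[, tsv_cols]
  write.table(format(tsv, scientific = FALSE, trim = TRUE, digits = 15),
              tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read a CIS table written by [write_cis_outputs()]
#'
#' @param path path to the `.tsv` file.
#' @return data.frame of CIS summaries (without member lists).
#' @export
read_cis_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  num <- c("start", "end", "peak_pos", "peak_height", "scale",
           "n_insertions", "n_samples")
  for (col in intersect(num, names(out))) out[[col]] <- as.numeric(out[[col]])
  out
}

#' Read a BED file of genomic regions
#'
#' Intervals are converted from BED (0-based half-open) to 1-based closed
#' coordinates and sorted per chromosome. Overlapping intervals are kept
#' as-is; downstream consumers resolve overlap.
#'
#' @param path file path.
#' @param genome optional [genome_model()] used to validate chromosomes.
#' @param name label for the set.
#' @return data.frame `chrom, start, end` of class `region_set`.
#' @export
read_regions_bed <- function(path, genome = NULL, name = basename(path)) {
  raw <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  } else {
    if (ncol(raw) < 3) stop_field("region BED must have >= 3 columns")
    out <- data.frame(chrom = as.character(raw[[1]]),
                      start = as.numeric(raw[[2]]) + 1,
                      end = as.numeric(raw[[3]]),
                      stringsAsFactors = FALSE)
    if (any(out$start > out$end)) stop_field("region with start > end")
    if (!is.null(genome)) {
      unk <- !out$chrom %in% names(genome$chrom_lengths)
      if (any(unk)) stop_field("region on unknown chromosome '%s'",
                               out$chrom[which(unk)[1]])
      if (any(out$end > genome$chrom_lengths[out$chrom])) {
        stop_field("region extends beyond chromosome end")
      }
    }
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, name = name, class = c("region_set", "data.frame"))
}

#' Write regions as BED3 (1-based closed back to 0-based half-open)
#' @param regions region data.frame with `chrom, start, end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Tab-separated with header columns `gene_id, chrom, tss_pos,
#' gene_strand` (1-based TSS positions).
#'
#' @param path file path.
#' @return data.frame suitable for the `tss` slot of [genome_model()].
#' @export
read_tss_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss_pos", "gene_strand")
  if (!all(need %in% names(out))) {
    stop_field("TSS table needs header columns %s", paste(need, collapse = ", "))
  }
  out$tss_pos <- as.numeric(out$tss_pos)
  out
}

#' Read gene-set definitions
#'
#' One set per line: `set_name<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a set are deduplicated with a warning; an empty file gives an
#' empty list.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_genesets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop_field("duplicated gene-set name '%s'", nm[duplicated(nm)][1])
  sets <- lapply(parts, function(p) p[-1L][nzchar(p[-1L])])
  dup <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    warning(sprintf("duplicate genes within set(s): %s (deduplicated)",
                    paste(nm[dup], collapse = ", ")))
    sets <- lapply(sets, unique)
  }
  setNames(sets, nm)
}
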