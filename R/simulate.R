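# Synthetic integration-cohort generator with a planted-truth table.
# The generator emulates the structure the analysis assumes: a
# TSS-preferential background of gamma-retroviral integration, driver
# loci under oncogenic selection with orientation bias and clonal
# expansion, passenger insertions co-amplified with their clone, and
# optional genotype-restricted drivers.

#' Simulation configuration
#'
#' @param chrom_lengths named chromosome lengths (default: mm9-sized).
#' @param n_genes number of annotated genes (TSS drawn uniformly).
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene length
#'   parameters (bp).
#' @param n_samples number of tumours.
#' @param genotypes genotype label per sample (length `n_samples`).
#' @param background_per_sample background insertions per sample.
#' @param tss_weight mixture weight `w` of the TSS-directed background
#'   component (in `[0, 1]`).
#' @param tss_decay double-exponential (Laplace) offset scale around the
#'   chosen TSS, bp.
#' @param drivers data.frame with one row per driver locus:
#'   `driver_id, chrom, locus, window, orientation_prob, selection_prob,
#'   genotype` (`NA` = unrestricted). `orientation_prob` is the
#'   probability of forward orientation; `selection_prob` the per-sample
#'   probability that the driver is hit and clonally selected.
#' @param passenger_rate Poisson mean of passenger insertions carried by
#'   each selected clone (placed uniformly, sharing the clone's read
#'   count).
#' @param bg_read_p geometric parameter of background read counts
#'   (support 1-`bg_read_max`).
#' @param bg_read_max cap on background reads (below the expansion
#'   threshold).
#' @param exp_read_meanlog,exp_read_sdlog log-normal parameters of the
#'   clonal-expansion read counts added on top of `exp_read_floor`.
#' @param exp_read_floor minimum reads of an expanded clone.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = mm9_genome()$chrom_lengths,
                       n_genes = 20000,
                       gene_length_meanlog = log(20000),
                       gene_length_sdlog = 0.8,
                       n_samples = 28,
                       genotypes = rep("double_tg", n_samples),
                       background_per_sample = 407,
                       tss_weight = 0.25,
                       tss_decay = 10000,
                       drivers = NULL,
                       passenger_rate = 0.12,
                       bg_read_p = 0.25,
                       bg_read_max = 99,
                       exp_read_meanlog = log(400),
                       exp_read_sdlog = 1.2,
                       exp_read_floor = 100,
                       seed = 1) {
  if (is.null(seed)) stop_field("seed is mandatory")
  if (tss_weight < 0 || tss_weight > 1) stop_field("tss_weight must be in [0, 1]")
  if (length(genotypes) != n_samples) {
    stop_field("genotypes must have length n_samples")
  }
  if (is.null(drivers)) {
    drivers <- default_driver_table(chrom_lengths)
  }
  need <- c("driver_id", "chrom", "locus", "window", "orientation_prob",
            "selection_prob", "genotype")
  if (!all(need %in% names(drivers))) {
    stop_field("drivers must have columns %s", paste(need, collapse = ", "))
  }
  if (any(!drivers$chrom %in% names(chrom_lengths)) ||
      any(drivers$locus < 1 | drivers$locus > chrom_lengths[drivers$chrom])) {
    stop_field("driver locus outside genome")
  }
  if (any(drivers$orientation_prob < 0.5 | drivers$orientation_prob > 1)) {
    stop_field("orientation_prob must be in [0.5, 1]")
  }
  if (any(drivers$selection_prob < 0 | drivers$selection_prob > 1)) {
    stop_field("selection_prob must be in [0, 1]")
  }
  structure(list(
    chrom_lengths = chrom_lengths, n_genes = n_genes,
    gene_length_meanlog = gene_length_meanlog,
    gene_length_sdlog = gene_length_sdlog,
    n_samples = n_samples, genotypes = genotypes,
    background_per_sample = background_per_sample,
    tss_weight = tss_weight, tss_decay = tss_decay, drivers = drivers,
    passenger_rate = passenger_rate, bg_read_p = bg_read_p,
    bg_read_max = bg_read_max, exp_read_meanlog = exp_read_meanlog,
    exp_read_sdlog = exp_read_sdlog, exp_read_floor = exp_read_floor,
    seed = seed
  ), class = "sim_config")
}

# deterministic driver placement: loci spread over chromosomes
# proportionally to length, at evenly spaced quantile positions, with a
# 60/40 mix of enhancer-mode (orientation_prob 0.9) and unbiased (0.5)
# drivers interleaved across the genome
default_driver_table <- function(chrom_lengths, n_drivers = 50,
                                 window = 10000, selection_prob = 0.7) {
  cum <- cumsum(as.numeric(chrom_lengths))
  alloc <- diff(c(0, round(cum / cum[length(cum)] * n_drivers)))
  rows <- list()
  for (ci in seq_along(chrom_lengths)) {
    k <- alloc[ci]
    if (k == 0) next
    pos <- round(seq_len(k) / (k + 1) * chrom_lengths[[ci]])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = names(chrom_lengths)[ci], locus = pos
    )
  }
  d <- do.call(rbind, rows)
  n <- nrow(d)
  d$driver_id <- sprintf("drv%02d", seq_len(n))
  d$window <- window
  d$orientation_prob <- ifelse(seq_len(n) %% 5 %in% c(1, 2, 3), 0.9, 0.5)
  d$selection_prob <- selection_prob
  d$genotype <- NA_character_
  d[, c("driver_id", "chrom", "locus", "window", "orientation_prob",
        "selection_prob", "genotype")]
}

#' Default screen-sized simulation configuration
#'
#' A cohort of the size and composition of a deep-sequenced MoMLV
#' progression screen: 28 tumours on an mm9-sized genome, about 12,485
#' insertions in total, a TSS-preferential background, and 50 driver
#' loci under selection of which 60% are enhancer-mode (orientation
#' probability 0.9) and 40% unbiased (0.5).
#'
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
default_screen_config <- function(seed = 1) {
  sim_config(seed = seed)
}

rlaplace <- function(n, scale) {
  (2 * (runif(n) < 0.5) - 1) * rexp(n, rate = 1 / scale)
}

#' Simulate an integration cohort with planted truth
#'
#' Background insertions are TSS-directed with probability `tss_weight`
#' (double-exponential offset of scale `tss_decay` around a uniformly
#' chosen TSS) and uniform otherwise, with fair-coin strands and read
#' counts below the expansion floor. For each sample and each driver
#' compatible with the sample's genotype, with probability
#' `selection_prob` a clonally expanded insertion is planted uniformly
#' within the driver window, forward-oriented with probability
#' `orientation_prob`, with reads at or above the expansion floor; the
#' clone also carries a Poisson number of passenger insertions at
#' uniform positions sharing its read count. Deterministic for a fixed
#' seed.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list of class `sim_cohort`: `sites` (insertion-site
#'   data.frame), `truth` (row-aligned data.frame `role, driver_id,
#'   clone_id` with a `drivers` attribute summarising planted drivers),
#'   `genome` (a [genome_model()] with simulated TSS/gene annotation) and
#'   `config`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  genome0 <- genome_model(config$chrom_lengths)
  with_seed(seed, {
    # annotation
    gp <- uniform_positions(config$n_genes, genome0)
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    glen <- pmax(200, round(rlnorm(config$n_genes, config$gene_length_meanlog,
                                   config$gene_length_sdlog)))
    lens <- config$chrom_lengths[gp$chrom]
    gstart <- ifelse(strand == "+", gp$pos, pmax(1, gp$pos - glen + 1))
    gend <- ifelse(strand == "+", pmin(lens, gp$pos + glen - 1), gp$pos)
    tss <- data.frame(gene_id = sprintf("gene%05d", seq_len(config$n_genes)),
                      chrom = gp$chrom, tss_pos = gp$pos, gene_strand = strand)
    genes <- data.frame(gene_id = tss$gene_id, chrom = gp$chrom,
                        start = gstart, end = gend)
    genome <- genome_model(config$chrom_lengths, tss = tss, genes = genes)

    # background
    nb <- config$n_samples * config$background_per_sample
    sample_ids <- sprintf("T%02d", seq_len(config$n_samples))
    bg_sample <- rep(sample_ids, each = config$background_per_sample)
    near_tss <- runif(nb) < config$tss_weight
    u <- uniform_positions(nb, genome0)
    chrom <- u$chrom
    pos <- u$pos
    if (any(near_tss)) {
      gi <- sample.int(config$n_genes, sum(near_tss), replace = TRUE)
      off <- round(rlaplace(sum(near_tss), config$tss_decay))
      chrom[near_tss] <- tss$chrom[gi]
      pos[near_tss] <- pmin(pmax(tss$tss_pos[gi] + off, 1),
                            config$chrom_lengths[tss$chrom[gi]])
    }
    bg <- data.frame(
      chrom = chrom, pos = pos,
      strand = sample(c("+", "-"), nb, replace = TRUE),
      sample_id = bg_sample,
      genotype = rep(config$genotypes, each = config$background_per_sample),
      reads = pmin(config$bg_read_max, 1 + rgeom(nb, config$bg_read_p))
    )
    bg_truth <- data.frame(role = rep("background", nb),
                           driver_id = NA_character_, clone_id = NA_character_)

    # drivers and their passengers
    drv <- config$drivers
    grid <- expand.grid(sample = seq_len(config$n_samples),
                        driver = seq_len(nrow(drv)))
    eligible <- is.na(drv$genotype[grid$driver]) |
      drv$genotype[grid$driver] == config$genotypes[grid$sample]
    hit <- eligible & runif(nrow(grid)) < drv$selection_prob[grid$driver]
    gi <- grid[hit, , drop = FALSE]
    ndrv <- nrow(gi)
    if (ndrv > 0) {
      w <- drv$window[gi$driver]
      lens_d <- config$chrom_lengths[drv$chrom[gi$driver]]
      dpos <- drv$locus[gi$driver] +
        floor(runif(ndrv, -w, w + 1))
      dpos <- pmin(pmax(dpos, 1), lens_d)
      dreads <- config$exp_read_floor +
        round(rlnorm(ndrv, config$exp_read_meanlog, config$exp_read_sdlog))
      clone <- sprintf("%s_%s", sample_ids[gi$sample], drv$driver_id[gi$driver])
      dsites <- data.frame(
        chrom = drv$chrom[gi$driver], pos = dpos,
        strand = ifelse(runif(ndrv) < drv$orientation_prob[gi$driver], "+", "-"),
        sample_id = sample_ids[gi$sample],
        genotype = config$genotypes[gi$sample],
        reads = dreads
      )
      d_truth <- data.frame(role = rep("driver", ndrv),
                            driver_id = drv$driver_id[gi$driver],
                            clone_id = clone)
      npass <- rpois(ndrv, config$passenger_rate)
      pi <- rep(seq_len(ndrv), npass)
      np <- length(pi)
      if (np > 0) {
        pu <- uniform_positions(np, genome0)
        psites <- data.frame(
          chrom = pu$chrom, pos = pu$pos,
          strand = sample(c("+", "-"), np, replace = TRUE),
          sample_id = dsites$sample_id[pi],
          genotype = dsites$genotype[pi],
          reads = dsites$reads[pi]
        )
        p_truth <- data.frame(role = rep("passenger", np),
                              driver_id = d_truth$driver_id[pi],
                              clone_id = d_truth$clone_id[pi])
      } else {
        psites <- dsites[0, ]
        p_truth <- d_truth[0, ]
      }
      sites <- rbind(bg, dsites, psites)
      truth <- rbind(bg_truth, d_truth, p_truth)
    } else {
      sites <- bg
      truth <- bg_truth
    }
    rownames(sites) <- rownames(truth) <- NULL
    planted <- truth$role == "driver"
    carriers <- split(sites$sample_id[planted], truth$driver_id[planted])
    drv$n_planted <- vapply(drv$driver_id, function(id) {
      length(carriers[[id]] %||% character(0))
    }, 0L)
    drv$samples <- lapply(drv$driver_id, function(id) {
      unique(carriers[[id]] %||% character(0))
    })
    attr(truth, "drivers") <- drv
    structure(list(sites = validate_sites(sites, genome), truth = truth,
                   genome = genome, config = config),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d insertions in %d samples (%d driver, %d passenger, %d background)\n",
    nrow(x$sites), length(unique(x$sites$sample_id)),
    sum(x$truth$role == "driver"), sum(x$truth$role == "passenger"),
    sum(x$truth$role == "background")
  ))
  invisible(x)
}

#' Score CIS calls against the planted truth
#'
#' Sensitivity is the fraction of drivers with at least two planted
#' insertions that are recovered by a called CIS: the CIS extent
#' contains the driver locus or at least one of the driver's planted
#' insertions (extents track the dense subcluster, which can sit
#' slightly off the window centre). The false-CIS rate is the fraction
#' of called CISs containing no planted driver insertion. When orientation results are supplied, the biased-CIS set
#' (q < `q_cut`) is scored against drivers with orientation probability
#' above 0.5: recall over enhancer-mode drivers with a called CIS,
#' false-flag rate over unbiased drivers with a called CIS, and
#' precision of the biased set.
#'
#' @param cis a `cis_set` called on the simulated cohort.
#' @param cohort a `sim_cohort`.
#' @param orientation optional `orientation_result` for `cis`.
#' @param q_cut biased-set cutoff (strict) on q.
#' @return list of scores (see Details).
#' @export
score_recovery <- function(cis, cohort, orientation = NULL, q_cut = 0.05) {
  stopifnot(inherits(cohort, "sim_cohort"))
  drv <- attr(cohort$truth, "drivers")
  if (any(!cis$chrom %in% names(cohort$genome$chrom_lengths))) {
    stop_field("CIS chromosomes do not match the simulated genome")
  }
  eligible <- drv[drv$n_planted >= 2, , drop = FALSE]
  locus_in_cis <- function(chr, pos) {
    any(cis$chrom == chr & cis$start <= pos & cis$end >= pos)
  }
  dsites <- cohort$sites[cohort$truth$role == "driver", , drop = FALSE]
  dsites$driver_id <- cohort$truth$driver_id[cohort$truth$role == "driver"]
  recovered <- vapply(seq_len(nrow(eligible)), function(i) {
    if (locus_in_cis(eligible$chrom[i], eligible$locus[i])) return(TRUE)
    mine <- dsites[dsites$driver_id == eligible$driver_id[i], , drop = FALSE]
    any(vapply(seq_len(nrow(mine)), function(j) {
      locus_in_cis(mine$chrom[j], mine$pos[j])
    }, TRUE))
  }, TRUE)
  sens <- if (nrow(eligible)) mean(recovered) else NA_real_
  has_driver <- vapply(seq_len(nrow(cis)), function(i) {
    any(dsites$chrom == cis$chrom[i] & dsites$pos >= cis$start[i] &
          dsites$pos <= cis$end[i])
  }, TRUE)
  false_rate <- if (nrow(cis)) mean(!has_driver) else NA_real_
  out <- list(sensitivity = sens, false_cis_rate = false_rate,
              n_eligible_drivers = nrow(eligible), n_called = nrow(cis))
  if (!is.null(orientation)) {
    flagged_ids <- biased_cis_set(orientation, q_cut)$cis_id
    cis_of_driver <- vapply(seq_len(nrow(drv)), function(i) {
      j <- which(cis$chrom == drv$chrom[i] & cis$start <= drv$locus[i] &
                   cis$end >= drv$locus[i])
      if (length(j)) return(cis$cis_id[j[1]])
      mine <- dsites[dsites$driver_id == drv$driver_id[i], , drop = FALSE]
      if (nrow(mine) == 0) return(NA_character_)
      hits <- vapply(seq_len(nrow(cis)), function(k) {
        sum(mine$chrom == cis$chrom[k] & mine$pos >= cis$start[k] &
              mine$pos <= cis$end[k])
      }, 0L)
      if (any(hits > 0)) cis$cis_id[which.max(hits)] else NA_character_
    }, "")
    detected <- !is.na(cis_of_driver)
    is_flagged <- cis_of_driver %in% flagged_ids
    enh <- detected & drv$orientation_prob > 0.5
    unb <- detected & drv$orientation_prob == 0.5
    out$biased_recall <- if (any(enh)) mean(is_flagged[enh]) else NA_real_
    out$biased_false_flag <- if (any(unb)) mean(is_flagged[unb]) else NA_real_
    driver_cis <- cis_of_driver[detected & drv$orientation_prob > 0.5]
    out$biased_precision <- if (length(flagged_ids)) {
      mean(flagged_ids %in% driver_cis)
    } else {
      NA_real_
    }
  }
  out
}
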