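# End-to-end orchestration: simulate (or load) -> merge -> call-cis ->
# orientation -> saturation, driven by one config and one seed, with a
# machine-readable report.

#' Ranked CIS table
#'
#' CISs sorted by number of member insertions (descending), ties broken
#' by higher mean reads per RIS, then by coordinate; columns are
#' recomputed from the member lists.
#'
#' @param sites the cohort.
#' @param cis a `cis_set`.
#' @param top_n number of rows to keep (>= 1).
#' @return data.frame `cis_id, chrom, start, end, n_insertions,
#'   n_samples, mean_reads`.
#' @export
report_rank_table <- function(sites, cis, top_n = 25) {
  if (top_n < 1) stop_field("top_n must be >= 1")
  stats <- cis_member_stats(cis, sites)
  out <- data.frame(cis_id = cis$cis_id, chrom = cis$chrom,
                    start = cis$start, end = cis$end,
                    n_insertions = stats$n_insertions,
                    n_samples = stats$n_samples,
                    mean_reads = stats$mean_reads)
  o <- order(-out$n_insertions, -out$mean_reads, out$chrom, out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_n)
}

pipeline_stages <- c("simulate", "merge", "call_cis", "orientation",
                     "saturation", "rank_table")

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_field("config file not found: %s", config)
    cfg <- yaml::read_yaml(config)
    cfg$config_hash <- unname(tools::md5sum(config))
    cfg
  } else if (is.list(config)) {
    config
  } else {
    stop_field("config must be a file path or a list")
  }
}

#' Run the full screen-analysis pipeline from a config
#'
#' Stages run in dependency order; each stage's randomness is derived
#' from the single top-level `seed`, so two runs with the same config
#' are identical. The config is a list (or YAML file) with fields:
#' `seed` (required); `stages` (subset of `simulate, merge, call_cis,
#' orientation, saturation, rank_table`); `input` (`bed` path and
#' `genome` chromosome lengths, when not simulating); `simulate`
#' (overrides for [sim_config()]); `merge` (`max_gap`); `gkc` (overrides
#' for [gkc_config()]); `orientation` (`q_cut`); `saturation`
#' (`half_width`, `max_combos`, `control`); `rank_table` (`top_n`).
#'
#' @param config list or path to a YAML file.
#' @param out_dir optional directory for the report (`report.json`) and
#'   TSV/BED sidecars.
#' @return the report, a named list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$seed)) stop_field("config field 'seed' is required")
  stages <- cfg$stages %||% pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop_field("unknown stage '%s'", bad[1])
  report <- list(
    package = "cisSelect",
    version = as.character(packageVersion("cisSelect")),
    seed = cfg$seed,
    config_hash = cfg$config_hash %||% NA_character_,
    stages = stages
  )

  cohort <- NULL
  genome <- NULL
  sim <- NULL
  if ("simulate" %in% stages) {
    sc_args <- cfg$simulate %||% list()
    if (!is.null(sc_args$chrom_lengths)) {
      sc_args$chrom_lengths <- unlist(sc_args$chrom_lengths)
    }
    if (!is.null(sc_args$drivers) && !is.data.frame(sc_args$drivers)) {
      sc_args$drivers <- as.data.frame(sc_args$drivers)
    }
    sc_args$seed <- derive_seed(cfg$seed, 1L)
    sc <- do.call(sim_config, sc_args)
    sim <- simulate_cohort(sc)
    cohort <- sim$sites
    genome <- sim$genome
    report$simulate <- list(
      n_sites = nrow(cohort),
      n_samples = length(unique(cohort$sample_id)),
      n_drivers = nrow(sc$drivers),
      seed = sc$seed
    )
  } else {
    if (is.null(cfg$input$bed) || is.null(cfg$input$genome)) {
      stop_field("stage needs an upstream cohort: provide input$bed and input$genome or add the simulate stage")
    }
    genome <- genome_model(unlist(cfg$input$genome))
    cohort <- read_ris_bed(cfg$input$bed, genome,
                           name_dialect = cfg$input$name_dialect %||% "sample")
    report$input <- list(bed = cfg$input$bed, n_sites = nrow(cohort))
  }

  if ("merge" %in% stages) {
    max_gap <- cfg$merge$max_gap %||% 3
    merged <- merge_sites(cohort, max_gap = max_gap,
                          ignore_strand = isTRUE(cfg$merge$ignore_strand))
    report$merge <- list(max_gap = max_gap, n_in = nrow(cohort),
                         n_unique_ris = nrow(merged))
    cohort <- merged
  }

  cis <- NULL
  if ("call_cis" %in% stages) {
    gk_args <- cfg$gkc %||% list()
    gk_args$seed <- gk_args$seed %||% derive_seed(cfg$seed, 2L)
    gk <- do.call(gkc_config, gk_args)
    cis <- call_cis(cohort, genome, gk)
    report$call_cis <- list(
      scales = gk$scales, alpha = gk$alpha, n_null = gk$n_null,
      seed = gk$seed, n_cis = nrow(cis)
    )
  }

  orient <- NULL
  if ("orientation" %in% stages) {
    if (is.null(cis)) stop_field("orientation stage requires call_cis")
    q_cut <- cfg$orientation$q_cut %||% 0.05
    orient <- orientation_test(cis, cohort)
    biased <- biased_cis_set(orient, q_cut)
    report$orientation <- list(
      q_cut = q_cut, n_tested = nrow(orient), n_biased = nrow(biased),
      biased_ids = biased$cis_id,
      p = orient$p, q = orient$q
    )
  }

  if ("saturation" %in% stages) {
    hw <- cfg$saturation$half_width %||% 7500
    mc <- cfg$saturation$max_combos %||% 1000
    sat_seed <- derive_seed(cfg$seed, 3L)
    sat_sites <- cohort
    if (!is.null(cis) && isTRUE(cfg$saturation$cis_members_only %||% TRUE)) {
      mem <- unique(unlist(cis$members))
      if (length(mem) > 0) sat_sites <- cohort[mem, , drop = FALSE]
    }
    curve <- coverage_curve(sat_sites, genome, half_width = hw,
                            max_combos = mc, seed = sat_seed)
    report$saturation <- list(half_width = hw, max_combos = mc,
                              seed = sat_seed,
                              real = as.data.frame(curve))
    if (isTRUE(cfg$saturation$control %||% TRUE)) {
      ctrl <- random_control(sat_sites, genome, half_width = hw,
                             max_combos = mc, seed = sat_seed)
      report$saturation$control <- as.data.frame(ctrl)
    }
  }

  if ("rank_table" %in% stages) {
    if (is.null(cis)) stop_field("rank_table stage requires call_cis")
    top_n <- cfg$rank_table$top_n %||% 25
    report$rank_table <- report_rank_table(cohort, cis, top_n)
  }

  if (!is.null(sim)) {
    report$truth_summary <- list(
      n_driver_insertions = sum(sim$truth$role == "driver"),
      n_passenger_insertions = sum(sim$truth$role == "passenger")
    )
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    write_ris_bed(cohort, file.path(out_dir, "cohort.bed"))
    if (!is.null(cis)) {
      write_cis_outputs(cis, file.path(out_dir, "cis"))
    }
    if (!is.null(orient)) {
      write.table(as.data.frame(orient), file.path(out_dir, "orientation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}
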