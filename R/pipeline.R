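#' Pipeline configuration
#'
#' Bundles either a synthetic-experiment configuration or paths to real
#' inputs with the analysis thresholds. Exactly one of `sim` and `paths`
#' must be given. All thresholds of the analysis are surfaced here; nothing
#' downstream hard-codes them.
#'
#' @param sim An [sim_config()] object, or `NULL`.
#' @param paths Named list of input paths (`expression` = named vector of
#'   per-tissue matrix files, `samples`, `annotation`, and optionally
#'   `escapees`, `branches`), or `NULL`.
#' @param alpha_primary Per-probe threshold of the primary screen.
#' @param alpha_consistency Relaxed threshold of the cross-tissue screen.
#' @param cluster_gap Proximity threshold (bp) for cluster calls.
#' @param min_branch_probes Minimum probes per branch in the age analysis.
#' @param out_dir Optional output directory for tab-delimited reports.
#' @return A `xsexbias_pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            alpha_primary = 0.001,
                            alpha_consistency = 0.01,
                            cluster_gap = 50000,
                            min_branch_probes = 10,
                            out_dir = NULL) {
  if (is.null(sim) == is.null(paths)) {
    abort("exactly one of 'sim' and 'paths' must be set",
          class = "xsexbias_config_error")
  }
  if (alpha_primary <= 0 || alpha_primary >= 1 ||
      alpha_consistency <= 0 || alpha_consistency >= 1) {
    abort("thresholds must lie in (0, 1)", class = "xsexbias_config_error")
  }
  structure(list(sim = sim, paths = paths, alpha_primary = alpha_primary,
                 alpha_consistency = alpha_consistency,
                 cluster_gap = cluster_gap,
                 min_branch_probes = min_branch_probes, out_dir = out_dir),
            class = "xsexbias_pipeline_config")
}

#' Run the full sex-bias analysis pipeline
#'
#' Standardizes each tissue matrix, screens every tissue for sex-biased
#' probes, tabulates bias counts by chromosome class with the three
#' enrichment/depletion contrasts (with and without escapee exclusion),
#' classifies cross-tissue consistency at the relaxed threshold, aggregates
#' to gene-level entries and calls proximity clusters of female-biased
#' entries, and — when a branch table is available — runs the gene-age
#' analysis. With `out_dir` set, every result table is written
#' tab-delimited together with a run log of parameters.
#'
#' @param config A [pipeline_config()].
#' @return Named list: `results`, `counts`, `enrichment`,
#'   `counts_no_escapees`, `enrichment_no_escapees`, `consistency`,
#'   `aggregates`, `clusters`, `report`, `age` (or `NULL`), plus the
#'   inputs used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "xsexbias_pipeline_config"))
  if (!is.null(config$sim)) {
    sim <- simulate_experiment(config$sim)
    tissues <- sim$tissues
    samples <- sim$samples
    ann <- sim$annotation
    escapees <- sim$annotation$gene_symbol[sim$truth$entries$escapee]
    branches <- sim_branch_table(sim)
  } else {
    p <- config$paths
    tissues <- purrr::map(p$expression, read_expression)
    if (is.null(names(tissues))) names(tissues) <- paste0("tissue", seq_along(tissues))
    samples <- read_samples(p$samples)
    ann <- read_annotation(p$annotation)
    escapees <- if (!is.null(p$escapees)) read_escapee_list(p$escapees) else mouse_escapees()
    branches <- if (!is.null(p$branches)) read_branch_table(p$branches) else NULL
    sim <- NULL
  }

  tissues <- purrr::map(tissues, standardize_expression)
  results <- test_experiment(tissues, samples, alpha = config$alpha_primary)
  counts <- tabulate_bias(results, ann, alpha = config$alpha_primary)
  contrasts <- c("XF_vs_XM", "XF_vs_AF", "XM_vs_AM")
  # a degenerate contrast (no biased probes in either class) is reported as
  # NA rather than aborting the run
  run_contrasts <- function(cts) {
    purrr::map_dfr(unique(cts$tissue), function(tis)
      purrr::map_dfr(contrasts, function(cmp)
        tryCatch(tidy(compare_classes(cts, tis, cmp)),
                 xsexbias_degenerate_error = function(e)
                   tibble(comparison = cmp, tissue = tis, n11 = NA_integer_,
                          n12 = NA_integer_, n21 = NA_integer_,
                          n22 = NA_integer_, odds_ratio = NA_real_,
                          p.value = NA_real_,
                          relative_difference = NA_real_))))
  }
  enrichment <- run_contrasts(counts)
  if (length(escapees) == 0) escapees <- "<none>"   # null runs plant none
  res_x <- suppressMessages(exclude_escapees(results, ann, escapees))
  ann_x <- filter(ann, .data$probe_id %in% unique(res_x$probe_id))
  counts_x <- tabulate_bias(res_x, ann_x, alpha = config$alpha_primary)
  enrichment_x <- run_contrasts(counts_x)

  results_weak <- test_experiment(tissues, samples,
                                  alpha = config$alpha_consistency)
  records <- consistent_probes(results_weak, alpha = config$alpha_consistency)
  aggregates <- aggregate_entries(records, ann)
  fem_x <- filter(aggregates, .data$direction == "female", .data$chrom == "X")
  clusters <- find_clusters(fem_x, max_gap = config$cluster_gap)
  report <- table2_report(records, results_weak, ann, aggregates,
                          alpha_strong = config$alpha_primary,
                          alpha_weak = config$alpha_consistency)
  age <- NULL
  if (!is.null(branches) && nrow(branches) > 0) {
    age <- purrr::map(setNames(names(tissues), names(tissues)), function(tis) {
      joined <- join_branches(filter(results, .data$tissue == tis), ann, branches)
      list(joined = joined,
           proportions = branch_proportions(joined,
                                            min_probes = config$min_branch_probes),
           split_female = tryCatch(tidy(age_split_test(joined, "female")),
                                   error = function(e) NULL),
           split_male = tryCatch(tidy(age_split_test(joined, "male")),
                                 error = function(e) NULL))
    })
  }
  out <- list(results = results, counts = counts, enrichment = enrichment,
              counts_no_escapees = counts_x,
              enrichment_no_escapees = enrichment_x,
              consistency = records, aggregates = aggregates,
              clusters = clusters, report = report, age = age,
              samples = samples, annotation = ann, sim = sim,
              config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, file) readr::write_tsv(tbl, file.path(dir, file),
                                            progress = FALSE)
  w(out$results, "results.tsv")
  w(out$counts, "bias_counts.tsv")
  w(out$enrichment, "enrichment.tsv")
  w(out$counts_no_escapees, "bias_counts_no_escapees.tsv")
  w(out$enrichment_no_escapees, "enrichment_no_escapees.tsv")
  flatten_lists <- function(tbl) {
    mutate(tbl, across(dplyr::where(is.list),
                       ~ purrr::map_chr(.x, function(v)
                         paste(format(v), collapse = ","))))
  }
  w(flatten_lists(out$consistency), "consistency.tsv")
  w(flatten_lists(out$aggregates), "aggregates.tsv")
  if (nrow(out$clusters) > 0) write_clusters(out$clusters,
                                             file.path(dir, "clusters.tsv"))
  w(out$report, "table2_style_report.tsv")
  cfg <- out$config
  log_lines <- c(
    sprintf("xsexbias %s", as.character(utils::packageVersion("xsexbias"))),
    sprintf("alpha_primary=%g", cfg$alpha_primary),
    sprintf("alpha_consistency=%g", cfg$alpha_consistency),
    sprintf("cluster_gap=%d", cfg$cluster_gap),
    sprintf("min_branch_probes=%d", cfg$min_branch_probes),
    if (!is.null(cfg$sim)) sprintf("sim_seed=%d", cfg$sim$seed),
    sprintf("derived_class_totals=%s",
            paste(sprintf("%s:%g", names(class_totals()), class_totals()),
                  collapse = ","))
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Recompute the fixture-derived reference numbers
#'
#' Re-runs every analysis that the packaged table fixtures support — the
#' relative-depletion contrasts, the multi-tissue entry counts, the
#' all-six-tissue escapee check and the Kdm5c-cluster call — and compares
#' each to its published value.
#'
#' @return Tibble with columns `check`, `expected`, `observed`, `pass`;
#'   attribute `ok` is `TRUE` when every row passes.
#' @export
fixtures_check <- function() {
  t2a <- load_fixture("table2A")
  t2b <- load_fixture("table2B")
  ann <- fixture_annotation(list(t2a, t2b))
  rec <- bind_rows(
    mutate(consistent_probes(fixture_records(t2a)), direction = "female"),
    mutate(consistent_probes(fixture_records(t2b)), direction = "male"))
  agg <- aggregate_entries(rec, ann)
  cts <- fixture_counts()
  dep <- function(tis) round(-100 * compare_classes(cts, tis, "XM_vs_AM")$relative_difference)
  fem6 <- filter(agg, .data$direction == "female", .data$n_tissues == 6)
  fem6_genes <- sort(unique(fem6$gene_symbol))
  esc_expected <- sort(c("Ddx3x", "Kdm6a", "Eif2s3x", "Xist", "5530601H04Rik",
                         "2610029G23Rik", "Kdm5c", "D930009K15Rik"))
  femX <- filter(agg, .data$direction == "female")
  cl <- find_clusters(femX, max_gap = 50000)
  kdm5c_entry <- agg$entry_id[agg$gene_symbol == "Kdm5c"][1]
  kdm5c_cl <- filter(cl, purrr::map_lgl(.data$members, ~ kdm5c_entry %in% .x))
  checks <- tibble(
    check = c("relative depletion of male-biased X probes, kidney (%)",
              "relative depletion of male-biased X probes, liver (%)",
              "female-biased gene entries",
              "male-biased gene entries",
              "female intron-marked probe rows",
              "genes female-biased in >2 tissues",
              "probes male-biased in >2 tissues",
              "probes male-biased in >=4 tissues",
              "genes female-biased in all six tissues",
              "all-six-tissue genes are known escapees",
              "Kdm5c cluster size under the 50 kb rule"),
    expected = c(25, 27, 94, 33, 8, 25, 2, 0, 8, 1, 5),
    observed = c(
      dep("Kidney"), dep("Liver"),
      n_distinct(t2a$entry_num, na.rm = TRUE),
      n_distinct(t2b$entry_num, na.rm = TRUE),
      sum(t2a$intron),
      count_multibias(agg, 3, "gene", direction = "female"),
      count_multibias(rec, 3, "probe", direction = "male"),
      count_multibias(rec, 4, "probe", direction = "male"),
      length(fem6_genes),
      as.integer(identical(fem6_genes, esc_expected)),
      if (nrow(kdm5c_cl) == 1) kdm5c_cl$n_members else NA_integer_
    )
  )
  checks <- mutate(checks, pass = .data$expected == .data$observed)
  structure(checks, ok = all(checks$pass))
}
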