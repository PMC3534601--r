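test_that("fisher_exact_p equals hypergeometric enumeration and fisher.test", {
  # worked example: [[3,1],[1,3]] has two-sided mass 34/70
  out <- fisher_exact_p(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(out$p, 34 / 70)
  expect_equal(out$odds_ratio, 9)
  # balanced table: no association
  expect_equal(fisher_exact_p(matrix(5, 2, 2))$p, 1)
  # transpose symmetry of the probability-mass criterion
  tab <- matrix(c(7, 2, 3, 11), 2)
  expect_equal(fisher_exact_p(tab)$p, fisher_exact_p(t(tab))$p)

  # agreement with the reference implementation across margins <= 30
  set.seed(55)
  for (i in 1:400) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_p(tab)$p, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_p(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "xsexbias_degenerate_error")
})

test_that("tabulate_bias reproduces planted class counts within tolerance", {
  cfg <- sim_config(seed = 77, n_tissues = 1, samples_per_sex = 20,
                    n_probes = c(A = 500, X = 1428, Y = 0, "NA" = 0),
                    frac_biased = list(A = c(female = 0, male = 0),
                                       X = c(female = 50 / 1428, male = 10 / 1428),
                                       "NA" = c(female = 0, male = 0)),
                    effect_range_x = c(1, 1), n_escapees = 0,
                    xist_like = FALSE, y_male_only = FALSE, clusters = list())
  sim <- simulate_experiment(cfg)
  res <- test_experiment(sim$tissues, sim$samples, alpha = 0.001)
  counts <- tabulate_bias(res, sim$annotation, alpha = 0.001)
  x_row <- dplyr::filter(counts, chrom_class == "X")
  expect_equal(x_row$n_probes, 1428)
  # planted 50 female / 10 male; power near 1, false positives near 0
  expect_gte(x_row$n_female, 45); expect_lte(x_row$n_female, 56)
  expect_gte(x_row$n_male, 7);  expect_lte(x_row$n_male, 14)
  expect_equal(x_row$pct_female, 100 * x_row$n_female / 1428)
  # 'all' margin equals the class sums
  all_row <- dplyr::filter(counts, chrom_class == "all")
  expect_equal(all_row$n_female,
               sum(dplyr::filter(counts, chrom_class != "all")$n_female))

  expect_error(tabulate_bias(res, sim$annotation[-1, ], alpha = 0.001),
               class = "xsexbias_metadata_error")
})

test_that("sex relabelling swaps the F and M columns exactly", {
  sim <- simulate_experiment(small_sim_config(seed = 14))
  smp <- sim$samples
  res <- test_experiment(sim$tissues, smp, alpha = 0.01)
  smp_sw <- dplyr::mutate(smp, sex = ifelse(sex == "female", "male", "female"))
  res_sw <- test_experiment(sim$tissues, smp_sw, alpha = 0.01)
  c1 <- tabulate_bias(res, sim$annotation, alpha = 0.01)
  c2 <- tabulate_bias(res_sw, sim$annotation, alpha = 0.01)
  expect_equal(c1$n_probes, c2$n_probes)
  expect_equal(c1$n_female, c2$n_male)
  expect_equal(c1$n_male, c2$n_female)
})

test_that("compare_classes builds the published contrasts from Table 1", {
  cts <- fixture_counts()
  kid <- compare_classes(cts, "Kidney", "XM_vs_AM")
  expect_equal(round(-100 * kid$relative_difference), 25)
  expect_lt(kid$p, 0.01)
  liv <- compare_classes(cts, "Liver", "XM_vs_AM")
  expect_equal(round(-100 * liv$relative_difference), 27)
  # X is enriched for female bias in every tissue
  for (tis in unique(cts$tissue)) {
    e <- compare_classes(cts, tis, "XF_vs_AF")
    expect_gt(e$relative_difference, 0)
    expect_lt(e$p, 0.001)
  }
  # equal fractions give relative difference 0 and p = 1 on balanced counts
  toy <- tibble::tibble(tissue = "t", chrom_class = c("X", "A"),
                        n_probes = c(100, 100), n_biased = c(10, 10),
                        n_female = c(10, 10), n_male = c(0, 0),
                        pct_biased = 10, pct_female = 10, pct_male = 0)
  e0 <- compare_classes(toy, "t", "XF_vs_AF")
  expect_equal(e0$relative_difference, 0)
  expect_equal(e0$p, 1)
  td <- tidy(e0)
  expect_equal(td$p.value, 1)
  expect_identical(td$comparison, "XF_vs_AF")
})

test_that("escapee exclusion removes exactly the escapee-linked probes", {
  t2a <- load_fixture("table2A")
  ann <- fixture_annotation(list(t2a))
  rec <- consistent_probes(fixture_records(t2a))
  before <- aggregate_entries(rec, ann)
  expect_gt(sum(before$n_tissues == 6), 0)
  rec_x <- suppressMessages(exclude_escapees(rec, ann))
  after <- aggregate_entries(rec_x, ann)
  # every all-six-tissue gene is a known escapee, so none survive
  expect_equal(sum(after$n_tissues == 6), 0)
  # empty intersection is the identity
  rec_id <- suppressMessages(exclude_escapees(rec, ann, c("NotAGene")))
  expect_identical(rec_id, rec)
  expect_error(exclude_escapees(rec, ann, character(0)),
               class = "xsexbias_config_error")
})

test_that("escapee exclusion on synthetic data leaves the planted residual", {
  cfg <- sim_config(seed = 41, n_tissues = 2, samples_per_sex = 20,
                    n_probes = c(A = 100, X = 600, Y = 0, "NA" = 0),
                    frac_biased = list(A = c(female = 0, male = 0),
                                       X = c(female = 0.1, male = 0),
                                       "NA" = c(female = 0, male = 0)),
                    effect_range_x = c(0.8, 1), n_escapees = 20,
                    escapee_effect = c(0.8, 1),
                    xist_like = FALSE, y_male_only = FALSE, clusters = list())
  sim <- simulate_experiment(cfg)
  res <- test_experiment(sim$tissues, sim$samples, alpha = 0.001)
  esc <- sim$annotation$gene_symbol[sim$truth$entries$escapee]
  counts <- tabulate_bias(res, sim$annotation, alpha = 0.001)
  res_x <- suppressMessages(exclude_escapees(res, sim$annotation, esc))
  ann_x <- dplyr::filter(sim$annotation,
                         probe_id %in% unique(res_x$probe_id))
  counts_x <- tabulate_bias(res_x, ann_x, alpha = 0.001)
  xf <- dplyr::filter(counts, tissue == "tissue1", chrom_class == "X")$n_female
  xf_x <- dplyr::filter(counts_x, tissue == "tissue1", chrom_class == "X")$n_female
  # the excess shrinks by about the 20 planted escapees ...
  expect_lt(xf_x, xf - 10)
  # ... but the planted non-escapee excess persists (60 planted at power ~1)
  expect_gt(xf_x, 40)
})

test_that("null enrichment contrasts rarely reject", {
  # 120 null replicates; degenerate tables (no biased probes) cannot reject
  cfg0 <- sim_config(seed = 1, n_tissues = 1, samples_per_sex = 10,
                     n_probes = c(A = 2000, X = 500, Y = 0, "NA" = 0),
                     n_escapees = 0, xist_like = FALSE, y_male_only = FALSE,
                     clusters = list())
  reps <- 120
  rejections <- 0L; comparisons <- 0L
  for (r in seq_len(reps)) {
    cfg0$seed <- 1000 + r
    sim <- simulate_null(cfg0)
    res <- test_experiment(sim$tissues, sim$samples, alpha = 0.001)
    counts <- tabulate_bias(res, sim$annotation, alpha = 0.001)
    for (cmp in c("XF_vs_XM", "XF_vs_AF", "XM_vs_AM")) {
      p <- tryCatch(compare_classes(counts, "tissue1", cmp)$p,
                    error = function(e) 1)
      comparisons <- comparisons + 1L
      if (p < 0.01) rejections <- rejections + 1L
    }
  }
  expect_lte(rejections / comparisons, 0.02)
})
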