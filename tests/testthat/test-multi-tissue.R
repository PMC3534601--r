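make_results <- function(...) {
  # rows: probe, tissue, p, delta
  rows <- list(...)
  tibble::tibble(
    probe_id = purrr::map_chr(rows, 1),
    tissue = purrr::map_chr(rows, 2),
    p = purrr::map_dbl(rows, 3),
    delta = purrr::map_dbl(rows, 4))
}

test_that("consistency requires two tissues and one direction", {
  res <- make_results(
    list("p1", "t1", 0.005, 0.5), list("p1", "t2", 0.008, 0.4),   # in: 2 tissues
    list("p2", "t1", 0.005, 0.5),                                  # out: 1 tissue
    list("p3", "t1", 0.005, 0.5), list("p3", "t2", 0.005, -0.5),  # out: mixed
    list("p4", "t1", 0.5, 0.5), list("p4", "t2", 0.005, 0.4),     # out: 1 sig
    list("p5", "t1", 0.001, -0.2), list("p5", "t2", 0.009, -0.3),
    list("p5", "t3", 0.5, 0.3))                                    # in: male
  rec <- consistent_probes(res, alpha = 0.01)
  expect_setequal(rec$probe_id, c("p1", "p5"))
  expect_identical(rec$direction[rec$probe_id == "p5"], "male")
  expect_equal(rec$n_tissues[rec$probe_id == "p1"], 2)
})

test_that("probes biased at the strict threshold in two tissues stay in the relaxed set", {
  sim <- simulate_experiment(small_sim_config(seed = 61))
  res <- test_experiment(sim$tissues, sim$samples, alpha = 0.001)
  strict_multi <- dplyr::filter(
    dplyr::count(dplyr::filter(res, call != "ns"), probe_id, call),
    n >= 2)
  rec <- consistent_probes(res, alpha = 0.01)
  # every direction-consistent strict multi-tissue probe must appear
  for (i in seq_len(nrow(strict_multi))) {
    expect_true(strict_multi$probe_id[i] %in% rec$probe_id)
  }
})

test_that("entry aggregation takes tissue unions and merges intronic probes", {
  ann <- tibble::tibble(
    probe_id = c("pa1", "pa2", "pa_i", "pb", "pi_solo"),
    entry_id = c("F1", "F1", "F1i", "F2", "F:pi_solo"),
    gene_symbol = c("GeneA", "GeneA", "GeneA", "GeneB", ""),
    chrom_class = "X", chrom = "X",
    start = c(100, 300, 150, 10000, 50000),
    stop = c(200, 450, 160, 11000, 50100),
    feature_class = c("gene", "gene", "intron", "gene", "intron"),
    ensembl_id = "")
  res <- make_results(
    list("pa1", "t1", 0.001, 0.5), list("pa1", "t2", 0.001, 0.5),
    list("pa2", "t3", 0.001, 0.5), list("pa2", "t4", 0.001, 0.5),
    list("pa_i", "t1", 0.001, 0.5), list("pa_i", "t5", 0.001, 0.5),
    list("pb", "t1", 0.001, 0.5), list("pb", "t2", 0.001, 0.5),
    list("pi_solo", "t1", 0.001, 0.5), list("pi_solo", "t2", 0.001, 0.5))
  rec <- consistent_probes(res, alpha = 0.01)
  agg <- aggregate_entries(rec, ann)
  a <- dplyr::filter(agg, entry_id == "F1")
  # union over two gene probes with disjoint tissue pairs plus the intron probe
  expect_equal(a$n_tissues, 5)
  expect_equal(a$start, 100); expect_equal(a$stop, 450)
  expect_false(a$intronic)
  expect_identical(a$gene_symbol, "GeneA")
  solo <- dplyr::filter(agg, entry_id == "F:pi_solo")
  expect_true(solo$intronic)

  expect_error(aggregate_entries(rec, dplyr::mutate(ann, entry_id = "")),
               class = "xsexbias_metadata_error")
})

test_that("multi-tissue counting distinguishes gene and probe levels", {
  # two entries of the same gene must count once at gene level
  agg <- tibble::tibble(
    entry_id = c("F46", "F47", "F50"),
    gene_symbol = c("Xist", "Xist", "Other"),
    direction = "female",
    n_tissues = c(6, 6, 2))
  expect_equal(count_multibias(agg, 3, "gene"), 1)
  rec <- tibble::tibble(probe_id = c("q1", "q2", "q3"),
                        direction = c("male", "male", "female"),
                        n_tissues = c(3, 4, 5))
  expect_equal(count_multibias(rec, 3, "probe", direction = "male"), 2)
  expect_equal(count_multibias(rec, 5, "probe", direction = "male"), 0)
  expect_equal(count_multibias(rec[0, ], 3, "probe"), 0)
  expect_error(count_multibias(rec, 1, "probe"),
               class = "xsexbias_argument_error")
})

test_that("single-linkage clustering follows the gap rule", {
  agg <- tibble::tibble(
    entry_id = c("e1", "e2", "e3"), gene_symbol = "", direction = "female",
    n_tissues = 2, chrom = "X",
    start = c(0, 20000, 200000), stop = c(10000, 30000, 210000))
  cl <- find_clusters(agg, max_gap = 50000)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 2)
  expect_setequal(cl$members[[1]], c("e1", "e2"))
  expect_lt(cl$max_internal_gap, 50000)

  # overlap counts as gap 0; order of input must not matter
  agg2 <- tibble::tibble(
    entry_id = c("a", "b"), gene_symbol = "", direction = "female",
    n_tissues = 2, chrom = "X", start = c(100, 50), stop = c(200, 150))
  cl2 <- find_clusters(agg2, max_gap = 1000)
  expect_equal(cl2$n_members, 2)
  shuffled <- agg[c(3, 1, 2), ]
  expect_equal(find_clusters(shuffled, max_gap = 50000), cl)

  # boundary: a gap exactly at the threshold does not join
  agg3 <- tibble::tibble(
    entry_id = c("a", "b"), gene_symbol = "", direction = "female",
    n_tissues = 2, chrom = "X", start = c(0, 60000), stop = c(10000, 70000))
  expect_equal(nrow(find_clusters(agg3, max_gap = 50000)), 0)
})

test_that("planted clusters are recovered with perfect precision and recall", {
  cfg <- sim_config(seed = 71, n_tissues = 3, samples_per_sex = 20,
                    n_probes = c(A = 50, X = 200, Y = 0, "NA" = 0),
                    frac_biased = list(A = c(female = 0, male = 0),
                                       X = c(female = 0, male = 0),
                                       "NA" = c(female = 0, male = 0)),
                    n_escapees = 0, xist_like = FALSE, y_male_only = FALSE,
                    clusters = list(list(n_genes = 5, max_gap = 40000),
                                    list(n_genes = 3, max_gap = 40000)),
                    cluster_n_tissues = 3, cluster_effect = c(0.8, 1.2))
  sim <- simulate_experiment(cfg)
  res <- test_experiment(sim$tissues, sim$samples, alpha = 0.01)
  rec <- consistent_probes(res, alpha = 0.01)
  agg <- aggregate_entries(rec, sim$annotation)
  truth <- dplyr::filter(sim$truth$entries, !is.na(cluster_id))
  # precondition of the property: every planted member detected as biased
  expect_true(all(truth$entry_id %in% agg$entry_id))
  fem_x <- dplyr::filter(agg, direction == "female", chrom == "X")
  cl <- find_clusters(fem_x, max_gap = 50000)
  called <- sort(unlist(cl$members))
  expect_identical(called, sort(truth$entry_id))       # precision & recall 1
  expect_equal(sort(cl$n_members), c(3, 5))
  expect_true(all(cl$max_internal_gap < 50000))
})

test_that("the fixture report reproduces the published table structure", {
  t2a <- load_fixture("table2A")
  ann <- fixture_annotation(list(t2a))
  fx_res <- fixture_records(t2a)
  rec <- consistent_probes(fx_res, alpha = 0.01)
  agg <- aggregate_entries(rec, ann)
  rep <- table2_report(rec, fx_res, ann, agg)
  expect_equal(nrow(rep), 133)
  # per-tissue cells reproduce the printed fold-change magnitudes
  ddx <- dplyr::filter(rep, probe_id == "1423042_at")
  expect_equal(ddx$fc_Ki, 1.35, tolerance = 1e-9)
  expect_identical(ddx$grade_Ki, "p<0.001")
  expect_true(is.na(dplyr::filter(rep, probe_id == "1448737_at")$fc_Lu))
  # the Kdm5c cluster region is marked as one cluster
  kdm <- dplyr::filter(rep, entry_id %in% paste0("F", 76:80))
  expect_equal(dplyr::n_distinct(kdm$cluster), 1)
  expect_false(any(is.na(kdm$cluster)))
  # empty input yields an empty report
  empty <- table2_report(rec[0, ], fx_res, ann)
  expect_equal(nrow(empty), 0)
})
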