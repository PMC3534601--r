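test_that("the generator is deterministic and honours class counts", {
  cfg <- small_sim_config(seed = 12)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$tissues, s2$tissues)
  expect_identical(s1$truth, s2$truth)
  cc <- table(s1$annotation$chrom_class)
  expect_equal(unname(cc[c("A", "X", "Y", "NA")]), c(400, 150, 4, 6),
               ignore_attr = TRUE)
  s3 <- simulate_experiment(small_sim_config(seed = 13))
  expect_false(identical(s1$tissues, s3$tissues))
  expect_identical(dim(s1$tissues[[1]]), dim(s3$tissues[[1]]))
})

test_that("a null configuration plants no effects anywhere", {
  sim <- simulate_null(small_sim_config(seed = 4))
  deltas <- as.matrix(sim$truth$probe_effects[-1])
  expect_true(all(deltas == 0))
  expect_false(any(sim$truth$entries$escapee))
  # two tissues share one annotation
  expect_length(sim$tissues, 2)
  expect_equal(nrow(sim$annotation), nrow(sim$tissues[[1]]))
})

test_that("Y probes are male-only and the Xist-like probe is extreme", {
  sim <- simulate_experiment(small_sim_config(seed = 21))
  ann <- sim$annotation
  expr <- sim$tissues[[1]]
  smp <- dplyr::filter(sim$samples, tissue == "tissue1")
  fcols <- smp$sample_id[smp$sex == "female"]
  y_ids <- ann$probe_id[ann$chrom_class == "Y"]
  y_f <- as.matrix(dplyr::filter(expr, probe_id %in% y_ids)[fcols])
  expect_true(all(y_f == 4.0))
  res <- test_tissue(expr, smp, alpha = 0.001)
  xist_id <- sim$truth$entries$probe_id[sim$truth$entries$xist_like]
  xist_row <- dplyr::filter(res, probe_id == xist_id)
  expect_identical(xist_row$call, "female")
  expect_gt(xist_row$fold_change, 64)   # planted 128-fold, noise allowed
  # escapees are female-biased in every tissue
  esc_ids <- sim$truth$entries$probe_id[sim$truth$entries$escapee]
  esc_delta <- dplyr::filter(sim$truth$probe_effects, probe_id %in% esc_ids)
  expect_true(all(as.matrix(esc_delta[-1]) > 0))
})

test_that("planted cluster members satisfy the configured gap and spacing", {
  cfg <- small_sim_config(seed = 31)
  sim <- simulate_experiment(cfg)
  ann <- sim$annotation
  ent <- dplyr::inner_join(sim$truth$entries, ann, by = "probe_id")
  cl <- dplyr::arrange(dplyr::filter(ent, !is.na(cluster_id)), start)
  gaps <- cl$start[-1] - cl$stop[-nrow(cl)]
  expect_true(all(gaps < 40000))
  # singletons are spaced at least 5x the 50 kb threshold apart
  x_single <- dplyr::arrange(
    dplyr::filter(ent, is.na(cluster_id), chrom == "X"), start)
  single_gaps <- x_single$start[-1] - x_single$stop[-nrow(x_single)]
  expect_true(all(single_gaps >= 250000 - 60000))  # cluster blocks intervene
})

test_that("empirical sex differences converge to the planted truth", {
  cfg <- sim_config(seed = 8, n_tissues = 1, samples_per_sex = 500,
                    n_probes = c(A = 50, X = 150, Y = 0, "NA" = 0),
                    frac_biased = list(A = c(female = 0.3, male = 0.3),
                                       X = c(female = 0.3, male = 0.3),
                                       "NA" = c(female = 0, male = 0)),
                    n_escapees = 0, xist_like = FALSE, y_male_only = FALSE,
                    clusters = list())
  sim <- simulate_experiment(cfg)
  smp <- sim$samples
  res <- test_tissue(sim$tissues[[1]], smp, alpha = 0.001)
  truth <- sim$truth$probe_effects
  joined <- dplyr::inner_join(res, truth, by = "probe_id")
  fit <- stats::lm(delta ~ tissue1, data = joined)
  expect_lt(abs(unname(stats::coef(fit)[2]) - 1), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_tissues = 0), class = "xsexbias_config_error")
  expect_error(sim_config(frac_biased = list(A = c(female = 1.2, male = 0),
                                             X = c(female = 0, male = 0),
                                             "NA" = c(female = 0, male = 0))),
               class = "xsexbias_config_error")
  expect_error(sim_config(branch_probs = rep(0.1, 12)),
               class = "xsexbias_config_error")
  # planted clusters must fit on the declared chromosome
  expect_error(
    sim_config(clusters = list(list(n_genes = 1000, max_gap = 5e6)),
               x_length = 1e6),
    class = "xsexbias_config_error")
})
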