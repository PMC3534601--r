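# Exact two-sided rank-sum p by enumeration of all rank assignments:
# p = 2 * min(P(W <= w), P(W >= w)) capped at 1, with W the rank sum of xs.
# Independent of the normal-approximation path it checks.
exact_rank_sum_p <- function(xs, ys) {
  n1 <- length(xs)
  pooled <- c(xs, ys)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  cb <- utils::combn(length(pooled), n1)
  ws <- colSums(matrix(r[cb], nrow = n1))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Null distribution of the Mann-Whitney U statistic (exact, via dwilcox) and
# the attained level of the continuity-corrected normal approximation at a
# nominal threshold.
attained_level <- function(n1, n2, alpha) {
  u <- 0:(n1 * n2)
  d <- stats::dwilcox(u, n1, n2)
  sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sigma
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  sum(d[p < alpha])
}

# small deterministic expression tibble: 2 groups shifted by delta per probe
toy_expr <- function(deltas, n_per_sex = 5, sd = 0.3, seed = 42,
                     baseline = 8) {
  set.seed(seed)
  ids <- sprintf("p%03d", seq_along(deltas))
  sid <- c(sprintf("F%02d", 1:n_per_sex), sprintf("M%02d", 1:n_per_sex))
  vals <- t(vapply(deltas, function(d) {
    c(rnorm(n_per_sex, baseline + d / 2, sd),
      rnorm(n_per_sex, baseline - d / 2, sd))
  }, numeric(2 * n_per_sex)))
  colnames(vals) <- sid
  dplyr::bind_cols(tibble::tibble(probe_id = ids),
                   tibble::as_tibble(as.data.frame(vals)))
}

toy_samples <- function(expr, tissue = "tissue1") {
  sid <- names(expr)[-1]
  tibble::tibble(sample_id = sid,
                 sex = ifelse(grepl("^F", sid), "female", "male"),
                 tissue = tissue)
}

# compact simulation configs used across test files
small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_tissues = 2, samples_per_sex = 10,
             n_probes = c(A = 400, X = 150, Y = 4, "NA" = 6),
             n_escapees = 5,
             clusters = list(list(n_genes = 3, max_gap = 40000)), ...)
}
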