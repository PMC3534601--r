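# Row-wise Wilcoxon rank-sum with normal approximation.
#
# Matches the large-sample path of stats::wilcox.test(): midranks for ties,
# tie-corrected variance, 0.5 continuity correction, two-sided p
# 2*min(P(Z<=z), P(Z>=z)). Vectorized over rows so whole-array screens and
# simulation replicates stay fast.
row_rank_sum <- function(mat, in_x) {
  n1 <- sum(in_x)
  n2 <- sum(!in_x)
  n <- n1 + n2
  stat <- apply(mat, 1L, function(v) {
    r <- rank(v)
    nt <- table(v)
    c(sum(r[in_x]), sum(nt^3 - nt))
  })
  U <- stat[1L, ] - n1 * (n1 + 1) / 2
  ties <- stat[2L, ]
  sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - ties / (n * (n - 1))))
  z <- U - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sigma
  p <- pmin(1, 2 * pnorm(-abs(z)))
  p[!is.finite(sigma) | sigma == 0] <- 1   # all values tied
  p
}

row_welch <- function(mat, in_x, pooled = FALSE) {
  n1 <- sum(in_x); n2 <- sum(!in_x)
  m1 <- rowMeans(mat[, in_x, drop = FALSE])
  m2 <- rowMeans(mat[, !in_x, drop = FALSE])
  v1 <- apply(mat[, in_x, drop = FALSE], 1L, stats::var)
  v2 <- apply(mat[, !in_x, drop = FALSE], 1L, stats::var)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se == 0 | !is.finite(se)
  # both groups constant: p = 1 if means equal, 0 if completely separated
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

#' Two-sided Wilcoxon rank-sum p-value (normal approximation)
#'
#' The standard large-sample approximation: midranks for ties, tie-corrected
#' variance and a 0.5 continuity correction. This is the screening statistic
#' used throughout the pipeline; exact small-sample enumeration exists in the
#' test suite as an oracle, not here.
#'
#' @param xs,ys Numeric vectors, at least 2 observations each.
#' @return Two-sided p-value in \[0, 1\].
#' @export
rank_sum_p <- function(xs, ys) {
  check_groups(xs, ys, min_n = 2)
  row_rank_sum(matrix(c(xs, ys), nrow = 1), c(rep(TRUE, length(xs)), rep(FALSE, length(ys))))
}

#' Two-sided two-sample t-test p-value
#'
#' Welch (unequal-variance) by default, with a pooled-variance option.
#'
#' @param xs,ys Numeric vectors, at least 2 observations each.
#' @param pooled Use the pooled-variance statistic instead of Welch.
#' @return Two-sided p-value in \[0, 1\].
#' @export
t_test_p <- function(xs, ys, pooled = FALSE) {
  check_groups(xs, ys, min_n = 2)
  if (stats::var(xs) == 0 && stats::var(ys) == 0) {
    if (mean(xs) == mean(ys)) return(1)
    abort("degenerate input: both groups constant with unequal means",
          class = "xsexbias_degenerate_error")
  }
  stats::t.test(xs, ys, var.equal = pooled)$p.value
}

#' Log2 sex difference and linear fold-change
#'
#' @param xs Female-group log2 intensities.
#' @param ys Male-group log2 intensities.
#' @return Named list: `delta` = mean(xs) - mean(ys) (log2 units),
#'   `fold_change` = 2^delta (linear female/male ratio).
#' @export
fold_change <- function(xs, ys) {
  if (length(xs) == 0 || length(ys) == 0) {
    abort("fold_change requires non-empty groups",
          class = "xsexbias_insufficient_data_error")
  }
  delta <- mean(xs) - mean(ys)
  list(delta = delta, fold_change = 2^delta)
}

check_groups <- function(xs, ys, min_n = 2) {
  if (length(xs) < min_n || length(ys) < min_n) {
    abort(sprintf("each group needs at least %d observations (got %d and %d)",
                  min_n, length(xs), length(ys)),
          class = "xsexbias_insufficient_data_error")
  }
  invisible(TRUE)
}

#' Screen one tissue for sex-biased probes
#'
#' Runs the per-probe Wilcoxon rank-sum (normal approximation) and Welch t
#' tests between female and male samples of one tissue, computes the log2
#' sex difference and fold-change, and classifies each probe at `alpha`
#' using the Wilcoxon p-value. No multiple-testing adjustment is applied;
#' the screening thresholds are deliberately unadjusted per-comparison
#' levels (conventionally 0.001 for the primary screen, 0.01 for the
#' cross-tissue consistency screen).
#'
#' @param expr Expression tibble (first column `probe_id`), columns covering
#'   the samples of `samples`.
#' @param samples Sample tibble (`sample_id`, `sex`, `tissue`) describing the
#'   expression columns; all expression columns must be annotated.
#' @param alpha Per-probe significance threshold for the bias call.
#' @param pooled_t Use the pooled-variance t statistic instead of Welch.
#' @return Tibble with one row per probe: `probe_id`, `mean_f`, `mean_m`,
#'   `delta`, `fold_change`, `p_wilcoxon`, `p_ttest`, `call`
#'   (`female`/`male`/`ns`).
#' @export
test_tissue <- function(expr, samples, alpha = 0.001, pooled_t = FALSE) {
  m <- expr_values(expr)
  missing <- setdiff(colnames(m), samples$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("no sex annotation for sample column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "xsexbias_metadata_error")
  }
  sex <- samples$sex[match(colnames(m), samples$sample_id)]
  in_f <- sex == "female"
  if (sum(in_f) < 2 || sum(!in_f) < 2) {
    abort("need at least 2 samples of each sex",
          class = "xsexbias_insufficient_data_error")
  }
  mean_f <- rowMeans(m[, in_f, drop = FALSE])
  mean_m <- rowMeans(m[, !in_f, drop = FALSE])
  delta <- mean_f - mean_m
  p_w <- row_rank_sum(m, in_f)
  p_t <- row_welch(m, in_f, pooled = pooled_t)
  call <- dplyr::case_when(p_w < alpha & delta > 0 ~ "female",
                           p_w < alpha & delta < 0 ~ "male",
                           TRUE ~ "ns")
  tibble(probe_id = expr$probe_id, mean_f = mean_f, mean_m = mean_m,
         delta = delta, fold_change = 2^delta,
         p_wilcoxon = p_w, p_ttest = p_t, call = call)
}

#' Screen every tissue of a multi-tissue experiment
#'
#' @param tissues Named list of expression tibbles (one per tissue).
#' @param samples Sample tibble covering all tissues.
#' @param alpha Per-probe significance threshold.
#' @param ... Passed to [test_tissue()].
#' @return Long tibble of [test_tissue()] results with a leading `tissue`
#'   column.
#' @export
test_experiment <- function(tissues, samples, alpha = 0.001, ...) {
  purrr::imap_dfr(tissues, function(expr, tis) {
    smp <- filter(samples, .data$tissue == tis)
    mutate(test_tissue(expr, smp, alpha = alpha, ...), tissue = tis,
           .before = 1)
  })
}

#' Write / read per-probe screening results
#'
#' Tab-delimited round-trip of the [test_tissue()] output.
#'
#' @param results Result tibble.
#' @param path File path.
#' @return `path` invisibly, or the re-read tibble.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
}
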