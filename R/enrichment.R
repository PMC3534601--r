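#' Tabulate biased probes by tissue and chromosome class
#'
#' Builds the per-tissue, per-chromosome-class count table of sex-biased
#' probes: for each class (autosomes `A`, `X`, `Y`, unmapped `NA`, and the
#' `all` margin) the number of probes in the class, the number called
#' female- and male-biased at `alpha`, and the corresponding percentages of
#' the class total.
#'
#' @param results Long result tibble from [test_experiment()] (columns
#'   `tissue`, `probe_id`, `p_wilcoxon`, `delta`), or a single-tissue
#'   [test_tissue()] result carrying a `tissue` column.
#' @param ann Probe annotation tibble; every probe in `results` must appear.
#' @param alpha Per-probe significance threshold for the bias calls.
#' @return Tibble with columns `tissue`, `chrom_class`, `n_probes`,
#'   `n_biased`, `n_female`, `n_male`, `pct_biased`, `pct_female`,
#'   `pct_male`.
#' @export
tabulate_bias <- function(results, ann, alpha = 0.001) {
  missing <- setdiff(unique(results$probe_id), ann$probe_id)
  if (length(missing) > 0) {
    abort(sprintf("probe(s) missing from annotation: %s%s",
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else ""),
          class = "xsexbias_metadata_error")
  }
  res <- left_join(results, select(ann, "probe_id", "chrom_class"),
                   by = "probe_id")
  res <- mutate(res,
                call = dplyr::case_when(
                  .data$p_wilcoxon < alpha & .data$delta > 0 ~ "female",
                  .data$p_wilcoxon < alpha & .data$delta < 0 ~ "male",
                  TRUE ~ "ns"))
  per_class <- summarise(group_by(res, .data$tissue, .data$chrom_class),
                         n_probes = n(),
                         n_female = sum(.data$call == "female"),
                         n_male = sum(.data$call == "male"),
                         .groups = "drop")
  all_row <- summarise(group_by(res, .data$tissue),
                       chrom_class = "all",
                       n_probes = n(),
                       n_female = sum(.data$call == "female"),
                       n_male = sum(.data$call == "male"),
                       .groups = "drop")
  out <- bind_rows(all_row, per_class)
  out <- mutate(out,
                n_biased = .data$n_female + .data$n_male,
                pct_biased = 100 * .data$n_biased / .data$n_probes,
                pct_female = 100 * .data$n_female / .data$n_probes,
                pct_male = 100 * .data$n_male / .data$n_probes)
  cls <- c("all", "A", "X", "Y", "NA")
  out <- arrange(out, .data$tissue, match(.data$chrom_class, cls))
  select(out, "tissue", "chrom_class", "n_probes", "n_biased", "n_female",
         "n_male", "pct_biased", "pct_female", "pct_male")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided p-value by the probability-mass criterion: the sum
#' of hypergeometric probabilities, over all tables with the observed
#' margins, of tables at most as probable as the observed one (the common
#' default of standard statistical environments). The odds ratio is the
#' sample cross-product ratio (Inf/0 allowed at the boundary).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List with elements `odds_ratio` and `p`.
#' @export
fisher_exact_p <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("fisher_exact_p requires a 2x2 table of non-negative integers",
          class = "xsexbias_degenerate_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("fisher_exact_p: zero margin", class = "xsexbias_degenerate_error")
  }
  m <- sum(tab[1, ])            # row-1 margin
  nn <- sum(tab[2, ])           # row-2 margin
  k <- sum(tab[, 1])            # col-1 margin
  support <- max(0, k - nn):min(k, m)
  d <- dhyper(support, m, nn, k)
  p_obs <- dhyper(tab[1, 1], m, nn, k)
  # relative tolerance absorbs floating-point ties in the mass comparison
  p <- min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p = p)
}

#' Chromosome-class enrichment/depletion contrast
#'
#' The three contrasts of the bias count table:
#' * `XF_vs_XM`: female- versus male-biased fractions within the X;
#' * `XF_vs_AF`: female-biased fraction on X versus autosomes;
#' * `XM_vs_AM`: male-biased fraction on X versus autosomes.
#'
#' Each builds a 2x2 table (biased-in-direction versus not) and applies the
#' two-sided Fisher exact test. For the cross-class contrasts the signed
#' relative difference `(X fraction - A fraction) / A fraction` is reported
#' (negative values are a relative depletion on X; -0.25 prints as a 25\%
#' depletion). Unmapped (`NA`-class) probes never enter these contrasts.
#'
#' @param counts Bias count table from [tabulate_bias()] (or the Table 1
#'   fixture joined to class totals via [fixture_counts()]).
#' @param tissue Tissue label to contrast.
#' @param comparison One of `"XF_vs_XM"`, `"XF_vs_AF"`, `"XM_vs_AM"`.
#' @return Object of class `xsexbias_enrichment`: a list with `comparison`,
#'   `tissue`, `contingency`, `odds_ratio`, `p`, `relative_difference`.
#' @export
compare_classes <- function(counts, tissue,
                            comparison = c("XF_vs_XM", "XF_vs_AF", "XM_vs_AM")) {
  comparison <- match.arg(comparison)
  tis <- tissue
  row_of <- function(cls) {
    r <- filter(counts, .data$tissue == tis, .data$chrom_class == cls)
    if (nrow(r) != 1 || r$n_probes == 0) {
      abort(sprintf("missing or degenerate counts for tissue '%s', class %s",
                    tis, cls), class = "xsexbias_degenerate_error")
    }
    r
  }
  x <- row_of("X")
  if (comparison == "XF_vs_XM") {
    tab <- matrix(c(x$n_female, x$n_probes - x$n_female,
                    x$n_male, x$n_probes - x$n_male),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("female", "male"), c("biased", "not")))
    rel <- NA_real_
  } else {
    a <- row_of("A")
    dir <- if (comparison == "XF_vs_AF") "n_female" else "n_male"
    tab <- matrix(c(x[[dir]], x$n_probes - x[[dir]],
                    a[[dir]], a$n_probes - a[[dir]]),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("X", "A"), c("biased", "not")))
    fx <- x[[dir]] / x$n_probes
    fa <- a[[dir]] / a$n_probes
    rel <- (fx - fa) / fa
  }
  ft <- fisher_exact_p(tab)
  structure(list(comparison = comparison, tissue = tis, contingency = tab,
                 odds_ratio = ft$odds_ratio, p = ft$p,
                 relative_difference = rel),
            class = "xsexbias_enrichment")
}

#' @export
print.xsexbias_enrichment <- function(x, ...) {
  cat(sprintf("Chromosome-class contrast %s, tissue %s\n", x$comparison, x$tissue))
  print(x$contingency)
  cat(sprintf("odds ratio %.4g, two-sided Fisher p = %.4g\n", x$odds_ratio, x$p))
  if (!is.na(x$relative_difference)) {
    cat(sprintf("relative difference on X: %+.1f%%\n", 100 * x$relative_difference))
  }
  invisible(x)
}

#' @export
tidy.xsexbias_enrichment <- function(x, ...) {
  tibble(comparison = x$comparison, tissue = x$tissue,
         n11 = x$contingency[1, 1], n12 = x$contingency[1, 2],
         n21 = x$contingency[2, 1], n22 = x$contingency[2, 2],
         odds_ratio = x$odds_ratio, p.value = x$p,
         relative_difference = x$relative_difference)
}

#' @export
glance.xsexbias_enrichment <- function(x, ...) {
  tibble(comparison = x$comparison, tissue = x$tissue,
         odds_ratio = x$odds_ratio, p.value = x$p,
         relative_difference = x$relative_difference)
}

#' Convert the Table 1 fixture into a bias count table
#'
#' Joins the fixture's biased counts to the derived chromosome-class probe
#' totals so that [compare_classes()] can run on the published counts.
#'
#' @param table1 Table 1 fixture tibble.
#' @param totals Named vector of class totals, by default [class_totals()].
#' @return Bias count table in the [tabulate_bias()] layout.
#' @export
fixture_counts <- function(table1 = load_fixture("table1"),
                           totals = class_totals()) {
  mutate(table1,
         n_probes = unname(totals[.data$chrom_class]),
         .after = "chrom_class")
}

#' Remove probes of known escapee genes
#'
#' Drops every probe whose gene symbol, printed alias, or intronic host gene
#' belongs to the escapee list. Used for the escapee-excluded (X') variant of
#' the enrichment contrasts, which asks how much of the female excess on X
#' survives once genes with established escape from X-inactivation are set
#' aside. Escapee symbols not present in the annotation are reported with an
#' informational message and ignored.
#'
#' @param results Result tibble with a `probe_id` column (per-tissue results,
#'   long results, or consistency records).
#' @param ann Probe annotation; `alias` / `host_gene` columns are used when
#'   present (fixture annotations carry symbols only).
#' @param escapees Character vector of escapee gene symbols,
#'   default [mouse_escapees()].
#' @return `results` without the escapee probes.
#' @export
exclude_escapees <- function(results, ann, escapees = mouse_escapees()) {
  if (length(escapees) == 0) {
    abort("escapee list is empty", class = "xsexbias_config_error")
  }
  keys <- ann$gene_symbol
  for (col in intersect(c("alias", "host_gene"), names(ann))) {
    keys <- ifelse(keys == "" | is.na(keys), ann[[col]], keys)
  }
  hit_symbols <- unique(c(ann$gene_symbol,
                          unlist(ann[intersect(c("alias", "host_gene"), names(ann))])))
  unknown <- setdiff(escapees, hit_symbols)
  if (length(unknown) > 0) {
    inform(sprintf("escapee symbol(s) not in annotation (ignored): %s",
                   paste(unknown, collapse = ", ")))
  }
  drop <- ann$probe_id[keys %in% escapees |
                         (if ("alias" %in% names(ann)) ann$alias %in% escapees else FALSE) |
                         (if ("host_gene" %in% names(ann)) ann$host_gene %in% escapees else FALSE)]
  filter(results, !.data$probe_id %in% drop)
}
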