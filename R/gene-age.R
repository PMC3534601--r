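#' Attach phylogenetic branch ages to tested probes
#'
#' Joins per-probe bias calls to a gene-to-branch table. Branches are the
#' strata (0--11) of a vertebrate phylogeny at which a gene's orthologs
#' first appear; branches 0--5 predate the radiation of placental mammals
#' (>100 myr). Matching is by Ensembl id with gene-symbol fallback; X-linked
#' probes without a match are excluded and counted in the coverage summary.
#'
#' @param results Per-probe results of one tissue (from [test_tissue()],
#'   carrying `probe_id` and `call`).
#' @param ann Probe annotation (`chrom_class`, `ensembl_id`, `gene_symbol`).
#' @param branches Branch table (`gene_key`, `branch`).
#' @return Tibble of X-linked probes with a branch: `probe_id`, `call`,
#'   `branch`. The attribute `coverage` holds a named vector with
#'   `n_x_probes`, `n_matched`, `n_unmatched`.
#' @export
join_branches <- function(results, ann, branches) {
  branches <- validate_branch_table(branches)
  x_ann <- filter(ann, .data$chrom_class == "X")
  joined <- inner_join(select(results, "probe_id", "call"),
                       select(x_ann, "probe_id", "ensembl_id", "gene_symbol"),
                       by = "probe_id")
  lookup <- setNames(branches$branch, branches$gene_key)
  branch <- unname(lookup[joined$ensembl_id])
  fallback <- is.na(branch)
  branch[fallback] <- unname(lookup[joined$gene_symbol[fallback]])
  joined$branch <- branch
  out <- select(filter(joined, !is.na(.data$branch)),
                "probe_id", "call", "branch")
  attr(out, "coverage") <- c(n_x_probes = nrow(joined),
                             n_matched = nrow(out),
                             n_unmatched = nrow(joined) - nrow(out))
  out
}

#' Per-branch sex-bias proportions
#'
#' For each branch, the fraction of probes called female- and male-biased.
#' Branches represented by fewer than `min_probes` probes are marked
#' excluded and carry no proportions (they stay in the table so the filter
#' is auditable).
#'
#' @param joined Output of [join_branches()].
#' @param min_probes Minimum probes for a branch to be included.
#' @return Tibble: `branch`, `n_probes`, `prop_female`, `prop_male`,
#'   `included`.
#' @export
branch_proportions <- function(joined, min_probes = 10) {
  out <- summarise(group_by(joined, .data$branch),
                   n_probes = n(),
                   prop_female = mean(.data$call == "female"),
                   prop_male = mean(.data$call == "male"),
                   .groups = "drop")
  out <- mutate(out, included = .data$n_probes >= min_probes,
                prop_female = if_else(.data$included, .data$prop_female, NA_real_),
                prop_male = if_else(.data$included, .data$prop_male, NA_real_))
  arrange(out, .data$branch)
}

#' Old-versus-young Fisher test of sex-bias proportions
#'
#' Splits probes at the 100-myr boundary (branches 0--5 old, 6--11 young)
#' and tests whether the proportion biased in the given direction differs
#' between the two strata, with the two-sided Fisher exact test on the 2x2
#' (biased, not) x (old, young) table.
#'
#' @param joined Output of [join_branches()].
#' @param direction `"female"` or `"male"`.
#' @param split_branch Last branch of the old stratum.
#' @return Object of class `xsexbias_agesplit` with the counts, odds ratio
#'   and p-value.
#' @export
age_split_test <- function(joined, direction = c("female", "male"),
                           split_branch = 5) {
  direction <- match.arg(direction)
  old <- joined$branch <= split_branch
  if (all(old) || !any(old)) {
    abort("age_split_test needs probes in both age strata",
          class = "xsexbias_degenerate_error")
  }
  biased <- joined$call == direction
  tab <- matrix(c(sum(biased & old), sum(!biased & old),
                  sum(biased & !old), sum(!biased & !old)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("old", "young"), c("biased", "not")))
  ft <- fisher_exact_p(tab)
  structure(list(direction = direction, split_branch = split_branch,
                 contingency = tab, odds_ratio = ft$odds_ratio, p = ft$p),
            class = "xsexbias_agesplit")
}

#' @export
print.xsexbias_agesplit <- function(x, ...) {
  cat(sprintf("Age split (%s bias), old = branches 0-%d\n",
              x$direction, x$split_branch))
  print(x$contingency)
  cat(sprintf("odds ratio %.4g, two-sided Fisher p = %.4g\n",
              x$odds_ratio, x$p))
  invisible(x)
}

#' @export
tidy.xsexbias_agesplit <- function(x, ...) {
  tibble(direction = x$direction, split_branch = x$split_branch,
         old_biased = x$contingency[1, 1], old_total = sum(x$contingency[1, ]),
         young_biased = x$contingency[2, 1], young_total = sum(x$contingency[2, ]),
         odds_ratio = x$odds_ratio, p.value = x$p)
}

#' @export
glance.xsexbias_agesplit <- function(x, ...) {
  tibble(direction = x$direction, odds_ratio = x$odds_ratio, p.value = x$p)
}
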