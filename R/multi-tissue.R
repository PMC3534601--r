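#' Probes with consistent sex-bias in multiple tissues
#'
#' A probe is consistently biased when it is significant at `alpha` in at
#' least two tissues with the same direction in every significant tissue;
#' probes significant in opposite directions in different tissues are
#' excluded. This is the relaxed-threshold (conventionally p<0.01)
#' cross-tissue screen: sensitivity is raised by the weaker per-tissue
#' cut-off and specificity recovered by demanding replication.
#'
#' @param results Long tibble with columns `probe_id`, `tissue`, `delta` and
#'   a p-value column (`p_wilcoxon`, or `p` as produced by
#'   [fixture_records()]).
#' @param alpha Per-tissue significance threshold.
#' @return Tibble with one row per consistent probe: `probe_id`, `direction`,
#'   `n_tissues`, `tissues` (list column of tissue labels) and `fold_changes`
#'   (list column of fold-change magnitudes in the significant tissues).
#' @export
consistent_probes <- function(results, alpha = 0.01) {
  pcol <- if ("p_wilcoxon" %in% names(results)) "p_wilcoxon" else "p"
  if (!all(c("probe_id", "tissue", "delta") %in% names(results)) ||
      !pcol %in% names(results)) {
    abort("results must carry probe_id, tissue, delta and a p-value column",
          class = "xsexbias_format_error")
  }
  sig <- filter(results, .data[[pcol]] < alpha, .data$delta != 0)
  sig <- mutate(sig, direction = if_else(.data$delta > 0, "female", "male"),
                fc_mag = 2^abs(.data$delta))
  out <- summarise(group_by(sig, .data$probe_id),
                   n_dir = n_distinct(.data$direction),
                   direction = first(.data$direction),
                   n_tissues = n(),
                   tissues = list(.data$tissue),
                   fold_changes = list(setNames(.data$fc_mag, .data$tissue)),
                   .groups = "drop")
  out <- filter(out, .data$n_dir == 1, .data$n_tissues >= 2)
  select(out, -"n_dir")
}

#' Aggregate consistent probes into gene-level entries
#'
#' Probes sharing a numbered entry label form one gene-level entry; probes
#' whose entry label carries the intron marker (trailing `i`) merge into
#' their numbered entry, while unnumbered intronic records stay standalone
#' and are flagged intronic. The significant-tissue sets of an entry's
#' probes are combined by union, and the entry's coordinates span the
#' member probes.
#'
#' @param records Consistency records from [consistent_probes()].
#' @param ann Probe annotation carrying `entry_id`, `gene_symbol`, `chrom`,
#'   `start`, `stop`, `feature_class`.
#' @return Tibble with one row per entry per direction: `entry_id`,
#'   `gene_symbol`, `direction`, `n_tissues` (size of the tissue union),
#'   `tissues` (list), `chrom`, `start`, `stop`, `intronic`.
#' @export
aggregate_entries <- function(records, ann) {
  no_entry <- setdiff(records$probe_id, ann$probe_id[ann$entry_id != ""])
  if (length(no_entry) > 0) {
    abort(sprintf("probe(s) without entry_id in annotation: %s",
                  paste(no_entry, collapse = ", ")),
          class = "xsexbias_metadata_error")
  }
  joined <- inner_join(records,
                       select(ann, "probe_id", "entry_id", "gene_symbol",
                              "chrom", "start", "stop", "feature_class"),
                       by = "probe_id")
  # trailing-i labels are intronic probes of the numbered entry they decorate
  joined <- mutate(joined,
                   base_entry = sub("i$", "", .data$entry_id),
                   intron_probe = .data$feature_class == "intron")
  out <- summarise(
    group_by(joined, .data$base_entry, .data$direction),
    gene_symbol = first(.data$gene_symbol[order(.data$intron_probe)]),
    n_tissues = length(unique(unlist(.data$tissues))),
    tissues = list(sort(unique(unlist(.data$tissues)))),
    chrom = first(.data$chrom),
    start = suppressWarnings(min(.data$start, na.rm = TRUE)),
    stop = suppressWarnings(max(.data$stop, na.rm = TRUE)),
    intronic = all(.data$intron_probe),
    n_probes = n(),
    .groups = "drop")
  out <- rename(out, entry_id = "base_entry")
  out <- mutate(out,
                start = if_else(is.finite(.data$start), .data$start, NA_real_),
                stop = if_else(is.finite(.data$stop), .data$stop, NA_real_))
  arrange(out, .data$direction, .data$chrom, .data$start)
}

#' Count multi-tissue biased units
#'
#' Counts units biased in at least `min_tissues` tissues. At the probe level
#' the units are individual probes (transcript-level counting); at the gene
#' level they are unique genes among aggregated entries, keyed by gene
#' symbol with the entry label as fallback for unannotated transcripts, so
#' a gene represented by several numbered entries is counted once.
#'
#' @param x Consistency records (`level = "probe"`) or entry aggregates
#'   (`level = "gene"`).
#' @param min_tissues Minimum size of the significant-tissue set (>= 2).
#' @param level `"gene"` or `"probe"`.
#' @param direction Optional filter, `"female"` or `"male"`.
#' @return Integer count.
#' @export
count_multibias <- function(x, min_tissues, level = c("gene", "probe"),
                            direction = NULL) {
  level <- match.arg(level)
  if (min_tissues < 2) {
    abort("min_tissues must be >= 2 (consistency already requires 2 tissues)",
          class = "xsexbias_argument_error")
  }
  if (!is.null(direction)) x <- filter(x, .data$direction == !!direction)
  if (nrow(x) == 0) return(0L)
  hit <- filter(x, .data$n_tissues >= min_tissues)
  if (level == "probe") return(nrow(hit))
  key <- if_else(hit$gene_symbol == "" | is.na(hit$gene_symbol),
                 hit$entry_id, hit$gene_symbol)
  length(unique(key))
}

#' Find proximity clusters of biased entries
#'
#' Single-linkage chaining along one chromosome: entries are sorted by start
#' coordinate and adjacent entries whose gap (next start minus current stop,
#' floored at 0 for overlaps; 1-based inclusive coordinates) is smaller than
#' `max_gap` join the same cluster. Clusters of at least two members are
#' reported. The conventional threshold for "close proximity" is 50 kb.
#'
#' @param aggregates Entry aggregates (usually the female-biased entries of
#'   one chromosome) with `entry_id`, `start`, `stop` and a single `chrom`.
#' @param max_gap Gap threshold in base pairs.
#' @return Tibble with one row per cluster: `cluster_id`, `n_members`,
#'   `members` (list of entry ids ordered by start), `chrom`, `start`,
#'   `stop`, `span`, `max_internal_gap`.
#' @export
find_clusters <- function(aggregates, max_gap = 50000) {
  agg <- filter(aggregates, !is.na(.data$start) & !is.na(.data$stop))
  if (nrow(agg) == 0) {
    return(tibble(cluster_id = integer(), n_members = integer(),
                  members = list(), chrom = character(), start = numeric(),
                  stop = numeric(), span = numeric(),
                  max_internal_gap = numeric()))
  }
  if (n_distinct(agg$chrom) > 1) {
    abort("find_clusters expects entries of a single chromosome",
          class = "xsexbias_metadata_error")
  }
  agg <- arrange(agg, .data$start, .data$stop)
  # running maximum of stop handles nested/overlapping entries
  reach <- cummax(agg$stop)
  gap <- pmax(0, agg$start - dplyr::lag(reach))
  new_cluster <- is.na(gap) | gap >= max_gap
  agg$cluster <- cumsum(new_cluster)
  agg$gap_to_prev <- if_else(new_cluster, NA_real_, gap)
  out <- summarise(group_by(agg, .data$cluster),
                   n_members = n(),
                   members = list(.data$entry_id),
                   chrom = first(.data$chrom),
                   start = min(.data$start),
                   stop = max(.data$stop),
                   span = max(.data$stop) - min(.data$start) + 1,
                   max_internal_gap = if (n() > 1)
                     max(.data$gap_to_prev[-1]) else NA_real_,
                   .groups = "drop")
  out <- filter(out, .data$n_members >= 2)
  mutate(select(out, -"cluster"), cluster_id = row_number(), .before = 1)
}

#' Write cluster calls as BED-like intervals
#'
#' @param clusters Cluster tibble from [find_clusters()].
#' @param path Output path (tab-delimited: chrom, start, stop, cluster_id,
#'   n_members).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  readr::write_tsv(select(clusters, "chrom", "start", "stop", "cluster_id",
                          "n_members"),
                   path, progress = FALSE)
  invisible(path)
}

#' Assemble a multi-tissue consistency report
#'
#' Per-probe rows in the layout of the published multi-tissue table:
#' fold-change magnitude or `ns` per tissue, significance grade, entry
#' label and cluster letter, with female- and male-biased sections
#' separated by the `direction` column.
#'
#' @param records Consistency records from [consistent_probes()] (both
#'   directions may be mixed).
#' @param results Long per-tissue results used to fill the per-tissue cells.
#' @param ann Annotation with `entry_id` and coordinates.
#' @param aggregates Optional entry aggregates used to attach cluster
#'   letters computed by [find_clusters()]; omitted columns stay empty.
#' @param alpha_strong,alpha_weak The two significance grades.
#' @return Tibble with one row per consistent probe and one fold-change
#'   column per tissue (`NA` where not significant).
#' @export
table2_report <- function(records, results, ann, aggregates = NULL,
                          alpha_strong = 0.001, alpha_weak = 0.01) {
  pcol <- if ("p_wilcoxon" %in% names(results)) "p_wilcoxon" else "p"
  tissues <- unique(results$tissue)
  base <- inner_join(records,
                     select(ann, "probe_id", "entry_id", "gene_symbol",
                            "chrom", "start", "stop", "feature_class"),
                     by = "probe_id")
  cells <- filter(results, .data$probe_id %in% records$probe_id)
  cells <- mutate(cells,
                  grade = dplyr::case_when(
                    .data[[pcol]] < alpha_strong ~ paste0("p<", format(alpha_strong)),
                    .data[[pcol]] < alpha_weak ~ paste0("p<", format(alpha_weak)),
                    TRUE ~ NA_character_),
                  fc_mag = if_else(is.na(.data$grade), NA_real_,
                                   2^abs(.data$delta)))
  fc_wide <- tidyr::pivot_wider(
    select(cells, "probe_id", "tissue", "fc_mag"),
    names_from = "tissue", values_from = "fc_mag", names_prefix = "fc_")
  grade_wide <- tidyr::pivot_wider(
    select(cells, "probe_id", "tissue", "grade"),
    names_from = "tissue", values_from = "grade", names_prefix = "grade_")
  out <- left_join(base, fc_wide, by = "probe_id")
  out <- left_join(out, grade_wide, by = "probe_id")
  out <- select(out, -"tissues", -"fold_changes")
  if (!is.null(aggregates) && nrow(aggregates) > 0) {
    fem <- filter(aggregates, .data$direction == "female", .data$chrom != "")
    cl <- purrr::map_dfr(split(fem, fem$chrom),
                         function(d) find_clusters(d))
    if (nrow(cl) > 0) {
      letters_map <- tidyr::unnest(select(cl, "cluster_id", "members"),
                                   "members")
      letters_map <- mutate(letters_map,
                            cluster = letters[.data$cluster_id],
                            entry_base = .data$members)
      out <- mutate(out, entry_base = sub("i$", "", .data$entry_id))
      out <- left_join(out, select(letters_map, "entry_base", "cluster"),
                       by = "entry_base")
      out <- select(out, -"entry_base")
    } else {
      out$cluster <- NA_character_
    }
  }
  arrange(out, .data$direction, .data$chrom, .data$start)
}
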