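fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "xsexbias")
  if (p == "") {
    abort(sprintf("packaged fixture '%s' not found", file),
          class = "xsexbias_config_error")
  }
  p
}

#' Load a packaged summary-table fixture
#'
#' The package ships transcriptions of two published summary tables of
#' sex-biased expression in six somatic mouse tissues:
#' * `table1` -- per-tissue, per-chromosome-class counts and percentages of
#'   probes called sex-biased at p<0.001 (columns `n_biased`, `n_female`,
#'   `n_male` and the corresponding percentages of all probes in the class);
#' * `table2A` / `table2B` -- per-probe records of female-biased
#'   (respectively male-biased) transcripts significant in at least two
#'   tissues at p<0.01, with probe alignment coordinates (1-based inclusive),
#'   per-tissue fold-change magnitude or `ns`, a two-level significance
#'   grade (`p<0.001` for values printed bold, `p<0.01` for italic), a
#'   gene-level entry label (a number; an `i` suffix marks intronic probes of
#'   the numbered gene, a bare `i` a standalone intronic record) and a
#'   cluster letter where the source marks genes less than 50 kb apart.
#'
#' @param name One of `"table1"`, `"table2A"`, `"table2B"`.
#' @return A tibble; see Details. Table 2 fixtures carry the parsed columns
#'   `start`, `stop` (numeric; `NA` for probes aligned to a random contig),
#'   `fc_*` (fold-change magnitude per tissue, `NA` where not significant),
#'   `grade_*` (significance grade per tissue), `escapee` (printed
#'   known-escapee mark), `alias`, `feature_class`, `host_gene`,
#'   `entry_num`, `intron` and `direction`.
#' @export
load_fixture <- function(name = c("table1", "table2A", "table2B")) {
  name <- match.arg(name)
  if (name == "table1") {
    tbl <- readr::read_tsv(fixture_path("table1.tsv"),
                           col_types = "ccdddddd", na = character(),
                           progress = FALSE)
    return(tbl)
  }
  direction <- if (name == "table2A") "female" else "male"
  raw <- readr::read_tsv(fixture_path(paste0(name, ".tsv")),
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  raw$cluster[is.na(raw$cluster)] <- ""
  parse_coord <- function(x) {
    x <- sub("^\\^", "", x)
    suppressWarnings(as.numeric(x))   # "Rnd ..." -> NA (random contig)
  }
  cell_fc <- function(x) {
    bare <- gsub("\\*", "", x)
    ifelse(bare == "ns", NA_real_, suppressWarnings(as.numeric(bare)))
  }
  cell_grade <- function(x) {
    bare <- gsub("\\*", "", x)
    dplyr::case_when(
      bare == "ns" ~ NA_character_,
      grepl("^\\*\\*", x) ~ "p<0.001",
      grepl("^\\*", x) ~ "p<0.01",
      TRUE ~ NA_character_
    )
  }
  sym_raw <- raw$gene_symbol
  intronic <- grepl("intron\\)$", sym_raw)
  intergenic <- grepl("Intergenic\\)$", sym_raw)
  host <- ifelse(intronic, sub("^--- \\((.*) intron\\)$", "\\1", sym_raw), "")
  escapee <- grepl("\\*$", sym_raw)
  dual <- grepl("&$", sym_raw)
  sym <- sub("[*&]+$", "", sym_raw)
  alias <- ifelse(grepl("\\(", sym) & !intronic & !intergenic,
                  sub("^.*\\((.*)\\)$", "\\1", sym), "")
  sym <- trimws(sub(" *\\(.*\\)$", "", sym))
  sym[intronic | intergenic] <- ""
  out <- tibble(
    probe_id = raw$probe_id,
    start_align = raw$start_align,
    stop_align = raw$stop_align,
    start = parse_coord(raw$start_align),
    stop = parse_coord(raw$stop_align),
    gene_symbol = sym,
    alias = alias,
    host_gene = host,
    escapee = escapee,
    dual = dual,
    feature_class = dplyr::case_when(intronic ~ "intron",
                                     intergenic ~ "intergenic",
                                     TRUE ~ "gene"),
    entry = raw$entry,
    entry_num = suppressWarnings(as.integer(sub("i$", "", raw$entry))),
    intron = grepl("i$", raw$entry),
    cluster = raw$cluster,
    direction = direction
  )
  for (t in TISSUES_6) {
    out[[paste0("fc_", t)]] <- cell_fc(raw[[t]])
    out[[paste0("grade_", t)]] <- cell_grade(raw[[t]])
  }
  out
}

#' Derived chromosome-class probe totals
#'
#' The published summary table prints biased counts and the percentage each
#' count represents of its chromosome class, but never the class totals
#' themselves. The packaged `class_totals.tsv` records totals back-derived
#' from the count/percentage ratios (autosomes approximately 42,990 probes, X
#' 1,428, Y 33, unmapped 671); [derive_class_totals()] recomputes the
#' derivation from the Table 1 fixture as a consistency check.
#'
#' @return Named numeric vector of probe totals per chromosome class.
#' @export
class_totals <- function() {
  tbl <- readr::read_tsv(fixture_path("class_totals.tsv"), col_types = "cd",
                         na = character(), progress = FALSE)
  setNames(tbl$n_probes, tbl$chrom_class)
}

#' Re-derive chromosome-class totals from the Table 1 fixture
#'
#' Pools every count/percentage pair of a class (total, female and male
#' columns over all tissues, skipping cells printed as 0 or 0.00) and returns
#' `sum(counts) / sum(percentages/100)` per class.
#'
#' @param table1 Table 1 fixture tibble, from `load_fixture("table1")`.
#' @return Named numeric vector of derived totals (unrounded).
#' @export
derive_class_totals <- function(table1 = load_fixture("table1")) {
  long <- tidyr::pivot_longer(table1, cols = -c("tissue", "chrom_class"),
                              names_to = "col", values_to = "value")
  long <- mutate(long,
                 kind = if_else(grepl("^pct", .data$col), "pct", "count"),
                 grp = sub("^(pct_|n_)", "", .data$col))
  wide <- tidyr::pivot_wider(select(long, -"col"), names_from = "kind",
                             values_from = "value")
  wide <- filter(wide, .data$count > 0, .data$pct > 0)
  out <- summarise(group_by(wide, .data$chrom_class),
                   total = sum(.data$count) / sum(.data$pct / 100),
                   .groups = "drop")
  setNames(out$total, out$chrom_class)
}

#' Known mouse X-inactivation escapees
#'
#' The packaged list of 17 genes with established escape from X-chromosome
#' inactivation in mouse (Xist, Shroom4, Mid1, Kdm6a, Kdm5c, Jpx, Ftx,
#' Eif2s3x, Ddx3x, Car5b, Bgn, BC022960, D930009K15Rik, 6720401G13Rik,
#' 5530601H04Rik, 2610029G23Rik, 1810030O07Rik), used by default when
#' excluding escapees from enrichment contrasts.
#'
#' @return Character vector of gene symbols.
#' @export
mouse_escapees <- function() {
  read_escapee_list(fixture_path("escapees.tsv"))
}

#' Convert a Table 2 fixture into long per-probe, per-tissue records
#'
#' Expands the per-tissue fold-change/grade columns into one row per probe
#' and tissue with a pseudo p-value representing the printed significance
#' grade (midpoint value below the grade's threshold; 1 where `ns`), so that
#' the cross-tissue consistency operations can run unchanged on fixture data.
#'
#' @param fixture Tibble from `load_fixture("table2A")` or `"table2B"`.
#' @return Long tibble with columns `probe_id`, `tissue`, `fold_change`,
#'   `grade`, `p`, `delta` (signed log2 fold-change, negative for the
#'   male-biased table).
#' @export
fixture_records <- function(fixture) {
  sign <- if_else(fixture$direction[1] == "female", 1, -1)
  purrr::map_dfr(TISSUES_6, function(t) {
    fc <- fixture[[paste0("fc_", t)]]
    grade <- fixture[[paste0("grade_", t)]]
    tibble(
      probe_id = fixture$probe_id,
      tissue = t,
      fold_change = fc,
      grade = grade,
      p = dplyr::case_when(grade == "p<0.001" ~ 5e-4,
                           grade == "p<0.01" ~ 5e-3,
                           TRUE ~ 1),
      delta = if_else(is.na(fc), 0, sign * log2(fc))
    )
  })
}

#' Build a probe annotation from the Table 2 fixtures
#'
#' @param fixtures List of Table 2 fixture tibbles to combine (default both
#'   sections).
#' @return Annotation tibble in the layout of [read_annotation()]; all probes
#'   are X-linked, intronic probes carry their numbered host entry (or a
#'   standalone entry for the unnumbered intronic records).
#' @export
fixture_annotation <- function(fixtures = list(load_fixture("table2A"),
                                               load_fixture("table2B"))) {
  ann <- purrr::map_dfr(fixtures, function(fx) {
    prefix <- if (fx$direction[1] == "female") "F" else "M"
    entry_id <- ifelse(is.na(fx$entry_num),
                       paste0(prefix, ":", fx$probe_id),
                       paste0(prefix, fx$entry))
    tibble(
      probe_id = fx$probe_id,
      entry_id = entry_id,
      gene_symbol = if_else(fx$gene_symbol == "" & fx$host_gene != "",
                            fx$host_gene, fx$gene_symbol),
      chrom_class = "X",
      chrom = "X",
      start = fx$start,
      stop = fx$stop,
      feature_class = fx$feature_class,
      ensembl_id = "",
      alias = fx$alias,
      host_gene = fx$host_gene
    )
  })
  validate_annotation(ann)
}
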