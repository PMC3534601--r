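#' Read a log2 expression matrix
#'
#' Reads a tab-delimited expression table: header row of sample ids, first
#' column `probe_id`, one row per probe, cells holding log2 intensities.
#' Values are validated to be numeric and finite and probe ids to be unique.
#'
#' @param path Path to a tab-delimited file.
#' @return A tibble with a character `probe_id` column followed by one numeric
#'   column per sample, in file order.
#' @export
read_expression <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (names(tbl)[1] != "probe_id") {
    abort(sprintf("expression file %s: first column must be 'probe_id', found '%s'",
                  path, names(tbl)[1]), class = "xsexbias_format_error")
  }
  if (ncol(tbl) < 2) {
    abort(sprintf("expression file %s has no sample columns", path),
          class = "xsexbias_format_error")
  }
  dup <- tbl$probe_id[duplicated(tbl$probe_id)]
  if (length(dup) > 0) {
    abort(sprintf("expression file %s: duplicated probe id(s): %s",
                  path, paste(unique(dup), collapse = ", ")),
          class = "xsexbias_format_error")
  }
  dups <- names(tbl)[duplicated(names(tbl))]
  if (length(dups) > 0) {
    abort(sprintf("expression file %s: duplicated sample id(s): %s",
                  path, paste(unique(dups), collapse = ", ")),
          class = "xsexbias_format_error")
  }
  vals <- suppressWarnings(purrr::map(tbl[-1], as.numeric))
  bad <- purrr::map(vals, ~ which(!is.finite(.x)))
  offending <- purrr::keep(bad, ~ length(.x) > 0)
  if (length(offending) > 0) {
    line <- offending[[1]][1] + 1L   # + header line
    abort(sprintf("expression file %s: non-numeric or non-finite value in column '%s', line %d",
                  path, names(offending)[1], line),
          class = "xsexbias_format_error")
  }
  tibble(probe_id = tbl$probe_id, !!!vals)
}

#' Write a log2 expression matrix
#'
#' @param expr Expression tibble as returned by [read_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(names(expr)[1] == "probe_id")
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

expr_values <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$probe_id
  m
}

#' Standardize an expression matrix to a target pooled mean and SD
#'
#' Applies a single affine transform to the pooled matrix (not per probe or
#' per array) so that the grand mean and grand standard deviation of all
#' values equal the targets. The conventional targets for these arrays are a
#' mean of 8 and an SD of 2 on the log2 scale.
#'
#' @param expr Expression tibble (first column `probe_id`).
#' @param target_mean,target_sd Targets for the pooled mean and SD.
#' @return Expression tibble of the same shape.
#' @export
standardize_expression <- function(expr, target_mean = 8, target_sd = 2) {
  m <- expr_values(expr)
  mu <- mean(m)
  s <- stats::sd(as.vector(m))
  if (!is.finite(s) || s == 0) {
    abort("cannot standardize: pooled standard deviation is zero",
          class = "xsexbias_degenerate_error")
  }
  out <- (m - mu) / s * target_sd + target_mean
  tibble(probe_id = expr$probe_id, !!!as.data.frame(out))
}

CHROM_CLASSES <- c("A", "X", "Y", "NA")
FEATURE_CLASSES <- c("gene", "intron", "intergenic")

ANN_COLS <- c("probe_id", "entry_id", "gene_symbol", "chrom_class", "chrom",
              "start", "stop", "feature_class", "ensembl_id")

#' Read a probe annotation table
#'
#' Tab-delimited columns: `probe_id`, `entry_id`, `gene_symbol`,
#' `chrom_class` (A/X/Y/NA), `chrom`, `start`, `stop` (1-based inclusive),
#' `feature_class` (gene/intron/intergenic), `ensembl_id`. Probes with an
#' empty chromosome are given `chrom_class = "NA"` (unmapped).
#'
#' @param path Path to a tab-delimited annotation file.
#' @return A tibble with one validated row per probe.
#' @export
read_annotation <- function(path) {
  # everything is read as text first: the literal token "NA" is a valid
  # chrom_class (unmapped) and must not be eaten by the NA handling
  ann <- readr::read_tsv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  for (col in c("gene_symbol", "entry_id", "ensembl_id", "chrom")) {
    if (col %in% names(ann)) ann[[col]][is.na(ann[[col]])] <- ""
  }
  for (col in c("start", "stop")) {
    if (col %in% names(ann)) {
      x <- ann[[col]]
      x[x %in% c("", "NA")] <- NA
      ann[[col]] <- as.numeric(x)
    }
  }
  validate_annotation(ann)
}

#' Validate a probe annotation tibble
#'
#' @param ann Annotation tibble with the columns of [read_annotation()].
#' @return The validated (possibly repaired) tibble.
#' @export
validate_annotation <- function(ann) {
  missing_cols <- setdiff(ANN_COLS, names(ann))
  if (length(missing_cols) > 0) {
    abort(sprintf("annotation is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "xsexbias_format_error")
  }
  ann <- as_tibble(ann)[c(ANN_COLS, setdiff(names(ann), ANN_COLS))]
  dup <- ann$probe_id[duplicated(ann$probe_id)]
  if (length(dup) > 0) {
    abort(sprintf("annotation: duplicated probe id(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "xsexbias_format_error")
  }
  # unmapped convention: empty chromosome iff class NA
  unmapped <- is.na(ann$chrom) | ann$chrom == ""
  ann$chrom_class[unmapped] <- "NA"
  bad_class <- setdiff(unique(ann$chrom_class), CHROM_CLASSES)
  if (length(bad_class) > 0) {
    abort(sprintf("annotation: unknown chrom_class token(s): %s",
                  paste(bad_class, collapse = ", ")),
          class = "xsexbias_format_error")
  }
  bad_feature <- setdiff(unique(ann$feature_class), FEATURE_CLASSES)
  if (length(bad_feature) > 0) {
    abort(sprintf("annotation: unknown feature_class token(s): %s",
                  paste(bad_feature, collapse = ", ")),
          class = "xsexbias_format_error")
  }
  flipped <- !is.na(ann$start) & !is.na(ann$stop) & ann$start > ann$stop
  if (any(flipped)) {
    abort(sprintf("annotation: start > stop for probe(s): %s",
                  paste(ann$probe_id[flipped], collapse = ", ")),
          class = "xsexbias_format_error")
  }
  ann
}

#' Write a probe annotation table
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(validate_annotation(ann), path, progress = FALSE)
  invisible(path)
}

#' Read a sample table
#'
#' Tab-delimited columns `sample_id`, `sex` (`female`/`male`), `tissue`.
#'
#' @param path Path to a tab-delimited file.
#' @return A validated tibble.
#' @export
read_samples <- function(path) {
  smp <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  validate_samples(smp)
}

validate_samples <- function(samples) {
  stopifnot(all(c("sample_id", "sex", "tissue") %in% names(samples)))
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("sample table: duplicated sample id(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "xsexbias_format_error")
  }
  bad <- setdiff(unique(samples$sex), c("female", "male"))
  if (length(bad) > 0) {
    abort(sprintf("sample table: sex must be female/male, found: %s",
                  paste(bad, collapse = ", ")),
          class = "xsexbias_format_error")
  }
  as_tibble(samples)
}

#' Write a sample table
#' @param samples Sample tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(validate_samples(samples), path, progress = FALSE)
  invisible(path)
}

#' Read an escapee gene list
#'
#' One gene symbol per line (a header line `gene_symbol` is allowed).
#'
#' @param path Path to the list.
#' @return Character vector of gene symbols.
#' @export
read_escapee_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x <- x[x != "" & x != "gene_symbol"]
  if (length(x) == 0) {
    abort("escapee list is empty", class = "xsexbias_format_error")
  }
  unique(x)
}

#' Read a gene-to-phylogenetic-branch table
#'
#' Tab-delimited columns `gene_key` (Ensembl id or symbol) and `branch`
#' (integer 0--11, the phylogenetic stratum at which orthologs first appear).
#'
#' @param path Path to the table.
#' @return A tibble with columns `gene_key`, `branch`.
#' @export
read_branch_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "ci", progress = FALSE)
  stopifnot(all(c("gene_key", "branch") %in% names(tbl)))
  validate_branch_table(tbl)
}

validate_branch_table <- function(tbl) {
  if (any(tbl$branch < 0 | tbl$branch > 11)) {
    abort("branch table: branches must lie in 0..11",
          class = "xsexbias_format_error")
  }
  dup <- tbl$gene_key[duplicated(tbl$gene_key)]
  if (length(dup) > 0) {
    abort(sprintf("branch table: duplicated gene key(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "xsexbias_format_error")
  }
  as_tibble(tbl)
}
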