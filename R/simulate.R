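#' Configuration for a synthetic multi-tissue two-sex experiment
#'
#' Defaults emulate the probe composition and effect structure of a
#' six-tissue somatic screen on whole-genome expression arrays:
#' about 43,000 autosomal probes, 1,428 X probes, a handful of Y probes and
#' a few unmapped probes; log2 intensities centred at 8 with a pooled
#' spread of 2 (between-probe baseline SD 2, within-probe residual SD 0.5);
#' small female-biased X effects (log2 differences 0.07--1, i.e.
#' fold-changes 1.05--2) against larger autosomal effects in the two
#' "dimorphic" (kidney/liver-like) tissues; Y probes expressed in males
#' only; one Xist-like X probe with extreme female-only expression; a set
#' of escapee-like X genes female-biased in every tissue; planted positional
#' clusters of female-biased X genes; and gene-age branch labels 0--11.
#'
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @param n_tissues Number of tissues.
#' @param samples_per_sex Samples per sex per tissue (scalar or one value
#'   per tissue).
#' @param n_probes Named counts per chromosome class (`A`, `X`, `Y`, `NA`).
#' @param baseline_mean,baseline_sd Mean and SD of per-probe baseline log2
#'   intensities (the between-probe spread that dominates the pooled SD-2
#'   scale of standardized arrays).
#' @param noise_sd Within-probe residual SD in log2 units.
#' @param frac_biased Nested list: per class (`A`, `X`, `NA`), the fraction
#'   of probes planted as `female`- and `male`-biased in each tissue.
#' @param effect_range_x Range of |log2 difference| for X effects.
#' @param effect_range_a Range for autosomal effects in ordinary tissues.
#' @param dimorphic_effect_range_a Range for autosomal effects in the
#'   dimorphic tissues (allows |log2 difference| > 2, i.e. >4-fold).
#' @param n_dimorphic Number of leading tissues treated as dimorphic.
#' @param n_escapees Number of X entries female-biased in all tissues.
#' @param escapee_effect Range of |log2 difference| for escapee entries.
#' @param xist_like Plant one X probe with female-only expression
#'   (female mean `y_floor + 7`, male at `y_floor`, a 128-fold change).
#' @param y_male_only Express Y probes in males only, females at `y_floor`.
#' @param y_floor Fixed low intensity reported for a silent probe.
#' @param clusters List of planted female-biased clusters, each
#'   `list(n_genes =, max_gap =)`; members are female-biased in
#'   `cluster_n_tissues` tissues with effects from `cluster_effect`.
#' @param cluster_n_tissues,cluster_effect See `clusters`.
#' @param branch_probs Probabilities over branches 0--11 for X entries.
#' @param old_bias_weight Relative weight of old-branch (0--5) X probes when
#'   sampling female-biased probes; values > 1 enrich old genes among
#'   female-biased entries (age-by-bias interaction).
#' @param x_length Optional X-chromosome length (bp) used to validate the
#'   planted layout; `NULL` leaves the synthetic coordinate space
#'   unconstrained.
#' @return A validated `xsexbias_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_tissues = 6,
                       samples_per_sex = 30,
                       n_probes = c(A = 43000, X = 1428, Y = 16, "NA" = 30),
                       baseline_mean = 8, baseline_sd = 2, noise_sd = 0.5,
                       frac_biased = list(A = c(female = 0.05, male = 0.05),
                                          X = c(female = 0.10, male = 0.04),
                                          "NA" = c(female = 0.03, male = 0.03)),
                       effect_range_x = c(0.07, 1.0),
                       effect_range_a = c(0.07, 1.0),
                       dimorphic_effect_range_a = c(0.07, 2.5),
                       n_dimorphic = 2,
                       n_escapees = 10,
                       escapee_effect = c(0.2, 0.8),
                       xist_like = TRUE,
                       y_male_only = TRUE,
                       y_floor = 4.0,
                       clusters = list(list(n_genes = 5, max_gap = 40000),
                                       list(n_genes = 3, max_gap = 40000)),
                       cluster_n_tissues = 3,
                       cluster_effect = c(0.3, 0.8),
                       branch_probs = c(0.34, 0.10, 0.15, 0.05, 0.01, 0.08,
                                        0.06, 0.05, 0.005, 0.005, 0.07, 0.08),
                       old_bias_weight = 1,
                       x_length = NULL) {
  cfg <- list(seed = as.integer(seed), n_tissues = n_tissues,
              samples_per_sex = samples_per_sex, n_probes = n_probes,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, frac_biased = frac_biased,
              effect_range_x = effect_range_x, effect_range_a = effect_range_a,
              dimorphic_effect_range_a = dimorphic_effect_range_a,
              n_dimorphic = n_dimorphic, n_escapees = n_escapees,
              escapee_effect = escapee_effect, xist_like = xist_like,
              y_male_only = y_male_only, y_floor = y_floor,
              clusters = clusters, cluster_n_tissues = cluster_n_tissues,
              cluster_effect = cluster_effect, branch_probs = branch_probs,
              old_bias_weight = old_bias_weight, x_length = x_length)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (cfg$n_tissues < 1 || any(cfg$samples_per_sex < 1)) {
    abort("n_tissues and samples_per_sex must be positive",
          class = "xsexbias_config_error")
  }
  if (!all(c("A", "X", "Y", "NA") %in% names(cfg$n_probes)) ||
      any(cfg$n_probes < 0)) {
    abort("n_probes needs non-negative counts named A, X, Y, NA",
          class = "xsexbias_config_error")
  }
  fr <- unlist(cfg$frac_biased)
  if (any(fr < 0 | fr > 1)) {
    abort("biased fractions must lie in [0, 1]",
          class = "xsexbias_config_error")
  }
  if (abs(sum(cfg$branch_probs) - 1) > 1e-8 || length(cfg$branch_probs) != 12) {
    abort("branch_probs must be 12 probabilities summing to 1",
          class = "xsexbias_config_error")
  }
  if (length(cfg$samples_per_sex) == 1) {
    cfg$samples_per_sex <- rep(cfg$samples_per_sex, cfg$n_tissues)
  }
  if (length(cfg$samples_per_sex) != cfg$n_tissues) {
    abort("samples_per_sex must be scalar or one value per tissue",
          class = "xsexbias_config_error")
  }
  if (!is.null(cfg$x_length)) {
    need <- sum(purrr::map_dbl(cfg$clusters, function(cl)
      cl$n_genes * (cl$max_gap + 20000)))
    if (need > cfg$x_length) {
      abort("planted cluster specification exceeds the X-chromosome length",
            class = "xsexbias_config_error")
    }
  }
  structure(cfg, class = "xsexbias_sim_config")
}

# Lay out X entries along a synthetic chromosome: cluster blocks inserted at
# random slots among singleton genes; singletons are spaced >= 5x the 50 kb
# proximity threshold so no accidental clusters can arise, cluster members
# at gaps in [1 kb, max_gap).
layout_x_coords <- function(n_x, clusters) {
  n_clustered <- sum(purrr::map_dbl(clusters, "n_genes"))
  if (n_clustered > n_x) {
    abort("more clustered genes than X probes",
          class = "xsexbias_config_error")
  }
  n_single <- n_x - n_clustered
  units <- c(rep(0L, n_single), seq_along(clusters))  # 0 = singleton
  units <- units[sample.int(length(units), length(units))]
  start <- numeric(n_x); stop <- numeric(n_x); cluster_id <- rep(NA_integer_, n_x)
  pos <- 3e6
  i <- 1L
  for (u in units) {
    if (u == 0L) {
      len <- runif(1, 500, 20000)
      start[i] <- pos; stop[i] <- pos + len
      pos <- stop[i] + runif(1, 250000, 350000)
      i <- i + 1L
    } else {
      ng <- clusters[[u]]$n_genes
      for (j in seq_len(ng)) {
        len <- runif(1, 500, 20000)
        start[i] <- pos; stop[i] <- pos + len
        cluster_id[i] <- u
        pos <- stop[i] +
          if (j < ng) runif(1, 1000, clusters[[u]]$max_gap * 0.98)
          else runif(1, 250000, 350000)
        i <- i + 1L
      }
    }
  }
  tibble(start = round(start), stop = round(stop), cluster_id = cluster_id)
}

#' Generate a synthetic multi-tissue two-sex expression experiment
#'
#' Per tissue and probe, female samples are drawn from
#' Normal(baseline + delta/2, noise_sd) and male samples from
#' Normal(baseline - delta/2, noise_sd), where delta is the planted log2
#' sex difference (positive = female-biased) and the symmetric shift keeps
#' the pooled mean at the baseline. Y probes (and the male side of the
#' Xist-like probe) are replaced by a fixed low floor in the silent sex.
#' Planted escapees are female-biased in every tissue, cluster members in
#' `cluster_n_tissues` tissues, and the remaining effects are sampled
#' independently per tissue at the configured class fractions.
#'
#' @param config An [sim_config()] object.
#' @return List of class `xsexbias_sim` with elements `tissues` (named list
#'   of expression tibbles), `samples`, `annotation`, `truth`
#'   (`probe_effects`: probe x tissue planted deltas in long form;
#'   `entries`: per-probe escapee flag, cluster id, branch) and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  cfg <- validate_sim_config(unclass(config))
  set.seed(cfg$seed)
  n <- cfg$n_probes
  tissues <- paste0("tissue", seq_len(cfg$n_tissues))
  spsex <- if (length(cfg$samples_per_sex) == 1)
    rep(cfg$samples_per_sex, cfg$n_tissues) else cfg$samples_per_sex

  ids <- list(
    A = sprintf("simA_%05d_at", seq_len(n[["A"]])),
    X = sprintf("simX_%04d_at", seq_len(n[["X"]])),
    Y = sprintf("simY_%02d_at", seq_len(n[["Y"]])),
    "NA" = sprintf("simU_%03d_at", seq_len(n[["NA"]]))
  )

  # --- X layout, special roles -------------------------------------------
  xl <- layout_x_coords(n[["X"]], cfg$clusters)
  n_x <- n[["X"]]
  special <- rep("", n_x)
  special[!is.na(xl$cluster_id)] <- "cluster"
  free <- which(special == "")
  if (cfg$xist_like) {
    if (length(free) == 0) abort("no free X probe for the Xist-like feature",
                                 class = "xsexbias_config_error")
    xist_idx <- free[1]
    special[xist_idx] <- "xist"
    free <- free[-1]
  } else xist_idx <- NA_integer_
  if (cfg$n_escapees > length(free)) {
    abort("n_escapees exceeds available X probes",
          class = "xsexbias_config_error")
  }
  esc_idx <- free[sample.int(length(free), cfg$n_escapees)]
  special[esc_idx] <- "escapee"

  branch <- sample(0:11, n_x, replace = TRUE, prob = cfg$branch_probs)

  # --- annotation ---------------------------------------------------------
  a_chrom <- rep(as.character(1:19), length.out = n[["A"]])
  a_start <- 3e6 + 100000 * (seq_len(n[["A"]]) %/% 19)
  ann <- bind_rows(
    tibble(probe_id = ids$A, entry_id = sprintf("gA%05d", seq_len(n[["A"]])),
           gene_symbol = sprintf("SimA%05d", seq_len(n[["A"]])),
           chrom_class = "A", chrom = a_chrom,
           start = a_start, stop = a_start + 5000,
           feature_class = "gene", ensembl_id = sprintf("ENSSIMA%05d", seq_len(n[["A"]]))),
    tibble(probe_id = ids$X, entry_id = sprintf("gX%04d", seq_len(n_x)),
           gene_symbol = sprintf("SimX%04d", seq_len(n_x)),
           chrom_class = "X", chrom = "X",
           start = xl$start, stop = xl$stop,
           feature_class = "gene", ensembl_id = sprintf("ENSSIMX%04d", seq_len(n_x))),
    tibble(probe_id = ids$Y, entry_id = sprintf("gY%02d", seq_len(n[["Y"]])),
           gene_symbol = sprintf("SimY%02d", seq_len(n[["Y"]])),
           chrom_class = "Y", chrom = "Y",
           start = 3e6 + 50000 * seq_len(n[["Y"]]),
           stop = 3e6 + 50000 * seq_len(n[["Y"]]) + 5000,
           feature_class = "gene", ensembl_id = sprintf("ENSSIMY%02d", seq_len(n[["Y"]]))),
    tibble(probe_id = ids[["NA"]], entry_id = sprintf("gU%03d", seq_len(n[["NA"]])),
           gene_symbol = "", chrom_class = "NA", chrom = "",
           start = NA_real_, stop = NA_real_,
           feature_class = "gene", ensembl_id = "")
  )
  ann <- validate_annotation(ann)
  all_ids <- c(ids$A, ids$X, ids$Y, ids[["NA"]])
  n_total <- length(all_ids)

  baseline <- rnorm(n_total, cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- all_ids

  # --- planted effects ----------------------------------------------------
  runif_sign <- function(k, range) {
    runif(k, range[1], range[2]) * sample(c(-1, 1), k, replace = TRUE)
  }
  delta <- matrix(0, nrow = n_total, ncol = cfg$n_tissues,
                  dimnames = list(all_ids, tissues))
  x_off <- n[["A"]]                      # row offset of X probes

  # escapees + Xist-like: female-biased everywhere
  if (length(esc_idx) > 0) {
    esc_delta <- runif(length(esc_idx), cfg$escapee_effect[1], cfg$escapee_effect[2])
    delta[x_off + esc_idx, ] <- esc_delta      # recycled per column
  }
  if (cfg$xist_like) {
    delta[x_off + xist_idx, ] <- (cfg$y_floor + 7) - cfg$y_floor   # log2 FC 7
  }
  # cluster members: female-biased in the leading cluster_n_tissues tissues
  cl_members <- which(special == "cluster")
  if (length(cl_members) > 0) {
    kt <- min(cfg$cluster_n_tissues, cfg$n_tissues)
    delta[x_off + cl_members, seq_len(kt)] <-
      runif(length(cl_members) * kt, cfg$cluster_effect[1], cfg$cluster_effect[2])
  }
  # fraction-based effects, independent per tissue
  plain_x <- which(special == "")
  w_x <- if (cfg$old_bias_weight == 1) NULL else
    ifelse(branch[plain_x] <= 5, cfg$old_bias_weight, 1)
  for (t in seq_len(cfg$n_tissues)) {
    a_range <- if (t <= cfg$n_dimorphic) cfg$dimorphic_effect_range_a
               else cfg$effect_range_a
    for (cls in c("A", "X", "NA")) {
      fr <- cfg$frac_biased[[cls]]
      if (is.null(fr)) next
      pool <- switch(cls,
                     A = seq_len(n[["A"]]),
                     X = x_off + plain_x,
                     "NA" = n[["A"]] + n_x + n[["Y"]] + seq_len(n[["NA"]]))
      k_f <- round(fr[["female"]] * n[[cls]])
      k_m <- round(fr[["male"]] * n[[cls]])
      if (k_f + k_m == 0 || length(pool) == 0) next
      w <- if (cls == "X") w_x else NULL
      pick <- pool[sample.int(length(pool), min(k_f + k_m, length(pool)),
                              prob = w)]
      rng <- if (cls == "X") cfg$effect_range_x else a_range
      kf <- min(k_f, length(pick))
      if (kf > 0) delta[pick[seq_len(kf)], t] <-
          runif(kf, rng[1], rng[2])
      if (length(pick) > kf) delta[pick[(kf + 1):length(pick)], t] <-
          -runif(length(pick) - kf, rng[1], rng[2])
    }
  }
  # Y probes: male-only expression
  y_rows <- n[["A"]] + n_x + seq_len(n[["Y"]])
  if (cfg$y_male_only && n[["Y"]] > 0) {
    delta[y_rows, ] <- rep(cfg$y_floor - baseline[y_rows], cfg$n_tissues)
  }

  # --- expression matrices ------------------------------------------------
  expr <- vector("list", cfg$n_tissues)
  names(expr) <- tissues
  samples <- vector("list", cfg$n_tissues)
  for (t in seq_len(cfg$n_tissues)) {
    ns <- spsex[t]
    sid <- c(sprintf("%s_F%03d", tissues[t], seq_len(ns)),
             sprintf("%s_M%03d", tissues[t], seq_len(ns)))
    sex <- rep(c("female", "male"), each = ns)
    mu_f <- baseline + delta[, t] / 2
    mu_m <- baseline - delta[, t] / 2
    if (cfg$y_male_only && n[["Y"]] > 0) {
      mu_f[y_rows] <- cfg$y_floor
      mu_m[y_rows] <- baseline[y_rows]
    }
    if (cfg$xist_like) {
      mu_f[x_off + xist_idx] <- cfg$y_floor + 7
      mu_m[x_off + xist_idx] <- cfg$y_floor
    }
    vals <- matrix(rnorm(n_total * 2 * ns,
                         mean = c(rep(mu_f, ns), rep(mu_m, ns)),
                         sd = cfg$noise_sd),
                   nrow = n_total, ncol = 2 * ns,
                   dimnames = list(all_ids, sid))
    # silent-sex probes report the fixed floor, not a noisy draw
    if (cfg$y_male_only && n[["Y"]] > 0) {
      vals[y_rows, sex == "female"] <- cfg$y_floor
    }
    if (cfg$xist_like) {
      vals[x_off + xist_idx, sex == "male"] <- cfg$y_floor
    }
    expr[[t]] <- tibble(probe_id = all_ids, !!!as.data.frame(vals))
    samples[[t]] <- tibble(sample_id = sid, sex = sex, tissue = tissues[t])
  }

  truth_effects <- as_tibble(delta, rownames = "probe_id")
  entries <- tibble(
    probe_id = all_ids,
    entry_id = ann$entry_id,
    escapee = seq_len(n_total) %in% (x_off + esc_idx),
    cluster_id = c(rep(NA_integer_, n[["A"]]), xl$cluster_id,
                   rep(NA_integer_, n[["Y"]] + n[["NA"]])),
    xist_like = if (cfg$xist_like) seq_len(n_total) == (x_off + xist_idx)
                else FALSE,
    branch = c(rep(NA_integer_, n[["A"]]), branch,
               rep(NA_integer_, n[["Y"]] + n[["NA"]]))
  )
  structure(list(tissues = expr, samples = bind_rows(samples),
                 annotation = ann,
                 truth = list(probe_effects = truth_effects,
                              entries = entries),
                 config = cfg),
            class = "xsexbias_sim")
}

#' Generate a null experiment (no sex effects)
#'
#' As [simulate_experiment()] with every planted effect forced to zero and
#' the Y-chromosome and Xist-like features disabled, so any downstream
#' positive is a false positive.
#'
#' @param config An [sim_config()] object; effect settings are overridden.
#' @return A `xsexbias_sim` object whose planted deltas are all zero.
#' @export
simulate_null <- function(config = sim_config()) {
  cfg <- unclass(validate_sim_config(unclass(config)))
  cfg$frac_biased <- purrr::map(cfg$frac_biased, ~ c(female = 0, male = 0))
  cfg$n_escapees <- 0
  cfg$clusters <- list()
  cfg$xist_like <- FALSE
  cfg$y_male_only <- FALSE
  simulate_experiment(validate_sim_config(cfg))
}

#' @export
print.xsexbias_sim <- function(x, ...) {
  cat(sprintf("Synthetic two-sex experiment: %d tissues, %d probes, seed %d\n",
              length(x$tissues), nrow(x$annotation), x$config$seed))
  invisible(x)
}

#' Branch table of a simulated experiment
#'
#' @param sim An `xsexbias_sim` object.
#' @return Tibble (`gene_key`, `branch`) covering the X entries, keyed by
#'   Ensembl id, ready for [join_branches()].
#' @export
sim_branch_table <- function(sim) {
  ent <- filter(sim$truth$entries, !is.na(.data$branch))
  ens <- sim$annotation$ensembl_id[match(ent$probe_id, sim$annotation$probe_id)]
  validate_branch_table(tibble(gene_key = ens, branch = ent$branch))
}
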