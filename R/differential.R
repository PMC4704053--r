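#' RKTM normalization
#'
#' Reads per kilobase of feature per million library reads:
#' `count / ((feature_len_bp/1000) * (library_total/1e6))`. Applied to
#' methylation-supporting read counts so features of different length
#' and libraries of different depth are comparable.
#'
#' @param count Read count(s) for the feature.
#' @param feature_len_bp Feature length in bp (> 0).
#' @param library_total Library total read count (> 0).
#' @return RKTM value(s).
#' @examples
#' rktm(100, 1000, 1e6) # 100
#' @export
rktm <- function(count, feature_len_bp, library_total) {
  if (any(feature_len_bp <= 0) || any(library_total <= 0)) {
    abort("feature length and library total must be positive",
          class = "methylscape_input_error")
  }
  count / ((feature_len_bp / 1000) * (library_total / 1e6))
}

#' Two-sided Fisher's exact test on a 2x2 methylation table
#'
#' Tests whether the methylated/unmethylated read split differs between
#' treatment and control: the two-sided p sums all hypergeometric
#' tables (at fixed margins) with probability at most that of the
#' observed table. Vectorized over features. A zero margin (no reads in
#' one condition, or no methylated/unmethylated reads anywhere) carries
#' no information and returns p = 1 by convention.
#'
#' @param m_t,u_t Methylated/unmethylated counts in treatment.
#' @param m_c,u_c Methylated/unmethylated counts in control.
#' @return Vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(m_t, u_t, m_c, u_c) {
  n <- length(m_t)
  stopifnot(length(u_t) == n, length(m_c) == n, length(u_c) == n,
            all(c(m_t, u_t, m_c, u_c) >= 0))
  vapply(seq_len(n), function(i) {
    tab <- matrix(c(m_t[i], u_t[i], m_c[i], u_c[i]), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    min(1, fisher.test(tab)$p.value)  # guards FP overshoot above 1
  }, numeric(1))
}

#' Pool calls into per-feature methylation summaries
#'
#' Aggregates read counts over each gene x region x context (per
#' condition), attaches the feature length, the condition's library
#' total, RKTM and the pooled ML. The library total is, per the RKTM
#' definition used here, the condition's total methylation-supporting
#' reads (`library_mode = "methylated"`); set `"all"` to normalize by
#' all covered reads instead.
#'
#' @param calls Calls with a `condition` column covering the conditions
#'   to pool.
#' @param gene_models Region intervals from [build_gene_models()].
#' @param library_mode `"methylated"` (default) or `"all"`.
#' @return Tibble (`gene_id`, `region`, `context`, `condition`,
#'   `count_m`, `total`, `length_bp`, `library_total`, `rktm`, `ml`).
#' @export
feature_methylation <- function(calls, gene_models,
                                library_mode = c("methylated", "all")) {
  library_mode <- match.arg(library_mode)
  stopifnot_cols(calls, c("chrom", "pos", "context", "count_m", "count_u",
                          "condition"), "calls")
  libs <- calls |>
    group_by(.data$condition) |>
    summarise(library_total = if (library_mode == "methylated")
      sum(.data$count_m) else sum(.data$count_m) + sum(.data$count_u),
      .groups = "drop")
  lens <- gene_models |>
    group_by(.data$gene_id, .data$region) |>
    summarise(length_bp = sum(.data$end - .data$start), .groups = "drop")
  joined <- overlap_join(
    calls[, c("chrom", "pos", "context", "count_m", "count_u", "condition")],
    gene_models, keep = c("gene_id", "region"))
  joined |>
    group_by(.data$gene_id, .data$region, .data$context, .data$condition) |>
    summarise(count_m = sum(.data$count_m),
              total = sum(.data$count_m) + sum(.data$count_u),
              .groups = "drop") |>
    left_join(lens, by = c("gene_id", "region")) |>
    left_join(libs, by = "condition") |>
    mutate(rktm = rktm(.data$count_m, .data$length_bp, .data$library_total),
           ml = ifelse(.data$total > 0, .data$count_m / .data$total,
                       NA_real_))
}

#' Call differentially methylated features between two conditions
#'
#' Per feature x context: Fisher's exact test on the pooled
#' (methylated, unmethylated) read counts of the two conditions,
#' Benjamini-Hochberg across every test in the run, and a fold filter
#' on the RKTM ratio. A feature is significant when `q < fdr` and the
#' fold change (the RKTM ratio or its reciprocal, whichever exceeds 1)
#' is greater than `fold`. Direction is `hyper` when the treatment ML
#' exceeds the control ML. Features with zero coverage in either
#' condition are excluded. When one side's count is zero, a 0.5
#' pseudocount enters the RKTM ratio only (never the Fisher table) so
#' fold changes stay finite.
#'
#' @param features Output of [feature_methylation()] covering both
#'   conditions.
#' @param treatment,control Condition labels.
#' @param fdr BH threshold (default 0.05).
#' @param fold Fold-change threshold (default 2, strict inequality).
#' @param ratio_mode `"rktm"` (default) or `"ml"`: which quantity the
#'   fold filter is computed on.
#' @return A `meth_diff` tibble: `gene_id`, `region`, `context`,
#'   counts and MLs per side, `rktm_t`, `rktm_c`, `log2_ratio`,
#'   `fold_change`, `p`, `q`, `direction`, `significant`.
#' @export
call_differential_features <- function(features, treatment = "ATR",
                                       control = "CK", fdr = 0.05,
                                       fold = 2,
                                       ratio_mode = c("rktm", "ml")) {
  ratio_mode <- match.arg(ratio_mode)
  have <- unique(features$condition)
  if (!all(c(treatment, control) %in% have)) {
    abort("features must cover both the treatment and control condition",
          class = "methylscape_input_error")
  }
  wide <- features |>
    filter(.data$condition %in% c(treatment, control)) |>
    mutate(side = ifelse(.data$condition == treatment, "t", "c")) |>
    select("gene_id", "region", "context", "side", "count_m", "total",
           "length_bp", "library_total", "ml") |>
    tidyr::pivot_wider(names_from = "side",
                       values_from = c("count_m", "total", "ml",
                                       "library_total"),
                       values_fill = NA)
  mismatched <- !stats::complete.cases(
    wide[, c("total_t", "total_c")]) | wide$total_t == 0 | wide$total_c == 0
  wide <- wide[!mismatched, , drop = FALSE]
  if (nrow(wide) == 0) {
    abort("no feature has coverage in both conditions",
          class = "methylscape_input_error")
  }
  wide <- wide |>
    mutate(
      rktm_t = rktm(.data$count_m_t, .data$length_bp, .data$library_total_t),
      rktm_c = rktm(.data$count_m_c, .data$length_bp, .data$library_total_c),
      p = fisher_exact_2x2(.data$count_m_t,
                           .data$total_t - .data$count_m_t,
                           .data$count_m_c,
                           .data$total_c - .data$count_m_c),
      q = benjamini_hochberg(.data$p))
  if (ratio_mode == "rktm") {
    num_t <- ifelse(wide$count_m_t == 0 | wide$count_m_c == 0,
                    wide$count_m_t + 0.5, wide$count_m_t)
    num_c <- ifelse(wide$count_m_t == 0 | wide$count_m_c == 0,
                    wide$count_m_c + 0.5, wide$count_m_c)
    r <- rktm(num_t, wide$length_bp, wide$library_total_t) /
      rktm(num_c, wide$length_bp, wide$library_total_c)
  } else {
    r <- (wide$ml_t + ifelse(wide$ml_t == 0 | wide$ml_c == 0, 0.5 /
                               wide$total_t, 0)) /
      (wide$ml_c + ifelse(wide$ml_t == 0 | wide$ml_c == 0,
                          0.5 / wide$total_c, 0))
  }
  out <- wide |>
    mutate(log2_ratio = log2(r),
           fold_change = pmax(r, 1 / r),
           direction = ifelse(.data$ml_t > .data$ml_c, "hyper", "hypo"),
           significant = .data$q < fdr & .data$fold_change > fold) |>
    select("gene_id", "region", "context", "count_m_t", "total_t", "ml_t",
           "count_m_c", "total_c", "ml_c", "rktm_t", "rktm_c",
           "log2_ratio", "fold_change", "p", "q", "direction",
           "significant") |>
    arrange(.data$q, .data$gene_id)
  structure(out, class = c("meth_diff", class(tibble())),
            treatment = treatment, control = control, fdr = fdr,
            fold = fold, ratio_mode = ratio_mode)
}

#' @export
tidy.meth_diff <- function(x, ...) as_tibble(unclass_keep(x))

#' @export
glance.meth_diff <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    n_hyper = sum(x$significant & x$direction == "hyper"),
    n_hypo = sum(x$significant & x$direction == "hypo"),
    fdr = attr(x, "fdr"),
    fold = attr(x, "fold")
  )
}

#' Call differentially methylated regions from window profiles
#'
#' Runs the feature-level differential test on aligned window tilings
#' of the two conditions, then merges significant windows that are at
#' most `merge_gap` bp apart and share context and direction into DMR
#' intervals.
#'
#' @param windows_t,windows_c Window profiles from
#'   [sliding_window_levels()] for treatment and control (same tiling).
#' @param fdr,fold As in [call_differential_features()].
#' @param merge_gap Maximum gap (bp) between significant windows merged
#'   into one DMR (default 0: adjacent windows only).
#' @return Tibble of DMRs: `chrom`, `start`, `end`, `context`,
#'   `direction`, `n_windows`, `q` (smallest window q inside the DMR).
#' @export
call_dmrs <- function(windows_t, windows_c, fdr = 0.05, fold = 2,
                      merge_gap = 0) {
  key <- c("chrom", "start", "end", "context")
  tab <- inner_join(
    windows_t |> select(all_of(key), count_m_t = "count_m",
                        total_t = "total", ml_t = "ml"),
    windows_c |> select(all_of(key), count_m_c = "count_m",
                        total_c = "total", ml_c = "ml"),
    by = key) |>
    filter(.data$total_t > 0, .data$total_c > 0)
  if (nrow(tab) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  context = character(), direction = character(),
                  n_windows = integer(), q = double()))
  }
  lib_t <- sum(windows_t$count_m, na.rm = TRUE)
  lib_c <- sum(windows_c$count_m, na.rm = TRUE)
  len <- tab$end - tab$start
  num_t <- ifelse(tab$count_m_t == 0 | tab$count_m_c == 0,
                  tab$count_m_t + 0.5, tab$count_m_t)
  num_c <- ifelse(tab$count_m_t == 0 | tab$count_m_c == 0,
                  tab$count_m_c + 0.5, tab$count_m_c)
  r <- rktm(num_t, len, lib_t) / rktm(num_c, len, lib_c)
  tab <- tab |>
    mutate(
      p = fisher_exact_2x2(.data$count_m_t,
                           .data$total_t - .data$count_m_t,
                           .data$count_m_c,
                           .data$total_c - .data$count_m_c),
      q = benjamini_hochberg(.data$p),
      fold_change = pmax(r, 1 / r),
      direction = ifelse(.data$ml_t > .data$ml_c, "hyper", "hypo"),
      significant = .data$q < fdr & .data$fold_change > fold)
  sig <- tab |>
    filter(.data$significant) |>
    arrange(.data$chrom, .data$context, .data$direction, .data$start)
  if (nrow(sig) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  context = character(), direction = character(),
                  n_windows = integer(), q = double()))
  }
  sig |>
    group_by(.data$chrom, .data$context, .data$direction) |>
    mutate(new_run = cumsum(c(
      TRUE, .data$start[-1] > .data$end[-dplyr::n()] + merge_gap))) |>
    group_by(.data$chrom, .data$context, .data$direction, .data$new_run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = dplyr::n(), q = min(.data$q),
              .groups = "drop") |>
    select("chrom", "start", "end", "context", "direction", "n_windows",
           "q") |>
    arrange(.data$chrom, .data$start, .data$context)
}

#' Summarize differential results into a non-redundant gene table
#'
#' Collapses significant feature-level results to one row per gene:
#' which regions are hyper- or hypomethylated (a gene may be hyper in
#' one region and hypo in another; both are kept) and an overall
#' classification (`hyper`, `hypo`, or `mixed`).
#'
#' @param diff A `meth_diff` tibble.
#' @return Tibble (`gene_id`, `regions_hyper`, `regions_hypo`,
#'   `classification`).
#' @export
summarize_dmgs <- function(diff) {
  sig <- as_tibble(unclass_keep(diff)) |> filter(.data$significant)
  if (nrow(sig) == 0) {
    return(tibble(gene_id = character(), regions_hyper = character(),
                  regions_hypo = character(), classification = character()))
  }
  sig |>
    distinct(.data$gene_id, .data$region, .data$direction) |>
    group_by(.data$gene_id) |>
    summarise(
      regions_hyper = paste(sort(unique(
        .data$region[.data$direction == "hyper"])), collapse = ","),
      regions_hypo = paste(sort(unique(
        .data$region[.data$direction == "hypo"])), collapse = ","),
      .groups = "drop") |>
    mutate(classification = dplyr::case_when(
      .data$regions_hyper != "" & .data$regions_hypo != "" ~ "mixed",
      .data$regions_hyper != "" ~ "hyper",
      TRUE ~ "hypo"))
}

#' Count region-direction overlaps among differentially methylated genes
#'
#' Membership counts for Venn-style overlap of the hyper and hypo gene
#' sets across regions.
#'
#' @param diff A `meth_diff` tibble.
#' @return Tibble (`direction`, `regions`, `n_genes`): for each
#'   direction, how many genes are significant in exactly that region
#'   combination.
#' @export
region_direction_overlap <- function(diff) {
  sig <- as_tibble(unclass_keep(diff)) |> filter(.data$significant)
  if (nrow(sig) == 0) {
    return(tibble(direction = character(), regions = character(),
                  n_genes = integer()))
  }
  sig |>
    distinct(.data$gene_id, .data$region, .data$direction) |>
    group_by(.data$direction, .data$gene_id) |>
    summarise(regions = paste(sort(unique(.data$region)), collapse = "+"),
              .groups = "drop") |>
    count(.data$direction, .data$regions, name = "n_genes")
}
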