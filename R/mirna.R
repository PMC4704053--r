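#' Pooled methylation level of precursor loci
#'
#' For each locus interval (e.g. a miRNA precursor), pools methylated
#' and unmethylated read counts over every covered cytosine in the
#' interval — both strands, all contexts — and reports the single
#' pooled ML per condition. Loci with zero covered cytosines get `NA`.
#'
#' @param calls Calls (or pileups) with `chrom`, `pos`, `count_m`,
#'   `count_u` and a `condition` column.
#' @param loci Tibble (`locus_id`, `chrom`, `start`, `end`), 0-based
#'   half-open (see [read_loci()]).
#' @return Tibble (`locus_id`, `condition`, `n_sites`, `count_m`,
#'   `total`, `ml`), one row per locus x condition present in `calls`;
#'   uncovered combinations appear with `ml = NA`.
#' @export
locus_methylation <- function(calls, loci) {
  stopifnot_cols(calls, c("chrom", "pos", "count_m", "count_u",
                          "condition"), "calls")
  stopifnot_cols(loci, c("locus_id", "chrom", "start", "end"), "loci")
  joined <- overlap_join(
    calls[, c("chrom", "pos", "count_m", "count_u", "condition")],
    loci, keep = "locus_id")
  grid <- tidyr::expand_grid(locus_id = loci$locus_id,
                             condition = unique(calls$condition))
  grid |>
    left_join(
      joined |>
        group_by(.data$locus_id, .data$condition) |>
        summarise(n_sites = dplyr::n(), count_m = sum(.data$count_m),
                  total = sum(.data$count_m) + sum(.data$count_u),
                  .groups = "drop"),
      by = c("locus_id", "condition")) |>
    mutate(n_sites = tidyr::replace_na(.data$n_sites, 0L),
           ml = ifelse(!is.na(.data$total) & .data$total > 0,
                       .data$count_m / .data$total, NA_real_))
}

#' log2 ratio of treatment to control methylation levels
#'
#' `log2(ml_t / ml_c)`, the per-locus change statistic. Either side
#' zero, negative or `NA` yields `NA` (no finite ratio); full precision
#' is kept internally and tables round to 2 decimals only at reporting.
#'
#' @param ml_t,ml_c Methylation levels in treatment and control.
#' @return Numeric vector of log2 ratios.
#' @examples
#' log2_ml_ratio(0.19, 0.04) # 2.25 to 2 decimals
#' @export
log2_ml_ratio <- function(ml_t, ml_c) {
  out <- rep(NA_real_, length(ml_t))
  ok <- !is.na(ml_t) & !is.na(ml_c) & ml_t > 0 & ml_c > 0
  out[ok] <- log2(ml_t[ok] / ml_c[ok])
  out
}

#' Build a per-locus methylation ratio table
#'
#' Joins treatment and control locus MLs and computes the log2 ratio,
#' the two-fold flag (`|log2 ratio| >= 1`) and the direction (`up` when
#' treatment exceeds control). Loci lacking coverage in either
#' condition are kept with `NA` ratio but never pass the filter.
#'
#' @param calls Calls with a `condition` column covering both
#'   conditions.
#' @param loci Locus intervals (see [locus_methylation()]).
#' @param treatment,control Condition labels.
#' @return Tibble (`locus_id`, `ml_treatment`, `ml_control`,
#'   `log2_ratio`, `passes_two_fold`, `direction`).
#' @export
mirna_locus_table <- function(calls, loci, treatment = "ATR",
                              control = "CK") {
  lm <- locus_methylation(calls, loci)
  wide <- inner_join(
    lm |> filter(.data$condition == treatment) |>
      select("locus_id", ml_treatment = "ml"),
    lm |> filter(.data$condition == control) |>
      select("locus_id", ml_control = "ml"),
    by = "locus_id")
  wide |>
    mutate(log2_ratio = log2_ml_ratio(.data$ml_treatment,
                                      .data$ml_control),
           passes_two_fold = !is.na(.data$log2_ratio) &
             abs(.data$log2_ratio) >= 1,
           direction = dplyr::case_when(
             is.na(.data$log2_ratio) ~ NA_character_,
             .data$ml_treatment > .data$ml_control ~ "up",
             TRUE ~ "down"))
}

#' Two-fold filter on locus methylation ratios
#'
#' Retains loci whose methylation changed at least two-fold between
#' conditions (`|log2 ratio| >= 1`), labelled with direction.
#'
#' @param records Tibble with a `log2_ratio` column (and optionally
#'   `ml_treatment`/`ml_control` for direction).
#' @param threshold Minimum absolute log2 ratio (default 1).
#' @return The retained subset, with a `direction` column.
#' @export
two_fold_filter <- function(records, threshold = 1) {
  out <- records |>
    filter(!is.na(.data$log2_ratio), abs(.data$log2_ratio) >= threshold)
  if (!"direction" %in% names(out)) {
    out$direction <- ifelse(out$log2_ratio > 0, "up", "down")
  }
  out
}

#' Reference methylation levels of rice miRNA precursor loci
#'
#' Loads the bundled table of per-locus methylation levels reported for
#' 15 rice miRNA precursor loci under atrazine exposure (treatment)
#' versus control, together with the log2 ratio as printed in the
#' source report. For 5 of the 15 loci the printed "log2" column
#' actually contains the raw ML ratio rather than its log2; the
#' `consistent` column flags the 10 rows whose printed value matches
#' `log2(ml_treatment/ml_control)` to 2 decimals, and the discrepancy
#' is preserved as published rather than corrected.
#'
#' @return Tibble (`locus_id`, `ml_treatment`, `ml_control`,
#'   `reported_log2_ratio`, `consistent`).
#' @export
mirna_reference_table <- function() {
  path <- system.file("extdata", "mirna_loci_ml.tsv",
                      package = "methylscape", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
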