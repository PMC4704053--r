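#' Exact two-library differential expression test (Audic-Claverie)
#'
#' The classic exact Poisson-based test for comparing one gene's counts
#' between two unreplicated libraries: given `count_a` in a library of
#' size `lib_a`, the count in the second library follows the
#' posterior-predictive distribution, a negative binomial with
#' `size = count_a + 1` and `prob = lib_a / (lib_a + lib_b)`. The
#' two-sided p is twice the smaller tail, capped at 1. Vectorized.
#'
#' The default `"audic_claverie"` method conditions on `count_a`
#' exactly as above; it is therefore not perfectly invariant under
#' swapping the two libraries (the predictive's tails differ slightly
#' depending on which count conditions). The `"conditional"` method is
#' the classic exact Poisson rate test — given the total
#' `count_a + count_b`, `count_a` is binomial with probability
#' `lib_a/(lib_a + lib_b)` — which is exactly swap-symmetric and agrees
#' closely with the predictive at moderate counts.
#'
#' @param count_a,count_b Raw counts per gene in the two libraries.
#' @param lib_a,lib_b Library sizes.
#' @param method `"audic_claverie"` (posterior predictive, default) or
#'   `"conditional"` (exact conditional binomial, swap-symmetric).
#' @return Two-sided p-values; `NA` where both counts are zero (no
#'   information).
#' @export
de_test <- function(count_a, count_b, lib_a, lib_b,
                    method = c("audic_claverie", "conditional")) {
  method <- match.arg(method)
  stopifnot(all(count_a >= 0), all(count_b >= 0), lib_a > 0, lib_b > 0)
  prob_a <- lib_a / (lib_a + lib_b)
  if (method == "audic_claverie") {
    p_low <- pnbinom(count_b, size = count_a + 1, prob = prob_a)
    p_high <- pnbinom(count_b - 1, size = count_a + 1, prob = prob_a,
                      lower.tail = FALSE)
  } else {
    s <- count_a + count_b
    p_low <- pbinom(count_a - 1, s, prob_a, lower.tail = FALSE)  # b small
    p_high <- pbinom(count_a, s, prob_a)                         # b large
  }
  p <- pmin(1, 2 * pmin(p_low, p_high))
  p[count_a == 0 & count_b == 0] <- NA_real_
  p
}

#' Call differentially expressed genes between two unreplicated libraries
#'
#' Computes the exact two-library p per gene, adjusts with
#' Benjamini-Hochberg, and flags genes with `q <= fdr` and
#' `|log2FC| >= min_log2fc`. The log2 fold change is computed on
#' library-size-normalized counts with a pseudocount of 1:
#' `log2(((count_atr + 1)/lib_atr) / ((count_ck + 1)/lib_ck))`.
#' Genes with zero counts in both libraries are excluded from testing.
#'
#' @param expression Tibble with `gene_id`, `count_ck`, `count_atr`.
#' @param lib_ck,lib_atr Library sizes (default: column totals).
#' @param fdr BH threshold (default 0.001).
#' @param min_log2fc Minimum absolute log2 fold change (default 1).
#' @return A `meth_de` tibble: `gene_id`, counts, `log2fc`, `p`, `q`,
#'   `direction` (`up`/`down`, treatment over control), `significant`.
#' @export
call_de <- function(expression, lib_ck = sum(expression$count_ck),
                    lib_atr = sum(expression$count_atr), fdr = 0.001,
                    min_log2fc = 1) {
  stopifnot_cols(expression, c("gene_id", "count_ck", "count_atr"),
                 "expression")
  out <- expression |>
    filter(.data$count_ck + .data$count_atr > 0) |>
    mutate(
      log2fc = log2(((.data$count_atr + 1) / lib_atr) /
                      ((.data$count_ck + 1) / lib_ck)),
      p = de_test(.data$count_ck, .data$count_atr, lib_ck, lib_atr),
      q = benjamini_hochberg(.data$p),
      direction = ifelse(.data$log2fc > 0, "up", "down"),
      significant = .data$q <= fdr & abs(.data$log2fc) >= min_log2fc)
  structure(out, class = c("meth_de", class(tibble())),
            lib_ck = lib_ck, lib_atr = lib_atr, fdr = fdr,
            min_log2fc = min_log2fc)
}

#' @export
tidy.meth_de <- function(x, ...) as_tibble(unclass_keep(x))

#' @export
glance.meth_de <- function(x, ...) {
  tibble(n_tested = nrow(x), n_significant = sum(x$significant),
         n_up = sum(x$significant & x$direction == "up"),
         n_down = sum(x$significant & x$direction == "down"),
         fdr = attr(x, "fdr"), min_log2fc = attr(x, "min_log2fc"))
}

#' Joint methylation-expression filter
#'
#' Retains gene x region pairs that are both differentially methylated
#' (raw Fisher `p < p_meth` and fold change `>= fold_meth` — a raw-p
#' screen, deliberately laxer than the FDR-based DMG caller, with both
#' significance columns kept) and differentially expressed (the
#' [call_de()] flag). Each retained pair is labelled with its quadrant,
#' e.g. `upstream-hyper/expr-down`.
#'
#' @param diff A `meth_diff` tibble (all tested features).
#' @param de A `meth_de` tibble.
#' @param p_meth Raw methylation p threshold (default 0.05).
#' @param fold_meth Methylation fold-change threshold (default 2,
#'   inclusive).
#' @return Tibble: `gene_id`, `region`, `context`, `meth_direction`,
#'   `meth_log2_ratio`, `meth_p`, `meth_q`, `expr_direction`, `log2fc`,
#'   `expr_q`, `quadrant`.
#' @export
joint_filter <- function(diff, de, p_meth = 0.05, fold_meth = 2) {
  diff <- as_tibble(unclass_keep(diff))
  de <- as_tibble(unclass_keep(de))
  meth_pass <- diff |>
    filter(.data$p < p_meth, .data$fold_change >= fold_meth)
  expr_pass <- de |> filter(.data$significant)
  meth_pass |>
    inner_join(expr_pass, by = "gene_id",
               suffix = c("_meth", "_expr")) |>
    transmute(
      gene_id = .data$gene_id, region = .data$region,
      context = .data$context,
      meth_direction = .data$direction_meth,
      meth_log2_ratio = .data$log2_ratio,
      meth_p = .data$p_meth, meth_q = .data$q_meth,
      expr_direction = .data$direction_expr,
      log2fc = .data$log2fc, expr_q = .data$q_expr,
      quadrant = paste0(.data$region, "-", .data$direction_meth,
                        "/expr-", .data$direction_expr)) |>
    arrange(.data$region, .data$gene_id)
}

#' Count joint genes per region and methylation direction
#'
#' The headline layout of a joint methylation-expression screen: how
#' many genes are up- (hyper) or down- (hypo) methylated in each region
#' among the jointly filtered set.
#'
#' @param joint Output of [joint_filter()].
#' @return Tibble (`region`, `meth_direction`, `n_genes`).
#' @export
joint_region_counts <- function(joint) {
  joint |>
    distinct(.data$gene_id, .data$region, .data$meth_direction) |>
    count(.data$region, .data$meth_direction, name = "n_genes")
}

#' Methylation-expression association summary
#'
#' For every region (and optionally gene class), the Spearman rank
#' correlation between the methylation change (log2 RKTM ratio) and the
#' expression change (log2FC) over all genes tested in both assays,
#' plus quadrant counts (hyper/hypo x up/down).
#'
#' @param diff A `meth_diff` tibble (all tested features; pooled over
#'   contexts by taking the minimum-p context per gene x region).
#' @param de A `meth_de` tibble (all tested genes).
#' @param classes Optional tibble (`gene_id`, `class`); genes without a
#'   label are grouped as `"other"`. Without it all genes form one
#'   class, `"all"`.
#' @return Tibble (`region`, `class`, `n`, `rho`, `p_value`,
#'   `n_hyper_up`, `n_hyper_down`, `n_hypo_up`, `n_hypo_down`).
#' @export
association_summary <- function(diff, de, classes = NULL) {
  diff <- as_tibble(unclass_keep(diff))
  de <- as_tibble(unclass_keep(de))
  meth <- diff |>
    group_by(.data$gene_id, .data$region) |>
    slice_min(.data$p, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("gene_id", "region", "meth_direction" = "direction",
           "meth_log2_ratio" = "log2_ratio")
  tab <- meth |>
    inner_join(de |> select("gene_id", "log2fc", "expr_direction" =
                              "direction"),
               by = "gene_id")
  if (is.null(classes)) {
    tab$class <- "all"
  } else {
    tab <- tab |>
      left_join(classes, by = "gene_id") |>
      mutate(class = dplyr::coalesce(.data$class, "other"))
  }
  tab |>
    group_by(.data$region, .data$class) |>
    summarise(
      n = dplyr::n(),
      rho = tryCatch(
        cor.test(.data$meth_log2_ratio, .data$log2fc,
                 method = "spearman", exact = FALSE)$estimate,
        error = function(e) NA_real_),
      p_value = tryCatch(
        cor.test(.data$meth_log2_ratio, .data$log2fc,
                 method = "spearman", exact = FALSE)$p.value,
        error = function(e) NA_real_),
      n_hyper_up = sum(.data$meth_direction == "hyper" &
                         .data$expr_direction == "up"),
      n_hyper_down = sum(.data$meth_direction == "hyper" &
                           .data$expr_direction == "down"),
      n_hypo_up = sum(.data$meth_direction == "hypo" &
                        .data$expr_direction == "up"),
      n_hypo_down = sum(.data$meth_direction == "hypo" &
                          .data$expr_direction == "down"),
      .groups = "drop")
}
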