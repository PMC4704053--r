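#' @export
autoplot.meth_windows <- function(object, smooth = FALSE, ...) {
  df <- as_tibble(unclass_keep(object))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$ml,
                                   colour = .data$context)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "methylation level",
                  colour = "context") +
    ggplot2::theme_minimal()
}

#' Plot a chromosome-scale methylation profile
#'
#' Smoothed per-context ML along each chromosome, one panel per
#' chromosome (and per condition when present).
#'
#' @param profile Output of [chromosome_profile()], optionally with a
#'   `condition` column.
#' @return A ggplot object.
#' @export
plot_chromosome_profile <- function(profile) {
  df <- as_tibble(unclass_keep(profile))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$ml_smooth,
    colour = .data$context)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "position (Mb)", y = "methylation level (smoothed)",
                  colour = "context") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(df)) {
    p + ggplot2::facet_grid(condition ~ chrom, scales = "free_x")
  } else {
    p + ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x")
  }
}

#' Plot a gene-region methylation metaprofile
#'
#' Per-context mean ML across the binned upstream/genebody/downstream
#' (or sub-feature) axis, 5'->3'.
#'
#' @param metaprofile Output of [feature_metaprofile()], optionally
#'   with a `condition` column.
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(metaprofile) {
  df <- metaprofile |>
    mutate(region = factor(.data$region, levels = unique(.data$region)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$ml,
                                        colour = .data$context)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "bin (5' to 3')", y = "methylation level",
                  colour = "context") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(df)) {
    p + ggplot2::facet_grid(condition ~ region)
  } else {
    p + ggplot2::facet_wrap(~region, nrow = 1)
  }
}

#' @export
autoplot.meth_diff <- function(object, ...) {
  df <- as_tibble(unclass_keep(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio,
                                   y = -log10(pmax(.data$q, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "log2 RKTM ratio (treatment / control)",
                  y = "-log10 q") +
    ggplot2::theme_minimal()
}

#' Plot methylation change against expression change
#'
#' The two-dimensional gene distribution behind the association
#' summary: per-region scatter of methylation log2 ratio versus
#' expression log2FC.
#'
#' @param diff A `meth_diff` tibble.
#' @param de A `meth_de` tibble.
#' @return A ggplot object.
#' @export
plot_association <- function(diff, de) {
  diff_df <- as_tibble(unclass_keep(diff)) |>
    group_by(.data$gene_id, .data$region) |>
    slice_min(.data$p, n = 1, with_ties = FALSE) |>
    ungroup()
  tab <- diff_df |>
    inner_join(as_tibble(unclass_keep(de)) |>
                 select("gene_id", "log2fc"), by = "gene_id")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2_ratio,
                                    y = .data$log2fc)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "methylation log2 ratio",
                  y = "expression log2 fold change") +
    ggplot2::theme_minimal()
}
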