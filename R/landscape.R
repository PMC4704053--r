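#' Context composition of methylated cytosines
#'
#' Fraction of methylated calls falling in each of CG, CHG, CHH. In
#' plant methylomes CG typically dominates (the source data scale is
#' roughly half of mCs at CG), so this is the first sanity summary of a
#' called methylome.
#'
#' @param calls A `meth_calls` tibble from [call_methylome()] (one
#'   condition).
#' @return Tibble (`context`, `n`, `fraction`); fractions sum to 1 when
#'   any methylated site exists, all-NA with a warning otherwise.
#' @export
context_composition <- function(calls) {
  stopifnot_cols(calls, c("context", "is_methylated"), "calls")
  mc <- calls |> filter(.data$is_methylated)
  out <- tibble(context = c("CG", "CHG", "CHH")) |>
    left_join(mc |> count(.data$context), by = "context") |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  if (sum(out$n) == 0) {
    warn("no methylated sites; context fractions are NA")
    out$fraction <- NA_real_
  } else {
    out$fraction <- out$n / sum(out$n)
  }
  out
}

#' Per-context methylation levels in sliding windows
#'
#' Tiles each chromosome with `width`-bp windows every `step` bp from
#' coordinate 0 and pools read counts per window and context:
#' `ML = sum(mC) / sum(mC + non-mC)` over covered sites in the window.
#' Pooling counts (rather than averaging site-level MLs) matches the ML
#' definition and naturally downweights low-coverage sites. With
#' `step < width` windows overlap and a site contributes to every
#' window containing it.
#'
#' @param calls Calls (or pileups) with `chrom`, `pos`, `context`,
#'   `count_m`, `count_u`.
#' @param width Window width in bp (default 200).
#' @param step Step between window starts (default `width`:
#'   non-overlapping tiling).
#' @param seqlens Optional named chromosome lengths; when given, empty
#'   windows are emitted with `ml = NA` so profiles tile the chromosome.
#' @return Tibble (`chrom`, `start`, `end`, `context`, `n_sites`,
#'   `count_m`, `total`, `ml`), a `meth_windows` object.
#' @export
sliding_window_levels <- function(calls, width = 200, step = width,
                                  seqlens = NULL) {
  stopifnot(width >= 1, step >= 1)
  stopifnot_cols(calls, c("chrom", "pos", "context", "count_m", "count_u"),
                 "calls")
  first_w <- pmax(0L, ceiling((calls$pos - width + 1) / step))
  last_w <- floor(calls$pos / step)
  reps <- last_w - first_w + 1L
  idx <- rep(seq_len(nrow(calls)), reps)
  win <- unlist(purrr::map2(first_w, last_w, seq), use.names = FALSE)
  expanded <- calls[idx, c("chrom", "pos", "context", "count_m", "count_u")]
  expanded$window <- win
  prof <- expanded |>
    group_by(.data$chrom, .data$window, .data$context) |>
    summarise(n_sites = dplyr::n(),
              count_m = sum(.data$count_m),
              total = sum(.data$count_m) + sum(.data$count_u),
              .groups = "drop") |>
    mutate(ml = ifelse(.data$total > 0, .data$count_m / .data$total, NA_real_))
  if (!is.null(seqlens)) {
    grid <- purrr::imap(seqlens, function(len, chrom) {
      tidyr::expand_grid(chrom = chrom,
                         window = 0:((len - 1) %/% step),
                         context = c("CG", "CHG", "CHH"))
    }) |> bind_rows()
    prof <- grid |>
      left_join(prof, by = c("chrom", "window", "context")) |>
      mutate(n_sites = tidyr::replace_na(.data$n_sites, 0L))
  }
  prof <- prof |>
    mutate(start = .data$window * step, end = .data$window * step + width) |>
    select("chrom", "start", "end", "context", "n_sites", "count_m",
           "total", "ml") |>
    arrange(.data$chrom, .data$start, .data$context)
  structure(prof, class = c("meth_windows", class(tibble())),
            width = width, step = step)
}

#' Chromosome-scale binned methylation profile
#'
#' Pools counts into consecutive `bin`-bp bins per context (same rule
#' as the sliding windows) and optionally smooths each per-chromosome,
#' per-context series with a centered moving average over `smooth_k`
#' bins. The 10-kb default matches the resolution at which
#' chromosome-level CG/CHG/CHH profiles are usually drawn.
#'
#' @param calls Calls with `chrom`, `pos`, `context`, `count_m`,
#'   `count_u`.
#' @param bin Bin width in bp (default 10000).
#' @param smooth_k Moving-average window in bins (default 5; 1 disables
#'   smoothing).
#' @param seqlens Optional named chromosome lengths (emit empty bins).
#' @return Tibble like [sliding_window_levels()] plus `ml_smooth`.
#' @export
chromosome_profile <- function(calls, bin = 10000, smooth_k = 5,
                               seqlens = NULL) {
  prof <- sliding_window_levels(calls, width = bin, step = bin,
                                seqlens = seqlens)
  prof |>
    group_by(.data$chrom, .data$context) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(ml_smooth = moving_average(.data$ml, smooth_k)) |>
    ungroup() |>
    arrange(.data$chrom, .data$start, .data$context)
}

#' Average methylation metaprofile across gene regions
#'
#' Rescales each gene's region (upstream, genebody, downstream, or any
#' sub-feature present in the models) to `n_bins` bins oriented 5'->3'
#' on the gene's own strand, then pools read counts per bin across
#' genes. Regions composed of several intervals (e.g. a CDS split by an
#' intron) are concatenated in transcription order before binning.
#' Genes with empty regions are skipped.
#'
#' @param calls Calls with `chrom`, `pos`, `context`, `count_m`,
#'   `count_u`.
#' @param gene_models Region intervals from [build_gene_models()].
#' @param n_bins Bins per region (default 20).
#' @param regions Regions to profile (default upstream, genebody,
#'   downstream; sub-features may be named too).
#' @return Tibble (`region`, `bin`, `context`, `n_sites`, `count_m`,
#'   `total`, `ml`).
#' @export
feature_metaprofile <- function(calls, gene_models, n_bins = 20,
                                regions = c("upstream", "genebody",
                                            "downstream")) {
  models <- gene_models |>
    filter(.data$region %in% regions, .data$end > .data$start) |>
    group_by(.data$gene_id, .data$region) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(offset = cumsum(dplyr::lag(.data$end - .data$start, default = 0L)),
           region_len = sum(.data$end - .data$start)) |>
    ungroup()
  joined <- overlap_join(
    calls[, c("chrom", "pos", "context", "count_m", "count_u")],
    models,
    keep = c("gene_id", "region", "start", "end", "strand", "offset",
             "region_len"))
  if (nrow(joined) == 0) {
    return(tibble(region = character(), bin = integer(),
                  context = character(), n_sites = integer(),
                  count_m = integer(), total = integer(), ml = double()))
  }
  rel <- joined$offset + (joined$pos - joined$start)
  rel <- ifelse(joined$strand == "-", joined$region_len - 1L - rel, rel)
  joined$bin <- pmin(n_bins - 1L,
                     as.integer(floor(rel / joined$region_len * n_bins)))
  joined |>
    group_by(.data$region, .data$bin, .data$context) |>
    summarise(n_sites = dplyr::n(),
              count_m = sum(.data$count_m),
              total = sum(.data$count_m) + sum(.data$count_u),
              .groups = "drop") |>
    mutate(ml = ifelse(.data$total > 0, .data$count_m / .data$total,
                       NA_real_)) |>
    arrange(factor(.data$region, levels = unique(regions)), .data$bin,
            .data$context)
}
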