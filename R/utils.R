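# Shared internal helpers.

# Overlap-join site rows onto interval rows (both 0-based half-open).
# Returns one row per (site, interval) hit: all site columns plus the
# interval columns named in `keep`.
overlap_join <- function(sites, intervals,
                         keep = setdiff(names(intervals), "chrom")) {
  if (nrow(sites) == 0 || nrow(intervals) == 0) {
    out <- sites[0, , drop = FALSE]
    for (k in keep) out[[k]] <- intervals[[k]][0]
    return(as_tibble(out))
  }
  nonempty <- intervals$end > intervals$start
  intervals <- intervals[nonempty, , drop = FALSE]
  sgr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L))
  igr <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start + 1L, intervals$end))
  hits <- GenomicRanges::findOverlaps(sgr, igr)
  out <- sites[S4Vectors::queryHits(hits), , drop = FALSE]
  ivl <- intervals[S4Vectors::subjectHits(hits), keep, drop = FALSE]
  # avoid clobbering site columns (e.g. both carry `strand`)
  clash <- intersect(names(ivl), names(out))
  names(ivl)[match(clash, names(ivl))] <- paste0(clash, "_feature")
  bind_cols(as_tibble(out), as_tibble(ivl))
}

# Pooled methylation level: sum(mC) / sum(mC + non-mC); NA when no reads.
pool_ml <- function(count_m, total) {
  tt <- sum(total)
  if (tt == 0) return(NA_real_)
  sum(count_m) / tt
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, k = 5) {
  if (k <= 1) return(x)
  half <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "methylscape_input_error")
  }
  invisible(df)
}
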