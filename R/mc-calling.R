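#' Estimate the bisulfite non-conversion rate
#'
#' Pools read counts over a set of sites declared unmethylated (a
#' spike-in, organelle genome, or simulator truth) and returns the
#' fraction of reads still reporting C. This is the error rate the
#' per-site binomial test is calibrated against.
#'
#' @param pileups Tibble with `count_m`, `count_u` over
#'   known-unmethylated sites only.
#' @param floor Lower floor applied when the control set shows zero
#'   non-conversion, to avoid degenerate p-values (default 1e-4).
#' @return The estimated rate, a single number in \[0, 1).
#' @export
estimate_nonconversion <- function(pileups, floor = 1e-4) {
  stopifnot_cols(pileups, c("count_m", "count_u"), "pileups")
  total <- sum(pileups$count_m) + sum(pileups$count_u)
  if (nrow(pileups) == 0 || total == 0) {
    abort("control set has zero total coverage",
          class = "methylscape_coverage_error")
  }
  eps <- sum(pileups$count_m) / total
  if (eps < floor) {
    inform(sprintf(
      "non-conversion estimate %.2g below floor; using %.2g", eps, floor))
    eps <- floor
  }
  eps
}

#' One-sided binomial test for methylation at a site
#'
#' Upper-tail exact binomial p-value
#' `P[X >= count_m | n = total, p = epsilon]`: the probability of seeing
#' at least the observed number of unconverted reads if the site were
#' unmethylated and only non-conversion produced C calls. Vectorized
#' over sites.
#'
#' @param count_m Methylated (unconverted) read counts.
#' @param total Total read counts (must be >= 1; sites with zero
#'   coverage have no p-value and should be excluded upstream).
#' @param epsilon Non-conversion rate.
#' @return Numeric vector of p-values; `count_m = 0` gives exactly 1.
#' @export
binomial_site_test <- function(count_m, total, epsilon) {
  stopifnot(all(total >= 1), epsilon >= 0, epsilon < 1)
  pbinom(count_m - 1, total, epsilon, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' The classic step-up rule: order the m p-values, compute `p * m / i`
#' at rank i, and enforce monotonicity from the largest rank down.
#' Output order matches input order; ties are preserved. (Agrees with
#' `stats::p.adjust(method = "BH")`, which the test suite uses as an
#' independent cross-check.)
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ord <- order(p)
  q <- numeric(m)
  q[ord] <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q
}

#' Call methylated cytosines in one condition at a controlled FDR
#'
#' Applies the binomial non-conversion test at every covered site,
#' adjusts genome-wide (all contexts together, per condition) with
#' Benjamini-Hochberg, and flags sites with `q <= fdr` as methylated.
#' The methylation level `ML = mC / (mC + non-mC)` is computed for every
#' tested site regardless of the call. Sites below `min_coverage` are
#' excluded from testing entirely.
#'
#' @param pileups Pileup tibble (`chrom`, `pos`, `strand`, `context`,
#'   `count_m`, `count_u`, optionally `condition`). If a `condition`
#'   column is present, BH is applied within each condition separately.
#' @param epsilon Non-conversion rate (from [estimate_nonconversion()]).
#' @param fdr FDR threshold for the methylated call (default 0.01).
#' @param min_coverage Minimum total reads for a site to be tested
#'   (default 4).
#' @return A `meth_calls` tibble: input site columns plus `total`,
#'   `ml`, `p`, `q`, `is_methylated`.
#' @export
call_methylome <- function(pileups, epsilon, fdr = 0.01, min_coverage = 4) {
  stopifnot_cols(pileups, c("count_m", "count_u"), "pileups")
  calls <- pileups |>
    mutate(total = .data$count_m + .data$count_u) |>
    filter(.data$total >= max(1, min_coverage))
  max_frac <- if (nrow(calls)) max(calls$count_m / calls$total) else 0
  if (epsilon >= max_frac && nrow(calls) > 0) {
    warn("epsilon is not below the maximum observed methylated fraction; no site can be called")
  }
  calls <- calls |>
    mutate(ml = .data$count_m / .data$total,
           p = binomial_site_test(.data$count_m, .data$total, epsilon))
  if ("condition" %in% names(calls)) {
    calls <- calls |>
      group_by(.data$condition) |>
      mutate(q = benjamini_hochberg(.data$p)) |>
      ungroup()
  } else {
    calls <- calls |> mutate(q = benjamini_hochberg(.data$p))
  }
  calls <- calls |> mutate(is_methylated = .data$q <= fdr)
  new_meth_calls(calls, epsilon = epsilon, fdr = fdr,
                 min_coverage = min_coverage)
}

new_meth_calls <- function(x, epsilon, fdr, min_coverage) {
  structure(x, class = c("meth_calls", class(tibble())),
            epsilon = epsilon, fdr = fdr, min_coverage = min_coverage)
}

#' @export
tidy.meth_calls <- function(x, ...) as_tibble(unclass_keep(x))

#' @export
glance.meth_calls <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    n_methylated = sum(x$is_methylated),
    mean_ml = mean(x$ml),
    epsilon = attr(x, "epsilon"),
    fdr = attr(x, "fdr"),
    min_coverage = attr(x, "min_coverage")
  )
}

unclass_keep <- function(x) {
  class(x) <- class(tibble())
  x
}
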