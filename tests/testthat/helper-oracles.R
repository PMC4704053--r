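# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# Enumerate cytosines by looping over every position on both strands.
oracle_enumerate <- function(seq, chrom = "chr1") {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  rows <- list()
  for (i in seq_len(n)) {
    # forward strand: base as-is, context 3' to the right
    if (chars[i] == "C" && i + 2 <= n) {
      w <- chars[c(i + 1, i + 2)]
      if (!any(w == "N")) {
        ctx <- if (w[1] == "G") "CG" else if (w[2] == "G") "CHG" else "CHH"
        rows[[length(rows) + 1]] <-
          data.frame(chrom = chrom, pos = i - 1L, strand = "+",
                     context = ctx)
      }
    }
    # reverse strand: complement base, context 3' to the left
    if (comp[chars[i]] == "C" && i - 2 >= 1) {
      w <- comp[chars[c(i - 1, i - 2)]]
      if (!any(w == "N")) {
        ctx <- if (w[1] == "G") "CG" else if (w[2] == "G") "CHG" else "CHH"
        rows[[length(rows) + 1]] <-
          data.frame(chrom = chrom, pos = i - 1L, strand = "-",
                     context = ctx)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), strand = character(),
               context = character())
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

# Upper-tail binomial probability by direct summation.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# BH step-up from its definition: q_i = min_{j: p_(j) >= p_(i) rank} ...
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    q[i] <- min(1, min(p[ord][rank_i:m] * m / (rank_i:m)))
  }
  q
}

# Two-sided Fisher p by enumerating every table with the same margins.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Audic-Claverie two-sided p by summing the posterior predictive
# p(y | x) = (N2/N1)^y * (x+y)! / (x! y! (1+N2/N1)^(x+y+1)) directly.
oracle_ac_p <- function(x, y, n1, n2) {
  r <- n2 / n1
  logp <- function(yy) {
    lchoose(x + yy, yy) + yy * log(r) - (x + yy + 1) * log(1 + r)
  }
  ys <- 0:ceiling(max(y + 300, x * r + 20 * sqrt((x + 1) * r) + 300))
  pm <- exp(logp(ys))
  p_low <- sum(pm[ys <= y])
  p_high <- sum(pm[ys >= y])
  min(1, 2 * min(p_low, p_high))
}

# Pooled ML over a set of rows.
oracle_pool_ml <- function(count_m, count_u) {
  tot <- sum(count_m) + sum(count_u)
  if (tot == 0) NA_real_ else sum(count_m) / tot
}

# Merge sorted significant windows with gap <= merge_gap, same key.
oracle_merge_windows <- function(df, merge_gap = 0) {
  out <- list()
  for (key in unique(paste(df$chrom, df$context, df$direction))) {
    sub <- df[paste(df$chrom, df$context, df$direction) == key, ]
    sub <- sub[order(sub$start), ]
    cur <- sub[1, ]
    n_in <- 1
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      if (sub$start[i] <= cur$end + merge_gap) {
        cur$end <- max(cur$end, sub$end[i]); n_in <- n_in + 1
      } else {
        cur$n_windows <- n_in; out[[length(out) + 1]] <- cur
        cur <- sub[i, ]; n_in <- 1
      }
    }
    cur$n_windows <- n_in
    out[[length(out) + 1]] <- cur
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$context), ]
}

# Tiny deterministic pileup table builder used across tests.
make_pileup <- function(chrom = "chr1", pos, context = "CG", count_m,
                        count_u, strand = "+", condition = NULL) {
  df <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                       strand = strand, context = context,
                       count_m = as.integer(count_m),
                       count_u = as.integer(count_u))
  if (!is.null(condition)) df$condition <- condition
  df
}
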