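calls_fixture <- function(n = 500, seed = 30, chrom_len = 5000) {
  set.seed(seed)
  pos <- sort(sample(0:(chrom_len - 1), n))
  make_pileup(pos = pos,
              context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
              count_m = rbinom(n, 20, 0.3),
              count_u = 0) |>
    dplyr::mutate(count_u = as.integer(20 - count_m),
                  is_methylated = count_m > 10)
}

test_that("context composition is the fraction of methylated calls", {
  calls <- dplyr::bind_rows(
    make_pileup(pos = 1:5, context = "CG", count_m = 5, count_u = 0),
    make_pileup(pos = 6:8, context = "CHG", count_m = 5, count_u = 0),
    make_pileup(pos = 9:10, context = "CHH", count_m = 5, count_u = 0)) |>
    dplyr::mutate(is_methylated = TRUE)
  comp <- context_composition(calls)
  expect_equal(comp$fraction[match(c("CG", "CHG", "CHH"), comp$context)],
               c(0.5, 0.3, 0.2))
  expect_equal(sum(comp$fraction), 1)
  # only CG methylated
  calls$is_methylated <- calls$context == "CG"
  comp <- context_composition(calls)
  expect_equal(comp$fraction[comp$context == "CG"], 1)
  # none methylated
  calls$is_methylated <- FALSE
  expect_warning(comp <- context_composition(calls), "no methylated")
  expect_true(all(is.na(comp$fraction)))
})

test_that("window levels equal brute-force recomputation from raw sites", {
  calls <- calls_fixture()
  win <- sliding_window_levels(calls, width = 200)
  for (i in sample(nrow(win), 25)) {
    rows <- calls[calls$pos >= win$start[i] & calls$pos < win$end[i] &
                    calls$context == win$context[i], ]
    expect_equal(win$ml[i], oracle_pool_ml(rows$count_m, rows$count_u))
    expect_equal(win$n_sites[i], nrow(rows))
  }
})

test_that("empty windows are NA and uniform fields are flat", {
  calls <- make_pileup(pos = c(10, 20, 710), count_m = 1, count_u = 1)
  win <- sliding_window_levels(calls, width = 200,
                               seqlens = c(chr1 = 1000))
  cg <- win[win$context == "CG", ]
  expect_equal(nrow(cg), 5)
  expect_equal(cg$ml[cg$start == 400], NA_real_)
  expect_equal(cg$ml[cg$start == 0], 0.5)
  expect_true(all(cg$ml[!is.na(cg$ml)] == 0.5))
})

test_that("overlapping windows include each site in every covering window", {
  calls <- make_pileup(pos = 150, count_m = 3, count_u = 1)
  win <- sliding_window_levels(calls, width = 200, step = 100)
  covering <- win[win$n_sites > 0, ]
  expect_equal(sort(covering$start), c(0, 100))
  expect_true(all(covering$ml == 0.75))
})

test_that("chromosome-wide ML is the count-weighted mean of window MLs", {
  calls <- calls_fixture(seed = 31)
  win <- sliding_window_levels(calls, width = 200)
  overall <- sum(calls$count_m) / sum(calls$count_m + calls$count_u)
  expect_equal(sum(win$count_m) / sum(win$total), overall)
  w <- win$total / sum(win$total)
  expect_equal(sum(w * win$ml), overall)
})

test_that("chromosome profile pools like windows and smooths", {
  calls <- calls_fixture(seed = 32, chrom_len = 60000, n = 2000)
  prof <- chromosome_profile(calls, bin = 10000, smooth_k = 1)
  win <- sliding_window_levels(calls, width = 10000)
  expect_equal(prof$ml, win$ml)
  expect_equal(prof$ml_smooth, prof$ml)
  sm <- chromosome_profile(calls, bin = 10000, smooth_k = 5)
  cg <- sm[sm$context == "CG", ]
  # interior smoothed value is the mean of its 5-bin neighbourhood
  i <- 3
  expect_equal(cg$ml_smooth[i], mean(cg$ml[(i - 2):(i + 2)]))
})

test_that("metaprofiles are flat for uniform methylomes and strand-symmetric", {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start = c(1000L, 5000L), end = c(2000L, 6000L),
    strand = c("+", "-"))
  models <- build_gene_models(genes, flank_bp = 500)
  pos <- c(500:2499, 4500:6499)
  calls <- make_pileup(pos = pos, count_m = 2, count_u = 2)
  mp <- feature_metaprofile(calls, models, n_bins = 10)
  expect_true(all(mp$ml == 0.5))
  # a gradient on the + gene mirrors onto the - gene when reflected
  grad_p <- make_pileup(pos = 1000:1999, count_m = rep(c(1L, 3L),
                                                       each = 500),
                        count_u = 2)
  grad_m <- make_pileup(pos = 5000:5999, count_m = rep(c(3L, 1L),
                                                       each = 500),
                        count_u = 2)
  mp_p <- feature_metaprofile(grad_p, models |>
                                dplyr::filter(gene_id == "gp"),
                              n_bins = 10, regions = "genebody")
  mp_m <- feature_metaprofile(grad_m, models |>
                                dplyr::filter(gene_id == "gm"),
                              n_bins = 10, regions = "genebody")
  expect_equal(mp_p$ml, mp_m$ml)
})

test_that("metaprofile bins equal brute-force pooling on a small fixture", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(1000L, 3000L, 7000L), end = c(1500L, 3500L, 7500L),
    strand = c("+", "-", "+"))
  models <- build_gene_models(genes, flank_bp = 200)
  calls <- calls_fixture(n = 800, seed = 33, chrom_len = 8000)
  n_bins <- 5
  mp <- feature_metaprofile(calls, models, n_bins = n_bins,
                            regions = "genebody")
  for (b in 0:(n_bins - 1)) {
    for (ctx in c("CG", "CHG", "CHH")) {
      mm <- uu <- 0
      for (g in seq_len(nrow(genes))) {
        s <- genes$start[g]; e <- genes$end[g]
        rows <- calls[calls$pos >= s & calls$pos < e &
                        calls$context == ctx, ]
        if (nrow(rows) == 0) next
        rel <- rows$pos - s
        if (genes$strand[g] == "-") rel <- (e - s) - 1 - rel
        bin <- pmin(n_bins - 1, floor(rel / (e - s) * n_bins))
        mm <- mm + sum(rows$count_m[bin == b])
        uu <- uu + sum(rows$count_u[bin == b])
      }
      got <- mp$ml[mp$bin == b & mp$context == ctx]
      if (mm + uu == 0) {
        expect_true(length(got) == 0 || is.na(got))
      } else {
        expect_equal(got, mm / (mm + uu))
      }
    }
  }
})
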