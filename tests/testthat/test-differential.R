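test_that("RKTM normalization follows its definition", {
  expect_equal(rktm(100, 1000, 1e6), 100)
  expect_equal(rktm(0, 1000, 1e6), 0)
  expect_equal(rktm(50, 500, 2e6), 50)
  expect_error(rktm(1, 0, 1e6), class = "methylscape_input_error")
  expect_error(rktm(1, 100, 0), class = "methylscape_input_error")
})

test_that("Fisher p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-10)
  # zero-margin convention
  expect_equal(fisher_exact_2x2(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_2x2(0, 5, 0, 5), 1)
  set.seed(40)
  for (i in 1:200) {
    tot <- sample(4:30, 1)
    cnt <- as.vector(stats::rmultinom(1, tot, runif(4, 0.05, 1)))
    expect_equal(fisher_exact_2x2(cnt[1], cnt[2], cnt[3], cnt[4]),
                 oracle_fisher(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-9)
  }
})

make_features <- function(df) {
  # df: gene_id, region, context, count_m_t, total_t, count_m_c, total_c
  dplyr::bind_rows(
    df |> dplyr::transmute(gene_id, region, context, condition = "ATR",
                           count_m = count_m_t, total = total_t),
    df |> dplyr::transmute(gene_id, region, context, condition = "CK",
                           count_m = count_m_c, total = total_c)) |>
    dplyr::group_by(condition) |>
    dplyr::mutate(length_bp = 1000,
                  library_total = max(sum(count_m), 1),
                  rktm = rktm(count_m, length_bp, library_total),
                  ml = count_m / total) |>
    dplyr::ungroup()
}

test_that("identical conditions yield no differential features", {
  set.seed(41)
  df <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:30), region = "genebody",
    context = "CG",
    count_m_t = rbinom(30, 200, 0.3), total_t = 200L)
  df$count_m_c <- df$count_m_t
  df$total_c <- df$total_t
  res <- call_differential_features(make_features(df))
  expect_equal(sum(res$significant), 0)
  expect_true(all(res$p > 1 - 1e-9))
})

test_that("direction labels follow the ML comparison and labels swap cleanly", {
  set.seed(42)
  df <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40), region = "upstream",
    context = "CG",
    count_m_t = c(rbinom(20, 400, 0.7), rbinom(20, 400, 0.15)),
    total_t = 400L,
    count_m_c = rbinom(40, 400, 0.3), total_c = 400L)
  feats <- make_features(df)
  res <- call_differential_features(feats)
  expect_true(all((res$direction == "hyper") == (res$ml_t > res$ml_c)))
  # swapping treatment/control flips direction, keeps p
  swapped <- call_differential_features(feats, treatment = "CK",
                                        control = "ATR")
  key <- paste(res$gene_id, res$region, res$context)
  skey <- paste(swapped$gene_id, swapped$region, swapped$context)
  m <- match(key, skey)
  expect_equal(res$p, swapped$p[m])
  both <- res$ml_t != res$ml_c
  expect_true(all(res$direction[both] != swapped$direction[m][both]))
  expect_gt(sum(res$significant), 0)
})

test_that("zero-coverage features are excluded and pseudocounts bound ratios", {
  df <- tibble::tibble(
    gene_id = c("g1", "g2"), region = "genebody", context = "CG",
    count_m_t = c(50L, 10L), total_t = c(100L, 50L),
    count_m_c = c(0L, 0L), total_c = c(100L, 0L))
  res <- call_differential_features(make_features(df))
  expect_equal(res$gene_id, "g1")  # g2 has no control coverage
  expect_true(is.finite(res$fold_change))
})

test_that("DMR calling merges adjacent significant windows", {
  win <- function(start, count_m_t, count_m_c, total = 400L) {
    tibble::tibble(chrom = "chr1", start = start, end = start + 200L,
                   context = "CG", n_sites = 10L,
                   count_m = NA_integer_, total = total, ml = NA_real_)
  }
  mk <- function(counts) {
    w <- dplyr::bind_rows(purrr::map(seq_along(counts), function(i) {
      win(200L * (i - 1L))
    })) |>
      dplyr::mutate(count_m = as.integer(counts),
                    ml = count_m / total)
    w
  }
  # neutral background windows keep the library totals comparable
  hot <- c(300, 280, 20, 30, 310, 25, 22, 18, 300, 290, rep(30, 50))
  cold <- rep(30, 60)
  dmrs <- call_dmrs(mk(hot), mk(cold))
  # windows 1-2 merge; 5 alone; 9-10 merge
  expect_equal(nrow(dmrs), 3)
  expect_equal(dmrs$n_windows, c(2, 1, 2))
  expect_equal(dmrs$start, c(0, 800, 1600))
  expect_equal(dmrs$end, c(400, 1000, 2000))
  expect_true(all(dmrs$direction == "hyper"))
  # no significant windows -> empty
  none <- call_dmrs(mk(cold), mk(cold))
  expect_equal(nrow(none), 0)
})

test_that("DMR merging equals a brute-force merge on a 20-window fixture", {
  set.seed(43)
  starts <- 200L * (0:19)
  sig <- tibble::tibble(
    chrom = "chr1", start = starts[c(1, 2, 3, 6, 8, 9, 15, 16, 20)],
    context = sample(c("CG", "CHG"), 9, replace = TRUE),
    direction = sample(c("hyper", "hypo"), 9, replace = TRUE))
  sig$end <- sig$start + 200L
  merged <- oracle_merge_windows(as.data.frame(sig), merge_gap = 0)
  # reconstruct counts that make exactly these windows significant
  mk_side <- function(hot) {
    tidyr::expand_grid(start = starts, context = c("CG", "CHG")) |>
      dplyr::mutate(chrom = "chr1", end = start + 200L, n_sites = 10L,
                    total = 500L) |>
      dplyr::left_join(sig |> dplyr::mutate(flag = TRUE),
                       by = c("chrom", "start", "end", "context")) |>
      dplyr::mutate(count_m = dplyr::case_when(
        !is.na(flag) & hot & direction == "hyper" ~ 400L,
        !is.na(flag) & hot & direction == "hypo" ~ 10L,
        TRUE ~ 100L),
        ml = count_m / total) |>
      dplyr::select(chrom, start, end, context, n_sites, count_m,
                    total, ml)
  }
  dmrs <- call_dmrs(mk_side(TRUE), mk_side(FALSE))
  expect_equal(nrow(dmrs), nrow(merged))
  ord <- order(dmrs$chrom, dmrs$start, dmrs$context, dmrs$direction)
  mord <- order(merged$chrom, merged$start, merged$context,
                merged$direction)
  expect_equal(dmrs$start[ord], merged$start[mord])
  expect_equal(dmrs$end[ord], merged$end[mord])
  expect_equal(dmrs$n_windows[ord], merged$n_windows[mord])
})

test_that("DMG summaries keep per-region directions distinct", {
  base <- tibble::tibble(
    gene_id = c("g1", "g2", "g2"),
    region = c("upstream", "upstream", "genebody"),
    context = "CG",
    direction = c("hyper", "hyper", "hypo"),
    significant = TRUE)
  dmg <- summarize_dmgs(structure(base, class = class(tibble::tibble())))
  g1 <- dmg[dmg$gene_id == "g1", ]
  expect_equal(g1$classification, "hyper")
  expect_equal(g1$regions_hyper, "upstream")
  g2 <- dmg[dmg$gene_id == "g2", ]
  expect_equal(g2$classification, "mixed")
  expect_equal(g2$regions_hyper, "upstream")
  expect_equal(g2$regions_hypo, "genebody")
})

test_that("region-direction overlap counts equal brute-force set algebra", {
  set.seed(44)
  genes <- sprintf("g%02d", 1:10)
  rows <- tidyr::expand_grid(gene_id = genes,
                             region = c("upstream", "genebody",
                                        "downstream")) |>
    dplyr::mutate(context = "CG",
                  direction = sample(c("hyper", "hypo"), dplyr::n(),
                                     replace = TRUE),
                  significant = runif(dplyr::n()) < 0.5)
  ov <- region_direction_overlap(
    structure(rows, class = class(tibble::tibble())))
  sig <- rows[rows$significant, ]
  for (dir in unique(ov$direction)) {
    sub <- sig[sig$direction == dir, ]
    combos <- tapply(sub$region, sub$gene_id,
                     function(r) paste(sort(unique(r)), collapse = "+"))
    expected <- table(unlist(combos))
    for (cmb in names(expected)) {
      expect_equal(
        ov$n_genes[ov$direction == dir & ov$regions == cmb],
        as.integer(expected[[cmb]]))
    }
  }
})
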