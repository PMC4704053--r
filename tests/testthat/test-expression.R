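test_that("the two-library exact test matches its brute-force form", {
  expect_equal(de_test(10, 10, 1e6, 1e6), 1)
  expect_equal(de_test(0, 20, 1e6, 1e6), oracle_ac_p(0, 20, 1e6, 1e6),
               tolerance = 1e-9)
  # the conditional variant is exactly swap-symmetric
  expect_equal(de_test(3, 17, 1e6, 2e6, method = "conditional"),
               de_test(17, 3, 2e6, 1e6, method = "conditional"),
               tolerance = 1e-12)
  set.seed(49)
  for (i in 1:50) {
    x <- sample(0:50, 1); y <- sample(0:50, 1)
    n1 <- runif(1, 5e5, 2e6); n2 <- runif(1, 5e5, 2e6)
    expect_equal(de_test(x, y, n1, n2, method = "conditional"),
                 de_test(y, x, n2, n1, method = "conditional"),
                 tolerance = 1e-12)
  }
  expect_true(is.na(de_test(0, 0, 1e6, 1e6)))
  set.seed(50)
  for (i in 1:150) {
    x <- sample(0:40, 1); y <- sample(0:40, 1)
    n1 <- runif(1, 5e5, 2e6); n2 <- runif(1, 5e5, 2e6)
    expect_equal(de_test(x, y, n1, n2), oracle_ac_p(x, y, n1, n2),
                 tolerance = 1e-7)
  }
})

test_that("DE calling applies both the FDR and the fold threshold", {
  # a gene at |log2FC| just under 1 is never flagged, however small p is
  expr <- tibble::tibble(
    gene_id = c(sprintf("null%02d", 1:20), "big"),
    count_ck = c(rep(1000L, 20), 40000L),
    count_atr = c(rep(1000L, 20), as.integer(round(40001 * 2^0.99)) ))
  de <- call_de(expr, lib_ck = 1e6, lib_atr = 1e6)
  big <- de[de$gene_id == "big", ]
  expect_lt(big$q, 1e-10)
  expect_lt(abs(big$log2fc), 1)
  expect_false(big$significant)
  # a strongly shifted, highly expressed gene is flagged with direction
  expr2 <- tibble::tibble(gene_id = c("dn", sprintf("n%02d", 1:20)),
                          count_ck = c(8000L, rep(500L, 20)),
                          count_atr = c(2000L, rep(500L, 20)))
  de2 <- call_de(expr2, lib_ck = 1e6, lib_atr = 1e6)
  dn <- de2[de2$gene_id == "dn", ]
  expect_true(dn$significant)
  expect_equal(dn$direction, "down")
})

test_that("null expression simulations produce essentially no calls", {
  genes <- tibble::tibble(gene_id = sprintf("g%04d", 1:2000))
  expr <- simulate_expression(genes, effects = NULL, noise_sd = 0,
                              seed = 51)
  de <- call_de(expr)
  expect_lte(mean(de$significant), 0.001 + 3 * sqrt(0.001 / nrow(de)))
})

test_that("the joint filter is the intersection of both screens", {
  diff <- tibble::tibble(
    gene_id = c("a", "b", "c"), region = "upstream", context = "CG",
    direction = c("hyper", "hyper", "hypo"),
    log2_ratio = c(1.5, 1.5, -1.5), fold_change = c(2.8, 2.8, 2.8),
    p = c(0.001, 0.2, 0.001), q = c(0.01, 0.5, 0.01),
    significant = c(TRUE, FALSE, TRUE))
  de_tbl <- structure(
    tibble::tibble(gene_id = c("a", "b"), log2fc = c(-2, -2),
                   p = 1e-6, q = 1e-5, direction = "down",
                   significant = TRUE),
    class = c("meth_de", class(tibble::tibble())))
  j <- joint_filter(structure(diff,
                              class = c("meth_diff",
                                        class(tibble::tibble()))),
                    de_tbl)
  # only "a" passes both (b fails methylation p, c fails expression)
  expect_equal(j$gene_id, "a")
  expect_equal(j$quadrant, "upstream-hyper/expr-down")
  # empty DE set -> empty joint set
  de_empty <- structure(de_tbl[0, ],
                        class = c("meth_de", class(tibble::tibble())))
  expect_equal(nrow(joint_filter(
    structure(diff, class = c("meth_diff", class(tibble::tibble()))),
    de_empty)), 0)
})

test_that("joint region counts equal brute-force set algebra on 20 genes", {
  set.seed(52)
  genes <- sprintf("g%02d", 1:20)
  diff <- tidyr::expand_grid(gene_id = genes,
                             region = c("upstream", "genebody")) |>
    dplyr::mutate(context = "CG",
                  direction = sample(c("hyper", "hypo"), dplyr::n(),
                                     replace = TRUE),
                  log2_ratio = ifelse(direction == "hyper", 1.6, -1.6),
                  fold_change = sample(c(1.2, 3), dplyr::n(),
                                       replace = TRUE),
                  p = sample(c(0.01, 0.3), dplyr::n(), replace = TRUE),
                  q = p * 2, significant = p < 0.05 & fold_change > 2)
  de_tbl <- tibble::tibble(
    gene_id = genes, log2fc = sample(c(-2, 2), 20, replace = TRUE),
    p = 1e-6, q = 1e-5,
    direction = NA_character_,
    significant = sample(c(TRUE, FALSE), 20, replace = TRUE))
  de_tbl$direction <- ifelse(de_tbl$log2fc > 0, "up", "down")
  j <- joint_filter(
    structure(diff, class = c("meth_diff", class(tibble::tibble()))),
    structure(de_tbl, class = c("meth_de", class(tibble::tibble()))))
  counts <- joint_region_counts(j)
  # brute force: intersect the pass sets region by region
  de_pass <- de_tbl$gene_id[de_tbl$significant]
  for (reg in c("upstream", "genebody")) {
    for (dir in c("hyper", "hypo")) {
      manual <- diff[diff$region == reg & diff$direction == dir &
                       diff$p < 0.05 & diff$fold_change >= 2, ]
      expected <- length(intersect(manual$gene_id, de_pass))
      got <- counts$n_genes[counts$region == reg &
                              counts$meth_direction == dir]
      expect_equal(if (length(got)) got else 0L, expected)
    }
  }
  # every joint gene sits in both input pass sets
  expect_true(all(j$gene_id %in% de_pass))
  expect_true(all(paste(j$gene_id, j$region) %in%
                    paste(diff$gene_id, diff$region)[diff$p < 0.05 &
                                                       diff$fold_change >= 2]))
})

test_that("association summaries recover the coupling sign and conserve counts", {
  set.seed(53)
  n <- 400
  meth_change <- rnorm(n)
  diff <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:n), region = "upstream",
    context = "CG", direction = ifelse(meth_change > 0, "hyper", "hypo"),
    log2_ratio = meth_change, fold_change = 2^abs(meth_change),
    p = runif(n), q = runif(n), significant = FALSE)
  lfc <- -0.8 * meth_change + rnorm(n, 0, 0.5)
  de_tbl <- tibble::tibble(gene_id = diff$gene_id, log2fc = lfc,
                           p = runif(n), q = runif(n),
                           direction = ifelse(lfc > 0, "up", "down"),
                           significant = FALSE)
  a <- association_summary(
    structure(diff, class = c("meth_diff", class(tibble::tibble()))),
    structure(de_tbl, class = c("meth_de", class(tibble::tibble()))))
  expect_lt(a$rho, 0)
  expect_lt(a$p_value, 0.01)
  expect_equal(a$n_hyper_up + a$n_hyper_down + a$n_hypo_up +
                 a$n_hypo_down, a$n)
  # null coupling: correlation near zero
  de_null <- de_tbl
  de_null$log2fc <- rnorm(n, 0, 0.5)
  a0 <- association_summary(
    structure(diff, class = c("meth_diff", class(tibble::tibble()))),
    structure(de_null, class = c("meth_de", class(tibble::tibble()))))
  expect_lt(abs(a0$rho), 0.15)
  # class labels split the summary
  classes <- tibble::tibble(gene_id = diff$gene_id[1:100], class = "TF")
  ac <- association_summary(
    structure(diff, class = c("meth_diff", class(tibble::tibble()))),
    structure(de_tbl, class = c("meth_de", class(tibble::tibble()))),
    classes = classes)
  expect_setequal(ac$class, c("TF", "other"))
  expect_equal(sum(ac$n), n)
})
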