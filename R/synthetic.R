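#' Parameter set for the bisulfite pileup simulator
#'
#' Bundles every knob of the generative model: per-context Beta level
#' distributions, the fraction of sites truly methylated per context,
#' the bisulfite non-conversion rate, an optional symmetric sequencing
#' error toward C, and the mean per-strand read depth. The defaults
#' reproduce the qualitative plant methylome hierarchy (CG > CHG > CHH)
#' at the depth and conversion scale typical of plant WGBS libraries
#' (depth ~20x per strand, conversion ~99.6%).
#'
#' @param level_mean Named per-context mean of the Beta level
#'   distribution for truly methylated sites.
#' @param level_conc Beta concentration (shape1+shape2); larger is
#'   tighter around the mean.
#' @param meth_fraction Named per-context probability that a site is
#'   truly methylated at all.
#' @param epsilon Non-conversion rate: probability an unmethylated C
#'   reads as methylated.
#' @param seq_error Additional symmetric sequencing error toward C.
#' @param mean_depth Mean per-strand read depth (Poisson mean unless
#'   `fixed_depth`).
#' @param fixed_depth Use exactly `mean_depth` reads at every site
#'   (deterministic coverage for tests).
#' @return A `methylome_model` list.
#' @export
methylome_model <- function(level_mean = c(CG = 0.6, CHG = 0.35, CHH = 0.1),
                            level_conc = 10,
                            meth_fraction = c(CG = 0.5, CHG = 0.4, CHH = 0.1),
                            epsilon = 0.004,
                            seq_error = 0,
                            mean_depth = 20,
                            fixed_depth = FALSE) {
  stopifnot(all(level_mean >= 0 & level_mean <= 1),
            all(meth_fraction >= 0 & meth_fraction <= 1),
            epsilon >= 0, epsilon < 1, seq_error >= 0, seq_error < 1,
            mean_depth > 0, level_conc > 0)
  structure(
    list(level_mean = level_mean, level_conc = level_conc,
         meth_fraction = meth_fraction, epsilon = epsilon,
         seq_error = seq_error, mean_depth = mean_depth,
         fixed_depth = fixed_depth),
    class = "methylome_model")
}

#' Simulate a random genome
#'
#' I.i.d. bases at a fixed GC content. Rice-like euchromatin sits near
#' GC 0.43, the default used throughout the synthetic fixtures.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome (bp); recycled.
#' @param gc_fraction GC content, strictly inside (0, 1).
#' @param seed Optional RNG seed for reproducibility.
#' @return Named character vector of sequences (`chr1`, `chr2`, ...).
#' @export
simulate_genome <- function(n_chrom = 1, chrom_len = 100000,
                            gc_fraction = 0.43, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    abort("gc_fraction must be strictly between 0 and 1",
          class = "methylscape_input_error")
  }
  stopifnot(all(chrom_len >= 1), n_chrom >= 1)
  chrom_len <- rep_len(chrom_len, n_chrom)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  setNames(vapply(seq_len(n_chrom), function(i) {
    paste(sample(names(p), chrom_len[i], replace = TRUE, prob = p),
          collapse = "")
  }, character(1)), paste0("chr", seq_len(n_chrom)))
}

#' Simulate a gene annotation on a genome
#'
#' Places non-overlapping genes at a regular pitch along each
#' chromosome, with random strand and a simple two-exon structure
#' (5'UTR, CDS split by one intron, 3'UTR) so sub-feature statistics are
#' exercisable. Genes are spaced so that `flank`-sized upstream and
#' downstream regions of adjacent genes do not overlap when
#' `intergenic_len >= 2*flank`.
#'
#' @param genome Named character vector of sequences.
#' @param n_genes Total number of genes to place (capped by capacity).
#' @param gene_len Gene body length (bp).
#' @param intergenic_len Gap between consecutive gene bodies (bp).
#' @param seed Optional RNG seed (strand assignment).
#' @return Tibble: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, and a `features` list-column of sub-feature
#'   intervals.
#' @export
simulate_annotation <- function(genome, n_genes = 100, gene_len = 1000,
                                intergenic_len = 2200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pitch <- gene_len + intergenic_len
  slots <- purrr::imap(genome, function(seq, chrom) {
    n_fit <- max(0, (nchar(seq) - intergenic_len) %/% pitch)
    if (n_fit == 0) return(NULL)
    start <- intergenic_len %/% 2 + pitch * (seq_len(n_fit) - 1L)
    tibble(chrom = chrom, start = as.integer(start),
           end = as.integer(start + gene_len))
  })
  slots <- bind_rows(slots)
  if (nrow(slots) == 0) {
    abort("genome too small to place any gene",
          class = "methylscape_input_error")
  }
  genes <- head(slots, n_genes)
  genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$features <- purrr::pmap(
    genes[, c("start", "end", "strand")],
    function(start, end, strand) gene_structure(start, end, strand))
  genes[, c("gene_id", "chrom", "start", "end", "strand", "features")]
}

# Two-exon gene structure: utr5 / cds [intron] cds / utr3, strand-aware.
gene_structure <- function(start, end, strand) {
  len <- end - start
  utr <- max(20L, len %/% 10)
  mid <- start + len %/% 2
  intron_half <- max(10L, len %/% 12)
  intron <- c(mid - intron_half, mid + intron_half)
  exon1 <- c(start, intron[1]); exon2 <- c(intron[2], end)
  if (strand == "+") {
    utr5 <- c(start, start + utr); utr3 <- c(end - utr, end)
  } else {
    utr5 <- c(end - utr, end); utr3 <- c(start, start + utr)
  }
  cds <- tibble(region = "cds",
                start = c(max(exon1[1], start + utr), exon2[1]),
                end = c(exon1[2], min(exon2[2], end - utr)))
  bind_rows(
    tibble(region = "exon", start = c(exon1[1], exon2[1]),
           end = c(exon1[2], exon2[2])),
    tibble(region = "utr5", start = utr5[1], end = utr5[2]),
    cds,
    tibble(region = "intron", start = intron[1], end = intron[2]),
    tibble(region = "utr3", start = utr3[1], end = utr3[2])
  ) |> mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Describe treatment-induced methylation effects
#'
#' One row per targeted (gene, region, context): the treatment
#' methylome is shifted by `effect` on the level scale in the stated
#' direction at every matching cytosine, clamped to \[0, 1\].
#'
#' @param gene_id Character vector of target genes.
#' @param region Region per gene (`upstream`, `genebody`, `downstream`).
#' @param context Context per gene (`CG`, `CHG`, `CHH`).
#' @param direction `"hyper"` or `"hypo"`.
#' @param effect Level shift magnitude in \[0, 1\].
#' @return Tibble effect specification for [simulate_methylome()].
#' @export
treatment_effects <- function(gene_id, region = "upstream", context = "CG",
                              direction = "hyper", effect = 0.4) {
  tibble(gene_id = gene_id, region = region, context = context,
         direction = direction, effect = effect)
}

#' Simulate true methylation levels for control and treatment
#'
#' Each site is truly methylated with its context's `meth_fraction`;
#' methylated sites draw a level from the context's Beta distribution,
#' unmethylated sites have level 0. The treatment methylome equals the
#' control except at cytosines hit by an effect target, where the level
#' is shifted by the effect size and clamped to \[0, 1\].
#'
#' @param sites Tibble from [enumerate_cytosines()].
#' @param model A [methylome_model()].
#' @param gene_models Region intervals from [build_gene_models()];
#'   required when `effects` is non-NULL.
#' @param effects Effect specification from [treatment_effects()].
#' @param seed Optional RNG seed.
#' @return Truth tibble: site columns plus `level_ck`, `level_atr`.
#' @export
simulate_methylome <- function(sites, model, gene_models = NULL,
                               effects = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(model, "methylome_model"))
  n <- nrow(sites)
  frac <- model$meth_fraction[sites$context]
  mu <- model$level_mean[sites$context]
  is_meth <- runif(n) < frac
  level <- numeric(n)
  if (any(is_meth)) {
    shape1 <- mu[is_meth] * model$level_conc
    shape2 <- (1 - mu[is_meth]) * model$level_conc
    level[is_meth] <- rbeta(sum(is_meth), shape1, shape2)
  }
  truth <- sites
  truth$level_ck <- level
  truth$level_atr <- level
  if (!is.null(effects) && nrow(effects) > 0) {
    if (is.null(gene_models)) {
      abort("gene_models required when effects are given",
            class = "methylscape_input_error")
    }
    missing <- setdiff(effects$gene_id, gene_models$gene_id)
    if (length(missing) > 0) {
      abort(paste("effect target gene(s) absent from annotation:",
                  paste(missing, collapse = ", ")),
            class = "methylscape_effect_error")
    }
    targets <- gene_models |>
      inner_join(effects, by = c("gene_id", "region"))
    hit <- overlap_join(
      truth |> mutate(.row = dplyr::row_number()),
      targets,
      keep = c("context", "direction", "effect")
    ) |>
      filter(.data$context == .data$context_feature) |>
      distinct(.data$.row, .keep_all = TRUE)
    if (nrow(hit) > 0) {
      shift <- ifelse(hit$direction == "hyper", hit$effect, -hit$effect)
      truth$level_atr[hit$.row] <- pmin(1, pmax(0,
        truth$level_atr[hit$.row] + shift))
    }
  }
  truth
}

#' Simulate bisulfite read counts from true methylation levels
#'
#' Per site and condition, depth is Poisson (or fixed) at the model's
#' mean per-strand depth, and the methylated-read count is binomial
#' with success probability `m*(1 - err) + (1 - m)*epsilon`, where `m`
#' is the true level: methylated cytosines resist conversion while a
#' fraction `epsilon` of unmethylated cytosines fail to convert.
#'
#' @param truth Tibble from [simulate_methylome()].
#' @param model A [methylome_model()].
#' @param conditions Named vector mapping condition labels to the truth
#'   level column to read.
#' @param seed Optional RNG seed.
#' @return Long pileup tibble: site columns, `count_m`, `count_u`,
#'   `condition`.
#' @export
simulate_bisulfite_counts <- function(
    truth, model,
    conditions = c(CK = "level_ck", ATR = "level_atr"),
    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(model, "methylome_model"))
  site_cols <- intersect(c("chrom", "pos", "strand", "context"), names(truth))
  out <- purrr::imap(conditions, function(col, cond) {
    m <- truth[[col]]
    n <- length(m)
    depth <- if (model$fixed_depth) rep(as.integer(round(model$mean_depth)), n)
             else rpois(n, model$mean_depth)
    p_read_m <- m * (1 - model$seq_error) + (1 - m) * model$epsilon
    count_m <- rbinom(n, depth, p_read_m)
    truth[, site_cols] |>
      mutate(count_m = count_m, count_u = depth - count_m,
             condition = cond)
  })
  bind_rows(out)
}

#' Simulate a two-condition expression count table coupled to methylation
#'
#' Baseline relative expression per gene is log-normal; the treatment
#' mean is scaled by `2^log2FC`, where log2FC comes from the coupling
#' rule applied to the gene's methylation effect (default:
#' upstream-hyper genes are down-regulated at log2FC -1, genebody-hypo
#' genes up-regulated at +1, all others neutral) plus Gaussian noise.
#' Counts are Poisson at `library size x relative expression`.
#'
#' @param genes Gene table (`gene_id` column).
#' @param effects Effect specification from [treatment_effects()] (may
#'   be NULL: no coupling).
#' @param lib_ck,lib_atr Library sizes (expected total counts).
#' @param coupling Tibble (`region`, `direction`, `log2fc`) mapping a
#'   methylation effect to an expression response.
#' @param noise_sd SD of the Gaussian noise on true log2FC.
#' @param seed Optional RNG seed.
#' @return Tibble: `gene_id`, `count_ck`, `count_atr`, `true_log2fc`.
#' @export
simulate_expression <- function(genes, effects = NULL,
                                lib_ck = 2e6, lib_atr = 2e6,
                                coupling = default_coupling(),
                                noise_sd = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(lib_ck > 0, lib_atr > 0)
  n <- nrow(genes)
  lfc <- rep(0, n)
  if (!is.null(effects) && nrow(effects) > 0 && !is.null(coupling)) {
    eff <- effects |>
      inner_join(coupling, by = c("region", "direction"))
    idx <- match(eff$gene_id, genes$gene_id)
    ok <- !is.na(idx)
    lfc[idx[ok]] <- lfc[idx[ok]] + eff$log2fc[ok]
  }
  lfc <- lfc + rnorm(n, 0, noise_sd)
  base <- exp(rnorm(n, log(100), 1))
  rel <- base / sum(base)
  mu_ck <- lib_ck * rel
  mu_atr <- lib_atr * rel * 2^lfc
  tibble(gene_id = genes$gene_id,
         count_ck = rpois(n, mu_ck),
         count_atr = rpois(n, mu_atr),
         true_log2fc = lfc)
}

#' Default methylation-to-expression coupling rule
#' @return Tibble (`region`, `direction`, `log2fc`).
#' @export
default_coupling <- function() {
  tibble(region = c("upstream", "genebody"),
         direction = c("hyper", "hypo"),
         log2fc = c(-1, 1))
}

#' Simulate a complete two-condition bisulfite + expression experiment
#'
#' One call that wires the generators together: genome, annotation,
#' cytosine enumeration, control/treatment methylomes with the given
#' effect targets, bisulfite pileups for both conditions, and a coupled
#' expression table. All randomness flows from `seed` through
#' per-component substreams, so identical seeds give byte-identical
#' fixtures.
#'
#' @param n_chrom,chrom_len,gc_fraction Genome parameters.
#' @param n_genes,gene_len,intergenic_len Annotation parameters.
#' @param flank_bp Flank used for the region models.
#' @param model A [methylome_model()].
#' @param n_effect Number of genes given a treatment effect.
#' @param effect_region,effect_context,effect_direction,effect_size
#'   Effect target description (applied to the first `n_effect` genes
#'   after a seeded shuffle).
#' @param lib_ck,lib_atr Expression library sizes.
#' @param coupling Methylation-to-expression coupling rule.
#' @param seed Master seed.
#' @return List: `genome`, `genes`, `gene_models`, `sites`, `truth`,
#'   `pileups`, `expression`, `effects`, `seqlens`.
#' @export
simulate_methylation_experiment <- function(
    n_chrom = 1, chrom_len = 3.5e5, gc_fraction = 0.43,
    n_genes = 100, gene_len = 1000, intergenic_len = 2200,
    flank_bp = 1000,
    model = methylome_model(),
    n_effect = 10, effect_region = "upstream", effect_context = "CG",
    effect_direction = "hyper", effect_size = 0.4,
    lib_ck = 2e6, lib_atr = 2e6, coupling = default_coupling(),
    seed = 1) {
  set.seed(seed)
  sub <- sample.int(2^30, 6)
  genome <- simulate_genome(n_chrom, chrom_len, gc_fraction, seed = sub[1])
  genes <- simulate_annotation(genome, n_genes, gene_len, intergenic_len,
                               seed = sub[2])
  seqlens <- vapply(genome, nchar, integer(1))
  gene_models <- build_gene_models(
    genes[, c("gene_id", "chrom", "start", "end", "strand")],
    flank_bp = flank_bp, seqlens = seqlens)
  sites <- enumerate_cytosines(genome)
  effects <- NULL
  if (n_effect > 0) {
    set.seed(sub[3])
    target <- sample(genes$gene_id, min(n_effect, nrow(genes)))
    effects <- treatment_effects(target, effect_region, effect_context,
                                 effect_direction, effect_size)
  }
  truth <- simulate_methylome(sites, model, gene_models, effects,
                              seed = sub[4])
  pileups <- simulate_bisulfite_counts(truth, model, seed = sub[5])
  expression <- simulate_expression(genes, effects, lib_ck, lib_atr,
                                    coupling, seed = sub[6])
  list(genome = genome, genes = genes, gene_models = gene_models,
       sites = sites, truth = truth, pileups = pileups,
       expression = expression, effects = effects, seqlens = seqlens)
}

#' Write a simulated experiment to disk as plain-text files
#'
#' Emits FASTA, GFF3, one cytosine report per condition, the expression
#' table, and the truth tables, so the file-based pipeline entry points
#' can be exercised end to end.
#'
#' @param exp List from [simulate_methylation_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "genes.gff3"),
    pileup_ck = file.path(dir, "pileup_CK.tsv"),
    pileup_atr = file.path(dir, "pileup_ATR.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv")
  )
  write_fasta(exp$genome, paths$genome)
  write_gff3(exp$genes, paths$annotation)
  write_cytosine_report(
    exp$pileups |> filter(.data$condition == "CK"), paths$pileup_ck)
  write_cytosine_report(
    exp$pileups |> filter(.data$condition == "ATR"), paths$pileup_atr)
  readr::write_tsv(exp$expression, paths$expression, progress = FALSE)
  readr::write_tsv(exp$truth, paths$truth_sites, progress = FALSE)
  truth_genes <- exp$genes[, c("gene_id", "chrom", "start", "end", "strand")]
  if (!is.null(exp$effects)) {
    truth_genes <- truth_genes |>
      left_join(exp$effects, by = "gene_id")
  }
  readr::write_tsv(truth_genes, paths$truth_genes, progress = FALSE)
  invisible(paths)
}
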