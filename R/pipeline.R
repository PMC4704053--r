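#' Assemble a pipeline run configuration
#'
#' Collects the input paths and every analysis threshold in one
#' validated list. Defaults mirror the standard choices used throughout
#' the package: methylcytosine calling at 1% FDR, differential
#' methylation at FDR 0.05 with a two-fold RKTM ratio, differential
#' expression at FDR 0.001 with |log2FC| >= 1, 200-bp windows, 10-kb
#' chromosome bins, 2-kb flanks, minimum site coverage 4.
#'
#' @param genome,annotation,pileup_ck,pileup_atr,expression,loci Input
#'   file paths (`expression` and `loci` optional, NULL to skip those
#'   stages).
#' @param out_dir Output directory.
#' @param epsilon Non-conversion rate; `NULL` means estimate it from
#'   the least-methylated fraction of sites is not attempted — supply a
#'   rate or a `nonconversion_sites` BED of known-unmethylated sites.
#' @param nonconversion_sites Optional BED of known-unmethylated
#'   intervals used to estimate `epsilon` when it is NULL.
#' @param call_fdr,diff_fdr,fold,de_fdr,min_log2fc,window,bin,flank_bp,
#'   min_coverage,merge_gap,p_meth Analysis thresholds.
#' @param seed RNG seed recorded with the run (the analysis itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(genome, annotation, pileup_ck, pileup_atr,
                       expression = NULL, loci = NULL,
                       out_dir = "methylscape_out",
                       epsilon = NULL, nonconversion_sites = NULL,
                       call_fdr = 0.01, diff_fdr = 0.05, fold = 2,
                       de_fdr = 0.001, min_log2fc = 1,
                       window = 200, bin = 10000, flank_bp = 2000,
                       min_coverage = 4, merge_gap = 0, p_meth = 0.05,
                       seed = 1) {
  thresholds <- c(call_fdr = call_fdr, diff_fdr = diff_fdr, fold = fold,
                  de_fdr = de_fdr, min_log2fc = min_log2fc,
                  window = window, bin = bin, flank_bp = flank_bp,
                  min_coverage = min_coverage, p_meth = p_meth)
  if (any(thresholds <= 0)) {
    abort("all thresholds must be positive",
          class = "methylscape_config_error")
  }
  structure(
    list(genome = genome, annotation = annotation,
         pileup_ck = pileup_ck, pileup_atr = pileup_atr,
         expression = expression, loci = loci, out_dir = out_dir,
         epsilon = epsilon, nonconversion_sites = nonconversion_sites,
         call_fdr = call_fdr, diff_fdr = diff_fdr, fold = fold,
         de_fdr = de_fdr, min_log2fc = min_log2fc, window = window,
         bin = bin, flank_bp = flank_bp, min_coverage = min_coverage,
         merge_gap = merge_gap, p_meth = p_meth, seed = seed),
    class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("genome", "annotation", "pileup_ck", "pileup_atr",
              "expression", "loci", "nonconversion_sites", "out_dir")) {
    if (!is.null(raw[[k]]) && !grepl("^/", raw[[k]])) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  do.call(run_config, raw)
}

#' Run the full methylome analysis pipeline
#'
#' Orchestrates every stage from cytosine reports to final tables:
#' methylcytosine calling for both conditions, context composition,
#' window and chromosome profiles, gene metaprofiles, feature-level
#' differential methylation, DMR calling on windows, differential
#' expression, the joint methylation-expression filter, miRNA-locus
#' ratios, and a JSON summary of headline counts. All outputs are
#' plain-text tables written under `config$out_dir`; given identical
#' inputs the run is deterministic, so reruns are byte-identical.
#'
#' @param config A `run_config` list.
#' @return Invisibly, a list of the in-memory results
#'   (`calls`, `composition`, `windows`, `profile`, `metaprofile`,
#'   `features`, `diff`, `dmgs`, `dmrs`, `de`, `joint`, `mirna`,
#'   `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "methylscape_stage_error")
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  inputs <- stage("read_inputs", {
    genome <- as_genome(config$genome)
    list(
      genome = genome,
      seqlens = vapply(genome, nchar, integer(1)),
      models = build_gene_models(config$annotation,
                                 flank_bp = config$flank_bp,
                                 seqlens = vapply(genome, nchar,
                                                  integer(1))),
      pileups = bind_rows(
        read_cytosine_report(config$pileup_ck, condition = "CK"),
        read_cytosine_report(config$pileup_atr, condition = "ATR")))
  })

  epsilon <- stage("nonconversion", {
    if (!is.null(config$epsilon)) config$epsilon
    else if (!is.null(config$nonconversion_sites)) {
      ctrl <- read_loci(config$nonconversion_sites)
      estimate_nonconversion(
        overlap_join(inputs$pileups, ctrl, keep = "locus_id"))
    } else {
      abort("supply epsilon or nonconversion_sites")
    }
  })

  calls <- stage("mc_calling", {
    call_methylome(inputs$pileups, epsilon, fdr = config$call_fdr,
                   min_coverage = config$min_coverage)
  })
  calls_ck <- calls |> filter(.data$condition == "CK")
  calls_atr <- calls |> filter(.data$condition == "ATR")

  landscape <- stage("landscape", {
    comp <- bind_rows(
      context_composition(calls_ck) |> mutate(condition = "CK"),
      context_composition(calls_atr) |> mutate(condition = "ATR"))
    win_ck <- sliding_window_levels(calls_ck, width = config$window)
    win_atr <- sliding_window_levels(calls_atr, width = config$window)
    prof <- bind_rows(
      chromosome_profile(calls_ck, bin = config$bin) |>
        mutate(condition = "CK"),
      chromosome_profile(calls_atr, bin = config$bin) |>
        mutate(condition = "ATR"))
    meta <- bind_rows(
      feature_metaprofile(calls_ck, inputs$models) |>
        mutate(condition = "CK"),
      feature_metaprofile(calls_atr, inputs$models) |>
        mutate(condition = "ATR"))
    list(comp = comp, win_ck = win_ck, win_atr = win_atr, prof = prof,
         meta = meta)
  })

  diff <- stage("differential", {
    features <- feature_methylation(calls, inputs$models)
    call_differential_features(features, treatment = "ATR",
                               control = "CK", fdr = config$diff_fdr,
                               fold = config$fold)
  })
  dmgs <- stage("dmg_summary", summarize_dmgs(diff))
  dmrs <- stage("dmr_calling", {
    call_dmrs(landscape$win_atr, landscape$win_ck,
              fdr = config$diff_fdr, fold = config$fold,
              merge_gap = config$merge_gap)
  })

  de <- NULL; joint <- NULL
  if (!is.null(config$expression)) {
    de <- stage("expression", {
      call_de(read_expression_table(config$expression),
              fdr = config$de_fdr, min_log2fc = config$min_log2fc)
    })
    joint <- stage("joint_filter", {
      joint_filter(diff, de, p_meth = config$p_meth,
                   fold_meth = config$fold)
    })
  }

  mirna <- NULL
  if (!is.null(config$loci)) {
    mirna <- stage("mirna_loci", {
      mirna_locus_table(calls, read_loci(config$loci))
    })
  }

  stage("write_outputs", {
    readr::write_tsv(tidy(calls), out("site_calls.tsv"), progress = FALSE)
    readr::write_tsv(landscape$comp, out("context_composition.tsv"),
                     progress = FALSE)
    readr::write_tsv(as_tibble(unclass_keep(landscape$win_ck)),
                     out("windows_CK.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(unclass_keep(landscape$win_atr)),
                     out("windows_ATR.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(unclass_keep(landscape$prof)),
                     out("chromosome_profile.tsv"), progress = FALSE)
    readr::write_tsv(landscape$meta, out("metaprofile.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(diff), out("differential_features.tsv"),
                     progress = FALSE)
    readr::write_tsv(dmgs, out("dmg_table.tsv"), progress = FALSE)
    write_dmr_bed(dmrs, out("dmrs.bed"))
    if (!is.null(de)) {
      readr::write_tsv(tidy(de), out("differential_expression.tsv"),
                       progress = FALSE)
      readr::write_tsv(joint, out("joint_table.tsv"), progress = FALSE)
    }
    if (!is.null(mirna)) {
      readr::write_tsv(
        mirna |> mutate(log2_ratio = round(.data$log2_ratio, 2)),
        out("mirna_loci.tsv"), progress = FALSE)
    }
  })

  summary <- list(
    n_sites_tested = nrow(calls),
    n_methylated_ck = sum(calls_ck$is_methylated),
    n_methylated_atr = sum(calls_atr$is_methylated),
    n_diff_features = sum(diff$significant),
    n_dmgs = nrow(dmgs),
    n_dmgs_hyper = sum(dmgs$classification == "hyper"),
    n_dmgs_hypo = sum(dmgs$classification == "hypo"),
    n_dmrs = nrow(dmrs),
    n_de_genes = if (is.null(de)) NA else sum(de$significant),
    n_joint_genes = if (is.null(joint)) NA else
      length(unique(joint$gene_id)),
    n_mirna_two_fold = if (is.null(mirna)) NA else
      sum(mirna$passes_two_fold, na.rm = TRUE),
    epsilon = epsilon, seed = config$seed)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")

  invisible(list(calls = calls, composition = landscape$comp,
                 windows = list(CK = landscape$win_ck,
                                ATR = landscape$win_atr),
                 profile = landscape$prof, metaprofile = landscape$meta,
                 diff = diff, dmgs = dmgs, dmrs = dmrs, de = de,
                 joint = joint, mirna = mirna, summary = summary))
}
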