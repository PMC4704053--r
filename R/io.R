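#' Read a per-site cytosine report
#'
#' Reads the tab-separated "cytosine report" dialect: one row per
#' cytosine with columns chrom, position (1-based), strand, methylated
#' read count, unmethylated read count, context. A Bismark-style
#' CX report (same six columns plus a trailing trinucleotide column) is
#' accepted transparently; the extra column is ignored.
#'
#' @param path Path to the TSV (no header).
#' @param condition Optional condition label attached as a column.
#' @return Tibble with `chrom`, `pos` (0-based), `strand`, `count_m`,
#'   `count_u`, `context`, and `condition` if given.
#' @export
read_cytosine_report <- function(path, condition = NULL) {
  df <- readr::read_tsv(
    path, col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(df) < 6) {
    abort("cytosine report needs >= 6 columns", class = "methylscape_input_error")
  }
  out <- tibble(
    chrom = df[[1]],
    pos = as.integer(df[[2]]) - 1L,
    strand = df[[3]],
    count_m = as.integer(df[[4]]),
    count_u = as.integer(df[[5]]),
    context = df[[6]]
  )
  if (!is.null(condition)) out$condition <- condition
  out
}

#' Write a per-site cytosine report
#' @param pileups Tibble with `chrom`, `pos` (0-based), `strand`,
#'   `count_m`, `count_u`, `context`.
#' @param path Output TSV path (1-based positions, no header).
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(pileups, path) {
  readr::write_tsv(
    tibble(pileups$chrom, pileups$pos + 1L, pileups$strand,
           pileups$count_m, pileups$count_u, pileups$context),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read a two-condition expression count table
#' @param path TSV with header columns `gene_id`, `count_ck`, `count_atr`
#'   (control and treatment raw counts).
#' @return Tibble of the same columns.
#' @export
read_expression_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read gene class labels
#' @param path Two-column TSV (gene, class), no header.
#' @return Tibble with `gene_id`, `class`.
#' @export
read_gene_classes <- function(path) {
  readr::read_tsv(path, col_names = c("gene_id", "class"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Read precursor/locus intervals from BED or GFF3
#'
#' @param path BED (0-based half-open; name in column 4) or GFF3 file
#'   (1-based closed; locus id from the ID attribute).
#' @return Tibble with `locus_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
read_loci <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    ids <- if ("ID" %in% names(df)) as.character(df$ID) else
      paste0("locus_", seq_len(nrow(df)))
    return(tibble(locus_id = ids, chrom = as.character(df$seqnames),
                  start = df$start - 1L, end = df$end))
  }
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  tibble(
    locus_id = if (ncol(df) >= 4) as.character(df[[4]]) else
      paste0("locus_", seq_len(nrow(df))),
    chrom = as.character(df[[1]]),
    start = as.integer(df[[2]]), end = as.integer(df[[3]])
  )
}

#' Write genome sequences as FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}

#' Write a gene table (and simple two-exon structure) as GFF3
#'
#' Emits gene, mRNA, exon, CDS and UTR features when the gene table
#' carries sub-feature columns produced by [simulate_annotation()];
#' plain gene features otherwise.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, optionally a list-column `features` of
#'   sub-feature tibbles (`region`, `start`, `end`).
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  rows <- purrr::pmap(genes, function(gene_id, chrom, start, end, strand, ...) {
    dots <- list(...)
    gff_line <- function(type, s, e, id, parent = NULL) {
      attrs <- paste0("ID=", id)
      if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
      paste(chrom, "methylscape", type, s + 1L, e, ".", strand, ".", attrs,
            sep = "\t")
    }
    lines <- c(gff_line("gene", start, end, gene_id))
    feats <- dots$features
    if (!is.null(feats) && is.data.frame(feats)) {
      feats <- feats[feats$region != "intron", , drop = FALSE]
    }
    if (!is.null(feats) && is.data.frame(feats) && nrow(feats) > 0) {
      tx <- paste0(gene_id, ".1")
      lines <- c(lines, gff_line("mRNA", start, end, tx, gene_id))
      type_map <- c(utr5 = "five_prime_UTR", cds = "CDS",
                    utr3 = "three_prime_UTR", exon = "exon")
      for (i in seq_len(nrow(feats))) {
        lines <- c(lines, gff_line(
          type_map[[feats$region[i]]], feats$start[i], feats$end[i],
          paste0(tx, ".", feats$region[i], i), tx))
      }
    }
    lines
  })
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Write differentially methylated regions as BED6
#'
#' One line per merged DMR: name is the context, score is
#' `-10*log10(q)` (capped at 1000), strand is ".". The direction is
#' appended to the name as `context:hyper` / `context:hypo`.
#'
#' @param dmrs Tibble from [call_dmrs()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(1000, round(-10 * log10(pmax(dmrs$q, 1e-100)), 1))
  readr::write_tsv(
    tibble(dmrs$chrom, dmrs$start, dmrs$end,
           paste0(dmrs$context, ":", dmrs$direction), score, "."),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}
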