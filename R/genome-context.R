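#' Enumerate every cytosine in a genome with its sequence context
#'
#' Scans both strands of each chromosome and emits one row per cytosine
#' (forward-strand `C`, reverse-strand `G` on the forward sequence)
#' together with its methylation context: `CG`, `CHG` or `CHH`, where
#' H is A, C or T. The context is read from the two bases immediately
#' 3' of the cytosine on its own strand; sites whose two-base context
#' window contains an `N` or runs off the chromosome end are skipped,
#' so every emitted site has an unambiguous context.
#'
#' @param genome A named character vector of chromosome sequences
#'   (alphabet `A`, `C`, `G`, `T`, `N`), a `Biostrings::DNAStringSet`,
#'   or the path to a FASTA file.
#' @return A tibble with columns `chrom`, `pos` (0-based position on the
#'   forward coordinate system), `strand` (`+`/`-`) and `context`,
#'   sorted by `(chrom, pos, strand)`.
#' @examples
#' enumerate_cytosines(c(chr1 = "TACGT"))
#' @export
enumerate_cytosines <- function(genome) {
  genome <- as_genome(genome)
  out <- purrr::imap(genome, function(seq, chrom) {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
    if (length(bad) > 0) {
      abort(paste0("invalid bases in chromosome '", chrom, "': ",
                   paste(bad, collapse = ", ")),
            class = "methylscape_alphabet_error")
    }
    n <- length(chars)
    fwd <- which(chars == "C")
    fwd <- fwd[fwd <= n - 2L]
    f1 <- chars[fwd + 1L]; f2 <- chars[fwd + 2L]
    keep <- f1 != "N" & f2 != "N"
    fwd_tbl <- tibble(
      pos = fwd[keep] - 1L, strand = "+",
      context = classify_context(f1[keep], f2[keep])
    )
    rev <- which(chars == "G")
    rev <- rev[rev >= 3L]
    r1 <- comp_base(chars[rev - 1L]); r2 <- comp_base(chars[rev - 2L])
    keep <- r1 != "N" & r2 != "N"
    rev_tbl <- tibble(
      pos = rev[keep] - 1L, strand = "-",
      context = classify_context(r1[keep], r2[keep])
    )
    bind_rows(fwd_tbl, rev_tbl) |> mutate(chrom = chrom, .before = 1)
  })
  bind_rows(out) |> arrange(.data$chrom, .data$pos, .data$strand)
}

classify_context <- function(b1, b2) {
  out <- character(length(b1))
  out[b1 == "G"] <- "CG"
  out[b1 != "G" & b2 == "G"] <- "CHG"
  out[b1 != "G" & b2 != "G"] <- "CHH"
  out
}

comp_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]
}

#' Reverse-complement a set of chromosome sequences
#' @param genome Named character vector of sequences.
#' @return Named character vector, each sequence reverse-complemented.
#' @export
revcomp_genome <- function(genome) {
  vapply(genome, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome))) {
    abort("genome must be a named character vector, DNAStringSet or FASTA path",
          class = "methylscape_input_error")
  }
  genome
}

#' Build gene region models (upstream, genebody, downstream) from annotation
#'
#' Converts gene annotation into the long interval table used by all
#' region-level statistics: one row per gene x region interval, in
#' 0-based half-open coordinates. Upstream and downstream flanks are
#' `flank_bp` long, strand-aware (upstream is 5' of the transcription
#' start on the gene's own strand) and truncated at chromosome edges.
#' When the annotation carries exon/CDS/UTR features and
#' `include_subfeatures = TRUE`, sub-feature intervals (`utr5`, `cds`,
#' `intron`, `utr3`) nested in the genebody are emitted as well; introns
#' are the within-gene gaps between exons.
#'
#' @param annotation Path to a GFF3 file (1-based closed coordinates),
#'   or a tibble of genes with columns `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @param flank_bp Flank length in bp for upstream/downstream
#'   (default 2000, the common plant-methylome convention).
#' @param seqlens Optional named vector of chromosome lengths used to
#'   truncate flanks at the 3' chromosome edge.
#' @param include_subfeatures Emit utr5/cds/intron/utr3 rows when the
#'   annotation provides them (GFF3 input only).
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `region`,
#'   `start`, `end`. Empty intervals (zero length after truncation) are
#'   kept with `start == end` so callers can detect them.
#' @export
build_gene_models <- function(annotation, flank_bp = 2000, seqlens = NULL,
                              include_subfeatures = FALSE) {
  sub <- NULL
  if (is.character(annotation) && length(annotation) == 1) {
    parsed <- read_gff3_annotation(annotation)
    genes <- parsed$genes
    if (include_subfeatures) sub <- parsed$subfeatures
  } else {
    genes <- as_tibble(annotation)
    req <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(req %in% names(genes))) {
      abort("annotation tibble needs columns gene_id, chrom, start, end, strand",
            class = "methylscape_input_error")
    }
  }
  bad <- is.na(genes$start) | is.na(genes$end) | genes$end < genes$start
  if (any(bad)) {
    warn(paste(sum(bad), "gene(s) without usable coordinates skipped"))
    genes <- genes[!bad, ]
  }
  len_of <- function(chrom) {
    if (is.null(seqlens)) rep(Inf, length(chrom)) else unname(seqlens[chrom])
  }
  clip <- function(x, chrom) pmin(pmax(x, 0), len_of(chrom))
  plus <- genes$strand == "+"
  up_start <- ifelse(plus, genes$start - flank_bp, genes$end)
  up_end <- ifelse(plus, genes$start, genes$end + flank_bp)
  dn_start <- ifelse(plus, genes$end, genes$start - flank_bp)
  dn_end <- ifelse(plus, genes$end + flank_bp, genes$start)
  models <- bind_rows(
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           strand = genes$strand, region = "upstream",
           start = clip(up_start, genes$chrom), end = clip(up_end, genes$chrom)),
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           strand = genes$strand, region = "genebody",
           start = genes$start, end = genes$end),
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           strand = genes$strand, region = "downstream",
           start = clip(dn_start, genes$chrom), end = clip(dn_end, genes$chrom))
  )
  if (!is.null(sub) && nrow(sub) > 0) models <- bind_rows(models, sub)
  models |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$gene_id, .data$region, .data$start)
}

# GFF3 -> genes + sub-feature intervals, both 0-based half-open
read_gff3_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  ids <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  parents <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))
  is_gene <- df$type %in% c("gene", "transposable_element_gene")
  if (!any(is_gene)) is_gene <- df$type == "mRNA"
  genes <- tibble(
    gene_id = ids[is_gene], chrom = as.character(df$seqnames)[is_gene],
    start = df$start[is_gene] - 1L, end = df$end[is_gene],
    strand = as.character(df$strand)[is_gene]
  )
  # map mRNA -> gene so sub-features resolve to their gene id
  mrna <- df$type == "mRNA"
  tx2gene <- setNames(
    ifelse(is.na(parents[mrna]), ids[mrna], parents[mrna]), ids[mrna])
  resolve <- function(p) ifelse(p %in% names(tx2gene), tx2gene[p], p)
  type_map <- c(five_prime_UTR = "utr5", CDS = "cds", three_prime_UTR = "utr3")
  is_sub <- df$type %in% names(type_map)
  sub <- tibble(
    gene_id = unname(resolve(parents[is_sub])),
    chrom = as.character(df$seqnames)[is_sub],
    strand = as.character(df$strand)[is_sub],
    region = unname(type_map[df$type[is_sub]]),
    start = df$start[is_sub] - 1L, end = df$end[is_sub]
  )
  is_exon <- df$type == "exon"
  if (any(is_exon)) {
    introns <- tibble(
      gene_id = unname(resolve(parents[is_exon])),
      chrom = as.character(df$seqnames)[is_exon],
      strand = as.character(df$strand)[is_exon],
      start = df$start[is_exon] - 1L, end = df$end[is_exon]
    ) |>
      group_by(.data$gene_id, .data$chrom, .data$strand) |>
      arrange(.data$start, .by_group = TRUE) |>
      reframe(start = head(.data$end, -1), end = tail(.data$start, -1)) |>
      filter(.data$end > .data$start) |>
      mutate(region = "intron")
    sub <- bind_rows(sub, introns)
  }
  sub <- sub |> filter(!is.na(.data$gene_id)) |>
    select("gene_id", "chrom", "strand", "region", "start", "end")
  list(genes = genes |> filter(!is.na(.data$gene_id)), subfeatures = sub)
}
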