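# TFO and TTS detection and genomic-context labelling.

# source class of a transcript, e.g. "pre-mRNA" or "mature-lncRNA"
source_class_of <- function(kind, class) {
  paste0(ifelse(kind == "pre", "pre-", "mature-"), class)
}

# exon intervals of a gene expressed in pre-RNA (coding strand) coordinates
pre_exons_tx_space <- function(gene) {
  ex <- gene$exons[[1]]
  if (gene$strand == "+") {
    tibble(start = ex$start - gene$start, end = ex$end - gene$start)
  } else {
    dplyr::arrange(tibble(start = gene$end - ex$end, end = gene$end - ex$start), .data$start)
  }
}

region_label_pre <- function(tx_exons, start, end) {
  ov <- sum(interval_overlap(start, end, tx_exons$start, tx_exons$end))
  if (ov == end - start) "exon" else if (ov == 0L) "intron" else "junction"
}

#' Detect triplex-forming oligonucleotides (TFOs) in transcripts
#'
#' Scans each transcript for maximal runs over the three Hoogsteen motif
#' alphabets: the pyrimidine motif `[TC]` (binds parallel to the purine
#' strand of the target duplex), the purine motif `[GA]` (antiparallel), and
#' the purine-pyrimidine motif `[GT]` (either orientation). One record is
#' emitted per (transcript, motif, maximal run); a run whose letters satisfy
#' two motif alphabets (e.g. a pure-G run, valid under both `[GA]` and
#' `[GT]`) is reported under each motif, shares a `run_id`, and carries
#' `multi_motif = TRUE` so unique intervals can be counted separately from
#' per-motif records.
#'
#' @param transcripts Tibble with columns `transcript_id`, `gene_id`, `kind`
#'   (`"pre"` or `"mature"`), `class` (`"mRNA"` or `"lncRNA"`), `sequence`.
#' @param genes Gene-model tibble (see [read_gene_models()]) used to place
#'   each TFO on the genome and to label it `exon` / `intron` / `junction`.
#' @param min_len Minimum TFO length (default 20 bases).
#' @param error_rate Optional mismatch tolerance: a run may contain interior
#'   non-motif bases provided every window of 20 bases contains at most
#'   `floor(20 * error_rate)` of them and the run ends on motif bases.
#'   Default 0 (strict compliance with the motif alphabet).
#' @return Tibble of TFO records: `tfo_id`, `run_id`, `transcript_id`,
#'   `gene_id`, `source_class`, `motif`, `multi_motif`, `t_start`, `t_end`
#'   (transcript coordinates, 0-based half-open), `g_chrom`, `g_start`,
#'   `g_end` (genomic span), `g_blocks` (list-column of genomic blocks, >1
#'   block only for mature TFOs spanning exon junctions), `region`,
#'   `sequence`.
#' @export
detect_tfos <- function(transcripts, genes, min_len = 20L, error_rate = 0) {
  transcripts <- dplyr::mutate(transcripts, sequence = normalize_dna(.data$sequence, .data$transcript_id))
  gene_idx <- match(transcripts$gene_id, genes$gene_id)
  if (anyNA(gene_idx)) abort("Transcript references a gene absent from the gene models.")

  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    gene <- genes[gene_idx[i], ]
    tx_exons <- if (tr$kind == "pre") pre_exons_tx_space(gene) else NULL
    for (motif in names(MOTIF_ALPHABETS)) {
      runs <- find_tolerant_runs(tr$sequence, MOTIF_ALPHABETS[[motif]],
                                 min_len = min_len, error_rate = error_rate)
      if (nrow(runs) == 0L) next
      for (j in seq_len(nrow(runs))) {
        a <- runs$start[j]; b <- runs$end[j]
        blocks <- transcript_to_genome(gene, a, b, tr$kind)
        region <- if (tr$kind == "pre") region_label_pre(tx_exons, a, b) else "exon"
        rows[[length(rows) + 1L]] <- tibble(
          transcript_id = tr$transcript_id,
          gene_id = tr$gene_id,
          source_class = source_class_of(tr$kind, tr$class),
          motif = motif,
          t_start = a, t_end = b,
          g_chrom = blocks$chrom[1],
          g_start = min(blocks$start), g_end = max(blocks$end),
          g_blocks = list(blocks),
          region = region,
          sequence = substr(tr$sequence, a + 1L, b)
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(
      tfo_id = character(), run_id = character(), transcript_id = character(),
      gene_id = character(), source_class = character(), motif = character(),
      multi_motif = logical(), t_start = integer(), t_end = integer(),
      g_chrom = character(), g_start = integer(), g_end = integer(),
      g_blocks = list(), region = character(), sequence = character()
    ))
  }
  out <- bind_rows(rows) %>%
    mutate(run_id = paste(.data$transcript_id, .data$t_start, .data$t_end, sep = ":")) %>%
    group_by(.data$run_id) %>%
    mutate(multi_motif = dplyr::n() > 1L) %>%
    ungroup() %>%
    arrange(.data$transcript_id, .data$t_start, .data$motif) %>%
    mutate(tfo_id = new_id("tfo", dplyr::n(), width = 5L)) %>%
    select("tfo_id", "run_id", "transcript_id", "gene_id", "source_class",
           "motif", "multi_motif", "t_start", "t_end", "g_chrom", "g_start",
           "g_end", "g_blocks", "region", "sequence")
  out
}

#' Detect triplex-target sites (TTSs) on duplex DNA
#'
#' A TTS is a maximal homopurine:homopyrimidine tract of at least `min_len`
#' base pairs: a maximal run over `{A,G}` on the plus strand is reported with
#' purine strand `+`, and a maximal run over `{C,T}` with purine strand `-`
#' (its purine-strand sequence is the reverse complement of the plus-strand
#' substring). The two interval sets can never overlap.
#'
#' @param genome Named character vector of chromosome sequences (see
#'   [read_fasta()]).
#' @param genes Optional gene-model tibble; when supplied each TTS is
#'   labelled `intergenic` / `exon` / `intron` via [classify_location()].
#' @param min_len Minimum tract length (default 20 base pairs).
#' @param error_rate Optional windowed mismatch tolerance, as in
#'   [detect_tfos()].
#' @return Tibble of TTS records: `tts_id`, `chrom`, `start`, `end`
#'   (plus-strand, 0-based half-open), `purine_strand`, `seq` (purine strand,
#'   5'->3'), and `location` / `gene_id` when `genes` is given.
#' @export
detect_tts <- function(genome, genes = NULL, min_len = 20L, error_rate = 0) {
  genome <- normalize_dna(genome, id = names(genome) %||% "genome")
  per_chrom <- purrr::map_dfr(names(genome), function(chrom) {
    s <- genome[[chrom]]
    pur <- find_tolerant_runs(s, c("A", "G"), min_len, error_rate)
    pyr <- find_tolerant_runs(s, c("C", "T"), min_len, error_rate)
    sub_seq <- function(runs) {
      if (nrow(runs) == 0L) character() else substring(s, runs$start + 1L, runs$end)
    }
    bind_rows(
      mutate(pur, chrom = chrom, purine_strand = "+", seq = sub_seq(pur)),
      mutate(pyr, chrom = chrom, purine_strand = "-", seq = revcomp(sub_seq(pyr)))
    )
  })
  if (nrow(per_chrom) == 0L) {
    per_chrom <- tibble(chrom = character(), start = integer(), end = integer(),
                        purine_strand = character(), seq = character())
  }
  out <- per_chrom %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(tts_id = new_id("tts", dplyr::n(), width = 5L)) %>%
    select("tts_id", "chrom", "start", "end", "purine_strand", "seq")
  if (!is.null(genes)) {
    loc <- classify_location(out, genes)
    out$location <- loc$location
    out$gene_id <- loc$gene_id
  }
  out
}

#' Classify genomic intervals as intergenic, exonic or intronic
#'
#' Assignment is by majority overlap: an interval overlapping no gene is
#' `intergenic`; otherwise it is assigned to the gene with the largest
#' overlap (ties broken by gene id), and within that gene to `exon` or
#' `intron` by the larger overlapping base count, ties going to `exon`.
#'
#' @param records Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes Gene-model tibble.
#' @return Tibble with columns `location` and `gene_id` (NA when
#'   intergenic), row-aligned with `records`.
#' @export
classify_location <- function(records, genes) {
  n <- nrow(records)
  location <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (n == 0L || nrow(genes) == 0L) {
    return(tibble(location = location, gene_id = gene_id))
  }
  rec_gr <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(records$start + 1L, records$end))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(rec_gr, gene_gr)
  if (length(hits) > 0L) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov_w <- GenomicRanges::width(IRanges::pintersect(rec_gr[qh], gene_gr[sh]))
    best <- tibble(rec = qh, gene = sh, w = ov_w, gid = genes$gene_id[sh]) %>%
      arrange(.data$rec, desc(.data$w), .data$gid) %>%
      group_by(.data$rec) %>% slice(1) %>% ungroup()
    # per-record exonic overlap within the chosen gene
    for (k in seq_len(nrow(best))) {
      i <- best$rec[k]
      g <- genes[best$gene[k], ]
      ex <- g$exons[[1]]
      exon_ov <- sum(interval_overlap(records$start[i], records$end[i], ex$start, ex$end))
      intron_ov <- best$w[k] - exon_ov
      location[i] <- if (exon_ov >= intron_ov) "exon" else "intron"
      gene_id[i] <- best$gid[k]
    }
  }
  tibble(location = location, gene_id = gene_id)
}
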