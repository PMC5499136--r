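# Sequence and annotation I/O.
#
# Internal coordinate convention is 0-based half-open everywhere; GFF3 and
# BED conversions happen at this boundary only.  Gene models are tibbles with
# one row per gene and a list-column of exon intervals.

#' Read a FASTA file into a named vector of normalised DNA sequences
#'
#' Sequences are uppercased and U is mapped to T, so RNA FASTA input is
#' accepted transparently. Record order is preserved. Characters outside
#' `{A,C,G,T,N,U}` raise an error naming the record and position.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A named character vector, one element per record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgu"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  if (length(out) == 0L) return(setNames(character(), character()))
  normalize_dna(out, id = names(out))
}

#' Write named sequences to a FASTA file
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features linked by `ID`/`Parent` attributes into
#' a gene-model tibble: one row per gene with columns `gene_id`, `chrom`,
#' `strand`, `start`, `end` (0-based half-open), `class` (`"mRNA"` or
#' `"lncRNA"`, taken from a `class` or `gene_biotype` attribute when present)
#' and a list-column `exons` of sorted, non-overlapping exon intervals in
#' genomic coordinates. Introns are the gaps between consecutive exons (see
#' [gene_introns()]).
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  type <- as.character(meta$type)
  is_gene <- type == "gene"
  is_exon <- type == "exon"

  gene_ids <- as.character(meta$ID[is_gene])
  cls <- rep("mRNA", sum(is_gene))
  for (col in c("class", "gene_biotype", "biotype")) {
    if (col %in% names(meta)) {
      v <- as.character(meta[[col]][is_gene])
      cls <- ifelse(is.na(v), cls, v)
      break
    }
  }
  genes <- tibble(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    class = cls
  )
  if (anyDuplicated(genes$gene_id)) abort("Duplicate gene IDs in GFF3.")

  parent <- meta$Parent[is_exon]
  parent <- vapply(as.list(parent), function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  exons <- tibble(
    gene_id = parent,
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon]
  )
  orphan <- setdiff(exons$gene_id, genes$gene_id)
  if (length(orphan) > 0 || anyNA(exons$gene_id)) {
    abort(sprintf(
      "Exon(s) without a parent gene feature: %s",
      paste(head(stats::na.omit(c(orphan, if (anyNA(exons$gene_id)) "<missing Parent>")), 5), collapse = ", ")
    ))
  }
  build_gene_models(genes, exons)
}

# Assemble and validate a gene-model tibble from flat gene and exon tables.
build_gene_models <- function(genes, exons) {
  exon_list <- split(exons[c("start", "end")], exons$gene_id)
  genes$exons <- lapply(genes$gene_id, function(g) {
    ex <- exon_list[[g]]
    if (is.null(ex) || nrow(ex) == 0L) {
      abort(sprintf("Gene %s has no exons.", g))
    }
    ex <- dplyr::arrange(as_tibble(ex), .data$start)
    if (any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(sprintf("Overlapping exons within gene %s.", g))
    }
    ex
  })
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (min(ex$start) < genes$start[i] || max(ex$end) > genes$end[i]) {
      abort(sprintf("Exons of gene %s extend outside the gene span.", genes$gene_id[i]))
    }
  }
  as_tibble(genes)
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gene_models()]; internal 0-based half-open coordinates
#' are emitted as standard 1-based closed GFF3, with a `class` attribute on
#' gene features.
#'
#' @param genes A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf(
      "%s\ttriplexmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s;class=%s",
      g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$class
    ))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\ttriplexmap\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        g$chrom, ex$start[j] + 1L, ex$end[j], g$strand, g$gene_id, j, g$gene_id
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive introns from gene models
#'
#' Introns are the gaps between consecutive exons; exons and introns together
#' tile the gene span.
#'
#' @param genes A gene-model tibble.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_introns <- function(genes) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    if (nrow(ex) < 2L) {
      return(tibble(gene_id = character(), chrom = character(),
                    start = integer(), end = integer()))
    }
    tibble(
      gene_id = genes$gene_id[i],
      chrom = genes$chrom[i],
      start = ex$end[-nrow(ex)],
      end = ex$start[-1]
    )
  })
}

#' Map a transcript interval to genomic coordinates
#'
#' For pre-RNAs (unspliced) the transcript is the gene span read on the
#' coding strand, so an interval maps to a single genomic interval, reversed
#' for minus-strand genes. For mature transcripts (exon concatenation in
#' strand order) an interval may split across exon junctions into several
#' genomic blocks.
#'
#' @param gene One row of a gene-model tibble.
#' @param start,end Transcript interval, 0-based half-open.
#' @param kind `"pre"` or `"mature"`.
#' @return A tibble of genomic blocks (`chrom`, `start`, `end`), sorted by
#'   genomic position; block lengths sum to `end - start`.
#' @export
transcript_to_genome <- function(gene, start, end, kind = c("pre", "mature")) {
  kind <- match.arg(kind)
  if (start < 0L || end < start) abort("Invalid transcript interval.")
  tx_len <- if (kind == "pre") gene$end - gene$start else sum(gene$exons[[1]]$end - gene$exons[[1]]$start)
  if (end > tx_len) {
    abort(sprintf("Transcript interval [%d,%d) out of bounds (length %d).", start, end, tx_len))
  }
  if (kind == "pre") {
    if (gene$strand == "+") {
      gs <- gene$start + start; ge <- gene$start + end
    } else {
      gs <- gene$end - end; ge <- gene$end - start
    }
    blocks <- tibble(start = gs, end = ge)
  } else {
    ex <- gene$exons[[1]]
    if (gene$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
    lens <- ex$end - ex$start
    cs <- cumsum(c(0L, lens))
    blocks <- purrr::map_dfr(seq_len(nrow(ex)), function(i) {
      oa <- max(start, cs[i]); ob <- min(end, cs[i + 1])
      if (oa >= ob) return(empty_interval_tbl())
      if (gene$strand == "+") {
        tibble(start = ex$start[i] + (oa - cs[i]), end = ex$start[i] + (ob - cs[i]))
      } else {
        tibble(start = ex$end[i] - (ob - cs[i]), end = ex$end[i] - (oa - cs[i]))
      }
    })
  }
  dplyr::arrange(
    tibble(chrom = gene$chrom, start = as.integer(blocks$start), end = as.integer(blocks$end)),
    .data$start
  )
}

#' Write genomic records to a BED6 file
#'
#' @param records Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   an id column (`name_col`), and optionally `strand`.
#' @param path Output path.
#' @param name_col Column used for the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path, name_col = "id") {
  strand <- if ("strand" %in% names(records)) records$strand else rep(".", nrow(records))
  strand <- ifelse(strand %in% c("+", "-"), strand, ".")
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s",
    records$chrom, records$start, records$end,
    records[[name_col]], records$end - records$start, strand
  )
  writeLines(lines, path)
  invisible(path)
}
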