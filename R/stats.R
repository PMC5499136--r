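# Genomic distribution statistics: localization tables, chromosome binning,
# density baseline, per-gene / per-transcript summaries and the
# cumulative-share selection of triplex-enriched genes and transcripts.

#' Localization table for genomic records
#'
#' Assigns each record one category via [classify_location()] and tabulates
#' counts and percentages for the rows `genome` (all records), `genes`
#' (exon + intron assigned), `introns` and `exons`.
#'
#' @param records Tibble with `chrom`, `start`, `end`.
#' @param genes Gene-model tibble.
#' @return Tibble with columns `category`, `count`, `percent`.
#' @export
localization_table <- function(records, genes) {
  n <- nrow(records)
  loc <- if (n > 0) classify_location(records, genes)$location else character()
  counts <- c(
    genome = n,
    genes = sum(loc != "intergenic"),
    introns = sum(loc == "intron"),
    exons = sum(loc == "exon")
  )
  tibble(
    category = names(counts),
    count = unname(as.integer(counts)),
    percent = if (n > 0) unname(100 * counts / n) else rep(0, length(counts))
  )
}

#' Count triplex sites in fixed-size chromosome bins
#'
#' Each site is assigned to the bin containing its interval midpoint (sites
#' are short relative to the bin size, so midpoint assignment avoids double
#' counting); bin counts conserve the total.
#'
#' @param sites Tibble with `chrom`, `start`, `end`.
#' @param bin_size Bin width in bases (default 200 kb).
#' @return Tibble with `chrom`, `bin` (0-based index; bin start is
#'   `bin * bin_size`), `count`, restricted to non-empty bins.
#' @export
bin_triplexes <- function(sites, bin_size = 200000L) {
  if (bin_size <= 0) abort("`bin_size` must be positive.")
  if (nrow(sites) == 0L) {
    return(tibble(chrom = character(), bin = integer(), count = integer()))
  }
  sites %>%
    mutate(bin = as.integer(((.data$start + .data$end) %/% 2L) %/% bin_size)) %>%
    count(.data$chrom, .data$bin, name = "count") %>%
    arrange(.data$chrom, .data$bin)
}

#' Pooled match-density baseline
#'
#' The baseline is the pooled number of TFO:TTS matches per 1000 bases of
#' gene sequence: matches assigned to a gene (default, `scope = "genic"`) or
#' all matches (`scope = "all"`) divided by the summed gene lengths.
#'
#' @param matches Match tibble with genomic target intervals.
#' @param genes Gene-model tibble.
#' @param scope `"genic"` or `"all"` (which matches enter the numerator).
#' @return A one-row tibble: `total_matches`, `total_gene_length`,
#'   `baseline` (matches per 1000 bases).
#' @export
density_baseline <- function(matches, genes, scope = c("genic", "all")) {
  scope <- match.arg(scope)
  total_len <- sum(genes$end - genes$start)
  if (total_len <= 0) abort("Total gene length is zero.")
  n_matches <- if (scope == "all" || nrow(matches) == 0L) {
    nrow(matches)
  } else {
    sum(classify_location(matches, genes)$location != "intergenic")
  }
  tibble(
    total_matches = as.integer(n_matches),
    total_gene_length = as.integer(total_len),
    baseline = 1000 * n_matches / total_len
  )
}

# Shared ranking/selection machinery for genes and transcripts: rank units
# by match count (or density), accumulate shares, take the minimal prefix
# reaching `cumulative_fraction`, then keep units above the density baseline.
rank_and_share <- function(units, rank_by = c("count", "density")) {
  rank_by <- match.arg(rank_by)
  units <- units %>%
    mutate(density = 1000 * .data$count / .data$length)
  if (rank_by == "count") {
    units <- arrange(units, desc(.data$count), desc(.data$density), .data$id)
  } else {
    units <- arrange(units, desc(.data$density), desc(.data$count), .data$id)
  }
  total <- sum(units$count)
  mutate(units, cumulative_share = if (total > 0) cumsum(.data$count) / total else 0)
}

select_above_baseline <- function(ranked, baseline, cumulative_fraction) {
  assert_fraction(cumulative_fraction, "cumulative_fraction")
  if (nrow(ranked) == 0L) return(character())
  reach <- which(ranked$cumulative_share >= cumulative_fraction)
  prefix_n <- if (length(reach) > 0) reach[1] else nrow(ranked)
  prefix <- ranked[seq_len(prefix_n), ]
  prefix$id[prefix$density > baseline]
}

#' Per-gene triplex summary
#'
#' Counts matches assigned to each gene (majority-overlap assignment via
#' [classify_location()]), computes the length-normalised density (matches
#' per 1000 bases) and the cumulative share of matches accounted for by
#' genes ranked at or above each gene.
#'
#' @param matches Match tibble.
#' @param genes Gene-model tibble.
#' @param rank_by Rank genes by raw `"count"` (default) or by `"density"`.
#' @return Tibble ordered by rank: `gene_id`, `length`, `count`, `density`,
#'   `cumulative_share`.
#' @export
gene_triplex_summary <- function(matches, genes, rank_by = "count") {
  assigned <- if (nrow(matches) > 0) classify_location(matches, genes)$gene_id else character()
  counts <- table(factor(assigned[!is.na(assigned)], levels = genes$gene_id))
  units <- tibble(
    id = genes$gene_id,
    length = genes$end - genes$start,
    count = as.integer(counts[genes$gene_id])
  )
  rank_and_share(units, rank_by) %>%
    rename(gene_id = "id")
}

#' Select triplex-enriched genes
#'
#' Implements the two-filter selection: rank genes, take the minimal prefix
#' that accounts for at least `cumulative_fraction` of all gene-assigned
#' matches, and within that prefix keep the genes whose match density
#' exceeds the pooled baseline.
#'
#' @param summaries Output of [gene_triplex_summary()].
#' @param baseline Baseline density (matches per 1000 bases), e.g.
#'   `density_baseline(...)$baseline`.
#' @param cumulative_fraction Share of matches the prefix must reach
#'   (default 0.75).
#' @return Character vector of selected gene ids (in ranking order).
#' @export
select_enriched <- function(summaries, baseline, cumulative_fraction = 0.75) {
  ranked <- rename(summaries, id = "gene_id")
  select_above_baseline(ranked, baseline, cumulative_fraction)
}

#' Select transcripts contributing to triplex formation
#'
#' As [select_enriched()], with matches grouped by their source transcript
#' and densities normalised by transcript length.
#'
#' @param matches Match tibble (must carry `transcript_id`).
#' @param transcripts Transcript tibble with `transcript_id` and `sequence`
#'   (or a `length` column).
#' @param baseline Baseline density (matches per 1000 bases).
#' @param cumulative_fraction Share of matches the prefix must reach.
#' @param rank_by Rank by `"count"` (default) or `"density"`.
#' @return Character vector of selected transcript ids.
#' @export
select_contributing_transcripts <- function(matches, transcripts, baseline,
                                            cumulative_fraction = 0.75,
                                            rank_by = "count") {
  lens <- if ("length" %in% names(transcripts)) {
    transcripts$length
  } else {
    nchar(transcripts$sequence)
  }
  counts <- table(factor(matches$transcript_id, levels = transcripts$transcript_id))
  units <- tibble(
    id = transcripts$transcript_id,
    length = lens,
    count = as.integer(counts[transcripts$transcript_id])
  )
  ranked <- rank_and_share(units, rank_by)
  select_above_baseline(ranked, baseline, cumulative_fraction)
}
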