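# Localization tables, binning, density baseline and enriched-gene /
# transcript selection.

two_exon_gene <- function(gene_id = "g1", chrom = "chr1", start = 0L, end = 1000L) {
  third <- (end - start) %/% 3L
  ex_start <- c(start, start + 2L * third)
  ex_end <- c(start + third, end)
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = "+", start = start, end = end,
    class = "mRNA",
    exons = list(tibble::tibble(start = ex_start, end = ex_end))
  )
}

test_that("localization table tabulates categories and percentages", {
  genes <- two_exon_gene() # exons [0,333) [666,1000), intron [333,666)
  recs <- tibble::tibble(chrom = "chr1", start = c(400L, 450L, 500L),
                         end = c(420L, 470L, 520L))
  tab <- localization_table(recs, genes)
  expect_equal(tab$count[tab$category == "genome"], 3L)
  expect_equal(tab$count[tab$category == "introns"], 3L)
  expect_equal(tab$percent[tab$category == "introns"], 100)
  expect_equal(tab$count[tab$category == "exons"], 0L)

  empty <- localization_table(recs[0, ], genes)
  expect_true(all(empty$count == 0L))
  expect_true(all(empty$percent == 0))
})

test_that("localization matches a planted 60/30/10 style design", {
  genes <- two_exon_gene(end = 3000L) # exons [0,1000) [2000,3000), intron [1000,2000)
  mk <- function(n, lo, hi) {
    tibble::tibble(chrom = "chr1", start = seq(lo, hi, length.out = n))
  }
  recs <- dplyr::bind_rows(
    dplyr::mutate(mk(6, 1100, 1800), end = start + 20),  # introns
    dplyr::mutate(mk(3, 100, 800), end = start + 20),    # exons
    dplyr::mutate(mk(1, 5000, 5000), end = start + 20)   # intergenic
  )
  recs$start <- as.integer(recs$start); recs$end <- as.integer(recs$end)
  tab <- localization_table(recs, genes)
  expect_equal(tab$count, c(10L, 9L, 6L, 3L))
  expect_equal(tab$percent, c(100, 90, 60, 30))
})

test_that("binning assigns sites to midpoint bins and conserves totals", {
  s <- tibble::tibble(chrom = "chr1", start = 249990L, end = 250010L)
  b <- bin_triplexes(s, 200000L)
  expect_equal(b$bin, 1L)

  expect_equal(nrow(bin_triplexes(s[0, ], 200000L)), 0L)

  withr::local_seed(12)
  many <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    start = sample.int(5000000L, 1000)
  )
  many$end <- many$start + 30L
  b2 <- bin_triplexes(many, 200000L)
  expect_equal(sum(b2$count), 1000L)
  expect_error(bin_triplexes(many, 0), "positive")
})

test_that("density baseline pools counts over summed gene lengths", {
  g1 <- two_exon_gene("g1", end = 1000L)
  in_gene <- function(n, gene_start) tibble::tibble(
    chrom = "chr1", start = gene_start + seq_len(n) * 30L,
    end = gene_start + seq_len(n) * 30L + 20L,
    transcript_id = "t1"
  )
  b1 <- density_baseline(in_gene(5, 0L), g1)
  expect_equal(b1$baseline, 5.0)

  # two genes of 1000 and 3000 bases with 10 matches each: pooled, not
  # averaged -> 20 matches / 4000 bases = 5.0 per kb
  genes <- dplyr::bind_rows(g1, two_exon_gene("g2", start = 5000L, end = 8000L))
  matches <- dplyr::bind_rows(in_gene(10, 0L), in_gene(10, 5000L))
  b2 <- density_baseline(matches, genes)
  expect_equal(b2$baseline, 5.0)
  expect_equal(b2$total_matches, 20L)
  expect_equal(b2$total_gene_length, 4000L)

  # genic scope drops intergenic matches from the numerator; "all" keeps them
  with_intergenic <- dplyr::bind_rows(
    matches, tibble::tibble(chrom = "chr1", start = 20000L, end = 20020L,
                            transcript_id = "t1")
  )
  expect_equal(density_baseline(with_intergenic, genes, "genic")$total_matches, 20L)
  expect_equal(density_baseline(with_intergenic, genes, "all")$total_matches, 21L)

  expect_error(density_baseline(matches, genes[0, ]), "zero")
})

test_that("gene summaries rank, accumulate shares and respect invariants", {
  genes <- dplyr::bind_rows(
    two_exon_gene("g1", end = 1000L),
    two_exon_gene("g2", start = 2000L, end = 3000L),
    two_exon_gene("g3", start = 4000L, end = 6000L)
  )
  matches <- tibble::tibble(
    chrom = "chr1",
    start = c(rep(100L, 6), rep(2100L, 3), rep(4100L, 1)),
    end = c(rep(120L, 6), rep(2120L, 3), rep(4120L, 1))
  )
  s <- gene_triplex_summary(matches, genes)
  expect_equal(s$gene_id, c("g1", "g2", "g3"))
  expect_equal(s$count, c(6L, 3L, 1L))
  expect_equal(s$density, c(6, 3, 0.5))
  expect_equal(s$cumulative_share, c(0.6, 0.9, 1.0))
  expect_true(all(diff(s$cumulative_share) >= 0))
})

test_that("selection equals exhaustive prefix evaluation on a 10-gene toy", {
  withr::local_seed(77)
  for (case in 1:25) {
    ids <- sprintf("g%02d", 1:10)
    counts <- sample(0:50, 10, replace = TRUE)
    lengths <- sample(500:5000, 10)
    baseline <- 1000 * sum(counts) / sum(lengths)
    frac <- sample(c(0.5, 0.75, 0.9), 1)
    summaries <- gene_triplex_summary_from_counts(ids, counts, lengths)
    got <- select_enriched(summaries, baseline, frac)
    want <- oracle_select(ids, counts, lengths, baseline, frac)
    expect_equal(got, want)
  }
})

test_that("a top gene below the baseline density is excluded", {
  # one very long gene holds 80% of matches but is density-poor
  summaries <- gene_triplex_summary_from_counts(
    c("big", "small"), c(80L, 20L), c(100000L, 500L)
  )
  baseline <- 1000 * 100 / 100500
  sel <- select_enriched(summaries, baseline, 0.75)
  expect_equal(sel, character())

  # a single gene holding everything with density above baseline is selected
  one <- gene_triplex_summary_from_counts("only", 10L, 1000L)
  expect_equal(select_enriched(one, 5, 0.75), "only")
})

test_that("raising the cumulative fraction never shrinks the prefix", {
  withr::local_seed(88)
  ids <- sprintf("g%02d", 1:12)
  counts <- sample(1:40, 12, replace = TRUE)
  lengths <- sample(500:3000, 12)
  summaries <- gene_triplex_summary_from_counts(ids, counts, lengths)
  prefix_size <- function(frac) {
    reach <- which(summaries$cumulative_share >= frac)
    if (length(reach)) reach[1] else nrow(summaries)
  }
  sizes <- vapply(seq(0.1, 1, by = 0.1), prefix_size, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("transcript selection mirrors gene selection with transcript lengths", {
  transcripts <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    sequence = c(strrep("A", 1000), strrep("A", 1000), strrep("A", 4000))
  )
  matches <- tibble::tibble(transcript_id = c(rep("t1", 8), rep("t3", 2)))
  sel <- select_contributing_transcripts(matches, transcripts, baseline = 1,
                                         cumulative_fraction = 0.75)
  expect_equal(sel, "t1")
  # transcripts with zero matches are never selected
  expect_false("t2" %in% sel)

  # single contributing transcript above baseline -> selected
  sel2 <- select_contributing_transcripts(
    tibble::tibble(transcript_id = rep("t2", 5)), transcripts,
    baseline = 1, cumulative_fraction = 0.75
  )
  expect_equal(sel2, "t2")
})
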