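# Target-signature derivation, exhaustive matching, self-match removal, and
# overlap merging.

mk_tfo <- function(sequence, motif, id = "tfo1", chrom = "chr1",
                   g_start = 0L, class = "pre-mRNA") {
  tibble::tibble(
    tfo_id = id, run_id = id, transcript_id = "t1", gene_id = "g1",
    source_class = class, motif = motif, multi_motif = FALSE,
    t_start = 0L, t_end = nchar(sequence),
    g_chrom = chrom, g_start = g_start, g_end = g_start + nchar(sequence),
    g_blocks = list(tibble::tibble(chrom = chrom, start = g_start,
                                   end = g_start + nchar(sequence))),
    region = "exon", sequence = sequence
  )
}

mk_tts <- function(seq, id = "tts1", chrom = "chr1", start = 5000L,
                   purine_strand = "+") {
  tibble::tibble(tts_id = id, chrom = chrom, start = start,
                 end = start + nchar(seq), purine_strand = purine_strand,
                 seq = seq)
}

test_that("signature derivation follows the Hoogsteen triad rules", {
  tc <- tfo_target_signatures(mk_tfo(paste0(strrep("T", 10), strrep("C", 10)), "TC"))
  expect_equal(tc$orientation, "parallel")
  expect_equal(tc$signature, paste0(strrep("A", 10), strrep("G", 10)))

  ga <- tfo_target_signatures(mk_tfo(paste0(strrep("G", 10), strrep("A", 10)), "GA"))
  expect_equal(ga$orientation, "antiparallel")
  expect_equal(ga$signature, paste0(strrep("A", 10), strrep("G", 10)))

  gt <- tfo_target_signatures(mk_tfo(paste0(strrep("G", 10), strrep("T", 10)), "GT"))
  expect_equal(sort(gt$orientation), c("antiparallel", "parallel"))
  expect_equal(gt$signature[gt$orientation == "parallel"],
               paste0(strrep("G", 10), strrep("A", 10)))
  expect_equal(gt$signature[gt$orientation == "antiparallel"],
               paste0(strrep("A", 10), strrep("G", 10)))

  # palindromic pure-G GT runs collapse to one signature, orientation both
  gg <- tfo_target_signatures(mk_tfo(strrep("G", 20), "GT"))
  expect_equal(gg$orientation, "both")

  expect_error(tfo_target_signatures(mk_tfo("GATCGATCGATCGATCGATC", "GA")),
               "outside the GA motif alphabet")
})

test_that("identical signature and target give one full-length match", {
  tfo <- mk_tfo(strrep("GA", 10), "GA", g_start = 0L)
  sig <- tfo_target_signatures(tfo)
  tts <- mk_tts(sig$signature, start = 5000L)
  m <- enumerate_matches(sig, tts, 20)
  expect_equal(nrow(m), 1L)
  expect_equal(m$length, 20L)
  expect_equal(c(m$tfo_offset, m$tts_offset), c(0L, 0L))
  expect_equal(c(m$start, m$end), c(5000L, 5020L))
})

test_that("shared substrings below the minimum length yield no match", {
  sig <- tibble::tibble(
    tfo_id = "x", orientation = "parallel",
    signature = paste0(strrep("A", 19), strrep("G", 6)), tfo_len = 25L,
    transcript_id = "t1", gene_id = "g1", source_class = "pre-mRNA",
    motif = "TC", g_chrom = "chr9", g_start = 0L, g_end = 25L
  )
  # longest shared substring with the 25-base signature is the 19 A's
  tts <- mk_tts(paste0("G", strrep("A", 19)))
  expect_equal(nrow(enumerate_matches(sig, tts, 20)), 0L)
})

test_that("matching equals the quadratic DP oracle on random purine strings", {
  withr::local_seed(404)
  for (case in 1:60) {
    a <- rand_dna(sample(25:70, 1), c("A", "G"))
    b <- rand_dna(sample(25:70, 1), c("A", "G"))
    k <- sample(c(5L, 8L, 12L), 1)
    got <- triplexmap:::maximal_common_substrings(a, b, k)
    want <- oracle_mcs(a, b, k)
    if (nrow(want) == 0L) {
      expect_true(is.null(got) || nrow(got) == 0L ||
                    all(got[, 3] < k))
    } else {
      got <- got[got[, 3] >= k, , drop = FALSE]
      got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
      expect_equal(unname(got[, 1]), want$a_off)
      expect_equal(unname(got[, 2]), want$b_off)
      expect_equal(unname(got[, 3]), want$len)
    }
  }
})

test_that("minus-strand targets convert to plus-strand genomic coordinates", {
  tfo <- mk_tfo(strrep("GA", 12), "GA")
  sig <- tfo_target_signatures(tfo)
  # plant the signature inside a longer minus-strand purine tract
  pur <- paste0("GG", sig$signature, "AA")
  tts <- mk_tts(pur, start = 7000L, purine_strand = "-")
  m <- enumerate_matches(sig, tts, 20)
  # the periodic repeat also matches at shifted diagonals (the "simple
  # shift" phenomenon); the full-length match has the exact coordinates
  expect_gte(nrow(m), 1L)
  full <- dplyr::filter(m, length == 24L)
  expect_equal(nrow(full), 1L)
  expect_equal(full$tts_offset, 2L)
  # purine strand is the minus strand: offsets count from the tract 3' end
  expect_equal(c(full$start, full$end), c(7000L + 28L - 2L - 24L, 7000L + 28L - 2L))
})

test_that("GT dual-orientation duplicates collapse to orientation 'both'", {
  # a fully mirror-symmetric GT run has identical signatures (one row,
  # orientation both); a mirror core inside an asymmetric run makes the two
  # distinct signatures hit the same genomic window, exercising the dedup
  core <- "GTGTGTGTGTGTGTGTGTGTG" # mirror-symmetric, 21 bases
  whole <- tfo_target_signatures(mk_tfo(core, "GT"))
  expect_equal(whole$orientation, "both")

  s <- paste0("TT", core, "GG")
  sig <- tfo_target_signatures(mk_tfo(s, "GT"))
  expect_equal(nrow(sig), 2L)
  tts <- mk_tts(chartr("T", "A", core), start = 9000L)
  m <- enumerate_matches(sig, tts, 20)
  full <- dplyr::filter(m, length == nchar(core))
  expect_equal(nrow(full), 1L)
  expect_equal(full$orientation, "both")
  expect_equal(c(full$start, full$end), c(9000L, 9021L))
})

test_that("self-matches are removed by overlap and exactness modes", {
  tfo <- mk_tfo(strrep("GA", 10), "GA", g_start = 5000L)
  sig <- tfo_target_signatures(tfo)
  tts_self <- mk_tts(strrep("GA", 10), id = "self", start = 5000L)
  tts_far <- mk_tts(tfo_target_signatures(tfo)$signature, id = "far",
                    chrom = "chr2", start = 100L)
  m <- enumerate_matches(sig, dplyr::bind_rows(tts_self, tts_far), 20)
  # the GA signature is the reverse of the sequence; the self tract matches
  # only if mirror-symmetric, so force the issue with an exact-target pair
  res <- remove_self_matches(m, tfo)
  expect_true(all(res$matches$chrom == "chr2" | res$matches$start != 5000L))

  # identical target interval: removed under both modes
  m_self <- tibble::tibble(
    tfo_id = "tfo1", tts_id = "self", chrom = "chr1",
    start = 5000L, end = 5020L, orientation = "antiparallel",
    tfo_offset = 0L, tts_offset = 0L, length = 20L,
    transcript_id = "t1", gene_id = "g1", source_class = "pre-mRNA", motif = "GA"
  )
  expect_equal(nrow(remove_self_matches(m_self, tfo, "overlap")$matches), 0L)
  expect_equal(nrow(remove_self_matches(m_self, tfo, "exact")$matches), 0L)
  expect_equal(remove_self_matches(m_self, tfo)$dropped_tfo_ids, "tfo1")

  # partial overlap with the source tract: removed only in overlap mode
  m_part <- dplyr::mutate(m_self, start = 5010L, end = 5030L)
  expect_equal(nrow(remove_self_matches(m_part, tfo, "overlap")$matches), 0L)
  expect_equal(nrow(remove_self_matches(m_part, tfo, "exact")$matches), 1L)

  # different chromosome: kept
  m_far <- dplyr::mutate(m_self, chrom = "chr2")
  expect_equal(nrow(remove_self_matches(m_far, tfo, "overlap")$matches), 1L)
})

mk_matches <- function(starts, ends, class = "pre-mRNA", chrom = "chr1") {
  tibble::tibble(
    tfo_id = paste0("tfo", seq_along(starts)), tts_id = "tts1",
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    orientation = "parallel", tfo_offset = 0L, tts_offset = 0L,
    length = as.integer(ends) - as.integer(starts),
    transcript_id = "t1", gene_id = "g1", source_class = class, motif = "TC"
  )
}

test_that("merging respects the strict >10-base overlap threshold", {
  # overlap 11 -> one site spanning the union
  m <- mk_matches(c(0, 14), c(25, 40))
  s <- merge_matches(m, 10)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start, s$end), c(0L, 40L))
  expect_equal(s$n_members, 2L)

  # overlap 10 -> two sites
  m2 <- mk_matches(c(0, 15), c(25, 40))
  expect_equal(nrow(merge_matches(m2, 10)), 2L)
})

test_that("merging is single-linkage and scoped per source class", {
  # chain: a-b overlap 11, b-c overlap 11, a-c disjoint -> one site
  m <- mk_matches(c(0, 14, 28), c(25, 39, 55))
  s <- merge_matches(m, 10)
  expect_equal(nrow(s), 1L)
  expect_equal(sort(unlist(s$tfo_ids)), c("tfo1", "tfo2", "tfo3"))

  # same intervals in different classes stay separate unless scope = global
  m$source_class <- c("pre-lncRNA", "pre-mRNA", "pre-mRNA")
  expect_equal(nrow(merge_matches(m, 10, "class")), 2L)
  expect_equal(nrow(merge_matches(m, 10, "global")), 1L)
})

test_that("merging equals the union-find oracle on random intervals", {
  withr::local_seed(550)
  for (case in 1:10) {
    n <- 120
    starts <- sample(0:2000, n, replace = TRUE)
    lens <- sample(20:60, n, replace = TRUE)
    m <- mk_matches(starts, starts + lens)
    s <- merge_matches(m, 10)
    want <- oracle_merge_partition(starts, starts + lens, 10L)
    expect_equal(nrow(s), length(unique(want)))
    # identical partitions: map each match to its site and compare groupings
    site_of <- integer(n)
    for (k in seq_len(nrow(s))) {
      ids <- as.integer(sub("tfo", "", unlist(s$tfo_ids[k])))
      site_of[ids] <- k
    }
    expect_equal(length(unique(paste(site_of, want))),
                 length(unique(site_of)))
    # conservation: member counts sum to the match count
    expect_equal(sum(s$n_members), n)
  }
})

test_that("merging is idempotent on merged site spans", {
  withr::local_seed(660)
  starts <- sample(0:3000, 200, replace = TRUE)
  m <- mk_matches(starts, starts + sample(20:80, 200, replace = TRUE))
  s1 <- merge_matches(m, 10)
  again <- mk_matches(s1$start, s1$end)
  s2 <- merge_matches(again, 10)
  expect_equal(nrow(s2), nrow(s1))
})
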