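# Synthetic-data generator: determinism, planted truth, validation errors,
# interaction and GO table construction.

test_that("synthetic outputs are pure functions of the spec", {
  spec <- synthetic_spec(n_chromosomes = 2, chrom_length = 30000, n_genes = 4,
                         gene_length = 1500, planted_tts = 4, planted_tfo = 6,
                         seed = 11)
  d1 <- simulate_triplex_data(spec)
  d2 <- simulate_triplex_data(spec)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$tts_truth, d2$tts_truth)
  expect_identical(d1$tfo_truth, d2$tfo_truth)
  expect_identical(d1$transcripts, d2$transcripts)

  # a different seed changes the realisation
  spec2 <- synthetic_spec(n_chromosomes = 2, chrom_length = 30000, n_genes = 4,
                          gene_length = 1500, planted_tts = 4, planted_tfo = 6,
                          seed = 12)
  expect_false(identical(simulate_triplex_data(spec2)$genome, d1$genome))

  # byte-identical files on disk
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_synthetic_fixture(d1, dir1)
  write_synthetic_fixture(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     label = f)
  }
})

test_that("nothing planted means nothing detectable", {
  spec <- synthetic_spec(n_chromosomes = 1, chrom_length = 30000, n_genes = 3,
                         gene_length = 1200, planted_tts = 0, planted_tfo = 0,
                         seed = 21)
  d <- simulate_triplex_data(spec)
  expect_equal(nrow(detect_tts(d$genome)), 0L)
  expect_equal(nrow(detect_tfos(d$transcripts, d$genes)), 0L)
  expect_equal(nrow(d$tts_truth), 0L)
  expect_equal(nrow(d$tfo_truth), 0L)
})

test_that("explicitly planted tracts appear verbatim in genome and truth", {
  tts <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2", "chr2"),
    start = c(100L, 500L, 900L, 200L, 5000L, 9000L, 15000L),
    length = c(20L, 35L, 60L, 24L, 40L, 21L, 55L),
    purine_strand = c("+", "-", "+", "-", "+", "-", "+")
  )
  spec <- synthetic_spec(n_chromosomes = 2, chrom_length = 30000, n_genes = 2,
                         gene_length = 1200, planted_tts = tts, planted_tfo = 0,
                         seed = 31)
  d <- simulate_triplex_data(spec)
  expect_equal(nrow(d$tts_truth), 7L)
  det <- detect_tts(d$genome)
  expect_equal(nrow(det), 7L)
  expect_equal(det$start, d$tts_truth$start)
  expect_equal(det$purine_strand, d$tts_truth$purine_strand)

  # a fixed purine sequence is planted verbatim
  tts2 <- tibble::tibble(chrom = "chr1", start = 1000L, length = 24L,
                         purine_strand = "+", sequence = strrep("AAG", 8))
  spec2 <- synthetic_spec(n_chromosomes = 1, chrom_length = 20000, n_genes = 2,
                          gene_length = 1000, planted_tts = tts2,
                          planted_tfo = 0, seed = 32)
  d2 <- simulate_triplex_data(spec2)
  expect_equal(substr(d2$genome[["chr1"]], 1001, 1024), strrep("AAG", 8))
})

test_that("planted TFO with a declared sequence must respect its motif", {
  tfo <- tibble::tibble(transcript_id = "t001", t_start = 100L, length = 20L,
                        motif = "GA", sequence = "GATCGATCGATCGATCGATC")
  expect_error(
    synthetic_spec(n_chromosomes = 1, chrom_length = 20000, n_genes = 2,
                   gene_length = 1000, planted_tts = 0, planted_tfo = tfo,
                   seed = 1),
    "outside the GA motif alphabet"
  )
})

test_that("invalid plantings are rejected with the feature named", {
  base <- list(n_chromosomes = 1L, chrom_length = 20000L, n_genes = 2L,
               gene_length = 1000L, planted_tts = 0L, seed = 1L)
  oob <- tibble::tibble(transcript_id = "t001", t_start = 995L, length = 20L,
                        motif = "GA")
  expect_error(do.call(synthetic_spec, c(base, list(planted_tfo = oob))),
               "out of transcript bounds")

  short <- tibble::tibble(transcript_id = "t001", t_start = 10L, length = 12L,
                          motif = "GA")
  expect_error(do.call(synthetic_spec, c(base, list(planted_tfo = short))),
               "shorter than 20")

  overlapping <- tibble::tibble(
    transcript_id = c("t001", "t001"), t_start = c(100L, 110L),
    length = c(30L, 30L), motif = c("GA", "GA")
  )
  expect_error(do.call(synthetic_spec, c(base, list(planted_tfo = overlapping))),
               "overlap")

  expect_error(
    synthetic_spec(n_chromosomes = 1, chrom_length = 20000, n_genes = 2,
                   gene_length = 1000, background_run_cap = 25, seed = 1),
    "below the 20-base detection minimum"
  )
})

test_that("background never contains spontaneous detectable runs", {
  # no plantings, several seeds: all four two-letter alphabets stay capped
  for (sd in 1:3) {
    spec <- synthetic_spec(n_chromosomes = 1, chrom_length = 40000, n_genes = 3,
                           gene_length = 1500, planted_tts = 0, planted_tfo = 0,
                           seed = sd)
    d <- simulate_triplex_data(spec)
    for (ab in list(c("A", "G"), c("C", "T"), c("G", "T"), c("A", "C"))) {
      expect_equal(nrow(find_maximal_runs(d$genome[[1]], ab, 20)), 0L)
    }
  }
})

test_that("interaction tables plant exact cliques", {
  # one module of 4 genes, no noise: C(4,2) = 6 edges
  tab <- simulate_interactions(letters[1:6], list(letters[1:4]), seed = 1)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$relation %in% c("suppression", "enhancement")))

  # no modules, no noise: empty table
  expect_equal(nrow(simulate_interactions(letters[1:6], list(), seed = 1)), 0L)

  # noise edges are new unique pairs
  tab2 <- simulate_interactions(letters[1:10], list(letters[1:4]),
                                noise_edges = 5, seed = 2)
  expect_equal(nrow(tab2), 11L)
  expect_equal(anyDuplicated(paste(tab2$gene_a, tab2$gene_b)), 0L)

  # determinism
  expect_identical(tab2, simulate_interactions(letters[1:10], list(letters[1:4]),
                                               noise_edges = 5, seed = 2))

  expect_error(simulate_interactions(letters[1:3], list(c("a", "zz"))),
               "unknown gene ids")
})

test_that("GO tables plant one enriched term", {
  genes <- sprintf("g%02d", 1:40)
  study <- genes[1:5]
  # background rate 0: the enriched term annotates exactly the study genes
  tab <- simulate_go_table(genes, c("T1", "T2"), "T1", study,
                           background_rate = 0, seed = 9)
  expect_setequal(tab$gene[tab$term == "T1"], study)
  expect_equal(sum(tab$term == "T2"), 0L)

  tab2 <- simulate_go_table(genes, c("T1", "T2"), "T1", study,
                            background_rate = 0.2, seed = 9)
  expect_true(all(study %in% tab2$gene[tab2$term == "T1"]))
  expect_identical(tab2, simulate_go_table(genes, c("T1", "T2"), "T1", study,
                                           background_rate = 0.2, seed = 9))

  expect_error(simulate_go_table(genes, "T1", "T9", study), "enriched_term")
  expect_error(simulate_go_table(genes, "T1", "T1", "nope"), "study_genes")
})
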