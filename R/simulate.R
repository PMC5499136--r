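# Synthetic genomes, annotations, transcripts, interaction tables and GO
# tables with planted, fully known triplex structure, so every downstream
# stage can be tested against an exact truth set without external downloads.
#
# Construction guarantees:
#   * background sequence contains no run of length >= 20 over any of the
#     four two-letter alphabets {A,G}, {C,T}, {G,T}, {A,C} outside planted
#     tracts (pre-RNAs are genomic spans, so all three motif alphabets and
#     both duplex tract classes must be capped genome-wide);
#   * planted tracts are flanked by non-extending bases, so detected maximal
#     runs coincide exactly with the truth tables;
#   * GA/TC-motif TFO tracts are genuine homopurine:homopyrimidine duplex
#     tracts and are therefore listed in the TTS truth table too (this is
#     the origin of self-matches);
#   * all outputs are pure functions of the spec (which embeds its seed).

GENOMIC_ALPHABETS <- list(
  AG = c("A", "G"), CT = c("C", "T"), GT = c("G", "T"), AC = c("A", "C")
)

# complementary two-letter class used for run-breaking flanks
FLANK_LETTERS <- list(AG = c("C", "T"), CT = c("G", "A"),
                      GT = c("A", "C"), AC = c("G", "T"))

# random string over a two-letter alphabet with single-letter runs capped
rand_tract <- function(len, letters, max_homo = 8L) {
  x <- sample(letters, len, replace = TRUE)
  run <- 1L
  for (i in 2:len) {
    if (x[i] == x[i - 1L]) run <- run + 1L else run <- 1L
    if (run > max_homo) {
      x[i] <- setdiff(letters, x[i])
      run <- 1L
    }
  }
  paste(x, collapse = "")
}

# mirror-symmetric tract (s[i] == s[len + 1 - i]): the only sequences whose
# Hoogsteen target signature matches their own duplex tract
mirror_tract <- function(len, letters, max_homo = 8L) {
  half <- rand_tract(ceiling(len / 2), letters, max_homo)
  h <- seq_chars(half)
  s <- if (len %% 2 == 0L) c(h, rev(h)) else c(h, rev(h)[-1])
  paste(s, collapse = "")
}

# purine-space target signature used for decoy tracts (parallel for TC/GT,
# antiparallel for GA) — mirrors the derivation in tfo_target_signatures()
primary_signature <- function(motif, s) {
  switch(motif,
    TC = chartr("TC", "AG", s),
    GA = paste(rev(seq_chars(s)), collapse = ""),
    GT = chartr("T", "A", s)
  )
}

# genomic (plus-strand) alphabet key of a motif tract on a gene of `strand`
genomic_alphabet_key <- function(motif, strand) {
  plus <- c(TC = "CT", GA = "AG", GT = "GT")[[motif]]
  if (strand == "+") plus else c(CT = "AG", AG = "CT", GT = "AC")[[plus]]
}

#' Specify a synthetic triplex dataset
#'
#' Defines chromosomes, a deterministic gene layout, and planted TFO and TTS
#' features. Plantings can be given explicitly as tibbles, or as counts, in
#' which case random non-overlapping placements are drawn (seeded). In
#' random mode, a `matched_fraction` of TFOs additionally get a decoy TTS
#' planted in intergenic space whose purine-strand sequence equals the TFO's
#' target signature (so they have a non-self target); the remaining TFOs are
#' planted as mirror-symmetric GA/TC tracts, whose only admissible target is
#' their own duplex locus (self-matches).
#'
#' @param n_chromosomes,chrom_length Number and length (bases) of
#'   chromosomes.
#' @param n_genes Total number of genes, laid out round-robin across
#'   chromosomes, strands alternating.
#' @param gene_length Span of every gene in bases.
#' @param exons_per_gene Exons per gene (equal-sized, introns between).
#' @param lncrna_fraction Fraction of genes classed `lncRNA` (rest `mRNA`).
#' @param planted_tts Either a count, or a tibble with columns `chrom`,
#'   `start`, `length` (>= 20), `purine_strand`, and optionally `sequence`
#'   (the purine-strand sequence 5'->3').
#' @param planted_tfo Either a count, or a tibble with columns
#'   `transcript_id`, `t_start`, `length` (>= 20), `motif`, and optionally
#'   `sequence` and `self_only`.
#' @param tts_length_range,tfo_length_range Length ranges for random
#'   plantings.
#' @param matched_fraction Fraction of random TFOs given a decoy target
#'   (default 0.75; the remaining quarter are self-only).
#' @param genic_target_fraction Fraction of decoy targets planted inside
#'   introns rather than intergenic space (default 0.5). An intronic purine
#'   tract is simultaneously a TTS and a motif run in the host pre-RNA, so
#'   such tracts are added to both truth tables — this is what makes genes
#'   targetable and the density/selection stages non-degenerate.
#' @param background_run_cap Maximum spontaneous two-letter-alphabet run in
#'   background sequence (must stay below 20, the detection minimum).
#' @param seed Integer seed; all outputs are pure functions of the spec.
#' @return A `synthetic_spec` object with resolved plantings and gene
#'   layout.
#' @export
synthetic_spec <- function(n_chromosomes = 2L, chrom_length = 100000L,
                           n_genes = 10L, gene_length = 3000L,
                           exons_per_gene = 3L, lncrna_fraction = 0.2,
                           planted_tts = 10L, planted_tfo = 10L,
                           tts_length_range = c(20L, 60L),
                           tfo_length_range = c(20L, 40L),
                           matched_fraction = 0.75,
                           genic_target_fraction = 0.5,
                           background_run_cap = 19L, seed = 1L) {
  assert_count(n_chromosomes, "n_chromosomes", 1L)
  assert_count(chrom_length, "chrom_length", 1000L)
  assert_count(n_genes, "n_genes", 1L)
  assert_count(exons_per_gene, "exons_per_gene", 1L)
  assert_count(background_run_cap, "background_run_cap", 2L)
  assert_fraction(lncrna_fraction, "lncrna_fraction")
  assert_fraction(matched_fraction, "matched_fraction")
  assert_fraction(genic_target_fraction, "genic_target_fraction")
  if (background_run_cap >= 20L) {
    abort("`background_run_cap` must stay below the 20-base detection minimum.")
  }

  chroms <- tibble(
    chrom = paste0("chr", seq_len(n_chromosomes)),
    length = as.integer(chrom_length)
  )
  genes <- synthetic_gene_layout(n_chromosomes, chrom_length, n_genes,
                                 gene_length, exons_per_gene, lncrna_fraction)
  transcripts_meta <- tibble(
    transcript_id = sub("^g", "t", genes$gene_id),
    gene_id = genes$gene_id,
    kind = "pre",
    class = genes$class,
    length = as.integer(gene_length)
  )

  spec <- structure(
    list(
      chroms = chroms, genes = genes, transcripts_meta = transcripts_meta,
      background_run_cap = as.integer(background_run_cap),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )

  with_seed(seed, {
    spec$planted_tfo <- resolve_planted_tfo(spec, planted_tfo, tfo_length_range,
                                            matched_fraction)
    validate_tfo_plantings(spec)
    spec$planted_tts <- resolve_planted_tts(spec, planted_tts, tts_length_range,
                                            genic_target_fraction)
  })
  validate_plantings(spec)
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec: %d chrom x %d bp, %d genes, %d planted TFOs, %d planted TTS tracts, seed %d>\n",
    nrow(x$chroms), x$chroms$length[1], nrow(x$genes),
    nrow(x$planted_tfo), sum(x$planted_tts$origin == "planted"), x$seed
  ))
  invisible(x)
}

synthetic_gene_layout <- function(n_chromosomes, chrom_length, n_genes,
                                  gene_length, exons_per_gene, lncrna_fraction) {
  per_chrom <- tabulate((seq_len(n_genes) - 1L) %% n_chromosomes + 1L,
                        nbins = n_chromosomes)
  if (any(per_chrom * (gene_length + 200L) > chrom_length)) {
    abort("Chromosomes too short for the requested gene layout.")
  }
  n_lnc <- round(lncrna_fraction * n_genes)
  rows <- list()
  gi <- 0L
  for (c_idx in seq_len(n_chromosomes)) {
    k <- per_chrom[c_idx]
    if (k == 0L) next
    spacing <- chrom_length %/% k
    for (j in seq_len(k)) {
      gi <- gi + 1L
      start <- (j - 1L) * spacing + (spacing - gene_length) %/% 2L
      rows[[gi]] <- tibble(
        gene_id = sprintf("g%03d", gi),
        chrom = paste0("chr", c_idx),
        strand = if (gi %% 2L == 1L) "+" else "-",
        start = as.integer(start),
        end = as.integer(start + gene_length),
        class = if (gi <= n_lnc) "lncRNA" else "mRNA"
      )
    }
  }
  genes <- bind_rows(rows)
  # equal-sized exons with introns between: 2E - 1 alternating segments
  genes$exons <- lapply(seq_len(nrow(genes)), function(i) {
    E <- exons_per_gene
    seg <- (genes$end[i] - genes$start[i]) %/% (2L * E - 1L)
    starts <- genes$start[i] + (seq_len(E) - 1L) * 2L * seg
    ends <- starts + seg
    ends[E] <- genes$end[i]
    tibble(start = as.integer(starts), end = as.integer(ends))
  })
  genes
}

# ---- random placement -------------------------------------------------------

# occupied-interval registry: planted tracts plus a 6-base exclusion margin
registry_conflicts <- function(reg, chrom, start, end, margin = 6L) {
  if (nrow(reg) == 0L) return(FALSE)
  same <- reg$chrom == chrom
  any(same & interval_overlap(start - margin, end + margin, reg$start, reg$end) > 0L)
}

resolve_planted_tfo <- function(spec, planted_tfo, len_range, matched_fraction) {
  if (is.data.frame(planted_tfo)) {
    tfo <- as_tibble(planted_tfo)
    if (!"self_only" %in% names(tfo)) tfo$self_only <- FALSE
    if (!"sequence" %in% names(tfo)) tfo$sequence <- NA_character_
    tfo$has_decoy <- FALSE
    return(tfo)
  }
  n <- planted_tfo
  if (n == 0L) {
    return(tibble(transcript_id = character(), t_start = integer(),
                  length = integer(), motif = character(),
                  self_only = logical(), sequence = character(),
                  has_decoy = logical()))
  }
  n_self <- ceiling((1 - matched_fraction) * n)
  reg <- tibble(chrom = character(), start = integer(), end = integer())
  rows <- list()
  tx_len <- spec$transcripts_meta$length[1]
  for (i in seq_len(n)) {
    self_only <- i > n - n_self
    motif <- if (self_only) sample(c("GA", "TC"), 1) else sample(c("TC", "GA", "GT"), 1)
    len <- sample(len_range[1]:len_range[2], 1)
    placed <- FALSE
    for (try in 1:500) {
      g_idx <- sample(nrow(spec$genes), 1)
      gene <- spec$genes[g_idx, ]
      t_start <- sample(6:(tx_len - len - 6L), 1)
      blocks <- transcript_to_genome(gene, t_start, t_start + len, "pre")
      if (!registry_conflicts(reg, gene$chrom, blocks$start, blocks$end)) {
        reg <- bind_rows(reg, tibble(chrom = gene$chrom,
                                     start = blocks$start, end = blocks$end))
        rows[[i]] <- tibble(
          transcript_id = spec$transcripts_meta$transcript_id[g_idx],
          t_start = as.integer(t_start), length = as.integer(len),
          motif = motif, self_only = self_only,
          sequence = NA_character_, has_decoy = !self_only
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) abort(sprintf("Could not place planted TFO %d without overlap.", i))
  }
  bind_rows(rows)
}

resolve_planted_tts <- function(spec, planted_tts, len_range,
                                genic_target_fraction = 0) {
  explicit <- is.data.frame(planted_tts)
  if (explicit) {
    tts <- as_tibble(planted_tts)
    if (!"sequence" %in% names(tts)) tts$sequence <- NA_character_
    tts$origin <- "planted"
    tts$decoy_for <- NA_integer_
  } else {
    tts <- tibble(chrom = character(), start = integer(), length = integer(),
                  purine_strand = character(), sequence = character(),
                  origin = character(), decoy_for = integer())
  }
  # registry seeded with planted TFO genomic tracts (and explicit TTSs)
  reg <- planted_tfo_genomic(spec)[c("chrom", "start", "end")]
  if (nrow(tts) > 0L) {
    reg <- bind_rows(reg, tibble(chrom = tts$chrom, start = tts$start,
                                 end = tts$start + tts$length))
  }
  intergenic <- intergenic_intervals(spec)
  place_intergenic <- function(len) {
    for (try in 1:500) {
      slot <- intergenic[sample(nrow(intergenic), 1), ]
      if (slot$end - slot$start < len + 16L) next
      start <- slot$start + sample.int(slot$end - slot$start - len - 15L, 1) + 7L
      if (!registry_conflicts(reg, slot$chrom, start, start + len)) {
        reg <<- bind_rows(reg, tibble(chrom = slot$chrom, start = start,
                                      end = start + len))
        return(tibble(chrom = slot$chrom, start = as.integer(start)))
      }
    }
    abort("Could not place a TTS tract without overlap.")
  }
  if (!explicit) {
    n <- planted_tts
    for (i in seq_len(n)) {
      len <- sample(len_range[1]:len_range[2], 1)
      pos <- place_intergenic(len)
      tts <- bind_rows(tts, tibble(
        chrom = pos$chrom, start = pos$start, length = as.integer(len),
        purine_strand = sample(c("+", "-"), 1),
        sequence = NA_character_, origin = "planted", decoy_for = NA_integer_
      ))
    }
  }
  # decoy targets for matched TFOs; a fraction go inside introns (becoming
  # motif runs in the host pre-RNA, added to the TFO truth at realization)
  introns <- gene_introns(spec$genes)
  place_intronic <- function(len) {
    ok <- introns[introns$end - introns$start >= len + 16L, ]
    if (nrow(ok) == 0L) return(NULL)
    for (try in 1:200) {
      slot <- ok[sample(nrow(ok), 1), ]
      start <- slot$start + sample.int(slot$end - slot$start - len - 15L, 1) + 7L
      if (!registry_conflicts(reg, slot$chrom, start, start + len)) {
        reg <<- bind_rows(reg, tibble(chrom = slot$chrom, start = start,
                                      end = start + len))
        return(tibble(chrom = slot$chrom, start = as.integer(start)))
      }
    }
    NULL
  }
  tfo <- spec$planted_tfo
  for (i in which(tfo$has_decoy)) {
    # an intronic decoy is itself a detectable TFO; only GA/TC parents give
    # that derived TFO a guaranteed non-self target (the parent's own tract)
    genic <- tfo$motif[i] %in% c("GA", "TC") &&
      stats::runif(1) < genic_target_fraction
    pos <- if (genic) place_intronic(tfo$length[i]) else NULL
    if (is.null(pos)) pos <- place_intergenic(tfo$length[i])
    tts <- bind_rows(tts, tibble(
      chrom = pos$chrom, start = pos$start, length = tfo$length[i],
      purine_strand = sample(c("+", "-"), 1),
      sequence = NA_character_, origin = "decoy", decoy_for = i
    ))
  }
  tts
}

planted_tfo_genomic <- function(spec) {
  tfo <- spec$planted_tfo
  if (nrow(tfo) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  gi <- match(tfo$transcript_id, spec$transcripts_meta$transcript_id)
  if (anyNA(gi)) {
    abort(sprintf("Planted TFO references unknown transcript '%s'.",
                  tfo$transcript_id[which(is.na(gi))[1]]))
  }
  purrr::map_dfr(seq_len(nrow(tfo)), function(i) {
    gene <- spec$genes[gi[i], ]
    blocks <- transcript_to_genome(gene, tfo$t_start[i],
                                   tfo$t_start[i] + tfo$length[i], "pre")
    tibble(chrom = gene$chrom, start = blocks$start, end = blocks$end,
           strand = gene$strand)
  })
}

intergenic_intervals <- function(spec) {
  purrr::map_dfr(seq_len(nrow(spec$chroms)), function(ci) {
    chrom <- spec$chroms$chrom[ci]
    g <- filter(spec$genes, .data$chrom == !!chrom) %>% arrange(.data$start)
    bounds <- c(0L, rbind(g$start, g$end), spec$chroms$length[ci])
    starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    tibble(chrom = chrom, start = starts, end = ends) %>%
      filter(.data$end - .data$start > 40L)
  })
}

validate_tfo_plantings <- function(spec) {
  tfo <- spec$planted_tfo
  tx_len <- spec$transcripts_meta$length
  names(tx_len) <- spec$transcripts_meta$transcript_id
  for (i in seq_len(nrow(tfo))) {
    if (tfo$length[i] < 20L) {
      abort(sprintf("Planted TFO %d shorter than 20 bases.", i))
    }
    if (!tfo$motif[i] %in% names(MOTIF_ALPHABETS)) {
      abort(sprintf("Planted TFO %d has unknown motif '%s'.", i, tfo$motif[i]))
    }
    L <- tx_len[[tfo$transcript_id[i]]]
    if (is.null(L) || tfo$t_start[i] < 0L || tfo$t_start[i] + tfo$length[i] > L) {
      abort(sprintf("Planted TFO %d out of transcript bounds.", i))
    }
    if (!is.na(tfo$sequence[i])) {
      s <- tfo$sequence[i]
      if (nchar(s) != tfo$length[i]) {
        abort(sprintf("Planted TFO %d sequence length mismatch.", i))
      }
      bad <- setdiff(unique(seq_chars(s)), MOTIF_ALPHABETS[[tfo$motif[i]]])
      if (length(bad) > 0) {
        abort(sprintf("Planted TFO %d sequence contains '%s', outside the %s motif alphabet.",
                      i, bad[1], tfo$motif[i]))
      }
    }
  }
  invisible(spec)
}

validate_plantings <- function(spec) {
  validate_tfo_plantings(spec)
  tts <- spec$planted_tts
  chrom_len <- setNames(spec$chroms$length, spec$chroms$chrom)
  for (i in seq_len(nrow(tts))) {
    if (tts$length[i] < 20L) abort(sprintf("Planted TTS %d shorter than 20 bases.", i))
    if (!tts$chrom[i] %in% names(chrom_len)) {
      abort(sprintf("Planted TTS %d on unknown chromosome '%s'.", i, tts$chrom[i]))
    }
    if (tts$start[i] < 2L || tts$start[i] + tts$length[i] > chrom_len[[tts$chrom[i]]] - 2L) {
      abort(sprintf("Planted TTS %d out of chromosome bounds.", i))
    }
    if (!tts$purine_strand[i] %in% c("+", "-")) {
      abort(sprintf("Planted TTS %d has invalid purine strand.", i))
    }
    # straddling a gene boundary would break exact planted recovery
    straddle <- spec$genes$chrom == tts$chrom[i] &
      interval_overlap(tts$start[i], tts$start[i] + tts$length[i],
                       spec$genes$start, spec$genes$end) > 0L &
      !(spec$genes$start <= tts$start[i] &
          spec$genes$end >= tts$start[i] + tts$length[i])
    if (any(straddle)) {
      abort(sprintf("Planted TTS %d straddles a gene boundary.", i))
    }
    if (!is.na(tts$sequence[i])) {
      bad <- setdiff(unique(seq_chars(tts$sequence[i])), c("A", "G"))
      if (length(bad) > 0) {
        abort(sprintf("Planted TTS %d purine sequence contains '%s'.", i, bad[1]))
      }
    }
  }
  # pairwise overlap check on genomic footprints (4-base flank clearance)
  foot <- bind_rows(
    planted_tfo_genomic(spec)[c("chrom", "start", "end")],
    if (nrow(tts) > 0) tibble(chrom = tts$chrom, start = tts$start,
                              end = tts$start + tts$length)
  )
  if (nrow(foot) > 1L) {
    foot <- arrange(foot, .data$chrom, .data$start)
    same <- foot$chrom[-1] == foot$chrom[-nrow(foot)]
    gap <- foot$start[-1] - foot$end[-nrow(foot)]
    if (any(same & gap < 4L)) {
      j <- which(same & gap < 4L)[1]
      abort(sprintf("Planted features overlap or touch near %s:%d.",
                    foot$chrom[j + 1], foot$start[j + 1]))
    }
  }
  invisible(spec)
}

# ---- realization ------------------------------------------------------------

# Materialise the spec: background + planted tracts + flanks + repair.
realize_synthetic <- function(spec) {
  with_seed(spec$seed + 1L, {
    tfo <- spec$planted_tfo
    tts <- spec$planted_tts

    # tract sequences (transcript space for TFOs, purine strand for TTSs)
    tfo$sequence <- vapply(seq_len(nrow(tfo)), function(i) {
      if (!is.na(tfo$sequence[i])) return(tfo$sequence[i])
      ab <- MOTIF_ALPHABETS[[tfo$motif[i]]]
      if (tfo$self_only[i]) mirror_tract(tfo$length[i], ab) else rand_tract(tfo$length[i], ab)
    }, character(1))
    tts$sequence <- vapply(seq_len(nrow(tts)), function(i) {
      if (!is.na(tts$sequence[i])) return(tts$sequence[i])
      if (tts$origin[i] == "decoy") {
        j <- tts$decoy_for[i]
        primary_signature(tfo$motif[j], tfo$sequence[j])
      } else {
        rand_tract(tts$length[i], c("A", "G"))
      }
    }, character(1))

    # Self-only TFOs must have no admissible target other than their own
    # tract. Over a two-letter alphabet, distinct tracts share 20-mers at
    # an appreciable (birthday-effect) rate, so regenerate each self-only
    # mirror tract until its signature shares no 20-mer with any other
    # tract's purine-strand sequence.
    kmers20 <- function(s, k = 20L) {
      if (nchar(s) < k) return(character())
      substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
    }
    tfo_purine <- vapply(seq_len(nrow(tfo)), function(i) {
      # purine-strand sequence of the TFO's own duplex tract (GA/TC motifs)
      switch(tfo$motif[i], GA = tfo$sequence[i],
             TC = chartr("TC", "AG", tfo$sequence[i]), GT = "")
    }, character(1))
    for (i in which(tfo$self_only)) {
      pool <- unique(unlist(lapply(
        c(tts$sequence, tfo_purine[-i]), kmers20
      )))
      for (try in 1:200) {
        sig <- primary_signature(tfo$motif[i], tfo$sequence[i])
        if (!any(kmers20(sig) %in% pool)) break
        tfo$sequence[i] <- mirror_tract(tfo$length[i],
                                        MOTIF_ALPHABETS[[tfo$motif[i]]])
        if (try == 200L) abort("Internal error: could not isolate a self-only tract.")
      }
      tfo_purine[i] <- switch(tfo$motif[i], GA = tfo$sequence[i],
                              TC = chartr("TC", "AG", tfo$sequence[i]))
    }

    # genomic footprints and plus-strand sequences
    tfo_gen <- planted_tfo_genomic(spec)
    tfo_gen$plus_seq <- as.character(ifelse(tfo_gen$strand == "+",
                                            tfo$sequence, revcomp(tfo$sequence)))
    tfo_gen$alph <- vapply(seq_len(nrow(tfo)), function(i) {
      genomic_alphabet_key(tfo$motif[i], tfo_gen$strand[i])
    }, character(1))
    tts_gen <- tibble(
      chrom = tts$chrom, start = tts$start, end = tts$start + tts$length,
      plus_seq = as.character(ifelse(tts$purine_strand == "+",
                                     tts$sequence, revcomp(tts$sequence))),
      alph = as.character(ifelse(tts$purine_strand == "+", "AG", "CT"))
    )
    tracts <- bind_rows(
      tfo_gen[c("chrom", "start", "end", "plus_seq", "alph")],
      tts_gen
    )

    # background, planting, flanks
    chrom_seqs <- list()
    protected <- list()
    for (ci in seq_len(nrow(spec$chroms))) {
      chrom <- spec$chroms$chrom[ci]
      n <- spec$chroms$length[ci]
      x <- sample(DNA_BASES, n, replace = TRUE)
      prot <- logical(n)
      tr <- filter(tracts, .data$chrom == !!chrom)
      for (k in seq_len(nrow(tr))) {
        s <- tr$start[k]; e <- tr$end[k]
        x[(s + 1L):e] <- seq_chars(tr$plus_seq[k])
        fl <- FLANK_LETTERS[[tr$alph[k]]]
        # immediate flank base breaks the tract alphabet; outer base differs
        x[c(s - 1L, s)] <- c(fl[2], fl[1])
        x[c(e + 1L, e + 2L)] <- c(fl[1], fl[2])
        prot[(s - 1L):(e + 2L)] <- TRUE
      }
      chrom_seqs[[chrom]] <- x
      protected[[chrom]] <- prot
    }

    # repair: break any unexpected >= 20-base two-letter run at an
    # unprotected position until only planted tracts remain detectable
    expected <- tracts %>%
      mutate(key = paste(.data$chrom, .data$alph, .data$start, .data$end))
    for (iter in 1:100) {
      dirty <- FALSE
      for (chrom in names(chrom_seqs)) {
        s <- paste(chrom_seqs[[chrom]], collapse = "")
        for (key in names(GENOMIC_ALPHABETS)) {
          runs <- find_maximal_runs(s, GENOMIC_ALPHABETS[[key]],
                                    min_len = spec$background_run_cap + 1L)
          if (nrow(runs) == 0L) next
          run_keys <- paste(chrom, key, runs$start, runs$end)
          bad <- which(!(run_keys %in% expected$key))
          for (b in bad) {
            dirty <- TRUE
            pos <- (runs$start[b] + 1L):runs$end[b]
            pos <- pos[!protected[[chrom]][pos]]
            if (length(pos) == 0L) {
              abort("Internal error: cannot repair a spontaneous run near a planted tract.")
            }
            p <- pos[ceiling(length(pos) / 2)]
            chrom_seqs[[chrom]][p] <- sample(FLANK_LETTERS[[key]], 1)
          }
        }
      }
      if (!dirty) break
      if (iter == 100L) abort("Internal error: background repair did not converge.")
    }

    genome <- vapply(chrom_seqs, paste, character(1), collapse = "")

    # verify planted tracts are recovered exactly (defensive construction check)
    for (chrom in names(genome)) {
      for (key in c("AG", "CT")) {
        runs <- find_maximal_runs(genome[[chrom]], GENOMIC_ALPHABETS[[key]], 20L)
        want <- filter(expected, .data$chrom == !!chrom, .data$alph == !!key)
        if (!setequal(paste(runs$start, runs$end), paste(want$start, want$end))) {
          abort("Internal error: realized TTS tracts do not match the truth set.")
        }
      }
    }

    # truth tables
    tts_truth <- bind_rows(
      tibble(chrom = tts$chrom, start = tts$start, end = tts$start + tts$length,
             purine_strand = tts$purine_strand, purine_seq = tts$sequence,
             origin = tts$origin),
      {
        sel <- tfo$motif %in% c("GA", "TC")
        tibble(
          chrom = tfo_gen$chrom[sel], start = tfo_gen$start[sel],
          end = tfo_gen$end[sel],
          purine_strand = as.character(ifelse(tfo_gen$alph[sel] == "AG", "+", "-")),
          purine_seq = as.character(ifelse(tfo_gen$alph[sel] == "AG",
                                           tfo_gen$plus_seq[sel],
                                           revcomp(tfo_gen$plus_seq[sel]))),
          origin = "tfo_tract"
        )
      }
    ) %>% arrange(.data$chrom, .data$start)

    gi <- match(tfo$transcript_id, spec$transcripts_meta$transcript_id)
    planted_truth <- tibble(
      transcript_id = tfo$transcript_id,
      gene_id = spec$transcripts_meta$gene_id[gi],
      source_class = source_class_of("pre", spec$transcripts_meta$class[gi]),
      motif = tfo$motif,
      t_start = tfo$t_start, t_end = tfo$t_start + tfo$length,
      g_chrom = tfo_gen$chrom, g_start = tfo_gen$start, g_end = tfo_gen$end,
      region = vapply(seq_len(nrow(tfo)), function(i) {
        region_label_pre(pre_exons_tx_space(spec$genes[gi[i], ]),
                         tfo$t_start[i], tfo$t_start[i] + tfo$length[i])
      }, character(1)),
      sequence = tfo$sequence,
      self_only = tfo$self_only,
      has_decoy = tfo$has_decoy,
      origin = "planted"
    )

    # TTS tracts lying inside a gene span are also motif runs in that
    # gene's pre-RNA, so they belong to the TFO truth table too
    genic_truth <- purrr::map_dfr(seq_len(nrow(tts_gen)), function(k) {
      g <- filter(spec$genes,
                  .data$chrom == tts_gen$chrom[k],
                  .data$start <= tts_gen$start[k],
                  .data$end >= tts_gen$end[k])
      if (nrow(g) == 0L) return(tibble())
      g <- g[1, ]
      if (g$strand == "+") {
        ta <- tts_gen$start[k] - g$start; tb <- tts_gen$end[k] - g$start
        tx_seq <- tts_gen$plus_seq[k]
        motif <- if (tts_gen$alph[k] == "AG") "GA" else "TC"
      } else {
        ta <- g$end - tts_gen$end[k]; tb <- g$end - tts_gen$start[k]
        tx_seq <- revcomp(tts_gen$plus_seq[k])
        motif <- if (tts_gen$alph[k] == "AG") "TC" else "GA"
      }
      ti <- match(g$gene_id, spec$transcripts_meta$gene_id)
      tibble(
        transcript_id = spec$transcripts_meta$transcript_id[ti],
        gene_id = g$gene_id,
        source_class = source_class_of("pre", spec$transcripts_meta$class[ti]),
        motif = motif, t_start = ta, t_end = tb,
        g_chrom = tts_gen$chrom[k], g_start = tts_gen$start[k],
        g_end = tts_gen$end[k],
        region = region_label_pre(pre_exons_tx_space(g), ta, tb),
        sequence = tx_seq, self_only = FALSE, has_decoy = FALSE,
        origin = "target_tract"
      )
    })
    tfo_truth <- bind_rows(planted_truth, genic_truth) %>%
      arrange(.data$transcript_id, .data$t_start)

    transcripts <- spec$transcripts_meta
    transcripts$sequence <- vapply(seq_len(nrow(transcripts)), function(i) {
      gene <- spec$genes[match(transcripts$gene_id[i], spec$genes$gene_id), ]
      s <- substr(genome[[gene$chrom]], gene$start + 1L, gene$end)
      if (gene$strand == "+") s else revcomp(s)
    }, character(1))

    list(genome = genome, genes = spec$genes, transcripts = transcripts,
         tts_truth = tts_truth, tfo_truth = tfo_truth)
  })
}

#' Generate the full synthetic dataset for a spec
#'
#' @param spec A `synthetic_spec`.
#' @return A list: `genome` (named character vector), `genes` (gene-model
#'   tibble), `transcripts` (pre-RNA tibble), `tts_truth` and `tfo_truth`
#'   (truth tables, 0-based half-open coordinates).
#' @export
simulate_triplex_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  realize_synthetic(spec)
}

#' Generate the synthetic genome, annotation and TTS truth table
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `genome`, `genes` and `tts_truth` (every detectable
#'   homopurine:homopyrimidine tract of >= 20 bp with exact coordinates —
#'   planted tracts, decoy targets, and tracts implied by GA/TC TFO
#'   plantings).
#' @export
simulate_genome <- function(spec) {
  r <- simulate_triplex_data(spec)
  r[c("genome", "genes", "tts_truth")]
}

#' Generate the synthetic pre-RNA transcripts and TFO truth table
#'
#' Each pre-RNA equals its gene's genomic span read on the coding strand;
#' planted motifs are the only runs of >= 20 bases over the three motif
#' alphabets.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `transcripts` and `tfo_truth`.
#' @export
simulate_transcripts <- function(spec) {
  r <- simulate_triplex_data(spec)
  r[c("transcripts", "tfo_truth")]
}

#' Generate a synthetic genetic-interaction table with planted modules
#'
#' Every planted module becomes a clique; `noise_edges` additional random
#' edges are added between genes not already connected.
#'
#' @param gene_ids Character vector of gene ids.
#' @param planted_modules List of character vectors (gene subsets).
#' @param noise_edges Number of random extra edges.
#' @param seed Integer seed.
#' @return Tibble with `gene_a`, `gene_b`, `relation`.
#' @export
simulate_interactions <- function(gene_ids, planted_modules = list(),
                                  noise_edges = 0L, seed = 1L) {
  for (m in planted_modules) {
    if (!all(m %in% gene_ids)) abort("Planted module contains unknown gene ids.")
  }
  with_seed(seed, {
    edges <- purrr::map_dfr(planted_modules, function(m) {
      if (length(m) < 2L) return(tibble(gene_a = character(), gene_b = character()))
      cmb <- utils::combn(sort(m), 2L)
      tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
    }) %>% distinct()
    if (noise_edges > 0L) {
      existing <- paste(edges$gene_a, edges$gene_b)
      added <- 0L
      while (added < noise_edges) {
        pair <- sort(sample(gene_ids, 2L))
        key <- paste(pair[1], pair[2])
        if (!key %in% existing) {
          edges <- bind_rows(edges, tibble(gene_a = pair[1], gene_b = pair[2]))
          existing <- c(existing, key)
          added <- added + 1L
        }
      }
    }
    if (nrow(edges) == 0L) {
      return(tibble(gene_a = character(), gene_b = character(),
                    relation = character()))
    }
    edges$relation <- sample(c("suppression", "enhancement"), nrow(edges),
                             replace = TRUE)
    arrange(edges, .data$gene_a, .data$gene_b)
  })
}

#' Generate a synthetic gene-to-GO-term table with one enriched term
#'
#' The enriched term annotates every study gene plus background-rate draws
#' from the remaining genes; all other terms annotate genes at the
#' background rate.
#'
#' @param gene_ids Population gene ids.
#' @param terms Character vector of term ids (must include `enriched_term`).
#' @param enriched_term The term planted as enriched.
#' @param study_genes Genes the enriched term must annotate (subset of
#'   `gene_ids`).
#' @param background_rate Per-gene annotation probability for unplanted
#'   assignments.
#' @param seed Integer seed.
#' @return Tibble with columns `gene`, `term`.
#' @export
simulate_go_table <- function(gene_ids, terms, enriched_term, study_genes,
                              background_rate = 0.05, seed = 1L) {
  if (!all(study_genes %in% gene_ids)) abort("`study_genes` must be drawn from `gene_ids`.")
  if (!enriched_term %in% terms) abort("`enriched_term` must be one of `terms`.")
  assert_fraction(background_rate, "background_rate")
  with_seed(seed, {
    rows <- purrr::map_dfr(terms, function(tm) {
      if (tm == enriched_term) {
        rest <- setdiff(gene_ids, study_genes)
        extra <- rest[stats::runif(length(rest)) < background_rate]
        tibble(gene = c(study_genes, extra), term = tm)
      } else {
        hit <- gene_ids[stats::runif(length(gene_ids)) < background_rate]
        tibble(gene = hit, term = tm)
      }
    })
    arrange(rows, .data$term, .data$gene)
  })
}

#' Write a synthetic dataset to disk as plain-text fixtures
#'
#' Writes the genome FASTA, GFF3 annotation, transcript FASTA, and truth
#' tables as TSV (headers note the 0-based half-open convention).
#'
#' @param data Output of [simulate_triplex_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixture <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(data$genome, file.path(dir, "genome.fa"))
  write_gene_models(data$genes, file.path(dir, "annotation.gff3"))
  write_fasta(setNames(data$transcripts$sequence, data$transcripts$transcript_id),
              file.path(dir, "transcripts.fa"))
  tsv_with_note <- function(x, path) {
    writeLines("# coordinates: 0-based half-open", path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  }
  tsv_with_note(data$tts_truth, file.path(dir, "tts_truth.tsv"))
  tsv_with_note(data$tfo_truth, file.path(dir, "tfo_truth.tsv"))
  readr::write_tsv(select(data$transcripts, -"sequence"),
                   file.path(dir, "transcripts_meta.tsv"))
  invisible(dir)
}
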