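# TFO:TTS matching in purine space: target-signature derivation, exhaustive
# maximal exact-match enumeration (seed-and-extend), self-match removal, and
# overlap merging of matches into triplex sites.

#' Derive purine-space target signatures for TFOs
#'
#' A TFO binds the purine strand of a target duplex; its admissible targets
#' can therefore be written as strings over `{A,G}` read 5'->3' along the
#' purine strand. The derivation follows the Hoogsteen triads: the
#' pyrimidine motif `[TC]` binds parallel (T·A:T, C·G:C, so T->A, C->G, same
#' direction); the purine motif `[GA]` binds antiparallel (G·G:C, A·A:T, so
#' the TFO is reversed with letters unchanged); the `[GT]` motif binds either
#' way (G->G, T->A; both the same-direction and the reversed signature are
#' emitted). When the two `[GT]` signatures coincide (e.g. pure-G runs) they
#' collapse to one row with orientation `"both"`.
#'
#' @param tfos TFO tibble from [detect_tfos()].
#' @return Tibble with one row per (TFO, orientation): `tfo_id`,
#'   `orientation` (`parallel`, `antiparallel` or `both`), `signature`, plus
#'   the TFO's length and carried metadata used downstream.
#' @export
tfo_target_signatures <- function(tfos) {
  sig_one <- function(motif, s) {
    bad <- setdiff(unique(seq_chars(s)), MOTIF_ALPHABETS[[motif]])
    if (length(bad) > 0) {
      abort(sprintf("Letter '%s' outside the %s motif alphabet.", bad[1], motif))
    }
    rev_s <- paste(rev(seq_chars(s)), collapse = "")
    switch(motif,
      TC = tibble(orientation = "parallel", signature = chartr("TC", "AG", s)),
      GA = tibble(orientation = "antiparallel", signature = rev_s),
      GT = tibble(
        orientation = c("parallel", "antiparallel"),
        signature = c(chartr("T", "A", s), chartr("T", "A", rev_s))
      )
    )
  }
  out <- purrr::map_dfr(seq_len(nrow(tfos)), function(i) {
    t <- tfos[i, ]
    sigs <- sig_one(t$motif, t$sequence)
    if (nrow(sigs) == 2L && sigs$signature[1] == sigs$signature[2]) {
      sigs <- tibble(orientation = "both", signature = sigs$signature[1])
    }
    mutate(sigs,
      tfo_id = t$tfo_id, transcript_id = t$transcript_id, gene_id = t$gene_id,
      source_class = t$source_class, motif = t$motif,
      tfo_len = nchar(t$sequence),
      g_chrom = t$g_chrom, g_start = t$g_start, g_end = t$g_end
    )
  })
  if (nrow(out) == 0L) {
    return(tibble(orientation = character(), signature = character(),
                  tfo_id = character(), transcript_id = character(),
                  gene_id = character(), source_class = character(),
                  motif = character(), tfo_len = integer(),
                  g_chrom = character(), g_start = integer(), g_end = integer()))
  }
  select(out, "tfo_id", "orientation", "signature", "tfo_len", "transcript_id",
         "gene_id", "source_class", "motif", "g_chrom", "g_start", "g_end")
}

# All maximal common substrings of length >= k between strings a and b,
# found by k-mer seeding on shared diagonals and outward extension.
# Returns a matrix with columns (a_off, b_off, len), 0-based offsets.
maximal_common_substrings <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(matrix(integer(), ncol = 3))
  bmers <- substring(b, 1:(nb - k + 1L), k:nb)
  amers <- substring(a, 1:(na - k + 1L), k:na)
  idx <- split(seq_along(bmers) - 1L, bmers)
  pos <- match(amers, names(idx))
  hit_i <- which(!is.na(pos))
  if (length(hit_i) == 0L) return(matrix(integer(), ncol = 3))
  ac <- seq_chars(a); bc <- seq_chars(b)
  seen <- character()
  out <- list()
  for (i in hit_i) {
    for (j in idx[[pos[i]]]) {
      key0 <- paste0((i - 1L) - j, "") # diagonal
      # extend seed (i-1, j) to the maximal run on its diagonal
      s_a <- i - 1L; s_b <- j
      while (s_a > 0L && s_b > 0L && ac[s_a] == bc[s_b]) { s_a <- s_a - 1L; s_b <- s_b - 1L }
      e_a <- (i - 1L) + k; e_b <- j + k
      while (e_a < na && e_b < nb && ac[e_a + 1L] == bc[e_b + 1L]) { e_a <- e_a + 1L; e_b <- e_b + 1L }
      key <- paste(s_a, s_b, sep = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- c(s_a, s_b, e_a - s_a)
      }
    }
  }
  do.call(rbind, out)
}

#' Enumerate all maximal zero-mismatch TFO:TTS matches
#'
#' For every (signature, TTS) pair, every maximal common substring of length
#' at least `min_len` between the signature and the TTS purine-strand
#' sequence is reported once, with its target interval converted to
#' plus-strand genomic coordinates through the TTS's purine-strand
#' orientation. Identical (TFO, target interval) pairs arising from the two
#' `[GT]` orientations are collapsed to one match with orientation `"both"`.
#'
#' @param signatures Signature tibble from [tfo_target_signatures()].
#' @param tts TTS tibble from [detect_tts()].
#' @param min_len Minimum match length (default 20).
#' @return Tibble of matches: `tfo_id`, `tts_id`, `chrom`, `start`, `end`
#'   (plus-strand genomic target interval), `orientation`, `tfo_offset`
#'   (0-based, in original TFO coordinates), `tts_offset` (0-based, along
#'   the purine strand), `length`, plus carried TFO metadata.
#' @export
enumerate_matches <- function(signatures, tts, min_len = 20L) {
  empty <- tibble(
    tfo_id = character(), tts_id = character(), chrom = character(),
    start = integer(), end = integer(), orientation = character(),
    tfo_offset = integer(), tts_offset = integer(), length = integer(),
    transcript_id = character(), gene_id = character(),
    source_class = character(), motif = character()
  )
  if (nrow(signatures) == 0L || nrow(tts) == 0L) return(empty)
  rows <- list()
  for (si in seq_len(nrow(signatures))) {
    sg <- signatures[si, ]
    for (ti in seq_len(nrow(tts))) {
      tt <- tts[ti, ]
      mcs <- maximal_common_substrings(sg$signature, tt$seq, min_len)
      if (is.null(mcs) || nrow(mcs) == 0L) next
      keep <- mcs[, 3] >= min_len
      if (!any(keep)) next
      mcs <- mcs[keep, , drop = FALSE]
      i0 <- mcs[, 1]; j0 <- mcs[, 2]; len <- mcs[, 3]
      if (tt$purine_strand == "+") {
        g_start <- tt$start + j0
      } else {
        g_start <- tt$end - j0 - len
      }
      tfo_offset <- if (sg$orientation == "antiparallel") sg$tfo_len - i0 - len else i0
      rows[[length(rows) + 1L]] <- tibble(
        tfo_id = sg$tfo_id, tts_id = tt$tts_id, chrom = tt$chrom,
        start = as.integer(g_start), end = as.integer(g_start + len),
        orientation = sg$orientation,
        tfo_offset = as.integer(tfo_offset), tts_offset = as.integer(j0),
        length = as.integer(len),
        transcript_id = sg$transcript_id, gene_id = sg$gene_id,
        source_class = sg$source_class, motif = sg$motif
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- bind_rows(rows)
  # collapse GT dual-orientation duplicates at the same locus (one physical site)
  out <- out %>%
    group_by(.data$tfo_id, .data$tts_id, .data$chrom, .data$start, .data$end) %>%
    mutate(orientation = if (dplyr::n_distinct(.data$orientation) > 1L) "both" else .data$orientation) %>%
    arrange(.data$tfo_offset, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start, .data$tfo_id, .data$tts_id)
  out
}

#' Remove self-matches (a TFO targeting its own genomic tract)
#'
#' Every TFO whose motif keeps it purine- or pyrimidine-pure is, on the
#' duplex it is transcribed from, itself a triplex-target site, so it
#' trivially matches its own locus. Such matches carry no information and
#' are removed: by default any match whose genomic target interval overlaps
#' the source TFO's own genomic interval by at least one base
#' (`mode = "overlap"`); `mode = "exact"` removes only coordinate-identical
#' targets.
#'
#' @param matches Match tibble from [enumerate_matches()].
#' @param tfos TFO tibble (for the source genomic intervals).
#' @param mode `"overlap"` (default) or `"exact"`.
#' @return A list with `matches` (the filtered tibble) and
#'   `dropped_tfo_ids` (TFOs whose every match was a self-match).
#' @export
remove_self_matches <- function(matches, tfos, mode = c("overlap", "exact")) {
  mode <- match.arg(mode)
  if (nrow(matches) == 0L) {
    return(list(matches = matches, dropped_tfo_ids = character()))
  }
  src <- tfos[match(matches$tfo_id, tfos$tfo_id), c("g_chrom", "g_start", "g_end")]
  same_chrom <- matches$chrom == src$g_chrom
  is_self <- if (mode == "overlap") {
    same_chrom & interval_overlap(matches$start, matches$end, src$g_start, src$g_end) >= 1L
  } else {
    same_chrom & matches$start == src$g_start & matches$end == src$g_end
  }
  kept <- matches[!is_self, ]
  dropped <- setdiff(unique(matches$tfo_id), unique(kept$tfo_id))
  list(matches = kept, dropped_tfo_ids = sort(dropped))
}

#' Merge overlapping matches into triplex sites
#'
#' Matches whose genomic target intervals overlap over more than
#' `overlap_threshold` bases (strictly: an overlap of at least
#' `overlap_threshold + 1` bases) are considered the same physical site and
#' collapsed by single-linkage clustering. Merging is performed separately
#' per source class (`scope = "class"`, the default, since per-class merged
#' totals are the quantity of interest) or across all classes
#' (`scope = "global"`).
#'
#' @param matches Match tibble.
#' @param overlap_threshold Bases of overlap above which two matches are the
#'   same site (default 10: "overlap over more than 10 bases").
#' @param scope `"class"` or `"global"`.
#' @return Tibble of merged sites: `site_id`, `source_class`, `chrom`,
#'   `start`, `end` (union span of members), `n_members`, `tfo_ids`
#'   (list-column of contributing TFO ids).
#' @export
merge_matches <- function(matches, overlap_threshold = 10L, scope = c("class", "global")) {
  scope <- match.arg(scope)
  if (nrow(matches) == 0L) {
    return(tibble(site_id = character(), source_class = character(),
                  chrom = character(), start = integer(), end = integer(),
                  n_members = integer(), tfo_ids = list()))
  }
  m <- matches
  if (scope == "global") m$source_class <- "all"
  out <- m %>%
    group_by(.data$source_class, .data$chrom) %>%
    arrange(.data$start, .data$end, .by_group = TRUE) %>%
    mutate(
      prev_max_end = dplyr::lag(cummax(.data$end), default = NA_integer_),
      joins = !is.na(.data$prev_max_end) &
        (pmin(.data$end, .data$prev_max_end) - .data$start) >= overlap_threshold + 1L,
      cluster = cumsum(!.data$joins)
    ) %>%
    group_by(.data$source_class, .data$chrom, .data$cluster) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      n_members = dplyr::n(),
      tfo_ids = list(sort(unique(.data$tfo_id))),
      .groups = "drop"
    ) %>%
    arrange(.data$source_class, .data$chrom, .data$start) %>%
    mutate(site_id = new_id("site", dplyr::n(), width = 6L)) %>%
    select("site_id", "source_class", "chrom", "start", "end", "n_members", "tfo_ids")
  out
}
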