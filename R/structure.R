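# Intramolecular pairing search: hairpin stems and long-range pairings used
# to estimate which TFOs sit inside potentially paired (inaccessible)
# regions of their host RNA.

#' Find maximal complementary stem pairs in an RNA sequence
#'
#' Enumerates every maximal pair of arms that could fold back on each other
#' by strict Watson-Crick pairing (A:T, G:C on the DNA-coded sequence; G:U
#' wobble optional): left arm `[i, i+l)` pairs with right arm `[j, j+l)`
#' read antiparallel, with arm length `l >= min_stem` and separation
#' `j - (i + l)` (the loop) within `[loop_min, loop_max]`. Maximality means
#' neither arm can be extended outward or inward while preserving
#' complementarity and the loop bounds. The defaults describe hairpins
#' (arms of at least 4 bases around a 4-8 base loop); long-range pairings
#' such as pseudoknot helices use arms of at least 10 bases separated by up
#' to 500 bases.
#'
#' @param sequence A single DNA-coded RNA sequence.
#' @param min_stem Minimum arm length (default 4).
#' @param loop_min,loop_max Allowed separation between the arms in bases
#'   (defaults 4 and 8).
#' @param wobble Allow G:T (G:U) pairs (default `FALSE`).
#' @return Tibble of stems: `left_start`, `left_end`, `right_start`,
#'   `right_end` (0-based half-open), `arm_len`, `separation`.
#' @export
#' @examples
#' find_stems("GGGGAAAACCCC", min_stem = 4, loop_min = 4, loop_max = 8)
find_stems <- function(sequence, min_stem = 4L, loop_min = 4L, loop_max = 8L,
                       wobble = FALSE) {
  if (min_stem < 1L) abort("`min_stem` must be >= 1.")
  if (loop_min > loop_max || loop_min < 0L) abort("Invalid loop bounds.")
  n <- nchar(sequence)
  empty <- tibble(left_start = integer(), left_end = integer(),
                  right_start = integer(), right_end = integer(),
                  arm_len = integer(), separation = integer())
  if (n < 2L * min_stem + loop_min) return(empty)
  ch <- seq_chars(sequence)
  pairs_ok <- function(x, y) {
    ok <- (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "G" & y == "C") | (x == "C" & y == "G")
    if (wobble) ok <- ok | (x == "G" & y == "T") | (x == "T" & y == "G")
    ok
  }
  out <- list()
  # Pairs (p, q) with p + q = s lie on one anti-diagonal; a stem is a
  # maximal run of complementary pairs along it, trimmed inward until the
  # loop is at least loop_min wide.
  for (s in seq(2L * min_stem + loop_min - 1L, 2L * n - 3L)) {
    p_lo <- max(0L, s - n + 1L)
    p_hi <- (s - 1L) %/% 2L
    if (p_hi < p_lo) next
    p <- p_lo:p_hi
    m <- pairs_ok(ch[p + 1L], ch[s - p + 1L])
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      p0 <- p[starts[k]]       # outermost pair
      p1 <- p[ends[k]]         # innermost pair
      sep <- s - 2L * p1 - 1L
      if (sep < loop_min) {
        trim <- ceiling((loop_min - sep) / 2)
        p1 <- p1 - trim
        sep <- s - 2L * p1 - 1L
      }
      if (p1 < p0 || sep > loop_max) next
      arm <- p1 - p0 + 1L
      if (arm < min_stem) next
      out[[length(out) + 1L]] <- c(p0, p1 + 1L, s - p1, s - p0 + 1L, arm, sep)
    }
  }
  if (length(out) == 0L) return(empty)
  m <- do.call(rbind, out)
  tibble(
    left_start = as.integer(m[, 1]), left_end = as.integer(m[, 2]),
    right_start = as.integer(m[, 3]), right_end = as.integer(m[, 4]),
    arm_len = as.integer(m[, 5]), separation = as.integer(m[, 6])
  ) %>% arrange(.data$left_start, .data$right_start)
}

#' Estimate the fraction of TFOs inside potentially paired regions
#'
#' For each transcript, searches for hairpin stems and long-range pairings
#' with [find_stems()]; a TFO counts as potentially paired when its
#' transcript interval overlaps any stem arm by at least one base.
#' Fractions are reported per source class.
#'
#' @param tfos TFO tibble from [detect_tfos()].
#' @param transcripts Transcript tibble (`transcript_id`, `sequence`).
#' @param hairpin Named list of hairpin parameters
#'   (`min_stem`, `loop_min`, `loop_max`).
#' @param longrange Named list of long-range parameters
#'   (`min_stem`, `loop_min`, `loop_max`).
#' @param wobble Allow G:U pairs (default `FALSE`).
#' @return Tibble per source class: `source_class`, `n_tfos`, `n_paired`,
#'   `fraction`.
#' @export
tfo_accessibility <- function(tfos, transcripts,
                              hairpin = list(min_stem = 4L, loop_min = 4L, loop_max = 8L),
                              longrange = list(min_stem = 10L, loop_min = 0L, loop_max = 500L),
                              wobble = FALSE) {
  if (nrow(tfos) == 0L) abort("Empty TFO set: paired fraction is undefined.")
  tx_ids <- unique(tfos$transcript_id)
  paired <- logical(nrow(tfos))
  for (tx in tx_ids) {
    s <- transcripts$sequence[match(tx, transcripts$transcript_id)]
    if (is.na(s)) abort(sprintf("Transcript %s not found.", tx))
    arms <- bind_rows(
      find_stems(s, hairpin$min_stem, hairpin$loop_min, hairpin$loop_max, wobble),
      find_stems(s, longrange$min_stem, longrange$loop_min, longrange$loop_max, wobble)
    )
    rows <- which(tfos$transcript_id == tx)
    if (nrow(arms) == 0L) next
    arm_iv <- rbind(
      cbind(arms$left_start, arms$left_end),
      cbind(arms$right_start, arms$right_end)
    )
    for (i in rows) {
      paired[i] <- any(interval_overlap(tfos$t_start[i], tfos$t_end[i],
                                        arm_iv[, 1], arm_iv[, 2]) >= 1L)
    }
  }
  tibble(source_class = tfos$source_class, paired = paired) %>%
    group_by(.data$source_class) %>%
    summarise(
      n_tfos = dplyr::n(),
      n_paired = sum(.data$paired),
      fraction = .data$n_paired / .data$n_tfos,
      .groups = "drop"
    )
}
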