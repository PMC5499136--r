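# Maximal motif-run detection: the core primitive behind both the TFO scan
# (runs over a Hoogsteen motif alphabet in a transcript) and the TTS scan
# (homopurine / homopyrimidine tracts on a chromosome).

#' Find maximal runs over an alphabet
#'
#' Returns every maximal substring of `sequence` composed only of letters in
#' `alphabet`, with length at least `min_len`. A run is maximal when its
#' flanking bases (where they exist) fall outside the alphabet; `N` and any
#' base outside the alphabet terminate runs.
#'
#' @param sequence A single DNA string (already normalised: uppercase, no U).
#' @param alphabet Character vector of allowed bases, e.g. `c("G","A")`.
#' @param min_len Minimum run length to report (default 20, the canonical
#'   minimum length for stable triplex formation used throughout).
#' @return Tibble with integer columns `start`, `end` (0-based half-open),
#'   sorted and non-overlapping.
#' @export
#' @examples
#' find_maximal_runs(strrep("TC", 10), c("T", "C"), 20)
find_maximal_runs <- function(sequence, alphabet, min_len = 20L) {
  assert_scalar_string(sequence, "sequence")
  n <- nchar(sequence)
  if (n == 0L) return(empty_interval_tbl())
  hit <- seq_chars(sequence) %in% alphabet
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

# Mismatch-tolerant variant: a run may contain interior non-motif bases as
# long as every window of `window` bases within it holds at most
# floor(window * error_rate) of them, and both run ends are motif bases.
# error_rate = 0 reduces to the exact scan.
find_tolerant_runs <- function(sequence, alphabet, min_len = 20L,
                               error_rate = 0, window = 20L) {
  n_err <- floor(window * error_rate)
  if (n_err == 0L) return(find_maximal_runs(sequence, alphabet, min_len))
  n <- nchar(sequence)
  if (n == 0L) return(empty_interval_tbl())
  mism <- !(seq_chars(sequence) %in% alphabet)
  if (n < window) return(empty_interval_tbl())
  cs <- c(0L, cumsum(mism))
  # 0-based window start i is "bad" when its mismatch count exceeds n_err;
  # a candidate segment is any maximal stretch containing no bad window.
  win_counts <- cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
  bad <- which(win_counts > n_err) - 1L
  seg_start <- c(0L, bad + 1L)
  seg_end <- c(bad + window - 2L, n - 1L) # inclusive; must not contain a bad window
  out <- list()
  for (k in seq_along(seg_start)) {
    s <- seg_start[k]; e <- seg_end[k]
    while (s <= e && mism[s + 1L]) s <- s + 1L
    while (e >= s && mism[e + 1L]) e <- e - 1L
    if (e - s + 1L >= max(min_len, window)) {
      out[[length(out) + 1L]] <- c(s, e + 1L)
    }
  }
  if (length(out) == 0L) return(empty_interval_tbl())
  iv <- unique(do.call(rbind, out))
  iv <- iv[order(iv[, 1], -iv[, 2]), , drop = FALSE]
  # drop segments nested inside another candidate
  keep <- rep(TRUE, nrow(iv))
  max_end <- -1L
  for (i in seq_len(nrow(iv))) {
    if (iv[i, 2] <= max_end) keep[i] <- FALSE
    max_end <- max(max_end, iv[i, 2])
  }
  tibble(start = as.integer(iv[keep, 1]), end = as.integer(iv[keep, 2]))
}
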