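# Internal helpers shared across modules. All coordinates handled here are
# 0-based half-open; conversion to/from 1-based closed happens only at the
# GFF3/BED boundary in io.R.

DNA_BASES <- c("A", "C", "G", "T")

# Motif alphabets for the third (RNA) strand, DNA-coded (U -> T).
MOTIF_ALPHABETS <- list(
  TC = c("T", "C"),
  GA = c("G", "A"),
  GT = c("G", "T")
)

revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Overlap in bases between two half-open intervals.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string.", what))
  }
}

assert_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", what, min))
  }
}

assert_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a number in [0, 1].", what))
  }
}

empty_interval_tbl <- function() {
  tibble(start = integer(), end = integer())
}

# Normalise a DNA/RNA sequence: uppercase, U -> T.  Errors on letters outside
# {A,C,G,T,N} naming the offending character.
normalize_dna <- function(x, id = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- stringr::str_locate(x, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf(
      "Illegal character '%s' at position %d of %s.",
      substr(x[i], bad[i], bad[i]), bad[i],
      if (length(id) == length(x)) id[i] else id
    ))
  }
  x
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

new_id <- function(prefix, n, width = max(4L, nchar(as.character(n)))) {
  if (n == 0L) return(character())
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}
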