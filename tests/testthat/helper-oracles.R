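# Independent brute-force oracles used to check the fast implementations.
# Each oracle is deliberately written with a different algorithmic idea than
# the code path it validates.

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Sliding-window oracle for maximal runs: membership vector -> boundaries by
# position differencing (the implementation uses rle()).
oracle_runs <- function(sequence, alphabet, min_len) {
  n <- nchar(sequence)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  mem <- strsplit(sequence, "")[[1]] %in% alphabet
  starts <- which(mem & !c(FALSE, mem[-n])) - 1L
  ends <- which(mem & !c(mem[-1], FALSE))
  keep <- (ends - starts) >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

# Exhaustive-substring oracle for tiny inputs: every substring checked for
# alphabet membership and maximality directly.
oracle_runs_exhaustive <- function(sequence, alphabet, min_len) {
  n <- nchar(sequence)
  ch <- strsplit(sequence, "")[[1]]
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L < min_len) next
      if (!all(ch[i:j] %in% alphabet)) next
      left_ok <- i == 1L || !(ch[i - 1L] %in% alphabet)
      right_ok <- j == n || !(ch[j + 1L] %in% alphabet)
      if (left_ok && right_ok) out[[length(out) + 1L]] <- c(i - 1L, j)
    }
  }
  if (length(out) == 0L) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# Quadratic dynamic-programming oracle for maximal common substrings:
# classic L[i,j] table, reporting runs that cannot be extended.
oracle_mcs <- function(a, b, min_len) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  na <- length(ac); nb <- length(bc)
  L <- matrix(0L, na + 1L, nb + 1L)
  out <- list()
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (ac[i] == bc[j]) L[i + 1L, j + 1L] <- L[i, j] + 1L
    }
  }
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      len <- L[i + 1L, j + 1L]
      if (len == 0L) next
      ends_here <- i == na || j == nb || ac[i + 1L] != bc[j + 1L]
      if (ends_here && len >= min_len) {
        out[[length(out) + 1L]] <- c(i - len, j - len, len)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(a_off = integer(), b_off = integer(), len = integer()))
  }
  m <- unique(do.call(rbind, out))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(a_off = m[, 1], b_off = m[, 2], len = m[, 3])
}

# Union-find oracle for single-linkage interval merging with an overlap
# threshold: all-pairs comparison plus transitive closure.
oracle_merge_partition <- function(starts, ends, overlap_threshold) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      ov <- min(ends[i], ends[j]) - max(starts[i], starts[j])
      if (ov >= overlap_threshold + 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Exhaustive prefix-search oracle for the 75%-cumulative selection.
oracle_select <- function(ids, counts, lengths, baseline, fraction) {
  dens <- 1000 * counts / lengths
  ord <- order(-counts, -dens, ids)
  ids <- ids[ord]; counts <- counts[ord]; dens <- dens[ord]
  total <- sum(counts)
  chosen <- character()
  for (p in seq_along(ids)) {
    if (total == 0) break
    if (sum(counts[1:p]) / total >= fraction) {
      chosen <- ids[1:p][dens[1:p] > baseline]
      break
    }
    if (p == length(ids)) chosen <- ids[dens > baseline]
  }
  chosen
}

# Brute-force oracle for stems: enumerate every candidate inner pair and
# separation, extend the arms outward base by base, and apply the
# maximality conditions directly.
oracle_stems <- function(sequence, min_stem, loop_min, loop_max) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  is_pair <- function(p, q) {
    p >= 1L && q <= n && p < q && comp[[ch[p]]] == ch[q]
  }
  out <- list()
  for (p in seq_len(n)) {
    for (sep in loop_min:loop_max) {
      q <- p + sep + 1L
      if (q > n) next
      if (!is_pair(p, q)) next
      # not inward-extendable (within the loop lower bound)?
      if (sep - 2L >= loop_min && is_pair(p + 1L, q - 1L)) next
      # extend outward from the inner pair as far as complementarity holds
      a <- 1L
      while (is_pair(p - a, q + a)) a <- a + 1L
      if (a < min_stem) next
      out[[length(out) + 1L]] <- c(p - a, p, q - 1L, q - 1L + a, a, sep)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      arm_len = integer(), separation = integer()))
  }
  m <- unique(do.call(rbind, out))
  m <- m[order(m[, 1], m[, 3]), , drop = FALSE]
  data.frame(left_start = m[, 1], left_end = m[, 2], right_start = m[, 3],
             right_end = m[, 4], arm_len = m[, 5], separation = m[, 6])
}

# Hypergeometric upper-tail oracle via binomial coefficients (closed-form
# enumeration of favourable draws).
oracle_hyper_tail <- function(N, K, n, k) {
  xs <- k:min(n, K)
  xs <- xs[n - xs <= N - K]
  if (length(xs) == 0L) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Direct enumeration over all C(N, n) draws (tiny N only).
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # first K elements are the annotated ones
  mean(hits >= k)
}

# Brute-force maximal cliques on small graphs via subset enumeration.
oracle_max_cliques <- function(nodes, edge_a, edge_b, min_size) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (e in seq_along(edge_a)) {
    adj[edge_a[e], edge_b[e]] <- TRUE
    adj[edge_b[e], edge_a[e]] <- TRUE
  }
  is_clique <- function(s) all(adj[s, s] | diag(length(s)))
  subsets <- list()
  for (sz in min_size:length(nodes)) {
    cmb <- utils::combn(nodes, sz, simplify = FALSE)
    subsets <- c(subsets, Filter(is_clique, cmb))
  }
  maximal <- Filter(function(s) {
    !any(vapply(subsets, function(t) {
      length(t) > length(s) && all(s %in% t)
    }, logical(1)))
  }, subsets)
  unique(lapply(maximal, sort))
}

expect_same_intervals <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  expect_equal(as.integer(got$start), as.integer(want$start))
  expect_equal(as.integer(got$end), as.integer(want$end))
}

# Build a gene-summary table from explicit counts/lengths (selection tests).
gene_triplex_summary_from_counts <- function(ids, counts, lengths) {
  units <- tibble::tibble(id = ids, length = as.integer(lengths),
                          count = as.integer(counts))
  dplyr::rename(triplexmap:::rank_and_share(units), gene_id = "id")
}
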