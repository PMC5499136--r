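# GO-term over-representation and the genetic-interaction network:
# construction, pruning of small components, and overlapping module
# detection by maximal-clique agglomeration.

#' Hypergeometric over-representation test for annotation terms
#'
#' For each term with at least one population annotation, tests whether the
#' study list is enriched: with `N` population genes, `K` of them annotated
#' with the term, `n` study genes and `k` annotated study genes, the p-value
#' is the upper hypergeometric tail `P(X >= k)`. P-values are adjusted
#' across tested terms by Benjamini-Hochberg (default) or Bonferroni.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of population (universe) gene ids.
#' @param go_table Tibble with columns `gene`, `term`; annotations outside
#'   the population are ignored.
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @return Tibble sorted by p-value: `term`, `k`, `n`, `K`, `N`, `p_value`,
#'   `q_value`.
#' @export
hypergeometric_enrichment <- function(study, population, go_table,
                                      correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  study <- unique(study)
  population <- unique(population)
  if (length(study) == 0L) abort("Empty study list.")
  if (!all(study %in% population)) abort("Study genes must be a subset of the population.")
  anno <- go_table %>%
    filter(.data$gene %in% population) %>%
    distinct(.data$gene, .data$term)
  N <- length(population)
  n <- length(study)
  out <- anno %>%
    group_by(.data$term) %>%
    summarise(
      K = dplyr::n(),
      k = sum(.data$gene %in% study),
      .groups = "drop"
    ) %>%
    mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1L, .data$K, N - .data$K, n, lower.tail = FALSE),
      q_value = p.adjust(.data$p_value, method = if (correction == "BH") "BH" else "bonferroni")
    ) %>%
    arrange(.data$p_value, .data$term) %>%
    select("term", "k", "n", "K", "N", "p_value", "q_value")
  out
}

#' Build a genetic-interaction graph among selected genes
#'
#' Keeps interactions whose both endpoints belong to the selected list,
#' drops self-loops, and collapses duplicate or antiparallel edge records
#' into one undirected edge; when both a suppression and an enhancement
#' record exist for a pair, the relation is `"both"`.
#'
#' @param selected Character vector of gene ids.
#' @param interactions Tibble with columns `gene_a`, `gene_b`, `relation`
#'   (`"suppression"` or `"enhancement"`).
#' @return An `interaction_graph` object: a list with `nodes` (genes with at
#'   least one kept edge) and `edges` (tibble `gene_a`, `gene_b`,
#'   `relation`, with `gene_a < gene_b`).
#' @export
build_graph <- function(selected, interactions) {
  edges <- interactions %>%
    filter(.data$gene_a %in% selected, .data$gene_b %in% selected,
           .data$gene_a != .data$gene_b) %>%
    mutate(
      a = pmin(.data$gene_a, .data$gene_b),
      b = pmax(.data$gene_a, .data$gene_b)
    ) %>%
    group_by(.data$a, .data$b) %>%
    summarise(
      relation = if (dplyr::n_distinct(.data$relation) > 1L) "both" else .data$relation[1],
      .groups = "drop"
    ) %>%
    rename(gene_a = "a", gene_b = "b") %>%
    arrange(.data$gene_a, .data$gene_b)
  structure(
    list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))), edges = edges),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = graph$nodes
  )
}

#' Prune small connected components from an interaction graph
#'
#' Removes connected components with fewer than `min_component_size` nodes
#' (disconnected pairs and triplets carry little network signal), reporting
#' how many genes were dropped.
#'
#' @param graph An `interaction_graph` from [build_graph()].
#' @param min_component_size Minimum component size to keep (default 4).
#' @return A list with `graph` (the pruned `interaction_graph`) and
#'   `dropped_genes` (character vector).
#' @export
prune_components <- function(graph, min_component_size = 4L) {
  if (length(graph$nodes) == 0L) {
    return(list(graph = graph, dropped_genes = character()))
  }
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  keep_comp <- which(comp$csize >= min_component_size)
  keep_nodes <- names(comp$membership)[comp$membership %in% keep_comp]
  dropped <- setdiff(graph$nodes, keep_nodes)
  edges <- filter(graph$edges, .data$gene_a %in% keep_nodes, .data$gene_b %in% keep_nodes)
  list(
    graph = structure(list(nodes = sort(keep_nodes), edges = edges),
                      class = "interaction_graph"),
    dropped_genes = sort(dropped)
  )
}

#' Detect overlapping network modules by clique agglomeration
#'
#' Enumerates maximal cliques of at least `min_clique` nodes and
#' agglomerates them: the pair of candidate modules with the highest
#' overlap similarity `|A intersect B| / min(|A|, |B|)` is merged until no
#' pair reaches `similarity_cut`. Modules may share genes, mirroring
#' spanning-cluster (EAGLE-style) community detection.
#'
#' @param graph An `interaction_graph`.
#' @param min_clique Minimum clique size to seed a module (default 3).
#' @param similarity_cut Overlap similarity below which modules stay
#'   separate (default 0.5).
#' @return Tibble with `module_id`, `n_genes`, `genes` (list-column of
#'   sorted gene ids), ordered by decreasing size.
#' @export
detect_modules <- function(graph, min_clique = 3L, similarity_cut = 0.5) {
  empty <- tibble(module_id = character(), n_genes = integer(), genes = list())
  if (length(graph$nodes) == 0L || nrow(graph$edges) == 0L) return(empty)
  g <- as_igraph(graph)
  cliques <- igraph::max_cliques(g, min = min_clique)
  if (length(cliques) == 0L) return(empty)
  mods <- lapply(cliques, function(cl) sort(names(cl)))
  mods <- mods[order(vapply(mods, function(m) paste(m, collapse = ","), character(1)))]
  repeat {
    if (length(mods) < 2L) break
    best <- c(0, NA, NA)
    for (i in seq_len(length(mods) - 1L)) {
      for (j in (i + 1L):length(mods)) {
        sim <- length(intersect(mods[[i]], mods[[j]])) / min(length(mods[[i]]), length(mods[[j]]))
        if (sim > best[1]) best <- c(sim, i, j)
      }
    }
    if (best[1] < similarity_cut) break
    i <- best[2]; j <- best[3]
    merged <- sort(union(mods[[i]], mods[[j]]))
    mods <- c(mods[-c(i, j)], list(merged))
  }
  mods <- mods[order(-vapply(mods, length, integer(1)),
                     vapply(mods, function(m) m[1], character(1)))]
  tibble(
    module_id = new_id("module", length(mods), width = 2L),
    n_genes = vapply(mods, length, integer(1)),
    genes = mods
  )
}
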