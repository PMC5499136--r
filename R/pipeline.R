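# End-to-end pipeline: detect -> match -> filter -> merge -> stats ->
# select -> structure -> enrich -> network, under a single validated
# config, with per-stage bookkeeping and a reproducibility manifest.

CONFIG_DEFAULTS <- list(
  genome = NULL, annotation = NULL, transcripts = NULL,
  interactions = NULL, go = NULL,
  min_tfo_length = 20L, min_tts_length = 20L, error_rate = 0,
  overlap_threshold = 10L, merge_scope = "class",
  bin_size = 200000L, cumulative_fraction = 0.75, rank_by = "count",
  min_stem = 4L, loop_min = 4L, loop_max = 8L,
  lr_stem = 10L, lr_max_sep = 500L,
  min_component_size = 4L, min_clique = 3L,
  self_match_mode = "overlap", baseline_scope = "genic", correction = "BH",
  seed = 1L
)

#' Build and validate a pipeline configuration
#'
#' Inputs (`genome`, `annotation`, `transcripts`, and optionally
#' `interactions` and `go`) may be file paths (FASTA / GFF3 / TSV) or the
#' corresponding in-memory objects. All thresholds default to the canonical
#' analysis parameters: 20-base minimum TFO/TTS length, zero mismatch rate,
#' merging of matches overlapping over more than 10 bases, 200-kb bins,
#' selection of genes covering 75% of matches with above-baseline density,
#' hairpin arms of 4+ bases around 4-8 base loops, long-range arms of 10+
#' bases up to 500 bases apart, and pruning of network components smaller
#' than 4 genes. Unknown keys are rejected.
#'
#' @param ... Named configuration values overriding the defaults.
#' @return A validated `triplex_config` object.
#' @export
triplex_config <- function(...) {
  user <- list(...)
  unknown <- setdiff(names(user), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(CONFIG_DEFAULTS, user, keep.null = TRUE)
  validate_triplex_config(cfg)
  structure(cfg, class = "triplex_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match [triplex_config()]
#'   arguments.
#' @return A validated `triplex_config`.
#' @export
read_triplex_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(triplex_config, vals)
}

validate_triplex_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(sprintf("Invalid configuration: %s", msg))
  chk(is.numeric(cfg$min_tfo_length) && cfg$min_tfo_length >= 1, "min_tfo_length must be >= 1")
  chk(is.numeric(cfg$min_tts_length) && cfg$min_tts_length >= 1, "min_tts_length must be >= 1")
  chk(is.numeric(cfg$error_rate) && cfg$error_rate >= 0 && cfg$error_rate <= 0.5,
      "error_rate must be in [0, 0.5]")
  chk(is.numeric(cfg$overlap_threshold) && cfg$overlap_threshold >= 0,
      "overlap_threshold must be >= 0")
  chk(cfg$merge_scope %in% c("class", "global"), "merge_scope must be 'class' or 'global'")
  chk(is.numeric(cfg$bin_size) && cfg$bin_size > 0, "bin_size must be positive")
  chk(is.numeric(cfg$cumulative_fraction) && cfg$cumulative_fraction >= 0 &&
        cfg$cumulative_fraction <= 1, "cumulative_fraction must be in [0, 1]")
  chk(cfg$rank_by %in% c("count", "density"), "rank_by must be 'count' or 'density'")
  chk(is.numeric(cfg$min_stem) && cfg$min_stem >= 1, "min_stem must be >= 1")
  chk(is.numeric(cfg$loop_min) && is.numeric(cfg$loop_max) &&
        cfg$loop_min >= 0 && cfg$loop_min <= cfg$loop_max,
      "loop bounds must satisfy 0 <= loop_min <= loop_max")
  chk(is.numeric(cfg$lr_stem) && cfg$lr_stem >= 1, "lr_stem must be >= 1")
  chk(is.numeric(cfg$lr_max_sep) && cfg$lr_max_sep >= 0, "lr_max_sep must be >= 0")
  chk(is.numeric(cfg$min_component_size) && cfg$min_component_size >= 1,
      "min_component_size must be >= 1")
  chk(is.numeric(cfg$min_clique) && cfg$min_clique >= 2,
      "min_clique must be >= 2")
  chk(cfg$self_match_mode %in% c("overlap", "exact"),
      "self_match_mode must be 'overlap' or 'exact'")
  chk(cfg$baseline_scope %in% c("genic", "all"),
      "baseline_scope must be 'genic' or 'all'")
  chk(cfg$correction %in% c("BH", "bonferroni"),
      "correction must be 'BH' or 'bonferroni'")
  chk(is.numeric(cfg$seed) && cfg$seed == as.integer(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && !grepl("\n", x)) reader(x) else x
}

read_table_input <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}

#' Read a transcript table (metadata TSV plus sequence FASTA)
#'
#' The metadata TSV must have columns `transcript_id`, `gene_id`, `kind`
#' (`"pre"`/`"mature"`) and `class` (`"mRNA"`/`"lncRNA"`); sequences come
#' either from a `sequence` column or from a FASTA file (default:
#' `transcripts.fa` next to the TSV) whose record names are transcript ids.
#'
#' @param meta_path Path to the metadata TSV.
#' @param fasta_path Optional path to the transcript FASTA.
#' @return A transcript tibble as consumed by [detect_tfos()].
#' @export
read_transcripts <- function(meta_path, fasta_path = NULL) {
  meta <- read_table_input(meta_path)
  need <- c("transcript_id", "gene_id", "kind", "class")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("Transcript table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"sequence" %in% names(meta)) {
    fasta_path <- fasta_path %||% file.path(dirname(meta_path), "transcripts.fa")
    fa <- read_fasta(fasta_path)
    meta$sequence <- unname(fa[meta$transcript_id])
    if (anyNA(meta$sequence)) abort("Transcript FASTA lacks records for some transcript ids.")
  }
  as_tibble(meta)
}

#' Run the full triplex-mapping pipeline
#'
#' Executes all stages in order: TFO detection, TTS detection, signature
#' derivation, exhaustive matching, self-match removal, overlap merging,
#' localization and binning statistics, density baseline and
#' gene/transcript selection, structural accessibility, and (when
#' interaction / GO inputs are provided) network construction, pruning,
#' module detection and GO enrichment. A stage failure aborts with the
#' stage name. When `out_dir` is given, every stage artifact is written as
#' plain TSV/BED plus a JSON manifest recording the configuration hash,
#' input checksums and per-stage record counts; re-running with identical
#' inputs and config reproduces byte-identical outputs.
#'
#' @param config A `triplex_config` (see [triplex_config()]).
#' @param out_dir Optional output directory.
#' @param verbose Log one line per stage to stderr.
#' @return A `triplex_run` object (list of all stage results plus the
#'   manifest), with [tidy()] and [glance()] methods.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  if (!inherits(config, "triplex_config")) abort("`config` must be a triplex_config.")
  validate_triplex_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  genome <- stage("read_genome", resolve_input(config$genome, read_fasta))
  genes <- stage("read_annotation", resolve_input(config$annotation, read_gene_models))
  transcripts <- stage("read_transcripts", resolve_input(config$transcripts, read_transcripts))
  interactions <- resolve_input(config$interactions, read_table_input)
  go_table <- resolve_input(config$go, read_table_input)
  if (is.null(genome) || is.null(genes) || is.null(transcripts)) {
    abort("Configuration must provide genome, annotation and transcripts.")
  }

  tfos <- stage("detect_tfos",
                detect_tfos(transcripts, genes, config$min_tfo_length, config$error_rate))
  say("detect_tfos: %d TFOs", nrow(tfos))
  tts <- stage("detect_tts",
               detect_tts(genome, genes, config$min_tts_length, config$error_rate))
  say("detect_tts: %d TTSs", nrow(tts))

  signatures <- stage("signatures", tfo_target_signatures(tfos))
  matches_raw <- stage("enumerate_matches",
                       enumerate_matches(signatures, tts, config$min_tfo_length))
  say("enumerate_matches: %d raw matches", nrow(matches_raw))
  filtered <- stage("remove_self_matches",
                    remove_self_matches(matches_raw, tfos, config$self_match_mode))
  matches <- filtered$matches
  say("remove_self_matches: %d matches kept, %d TFOs dropped",
      nrow(matches), length(filtered$dropped_tfo_ids))
  sites <- stage("merge_matches",
                 merge_matches(matches, config$overlap_threshold, config$merge_scope))
  say("merge_matches: %d sites", nrow(sites))

  localization <- stage("localization", {
    tabs <- list(TTS = localization_table(tts, genes))
    for (cls in sort(unique(sites$source_class))) {
      tabs[[cls]] <- localization_table(filter(sites, .data$source_class == cls), genes)
    }
    tabs
  })
  bins <- stage("bin_triplexes", bin_triplexes(sites, config$bin_size))
  baseline <- stage("density_baseline",
                    density_baseline(matches, genes, config$baseline_scope))
  gene_summary <- stage("gene_summary",
                        gene_triplex_summary(matches, genes, config$rank_by))
  selected_genes <- stage("select_enriched",
                          select_enriched(gene_summary, baseline$baseline,
                                          config$cumulative_fraction))
  selected_transcripts <- stage("select_transcripts",
    select_contributing_transcripts(matches, transcripts, baseline$baseline,
                                    config$cumulative_fraction, config$rank_by))
  say("selection: %d genes, %d transcripts (baseline %.3f / kb)",
      length(selected_genes), length(selected_transcripts), baseline$baseline)

  accessibility <- stage("tfo_accessibility", {
    if (nrow(tfos) > 0) {
      tfo_accessibility(
        tfos, transcripts,
        hairpin = list(min_stem = config$min_stem, loop_min = config$loop_min,
                       loop_max = config$loop_max),
        longrange = list(min_stem = config$lr_stem, loop_min = 0L,
                         loop_max = config$lr_max_sep)
      )
    } else {
      tibble(source_class = character(), n_tfos = integer(),
             n_paired = integer(), fraction = double())
    }
  })

  enrichment <- NULL
  if (!is.null(go_table) && length(selected_genes) > 0) {
    enrichment <- stage("enrichment",
                        hypergeometric_enrichment(selected_genes, genes$gene_id,
                                                  go_table, config$correction))
    say("enrichment: %d terms tested", nrow(enrichment))
  }
  network <- NULL
  if (!is.null(interactions)) {
    network <- stage("network", {
      graph <- build_graph(selected_genes, interactions)
      pruned <- prune_components(graph, config$min_component_size)
      modules <- detect_modules(pruned$graph, config$min_clique)
      list(graph = graph, pruned = pruned$graph,
           dropped_genes = pruned$dropped_genes, modules = modules)
    })
    say("network: %d nodes kept, %d modules",
        length(network$pruned$nodes), nrow(network$modules))
  }

  counts <- tibble(
    stage = c("tfos", "tts", "matches_raw", "matches", "dropped_tfos", "sites",
              "selected_genes", "selected_transcripts",
              "enrichment_terms", "network_nodes", "network_modules"),
    n = c(nrow(tfos), nrow(tts), nrow(matches_raw), nrow(matches),
          length(filtered$dropped_tfo_ids), nrow(sites),
          length(selected_genes), length(selected_transcripts),
          if (is.null(enrichment)) 0L else nrow(enrichment),
          if (is.null(network)) 0L else length(network$pruned$nodes),
          if (is.null(network)) 0L else nrow(network$modules))
  )
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    input_hash = rlang::hash(list(genome, genes$gene_id, transcripts$sequence,
                                  interactions, go_table)),
    counts = setNames(as.list(counts$n), counts$stage)
  )

  run <- structure(
    list(
      config = config, tfos = tfos, tts = tts, matches_raw = matches_raw,
      matches = matches, dropped_tfo_ids = filtered$dropped_tfo_ids,
      sites = sites, localization = localization, bins = bins,
      baseline = baseline, gene_summary = gene_summary,
      selected_genes = selected_genes,
      selected_transcripts = selected_transcripts,
      accessibility = accessibility, enrichment = enrichment,
      network = network, manifest = manifest
    ),
    class = "triplex_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
  w(select(run$tfos, -"g_blocks"), "tfo.tsv")
  w(run$tts, "tts.tsv")
  write_bed(run$tts, file.path(out_dir, "tts.bed"), name_col = "tts_id")
  w(select(run$matches, -dplyr::any_of("g_blocks")), "matches.tsv")
  w(mutate(run$sites, tfo_ids = purrr::map_chr(.data$tfo_ids, paste, collapse = ",")),
    "sites.tsv")
  loc <- purrr::imap_dfr(run$localization, ~ mutate(.x, table = .y, .before = 1))
  w(loc, "localization.tsv")
  w(run$bins, "bins.tsv")
  w(run$baseline, "baseline.tsv")
  w(run$gene_summary, "gene_summary.tsv")
  writeLines(run$selected_genes, file.path(out_dir, "selected_genes.txt"))
  writeLines(run$selected_transcripts, file.path(out_dir, "selected_transcripts.txt"))
  w(run$accessibility, "accessibility.tsv")
  if (!is.null(run$enrichment)) w(run$enrichment, "enrichment.tsv")
  if (!is.null(run$network)) {
    w(run$network$pruned$edges, "network_edges.tsv")
    w(mutate(run$network$modules,
             genes = purrr::map_chr(.data$genes, paste, collapse = ",")),
      "modules.tsv")
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.triplex_run <- function(x, ...) {
  cat("<triplex_run>\n")
  cnt <- x$manifest$counts
  cat(sprintf("  TFOs: %d   TTSs: %d\n", cnt$tfos, cnt$tts))
  cat(sprintf("  matches: %d raw -> %d after self-match removal -> %d merged sites\n",
              cnt$matches_raw, cnt$matches, cnt$sites))
  cat(sprintf("  baseline: %.3f matches / kb; selected %d genes, %d transcripts\n",
              x$baseline$baseline, cnt$selected_genes, cnt$selected_transcripts))
  invisible(x)
}

#' Tidy per-stage record counts of a pipeline run
#'
#' @param x A `triplex_run`.
#' @param ... Unused.
#' @return Tibble with columns `stage`, `n`.
#' @export
tidy.triplex_run <- function(x, ...) {
  tibble(stage = names(x$manifest$counts),
         n = as.integer(unlist(x$manifest$counts)))
}

#' One-row summary of a pipeline run
#'
#' @param x A `triplex_run`.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities.
#' @export
glance.triplex_run <- function(x, ...) {
  cnt <- x$manifest$counts
  tibble(
    n_tfos = cnt$tfos, n_tts = cnt$tts,
    n_matches_raw = cnt$matches_raw, n_matches = cnt$matches,
    n_dropped_tfos = cnt$dropped_tfos, n_sites = cnt$sites,
    baseline_per_kb = x$baseline$baseline,
    n_selected_genes = cnt$selected_genes,
    n_selected_transcripts = cnt$selected_transcripts
  )
}
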