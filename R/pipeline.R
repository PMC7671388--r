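#' Pipeline configuration
#'
#' Defaults follow the method's standard settings: pattern length 110 with
#' weight 10 (so 100 don't-care positions) and a cap of one million
#' sampled P-blocks.
#'
#' @param pattern_length pattern length `l` (default 110).
#' @param weight number of match positions `w` (default 10).
#' @param max_blocks cap `M` on sampled P-blocks (default 1e6).
#' @param seed RNG seed governing pattern generation, block sampling and
#'   the supertree heuristic; identical seeds give identical trees.
#' @param columns `"all"` or `"dontcare"` columns for the quartet
#'   likelihood.
#' @param tie_tol inconclusiveness tolerance on the top-two
#'   log-likelihood gap (default 1e-3).
#' @param params_policy `"fixed"` or `"gtr"` (see [best_topology()]).
#' @param pattern optional explicit [spaced_pattern()] overriding
#'   generation.
#' @param max_probes,restarts tuning knobs passed to [sample_pblocks()]
#'   and [find_cut()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(pattern_length = 110L, weight = 10L,
                       max_blocks = 1e6, seed = NULL,
                       columns = c("all", "dontcare"), tie_tol = 1e-3,
                       params_policy = c("fixed", "gtr"),
                       pattern = NULL, max_probes = 50L, restarts = 50L) {
  columns <- match.arg(columns)
  params_policy <- match.arg(params_policy)
  stopifnot(pattern_length >= 1L, weight >= 1L, weight <= pattern_length,
            max_blocks >= 0)
  structure(list(
    pattern_length = as.integer(pattern_length), weight = as.integer(weight),
    max_blocks = max_blocks, seed = seed, columns = columns,
    tie_tol = tie_tol, params_policy = params_policy, pattern = pattern,
    max_probes = as.integer(max_probes), restarts = as.integer(restarts)
  ), class = "run_config")
}

#' Run the full phylogeny pipeline
#'
#' FASTA in, Newick out: generate (or take) a spaced pattern, enumerate
#' spaced-word occurrences on both strands, sample homologous quartet
#' P-blocks, infer each block's maximum-likelihood topology, and
#' amalgamate the conclusive quartets into an unrooted supertree.
#'
#' @param inputs sequences as accepted by [enumerate_occurrences()]: a
#'   named list of DNA strings / `DNAStringSet`s, or a named character
#'   vector of FASTA paths (one file per taxon).
#' @param config a [run_config()].
#' @param quiet suppress progress messages (default `TRUE`).
#' @param keep_blocks also return the sampled `pblock`s (for dumping with
#'   [write_pblocks_tsv()]; default `FALSE`).
#' @return a list of class `spaq_run`: `tree` (`ape::phylo`), `newick`,
#'   and `report` (pattern, seed, occurrence/block/conclusive counts,
#'   excluded taxa, per-quartet tallies); `blocks` if `keep_blocks`.
#' @export
run_pipeline <- function(inputs, config = run_config(), quiet = TRUE,
                         keep_blocks = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  sequences <- as_taxon_sequences(inputs)
  if (length(sequences) < 4L)
    stop("usage error: at least 4 taxa are required")
  seed <- config$seed

  pattern <- config$pattern %||%
    generate_pattern(config$pattern_length, config$weight, seed = seed)
  say("pattern (l=%d, w=%d): %s", pattern$length, pattern$weight,
      format(pattern))

  index <- enumerate_occurrences(sequences, pattern)
  say("%d spaced-word occurrences in %d buckets", nrow(index$occ),
      length(index$bucket_start))
  occ_per_taxon <- tabulate(index$occ$taxon, nbins = length(index$taxa))
  excluded <- index$taxa[occ_per_taxon == 0L]
  if (length(excluded))
    warning("taxa with zero occurrences (excluded): ",
            paste(excluded, collapse = ", "))

  if (config$max_blocks == 0)
    stop("max_blocks = 0: no quartets to amalgamate")
  blocks <- sample_pblocks(index, max_blocks = config$max_blocks,
                           seed = if (!is.null(seed)) seed + 1L,
                           max_probes = config$max_probes)
  say("%d homologous P-blocks sampled", length(blocks))
  if (length(blocks) == 0L)
    stop("no homologous P-blocks found; cannot build a tree")

  results <- lapply(blocks, best_topology,
                    params_policy = config$params_policy,
                    tie_tol = config$tie_tol, columns = config$columns)
  concl <- !vapply(results, `[[`, logical(1), "inconclusive")
  say("%d conclusive / %d inconclusive quartet topologies",
      sum(concl), sum(!concl))
  if (!any(concl))
    stop("all sampled P-blocks were inconclusive; cannot build a tree")

  taxa_used <- setdiff(index$taxa, excluded)
  voted <- majority_quartets(results[concl])
  say("%d distinct quartet subsets after majority vote", nrow(voted))
  tree <- build_supertree(voted, taxa = taxa_used,
                          seed = if (!is.null(seed)) seed + 2L,
                          restarts = config$restarts)
  structure(list(
    tree = tree,
    newick = write_newick(tree),
    blocks = if (keep_blocks) blocks,
    report = list(
      pattern = format(pattern), seed = seed,
      n_taxa = length(taxa_used), excluded_taxa = excluded,
      n_occurrences = nrow(index$occ),
      n_blocks = length(blocks),
      n_conclusive = sum(concl),
      n_inconclusive = sum(!concl)
    )
  ), class = "spaq_run")
}

#' @export
print.spaq_run <- function(x, ...) {
  r <- x$report
  cat("<spaq_run>\n")
  cat(sprintf("  pattern: %s\n", r$pattern))
  cat(sprintf("  occurrences: %d; P-blocks: %d (%d conclusive, %d inconclusive)\n",
              r$n_occurrences, r$n_blocks, r$n_conclusive, r$n_inconclusive))
  cat(sprintf("  tree: %s\n", x$newick))
  invisible(x)
}
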