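#' Simulation configuration
#'
#' @param n_taxa number of taxa (>= 4 for a pipeline run).
#' @param sequence_length root sequence length in nucleotides.
#' @param model `"JC"` (equal frequencies, equal exchangeabilities) or
#'   `"GTR"` with explicit `params`.
#' @param params a [gtr_params()] used when `model = "GTR"`; for `"JC"`
#'   it is built automatically. Its `gamma_shape` (if finite) draws
#'   i.i.d. per-site rates from Gamma(alpha, alpha).
#' @param indel_rate expected indel events per site per unit branch length
#'   (0 disables indels; default 0).
#' @param indel_mean mean indel length (geometric; default 3).
#' @param seed RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 8L, sequence_length = 100000L,
                       model = c("JC", "GTR"), params = NULL,
                       indel_rate = 0, indel_mean = 3, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_taxa >= 4L, sequence_length >= 1L, indel_rate >= 0,
            indel_mean >= 1)
  if (is.null(params))
    params <- gtr_params()            # JC: all exchangeabilities 1, pi = 1/4
  else stopifnot(inherits(params, "gtr_params"))
  structure(list(
    n_taxa = as.integer(n_taxa),
    sequence_length = as.integer(sequence_length),
    model = model, params = params,
    indel_rate = indel_rate, indel_mean = indel_mean, seed = seed
  ), class = "sim_config")
}

#' Random unrooted binary tree
#'
#' Builds a topology by sequential random joins: starting from the
#' three-taxon star, each further leaf is attached to a uniformly chosen
#' existing edge. Branch lengths are drawn i.i.d. from
#' `branch_length_law`.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seed RNG seed (same seed, identical tree).
#' @param branch_length_law function `n -> n lengths`; default
#'   `Uniform(0.01, 0.03)`, giving average leaf-to-leaf distances around
#'   0.1 substitutions/site for 8-16 taxa — the divergence regime of
#'   closely related mammalian genomes.
#' @param tip_labels optional labels (default `t1..tn`).
#' @return an unrooted `ape::phylo` with branch lengths.
#' @export
random_tree <- function(n_taxa, seed = NULL,
                        branch_length_law = function(n) runif(n, 0.01, 0.03),
                        tip_labels = paste0("t", seq_len(n_taxa))) {
  n_taxa <- as.integer(n_taxa)
  stopifnot(n_taxa >= 3L, length(tip_labels) == n_taxa)
  with_seed(seed, {
    # edge list on node ids: leaves 1..n, internals n+1, n+2, ...
    n <- n_taxa
    root <- n + 1L
    edges <- rbind(c(root, 1L), c(root, 2L), c(root, 3L))
    next_node <- n + 2L
    for (leaf in seq_len(n)[-(1:3)]) {
      e <- sample.int(nrow(edges), 1L)
      mid <- next_node
      next_node <- next_node + 1L
      a <- edges[e, 1]; b <- edges[e, 2]
      edges <- rbind(edges[-e, , drop = FALSE],
                     c(a, mid), c(mid, b), c(mid, leaf))
    }
    tr <- list(edge = edges, Nnode = next_node - n - 1L,
               tip.label = tip_labels,
               edge.length = branch_length_law(nrow(edges)))
    class(tr) <- "phylo"
    attr(tr, "order") <- NULL
    ape::collapse.singles(tr)     # also normalizes internal node numbering
  })
}

#' Evolve sequences along a tree
#'
#' Draws a root sequence from the model's stationary base frequencies and
#' evolves it along every branch with transition probabilities
#' `P(t) = exp(Qt)` under the configured substitution model (branch
#' lengths are expected substitutions per site). Optional indels are
#' applied per branch as point events with geometric lengths; gene-level
#' events (duplication, loss, transfer) are not modeled.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param config a [sim_config()]; its `n_taxa` is ignored in favor of the
#'   tree's leaves.
#' @return a named character vector of DNA sequences, one per leaf.
#' @export
evolve <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            inherits(config, "sim_config"))
  params <- config$params
  eig <- gtr_eigen(params$exchangeabilities, params$base_freqs)
  pi <- eig$pi
  L <- config$sequence_length

  with_seed(config$seed, {
    site_rates <- if (is.finite(params$gamma_shape))
      stats::rgamma(L, shape = params$gamma_shape, rate = params$gamma_shape)
    else rep(1, L)

    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    rates <- vector("list", ntip + tree$Nnode)   # per-site rates follow indels
    seqs[[root]] <- sample.int(4L, L, replace = TRUE, prob = pi) - 1L
    rates[[root]] <- site_rates

    # parent-before-child traversal
    eidx <- preorder_edge_index(tree)
    edge <- tree$edge[eidx, , drop = FALSE]
    for (r in seq_len(nrow(edge))) {
      p <- edge[r, 1]; ch <- edge[r, 2]
      t <- tree$edge.length[eidx[r]]
      out <- evolve_branch(seqs[[p]], rates[[p]], t, eig, pi, config)
      seqs[[ch]] <- out$seq
      rates[[ch]] <- out$rates
    }
    res <- vapply(seq_len(ntip), function(i) decode_dna(seqs[[i]]),
                  character(1))
    names(res) <- tree$tip.label
    res
  })
}

# edges in an order where every parent precedes its children
preorder_edges <- function(tree) {
  idx <- preorder_edge_index(tree)
  tree$edge[idx, , drop = FALSE]
}

preorder_edge_index <- function(tree) {
  rev(ape::postorder(tree))
}

evolve_branch <- function(codes, site_rates, t, eig, pi, config) {
  # substitutions: category-free, per-site rate multiplies the branch length
  out <- codes
  ur <- unique(site_rates)
  if (length(ur) == 1L) {
    P <- trans_prob_matrix(eig, t * ur)
    for (s in 1:4) {
      idx <- which(codes == s - 1L)
      if (length(idx))
        out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                               prob = P[s, ]) - 1L
    }
  } else {
    # continuous per-site rates: group into quantile bins for speed
    bins <- cut(site_rates, breaks = unique(stats::quantile(
      site_rates, probs = seq(0, 1, length.out = 33L))), include.lowest = TRUE)
    for (b in levels(bins)) {
      sel <- which(bins == b)
      if (!length(sel)) next
      P <- trans_prob_matrix(eig, t * mean(site_rates[sel]))
      sub <- codes[sel]
      new <- sub
      for (s in 1:4) {
        idx <- which(sub == s - 1L)
        if (length(idx))
          new[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                 prob = P[s, ]) - 1L
      }
      out[sel] <- new
    }
  }
  rates <- site_rates
  # indels: Poisson number of events, geometric lengths
  if (config$indel_rate > 0) {
    n_events <- rpois(1L, config$indel_rate * t * length(out))
    for (e in seq_len(n_events)) {
      len <- rgeom(1L, prob = 1 / config$indel_mean) + 1L
      if (runif(1) < 0.5) {        # insertion
        at <- sample.int(length(out) + 1L, 1L) - 1L
        ins <- sample.int(4L, len, replace = TRUE, prob = pi) - 1L
        out <- append(out, ins, after = at)
        rates <- append(rates, rep(1, len), after = at)
      } else {                     # deletion
        if (length(out) <= len) next
        at <- sample.int(length(out) - len + 1L, 1L)
        keep <- -(at:(at + len - 1L))
        out <- out[keep]
        rates <- rates[keep]
      }
    }
  }
  list(seq = out, rates = rates)
}

trans_prob_matrix <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Write simulated sequences to FASTA
#'
#' One file per taxon, named `<taxon>.fasta`, under `dir`.
#'
#' @param seqs named character vector (from [evolve()]).
#' @param dir output directory (created if absent).
#' @return named vector of file paths (names = taxa).
#' @export
write_fasta <- function(seqs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(file.path(dir, paste0(names(seqs), ".fasta")),
                    names(seqs))
  for (i in seq_along(seqs)) {
    ss <- Biostrings::DNAStringSet(seqs[i])
    names(ss) <- names(seqs)[i]
    Biostrings::writeXStringSet(ss, paths[i])
  }
  paths
}
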