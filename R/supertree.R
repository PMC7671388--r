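#' Quartet multigraph over a taxon set
#'
#' Each embedded quartet topology `ab|cd` contributes six edges on the
#' nodes of the current taxon set: "good" edges (to be kept together) on
#' the sibling pairs `(a,b)` and `(c,d)`, and "bad" edges (separable) on
#' the four cross pairs. Only quartets with all four taxa inside `taxa`
#' are embedded.
#'
#' @param quartets conclusive quartet topologies: a data.frame/matrix with
#'   four columns (taxa; columns 1,2 are siblings, as are 3,4), or a list
#'   of `quartet_result`s (inconclusive entries are dropped).
#' @param taxa character vector, the current set `A`.
#' @param partial also embed quartets only partially inside `taxa`
#'   (default `FALSE`): a quartet `ab|cd` with three taxa `a,b,c` in `A`
#'   contributes the induced triplet constraint (good `(a,b)`, bad
#'   `(a,c)`, `(b,c)`); with two taxa in `A` it contributes one good edge
#'   if they are siblings, one bad edge otherwise. The supertree
#'   recursion uses this so that quartets spanning an earlier cut still
#'   inform deeper levels.
#' @return an object of class `quartet_graph` with symmetric `good` and
#'   `bad` weight matrices.
#' @export
build_graph <- function(quartets, taxa, partial = FALSE) {
  q <- as_quartet_table(quartets)
  n <- length(taxa)
  good <- matrix(0, n, n, dimnames = list(taxa, taxa))
  bad <- matrix(0, n, n, dimnames = list(taxa, taxa))
  add <- function(M, i, j) { M[i, j] <- M[i, j] + 1; M[j, i] <- M[i, j]; M }
  if (nrow(q)) {
    idx <- matrix(match(as.matrix(q), taxa), ncol = 4L)
    n_in <- rowSums(!is.na(idx))
    for (r in which(if (partial) n_in >= 2L else n_in == 4L)) {
      a <- idx[r, 1]; b <- idx[r, 2]; cc <- idx[r, 3]; d <- idx[r, 4]
      if (n_in[r] == 4L) {
        good <- add(good, a, b); good <- add(good, cc, d)
        bad <- add(bad, a, cc); bad <- add(bad, a, d)
        bad <- add(bad, b, cc); bad <- add(bad, b, d)
      } else if (n_in[r] == 3L) {
        # induced triplet: the intact sibling pair stays together, the
        # lone taxon from the other pair is separable from both
        if (is.na(a) || is.na(b)) {      # pair (c,d) intact
          lone <- if (is.na(a)) b else a
          good <- add(good, cc, d)
          bad <- add(bad, cc, lone); bad <- add(bad, d, lone)
        } else {                          # pair (a,b) intact
          lone <- if (is.na(cc)) d else cc
          good <- add(good, a, b)
          bad <- add(bad, a, lone); bad <- add(bad, b, lone)
        }
      } else {                            # exactly two inside
        inn <- which(!is.na(idx[r, ]))
        i <- idx[r, inn[1]]; j <- idx[r, inn[2]]
        if (identical(inn, c(1L, 2L)) || identical(inn, c(3L, 4L)))
          good <- add(good, i, j)
        else
          bad <- add(bad, i, j)
      }
    }
  }
  structure(list(taxa = taxa, good = good, bad = bad),
            class = "quartet_graph")
}

# normalize quartet input to a 4-column character table (cols 1,2 and 3,4
# are the sibling pairs)
as_quartet_table <- function(quartets) {
  if (inherits(quartets, "quartet_result")) quartets <- list(quartets)
  if (is.list(quartets) && !is.data.frame(quartets) &&
      (length(quartets) == 0L || inherits(quartets[[1]], "quartet_result"))) {
    rows <- lapply(quartets, function(q) {
      if (isTRUE(q$inconclusive)) NULL else q$split_taxa
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    q <- if (length(rows)) do.call(rbind, rows) else
      matrix(character(), 0, 4)
  } else {
    q <- as.matrix(quartets)
  }
  stopifnot(ncol(q) == 4L)
  mode(q) <- "character"
  as.data.frame(q, stringsAsFactors = FALSE)
}

#' Majority quartet topology per four-taxon subset
#'
#' Random block sampling can cover the same four taxa many times, and more
#' often for closely related taxa (which share more spaced words). Feeding
#' raw multiplicities into the cut heuristic biases its edge weights, so
#' the pipeline first reduces the conclusive topologies to one majority
#' topology per distinct four-taxon subset; subsets whose vote is tied are
#' dropped.
#'
#' @param quartets as in [build_graph()].
#' @return a 4-column character matrix (columns 1,2 and 3,4 are the
#'   sibling pairs), one row per decided subset.
#' @export
majority_quartets <- function(quartets) {
  q <- as_quartet_table(quartets)
  if (!nrow(q)) return(matrix(character(), 0, 4))
  qm <- as.matrix(q)
  sorted <- t(apply(qm, 1L, sort))
  subset_key <- apply(sorted, 1L, paste, collapse = "\r")
  # split id relative to the sorted subset: which of taxa 2..4 pairs with 1
  split_id <- vapply(seq_len(nrow(qm)), function(r) {
    pair <- if (sorted[r, 1] %in% qm[r, 1:2]) qm[r, 1:2] else qm[r, 3:4]
    partner <- setdiff(pair, sorted[r, 1])
    match(partner, sorted[r, 2:4])
  }, integer(1))
  rows <- lapply(split(seq_len(nrow(qm)), subset_key), function(i) {
    tb <- tabulate(split_id[i], nbins = 3L)
    if (sum(tb == max(tb)) > 1L) return(NULL)     # tied vote: drop
    s <- sorted[i[1], ]
    best <- which.max(tb)                          # s[1] pairs with s[best+1]
    others <- setdiff(2:4, best + 1L)
    c(s[1], s[best + 1L], s[others[1]], s[others[2]])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(matrix(character(), 0, 4))
  do.call(rbind, rows)
}

#' Minimum good/bad ratio cut of a quartet graph
#'
#' Searches for a nontrivial bipartition of the taxon set minimizing
#' `(good_cut + 1) / (bad_cut + 1)`, where `good_cut`/`bad_cut` are the
#' total good/bad edge weights crossing the cut (the +1 pseudo-count
#' regularizes the ratio when no bad edge is cut). Candidates are all
#' single-taxon splits plus `restarts` random bipartitions refined by
#' single-taxon moves accepted while the objective decreases.
#'
#' @param graph a [build_graph()] result.
#' @param seed RNG seed (deterministic result for fixed seed).
#' @param restarts number of random hill-climbing starts (default 50).
#' @return a list with `side1`, `side2` (taxon labels), `objective`,
#'   `good_cut`, `bad_cut`.
#' @export
find_cut <- function(graph, seed = NULL, restarts = 50L) {
  stopifnot(inherits(graph, "quartet_graph"))
  n <- length(graph$taxa)
  if (n < 2L) stop("contract violation: need at least 2 taxa to cut")
  good <- graph$good; bad <- graph$bad

  cut_weights <- function(side) {   # side: logical membership vector
    list(g = sum(good[side, !side]), b = sum(bad[side, !side]))
  }
  objective <- function(side) {
    w <- cut_weights(side)
    (w$g + 1) / (w$b + 1)
  }

  best_side <- NULL
  best_obj <- Inf
  consider <- function(side) {
    if (!any(side) || all(side)) return()
    o <- objective(side)
    if (o < best_obj) {
      best_obj <<- o
      best_side <<- side
    }
  }

  with_seed(seed, {
    for (i in seq_len(n)) {         # all single-taxon splits
      side <- rep(FALSE, n); side[i] <- TRUE
      consider(side)
    }
    if (n > 3L) {
      for (r in seq_len(restarts)) {
        side <- runif(n) < 0.5
        if (!any(side)) side[sample.int(n, 1L)] <- TRUE
        if (all(side)) side[sample.int(n, 1L)] <- FALSE
        cur <- objective(side)
        improved <- TRUE
        while (improved) {
          improved <- FALSE
          for (i in seq_len(n)) {
            cand <- side
            cand[i] <- !cand[i]
            if (!any(cand) || all(cand)) next
            o <- objective(cand)
            if (o < cur) {
              side <- cand; cur <- o; improved <- TRUE
            }
          }
        }
        consider(side)
      }
    }
  })
  w <- cut_weights(best_side)
  list(side1 = graph$taxa[best_side], side2 = graph$taxa[!best_side],
       objective = best_obj, good_cut = w$g, bad_cut = w$b)
}

#' Amalgamate quartet topologies into a supertree
#'
#' Recursive MaxCut-style partitioning: the current taxon set is split by
#' [find_cut()] on the multigraph of the quartets fully contained in it;
#' each side is partitioned recursively (quartets spanning a cut are
#' dropped below it). Sets of at most three taxa, and sets whose quartet
#' graph carries no information, become multifurcations. The result is an
#' unrooted topology-only tree (no branch lengths).
#'
#' @param quartets as in [build_graph()].
#' @param taxa the full taxon set (character). Defaults to the taxa
#'   appearing in `quartets`; taxa in `taxa` but in no quartet are
#'   attached at the root with a warning.
#' @param seed RNG seed for the cut heuristic.
#' @param restarts hill-climbing restarts per cut.
#' @return an unrooted `ape::phylo` tree.
#' @export
build_supertree <- function(quartets, taxa = NULL, seed = NULL,
                            restarts = 50L) {
  q <- as_quartet_table(quartets)
  qtaxa <- unique(unlist(q, use.names = FALSE))
  if (is.null(taxa)) taxa <- sort(qtaxa)
  taxa <- as.character(taxa)
  if (length(taxa) < 4L) stop("need at least 4 taxa for a supertree")
  orphan <- setdiff(taxa, qtaxa)
  if (length(orphan))
    warning("taxa in no quartet, attached at the root: ",
            paste(orphan, collapse = ", "))

  with_seed(seed, {
    core <- setdiff(taxa, orphan)
    nwk <- if (length(core) >= 2L) supertree_newick(q, core, restarts)
           else paste(vapply(core, quote_label, character(1)), collapse = ",")
    if (length(orphan))
      nwk <- paste0("(", nwk, ",",
                    paste(vapply(orphan, quote_label, character(1)),
                          collapse = ","), ")")
    tr <- ape::read.tree(text = paste0(nwk, ";"))
    ape::collapse.singles(if (ape::is.rooted(tr)) ape::unroot(tr) else tr)
  })
}

# recursive newick construction (labels are quoted to survive punctuation)
supertree_newick <- function(q, taxa, restarts) {
  if (length(taxa) == 1L) return(quote_label(taxa))
  if (length(taxa) == 2L)
    return(paste0("(", paste(vapply(taxa, quote_label, character(1)),
                             collapse = ","), ")"))
  # keep quartets with at least two taxa in the current set: spanning
  # quartets still contribute triplet/pair constraints (partial embedding)
  n_in <- (q[[1]] %in% taxa) + (q[[2]] %in% taxa) + (q[[3]] %in% taxa) +
    (q[[4]] %in% taxa)
  rel <- q[n_in >= 2L, , drop = FALSE]
  g <- build_graph(rel, taxa, partial = TRUE)
  if (sum(g$good) + sum(g$bad) == 0) {
    # no quartet information inside this set: multifurcation
    return(paste0("(", paste(vapply(taxa, quote_label, character(1)),
                             collapse = ","), ")"))
  }
  cut <- find_cut(g, seed = NULL, restarts = restarts)
  paste0("(", supertree_newick(rel, cut$side1, restarts), ",",
         supertree_newick(rel, cut$side2, restarts), ")")
}

quote_label <- function(x) {
  if (grepl("[^A-Za-z0-9_.|-]", x)) paste0("'", gsub("'", "''", x), "'") else x
}
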