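#' Sample homologous quartet P-blocks
#'
#' Repeatedly draws a random anchor occurrence from the remaining
#' occurrence list and probes other occurrences of the same spaced word
#' (same bucket) from other taxa, uniformly without replacement, until
#' three occurrences from three distinct other taxa each score positively
#' against the anchor — that quadruple is a homologous quartet P-block.
#' Accepted occurrences are removed, so no occurrence ever participates in
#' two blocks. Sampling stops when `max_blocks` blocks have been found,
#' when fewer than four occurrences remain, or when a long run of
#' consecutive anchors fails to produce a block (operationalizing "no
#' further P-blocks can be found").
#'
#' @param index an [enumerate_occurrences()] result.
#' @param matrix substitution matrix (default [default_matrix()]).
#' @param max_blocks cap `M` on the number of blocks (default 1e6).
#' @param seed RNG seed; a fixed seed makes the result fully deterministic.
#' @param max_probes failed probes allowed per anchor before it is
#'   abandoned (default 50).
#' @param stall_limit consecutive abandoned anchors that terminate the
#'   search; default `min(remaining occurrences, 1e5)`.
#' @return a list of `pblock` objects. Each has `taxa` (four distinct
#'   labels, row order of `alignment`), `alignment` (4 x l integer-coded
#'   matrix, rows ordered by sorted taxon label), `anchor` (row index of
#'   the anchor occurrence within `taxa`), `occurrences` (provenance
#'   data.frame with 1-based positions), `key`, and the `pattern` mask.
#' @export
sample_pblocks <- function(index, matrix = default_matrix(),
                           max_blocks = 1e6, seed = NULL, max_probes = 50L,
                           stall_limit = NULL) {
  stopifnot(inherits(index, "occurrence_index"), max_blocks >= 0)
  occ <- index$occ
  n <- nrow(occ)
  n_taxa <- length(index$taxa)
  if (n_taxa < 4L) {
    warning("fewer than 4 taxa in the occurrence index; no P-blocks")
    return(list())
  }
  if (max_blocks == 0 || n < 4L) return(list())

  l <- index$pattern$length
  mat16 <- as.vector(matrix)            # column-major 4x4 lookup
  taxon <- occ$taxon; record <- occ$record; strand <- occ$strand; pos <- occ$pos
  bucket_id <- index$bucket_id
  bstart <- index$bucket_start; bend <- index$bucket_end

  # buckets lacking 4 distinct taxa can never yield a block: skip cheaply
  bucket_ok <- vapply(seq_along(bstart), function(b) {
    rng <- bstart[b]:bend[b]
    length(rng) >= 4L && length(unique(taxon[rng])) >= 4L
  }, logical(1))

  window_codes <- function(i)
    index$seqs[[taxon[i]]][[record[i]]][[strand[i]]][(pos[i] + 1L):(pos[i] + l)]

  with_seed(seed, {
    alive <- rep(TRUE, n)
    n_alive <- n
    blocks <- vector("list", min(max_blocks, 4096))
    nb <- 0L
    stalled <- 0L
    limit <- function() {
      if (!is.null(stall_limit)) stall_limit else min(n_alive, 1e5)
    }

    while (nb < max_blocks && n_alive >= 4L && stalled < limit()) {
      # uniform over remaining occurrences via rejection (removals are rare)
      repeat {
        a <- sample.int(n, 1L)
        if (alive[a]) break
      }
      b <- bucket_id[a]
      if (!bucket_ok[b]) { stalled <- stalled + 1L; next }
      members <- bstart[b]:bend[b]
      cand <- members[alive[members] & taxon[members] != taxon[a] &
                        members != a]
      if (length(cand) < 3L) { stalled <- stalled + 1L; next }
      cand <- cand[sample.int(length(cand))]   # uniform, without replacement
      wa <- window_codes(a)
      partners <- integer(0)
      ptax <- integer(0)
      fails <- 0L
      for (cnd in cand) {
        if (taxon[cnd] %in% ptax) next       # taxon already represented
        wb <- window_codes(cnd)
        if (sum(mat16[wa * 4L + wb + 1L]) > 0) {
          partners <- c(partners, cnd)
          ptax <- c(ptax, taxon[cnd])
          if (length(partners) == 3L) break
        } else {
          fails <- fails + 1L
          if (fails >= max_probes) break
        }
      }
      if (length(partners) == 3L) {
        rows <- c(a, partners)
        alive[rows] <- FALSE
        n_alive <- n_alive - 4L
        nb <- nb + 1L
        if (nb > length(blocks)) length(blocks) <- 2L * length(blocks)
        blocks[[nb]] <- make_pblock(index, rows, anchor_row = a)
        stalled <- 0L
      } else {
        stalled <- stalled + 1L
      }
    }
    length(blocks) <- nb
    blocks
  })
}

# assemble a pblock object from occurrence row ids; rows ordered by taxon label
make_pblock <- function(index, rows, anchor_row) {
  occ <- index$occ
  labs <- index$taxa[occ$taxon[rows]]
  ord <- order(labs)
  rows <- rows[ord]
  labs <- labs[ord]
  l <- index$pattern$length
  aln <- matrix(NA_integer_, 4L, l, dimnames = list(labs, NULL))
  for (k in 1:4) {
    i <- rows[k]
    codes <- index$seqs[[occ$taxon[i]]][[occ$record[i]]][[occ$strand[i]]]
    aln[k, ] <- codes[(occ$pos[i] + 1L):(occ$pos[i] + l)]
  }
  offs <- which(index$pattern$mask == 1L)
  structure(list(
    taxa = labs,
    alignment = aln,
    anchor = which(rows == anchor_row),
    key = decode_dna(aln[1L, offs]),
    pattern = index$pattern,
    occurrences = data.frame(
      taxon = labs,
      record = occ$record[rows],
      strand = c("forward", "reverse")[occ$strand[rows]],
      position = occ$pos[rows] + 1L
    )
  ), class = "pblock")
}

#' Build a P-block directly from a four-row alignment
#'
#' Mainly for testing and for feeding externally produced gap-free
#' micro-alignments into [best_topology()].
#'
#' @param alignment 4 x l character matrix (one nucleotide per cell), or a
#'   length-4 named character vector of equal-length DNA strings.
#' @param pattern optional [spaced_pattern()] (needed only for
#'   don't-care-column selection).
#' @return a `pblock`.
#' @export
as_pblock <- function(alignment, pattern = NULL) {
  if (is.character(alignment) && is.null(dim(alignment))) {
    stopifnot(length(alignment) == 4L, !is.null(names(alignment)))
    codes <- lapply(alignment, encode_dna)
    stopifnot(length(unique(lengths(codes))) == 1L)
    aln <- do.call(rbind, codes)
  } else {
    stopifnot(is.matrix(alignment), nrow(alignment) == 4L,
              !is.null(rownames(alignment)))
    aln <- t(apply(alignment, 1L, function(r)
      encode_dna(paste(r, collapse = ""))))
  }
  if (anyNA(aln)) stop("alignment must contain only A,C,G,T")
  ord <- order(rownames(aln))
  aln <- aln[ord, , drop = FALSE]
  structure(list(
    taxa = rownames(aln), alignment = aln, anchor = 1L,
    key = NA_character_, pattern = pattern,
    occurrences = NULL
  ), class = "pblock")
}

#' @export
print.pblock <- function(x, ...) {
  cat(sprintf("<pblock> %d columns, taxa: %s\n",
              ncol(x$alignment), paste(x$taxa, collapse = ", ")))
  for (k in 1:4)
    cat(sprintf("  %-12s %s\n", x$taxa[k], decode_dna(x$alignment[k, ])))
  invisible(x)
}

#' Verify a block's homology certificate
#'
#' Recomputes the three anchor-vs-other spaced-word match scores.
#'
#' @param block a `pblock`.
#' @param matrix substitution matrix.
#' @return the three scores (anchor row excluded), all `> 0` for a
#'   homologous block.
#' @export
anchor_scores <- function(block, matrix = default_matrix()) {
  wa <- block$alignment[block$anchor, ]
  others <- setdiff(1:4, block$anchor)
  vapply(others, function(k) {
    wb <- block$alignment[k, ]
    sum(matrix[cbind(wa + 1L, wb + 1L)])
  }, numeric(1))
}

#' Write sampled P-blocks as TSV
#'
#' One row per occurrence: block id, taxon, record, strand, 1-based
#' position, spaced-word key, full window.
#'
#' @param blocks list of `pblock`s from [sample_pblocks()].
#' @param file output path or connection.
#' @export
write_pblocks_tsv <- function(blocks, file) {
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (is.null(b$occurrences)) return(NULL)
    data.frame(block = i, b$occurrences, key = b$key,
               window = apply(b$alignment, 1L, decode_dna))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
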