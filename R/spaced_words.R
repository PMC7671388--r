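#' Default nucleotide substitution scores
#'
#' The symmetric 4x4 score table used to separate homologous from background
#' spaced-word matches. Diagonal (identity) entries are positive, all
#' mismatch entries negative, with transitions (A:G, C:T) penalized far less
#' than transversions; the values derive from empirical substitution
#' frequencies at evolutionary distances typical of congeneric genomes.
#'
#' @return a 4x4 symmetric integer matrix with dimnames `A,C,G,T`.
#' @examples
#' default_matrix()["A", "A"]  # 91
#' @export
default_matrix <- function() {
  m <- matrix(c(
     91, -114,  -31, -123,
   -114,  100, -125,  -31,
    -31, -125,  100, -114,
   -123,  -31, -114,   91), 4, 4, byrow = TRUE,
    dimnames = list(.BASES, .BASES))
  storage.mode(m) <- "integer"
  m
}

#' Enumerate spaced-word occurrences
#'
#' Slides the pattern over every record of every taxon (and, by default,
#' over the reverse complement of every record) and collects one occurrence
#' per window position whose full `l`-nucleotide window contains only
#' `A,C,G,T`. Occurrences are bucketed by their spaced word (the
#' nucleotides at the pattern's match positions) with buckets in
#' lexicographic key order.
#'
#' @param sequences a named list, one element per taxon; each element is a
#'   character vector of DNA strings (one per record/contig) or a
#'   `Biostrings::DNAStringSet`. Alternatively a named character vector of
#'   FASTA file paths (one file per taxon; multi-record files allowed).
#' @param pattern a [spaced_pattern()].
#' @param include_reverse also enumerate the reverse complement of each
#'   record (default `TRUE`).
#' @return an object of class `occurrence_index`: a list with
#'   `occ` (data.frame: `taxon`, `record`, `strand`, `pos` 0-based window
#'   start on the stored strand, `key` integer-encoded spaced word),
#'   `seqs` (encoded sequences for window retrieval), `pattern`, `taxa`,
#'   and bucket bookkeeping. Rows of `occ` are sorted by key, ties in
#'   (taxon, strand, position) order.
#' @export
enumerate_occurrences <- function(sequences, pattern, include_reverse = TRUE) {
  stopifnot(inherits(pattern, "spaced_pattern"))
  sequences <- as_taxon_sequences(sequences)
  taxa <- names(sequences)
  l <- pattern$length
  w <- pattern$weight
  if (w > 26L) stop("pattern weight > 26 not supported by the key encoding")
  offs <- which(pattern$mask == 1L)     # 1-based offsets of match positions
  pow <- 4^((w - 1L):0)                 # big-endian => numeric order == lexicographic

  seqs <- vector("list", length(taxa))
  names(seqs) <- taxa
  occ_t <- list(); occ_r <- list(); occ_s <- list(); occ_p <- list(); occ_k <- list()
  n_chunk <- 0L
  strands <- if (include_reverse) 1:2 else 1L

  for (ti in seq_along(taxa)) {
    recs <- sequences[[ti]]
    seqs[[ti]] <- vector("list", length(recs))
    for (ri in seq_along(recs)) {
      fwd <- encode_dna(recs[[ri]])
      if (anyNA(fwd))
        warning(sprintf(
          "taxon '%s' record %d: %d non-ACGT position(s); overlapping windows skipped",
          taxa[ti], ri, sum(is.na(fwd))))
      per_strand <- vector("list", 2L)
      per_strand[[1L]] <- fwd
      if (include_reverse) per_strand[[2L]] <- revcomp_codes(fwd)
      seqs[[ti]][[ri]] <- per_strand
      if (length(fwd) < l) next
      for (st in strands) {
        codes <- per_strand[[st]]
        n <- length(codes)
        npos <- n - l + 1L
        # window validity: no NA anywhere in [i, i+l-1]
        csna <- cumsum(is.na(codes))
        nbad <- csna[l:n] - c(0, csna)[1:npos]
        valid <- nbad == 0L
        if (!any(valid)) next
        key <- numeric(npos)
        for (k in seq_len(w))
          key <- key + c(codes, 0L)[offs[k]:(offs[k] + npos - 1L)] * pow[k]
        idx <- which(valid)
        n_chunk <- n_chunk + 1L
        occ_t[[n_chunk]] <- rep.int(ti, length(idx))
        occ_r[[n_chunk]] <- rep.int(ri, length(idx))
        occ_s[[n_chunk]] <- rep.int(st, length(idx))
        occ_p[[n_chunk]] <- idx - 1L
        occ_k[[n_chunk]] <- key[idx]
      }
    }
  }

  occ <- data.frame(
    taxon  = if (n_chunk) unlist(occ_t) else integer(),
    record = if (n_chunk) unlist(occ_r) else integer(),
    strand = if (n_chunk) unlist(occ_s) else integer(),
    pos    = if (n_chunk) unlist(occ_p) else integer(),
    key    = if (n_chunk) unlist(occ_k) else numeric()
  )
  # lexicographic bucket order; within a bucket keep (taxon, strand, pos)
  ord <- order(occ$key, occ$taxon, occ$strand, occ$pos, method = "radix")
  occ <- occ[ord, , drop = FALSE]
  rownames(occ) <- NULL

  # bucket bookkeeping: run starts over the sorted keys
  if (nrow(occ)) {
    new_bucket <- c(TRUE, occ$key[-1L] != occ$key[-nrow(occ)])
    bucket_id <- cumsum(new_bucket)
    starts <- which(new_bucket)
    ends <- c(starts[-1L] - 1L, nrow(occ))
  } else {
    bucket_id <- integer(); starts <- integer(); ends <- integer()
  }

  structure(list(
    occ = occ, bucket_id = bucket_id,
    bucket_start = starts, bucket_end = ends,
    seqs = seqs, pattern = pattern, taxa = taxa,
    include_reverse = include_reverse
  ), class = "occurrence_index")
}

#' @export
print.occurrence_index <- function(x, ...) {
  cat(sprintf(
    "<occurrence_index> %d occurrences, %d buckets, %d taxa, pattern %s\n",
    nrow(x$occ), length(x$bucket_start), length(x$taxa), format(x$pattern)))
  invisible(x)
}

# normalize the `sequences` argument to a named list of character vectors
as_taxon_sequences <- function(sequences) {
  if (is.character(sequences) && !is.null(names(sequences)) &&
      all(file.exists(sequences))) {
    sequences <- lapply(sequences, function(f) {
      ss <- Biostrings::readDNAStringSet(f)
      as.character(ss)
    })
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))) ||
      anyDuplicated(names(sequences)))
    stop("sequences must be a named list with unique nonempty taxon names")
  lapply(sequences, function(s) {
    if (inherits(s, "DNAStringSet")) s <- as.character(s)
    unname(as.character(s))
  })
}

# integer codes of the full l-window of occurrence row i (internal fast path)
occurrence_window_codes <- function(index, i) {
  o <- index$occ[i, ]
  codes <- index$seqs[[o$taxon]][[o$record]][[o$strand]]
  codes[(o$pos + 1L):(o$pos + index$pattern$length)]
}

#' Extract one occurrence as a record
#'
#' @param index an `occurrence_index`.
#' @param i row number in `index$occ`.
#' @return a list with `taxon` (label), `record`, `strand`
#'   (`"forward"`/`"reverse"`), `position` (1-based window start on the
#'   stored strand), `key` (spaced word at the match positions) and
#'   `window` (the full `l`-nucleotide window).
#' @export
get_occurrence <- function(index, i) {
  stopifnot(inherits(index, "occurrence_index"),
            i >= 1L, i <= nrow(index$occ))
  o <- index$occ[i, ]
  win <- occurrence_window_codes(index, i)
  offs <- which(index$pattern$mask == 1L)
  list(
    taxon = index$taxa[o$taxon],
    record = o$record,
    strand = c("forward", "reverse")[o$strand],
    position = o$pos + 1L,
    key = decode_dna(win[offs]),
    window = decode_dna(win)
  )
}

#' Score a spaced-word match
#'
#' Sums substitution-matrix entries over all `l` aligned window columns of
#' two occurrences of the same spaced word. Match positions contribute
#' diagonal entries by construction; don't-care positions may contribute
#' mismatch penalties.
#'
#' @param a,b occurrence records as returned by [get_occurrence()] (any
#'   list with a `key` and a `window` string works).
#' @param matrix substitution matrix, default [default_matrix()].
#' @return integer score.
#' @export
score_match <- function(a, b, matrix = default_matrix()) {
  if (!identical(a$key, b$key))
    stop("contract violation: occurrences are not of the same spaced word")
  wa <- encode_dna(a$window)
  wb <- encode_dna(b$window)
  stopifnot(length(wa) == length(wb), !anyNA(wa), !anyNA(wb))
  sum(matrix[cbind(wa + 1L, wb + 1L)])
}

#' Number of occurrences in an index
#' @param index an `occurrence_index`.
#' @return integer count.
#' @export
n_occurrences <- function(index) nrow(index$occ)
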